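# File formats: FASTA sequences and label companions, model +
# parameterization JSON, tidy TSV metric tables, run manifests.

#' Read sequences from a FASTA file
#'
#' Any single-character alphabet is a legal FASTA payload here, including
#' dice symbols '1'-'6'. When the model alphabet is alphabetic (DNA),
#' records are uppercased before validation.
#'
#' @param path FASTA file.
#' @param alphabet Optional character vector; when given, every symbol of
#'   every record is validated against it and the first offender is
#'   reported with record id and position.
#' @return Tibble with columns `id` and `sequence`, in file order.
#' @export
read_sequences <- function(path, alphabet = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no records in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (!is.null(alphabet)) {
    if (all(grepl("^[A-Za-z]$", alphabet))) seqs <- toupper(seqs)
    fake <- list(alphabet = alphabet)
    for (i in seq_along(seqs)) encode_symbols(fake, seqs[[i]], id = ids[[i]])
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Read a per-position label companion file
#'
#' A FASTA-like file whose records carry one label character per sequence
#' position, with ids matching the sequence file.
#'
#' @param path Label file.
#' @param sequences Optional tibble from [read_sequences()]; when given,
#'   labels are joined onto it by id with id- and length-mismatch checks,
#'   and the labeled dataset is returned.
#' @param label_codes Optional character vector of legal label characters.
#' @return Tibble `id`, `labels`, or the joined dataset when `sequences`
#'   is supplied.
#' @export
read_labels <- function(path, sequences = NULL, label_codes = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no records in '%s'", path))
  labs <- tibble(id = unname(sub("\\s.*$", "", names(set))),
                 labels = unname(as.character(set)))
  if (!is.null(label_codes)) {
    for (i in seq_len(nrow(labs))) {
      chars <- unique(strsplit(labs$labels[[i]], "", fixed = TRUE)[[1L]])
      bad <- setdiff(chars, label_codes)
      if (length(bad) > 0L) {
        stop(sprintf("record '%s': unknown label character '%s'",
                     labs$id[[i]], bad[[1L]]))
      }
    }
  }
  if (is.null(sequences)) return(labs)
  missing <- setdiff(sequences$id, labs$id)
  if (length(missing) > 0L) {
    stop("no labels for record(s): ", paste(missing, collapse = ", "))
  }
  out <- dplyr::left_join(sequences, labs, by = "id")
  for (i in seq_len(nrow(out))) {
    nl <- nchar(out$labels[[i]])
    ns <- nchar(out$sequence[[i]])
    if (nl != ns) {
      stop(sprintf("record '%s': %d labels for %d positions", out$id[[i]], nl, ns))
    }
  }
  out
}

#' Write a labeled dataset as FASTA plus companions
#'
#' Writes `<prefix>.fasta` (symbols), `<prefix>.labels.fasta` (one label
#' character per position) and `<prefix>.meta.json` (generation metadata).
#'
#' @param dataset Tibble from [generate_dataset()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, prefix) {
  fa <- paste0(prefix, ".fasta")
  lf <- paste0(prefix, ".labels.fasta")
  mf <- paste0(prefix, ".meta.json")
  seqs <- Biostrings::BStringSet(setNames(dataset$sequence, dataset$id))
  Biostrings::writeXStringSet(seqs, fa, width = 80L)
  if (!is.null(dataset$labels)) {
    labs <- Biostrings::BStringSet(setNames(dataset$labels, dataset$id))
    Biostrings::writeXStringSet(labs, lf, width = 80L)
  }
  meta <- attr(dataset, "metadata") %||% list()
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(fa, lf, mf))
}

#' Serialize a model and its parameterization to JSON
#'
#' One schema-versioned document holds the model structure, the label
#' codes, the tying scheme and the parameter values, so the file cannot
#' drift from the code that produced it.
#'
#' @param example An `hmm_example` (or list with `model`,
#'   `parameterization`, `true_values`, `positive_labels`, `name`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(example, path) {
  pz <- example$parameterization
  doc <- list(
    schema_version = 1L,
    name = example$name %||% "custom",
    states = pz$states,
    alphabet = pz$alphabet,
    state_labels = as.list(example$model$state_labels),
    positive_labels = example$positive_labels,
    params = lapply(seq_len(nrow(pz$params)), function(i) {
      list(param = pz$params$param[i], role = pz$params$role[i],
           block = pz$params$block[i], kind = pz$params$kind[i],
           value = unname(example$true_values[[pz$params$param[i]]]))
    }),
    blocks = lapply(seq_len(nrow(pz$blocks)), function(i) {
      list(block = pz$blocks$block[i], mass = pz$blocks$mass[i])
    }),
    entries = lapply(seq_len(nrow(pz$entries)), function(i) {
      list(kind = pz$entries$kind[i], state = pz$entries$state[i],
           target = pz$entries$target[i],
           factors = as.list(pz$entries$factors[[i]]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a model + parameterization JSON document
#'
#' @param path File written by [write_model_json()].
#' @return An `hmm_example`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if ((doc$schema_version %||% 0L) != 1L) {
    stop(sprintf("unsupported model schema version in '%s'", path))
  }
  params <- dplyr::bind_rows(lapply(doc$params, function(p) {
    tibble(param = p$param, role = p$role,
           block = if (is.null(p$block)) NA_character_ else p$block,
           kind = p$kind, value = p$value)
  }))
  blocks <- dplyr::bind_rows(lapply(doc$blocks, function(b) {
    tibble(block = b$block, mass = b$mass)
  }))
  entries <- dplyr::bind_rows(lapply(doc$entries, function(e) {
    tibble(kind = e$kind, state = e$state, target = e$target,
           factors = list(unlist(e$factors)))
  }))
  pz <- hmm_parameterization(entries, params, blocks,
                             unlist(doc$states), unlist(doc$alphabet))
  new_example(doc$name, pz, param_values(pz),
              state_labels = unlist(doc$state_labels),
              positive_labels = unlist(doc$positive_labels))
}

#' Write a tidy metric table as TSV
#'
#' Tab-separated, header row, `.` for missing values — the format used by
#' all metric outputs.
#'
#' @param x Data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_metrics_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

# Run manifest: enough to byte-reproduce a CLI run.
write_run_manifest <- function(path, command, args, seed = NULL, inputs = character()) {
  digests <- if (length(inputs) > 0L) as.list(tools::md5sum(inputs)) else list()
  doc <- list(
    command = command,
    args = as.list(args),
    seed = seed,
    package_version = as.character(utils::packageVersion("linhmm")),
    input_md5 = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
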