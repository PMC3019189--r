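# shortcuts to internal builders used when constructing test fixtures
entry_rows <- linhmm:::entry_rows
param_row <- linhmm:::param_row
zero_counts_test <- function(model) linhmm:::zero_counts(model)
with_seed_test <- function(seed, expr) linhmm:::with_seed(seed, expr)
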