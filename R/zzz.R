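# data.table is used through :: calls; importing one symbol keeps
# data.table's calling-namespace detection (cedta) happy.
#' @importFrom data.table data.table
#' @importFrom stats rnbinom runif rnorm
NULL

.datatable.aware <- TRUE
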