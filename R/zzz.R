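#' @useDynLib strainforge, .registration = TRUE
#' @importFrom jsonlite write_json
#' @importFrom ape as.phylo write.tree
NULL
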