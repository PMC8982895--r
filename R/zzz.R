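#' @keywords internal
#' @useDynLib smmlasso, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

utils::globalVariables(c("gamma", "beta1", "critical", "day", "value",
                         "mouse_id", "fitted"))
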