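#' @importFrom rlang .data %||%
#' @importFrom broom tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats median coef predict
NULL

#' @export
broom::tidy

#' @export
broom::glance

#' @export
ggplot2::autoplot

utils::globalVariables(c("prob", "allocation"))
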