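#' Tidy and summarise fitted result objects
#'
#' broom-style accessors for the package's result classes. `tidy()` returns
#' the per-element table of a result (signature genes, consensus labels,
#' Dunn contrasts, feature importances, RFE ranking); `glance()` returns a
#' one-row-per-unit summary (signature sizes and AUROCs, PAC per k, omnibus
#' test, classifier metrics).
#'
#' @param x a `signature_set`, `consensus_result`, `group_comparison`,
#'   `classifier_report` or `rfe_result`.
#' @param ... unused.
#' @return a tibble.
#' @name ipfsubsets-tidiers
NULL
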