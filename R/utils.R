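#' @importFrom stats median p.adjust pnorm pt phyper quantile rnbinom runif var
#' @importFrom utils read.delim write.table head combn
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a parent seed
#'
#' Each stochastic stage of the pipeline draws its own seed from the global
#' seed by a fixed arithmetic derivation, so stages are individually
#' reproducible and inserting a new stage does not shift the streams of the
#' others. Seeds stay below 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param stage character scalar naming the stage.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_input(fmt, ...)
  invisible(TRUE)
}
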