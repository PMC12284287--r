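`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# seed handling: all generator entry points take an optional rng_seed; when
# NULL they draw from the ambient RNG stream so cohort generation stays
# reproducible from a single seed.
with_seed <- function(rng_seed, expr) {
  if (!is.null(rng_seed)) {
    stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L)
    set.seed(as.integer(rng_seed))
  }
  expr
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) c(1, 0, 0) else v / n
}

#' Significance stars for p-values
#'
#' Returns the conventional significance marks: \code{****} for p < 0.0001,
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for p < 0.05,
#' \code{"ns"} otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
p_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}
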