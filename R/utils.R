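# Small numeric helpers shared across modules.

#' Coefficient of variation of an ensemble of predictions
#'
#' Sample standard deviation divided by the mean. Predicted importance values
#' are non-negative, so a zero mean with any non-zero entry is mapped to
#' `Inf` (maximal relative spread) and an all-zero vector to 0.
#'
#' @param x Numeric vector.
#' @return A single non-negative number, possibly `Inf`.
#' @keywords internal
cv_value <- function(x) {
  m <- mean(x)
  if (m > 0) return(stats::sd(x) / m)
  if (any(x != 0)) return(Inf)
  0
}

# Min-max rescaling to [0, 1]; a constant column maps to all ones so that a
# metric on which every species ties contributes its full weight.
minmax_unit <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(rep(1, length(x)))
  (x - rng[1]) / diff(rng)
}

# Dense ranks for importance scores: rank 1 = largest score, ties broken by
# predictor name so ranks are a deterministic permutation of 1..P.
rank_by_score <- function(scores) {
  stopifnot(!is.null(names(scores)))
  ord <- order(-scores, names(scores))
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  names(r) <- names(scores)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
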