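# Model-reliability evaluation: fuzzy kappa on IV class maps, true skill
# statistic, bagging stability metrics (Top5, CVdev), the weighted ModRel
# composite with reliability classes, species range codes, and the
# cross-species predictor importance index.

#' IV class scheme for map comparison
#'
#' Ordinal classes used to compare observed and predicted importance-value
#' maps. IVs are rounded to the nearest integer and binned; the default
#' eight bins are \{0\}, 1-3, 4-6, 7-10, 11-20, 21-30, 31-50, 51-100
#' (classes 0..7). The similarity function `s(d)` scores the agreement of
#' two classes at index distance `d`: `s(0) = 1` (exact match) and the
#' default `s(d) = 2^-d` awards geometrically decaying partial credit to
#' near-miss classes.
#'
#' @param lower,upper Integer bin bounds (inclusive) partitioning 0..100.
#' @param similarity Function of the non-negative class-index distance,
#'   with `similarity(0) == 1`, non-increasing.
#' @return An object of class `iv_class_scheme`.
#' @export
iv_class_scheme <- function(lower = c(0, 1, 4, 7, 11, 21, 31, 51),
                            upper = c(0, 3, 6, 10, 20, 30, 50, 100),
                            similarity = function(d) 2^(-d)) {
  stopifnot(length(lower) == length(upper), lower[1] == 0,
            upper[length(upper)] == 100, all(upper >= lower),
            all(lower[-1] == upper[-length(upper)] + 1),
            isTRUE(all.equal(similarity(0), 1)))
  structure(list(lower = lower, upper = upper, n_classes = length(lower),
                 similarity = similarity),
            class = "iv_class_scheme")
}

#' Map importance values to ordinal classes
#'
#' @param iv Numeric IVs in `[0, 100]`.
#' @param scheme An [iv_class_scheme()].
#' @return Integer class indices starting at 0.
#' @examples
#' iv_to_class(c(0, 2, 25))  # 0 1 5
#' @export
iv_to_class <- function(iv, scheme = iv_class_scheme()) {
  if (anyNA(iv) || any(!is.finite(iv)) || any(iv < -1e-9 | iv > 100 + 1e-9)) {
    stop("iv values must lie in [0, 100]")
  }
  findInterval(round(pmin(pmax(iv, 0), 100)), scheme$lower) - 1L
}

similarity_matrix <- function(scheme) {
  k <- scheme$n_classes
  outer(seq_len(k) - 1, seq_len(k) - 1,
        function(i, j) scheme$similarity(abs(i - j)))
}

#' Fuzzy kappa between two categorical maps
#'
#' Cell-by-cell chance-corrected agreement between an observed and a
#' predicted class map in which near-miss classes receive partial credit
#' through the scheme's similarity function. Observed agreement is
#' `P_o = mean(s(obs_i, pred_i))`; expected agreement is
#' `P_e = sum_ij p_i q_j s(i, j)` with `p`, `q` the observed/predicted
#' marginal class frequencies; `FK = (P_o - P_e) / (1 - P_e)`. A perfect
#' match gives 1; with the identity similarity (`s = 1` iff `i = j`) FK
#' reduces to Cohen's kappa.
#'
#' @param observed,predicted Integer class vectors (0-based, as from
#'   [iv_to_class()]) over the same cells; if both are named they are
#'   aligned by name.
#' @param scheme An [iv_class_scheme()].
#' @return A number `<= 1`.
#' @export
fuzzy_kappa <- function(observed, predicted, scheme = iv_class_scheme()) {
  if (length(observed) == 0) stop("empty map")
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must cover the same cells")
  }
  if (!is.null(names(observed)) && !is.null(names(predicted))) {
    if (!setequal(names(observed), names(predicted))) {
      stop("observed and predicted must cover the same cells")
    }
    predicted <- predicted[names(observed)]
  }
  k <- scheme$n_classes
  if (any(observed < 0 | observed >= k | predicted < 0 | predicted >= k)) {
    stop("class indices outside the scheme")
  }
  s <- similarity_matrix(scheme)
  n <- length(observed)
  po <- mean(s[cbind(observed + 1, predicted + 1)])
  p <- tabulate(observed + 1, k) / n
  q <- tabulate(predicted + 1, k) / n
  pe <- as.numeric(t(p) %*% s %*% q)
  if (1 - pe < 1e-12) return(1)  # both maps concentrated on one class
  (po - pe) / (1 - pe)
}

#' Fuzzy kappa between two IV maps
#'
#' Classifies both IV vectors with the scheme, then calls [fuzzy_kappa()].
#'
#' @param observed_iv,predicted_iv Numeric IVs over the same cells.
#' @inheritParams fuzzy_kappa
#' @export
fuzzy_kappa_iv <- function(observed_iv, predicted_iv,
                           scheme = iv_class_scheme()) {
  fuzzy_kappa(iv_to_class(observed_iv, scheme),
              iv_to_class(predicted_iv, scheme), scheme)
}

#' True skill statistic on presence/absence
#'
#' `TSS = sensitivity + specificity - 1` from the 2x2 confusion table, with
#' IV > 0 read as presence. Computed only over cells with observed data; if
#' the observations are all one class the statistic is undefined and `NA`
#' is returned with a warning.
#'
#' @param observed,predicted Logical presence vectors over the same cells.
#' @return A number in `[-1, 1]`, or `NA`.
#' @export
tss <- function(observed, predicted) {
  if (length(observed) == 0) stop("empty map")
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must cover the same cells")
  }
  observed <- as.logical(observed); predicted <- as.logical(predicted)
  if (all(observed) || !any(observed)) {
    warning("observations are all one class; TSS undefined")
    return(NA_real_)
  }
  sens <- sum(observed & predicted) / sum(observed)
  spec <- sum(!observed & !predicted) / sum(!observed)
  sens + spec - 1
}

#' Top-five predictor stability across a bagging ensemble
#'
#' For each bagging tree, award `6 - r` points at every rank `r` (1..5)
#' where the tree's rank-`r` predictor equals the reference's rank-`r`
#' predictor, divide by the perfect-match sum of 15 (five points for the
#' first variable down to one for the fifth), and average over the trees.
#' All five matching in order scores 1; no matches scores 0. With a
#' reference of fewer than five variables the denominator stays 15. The
#' `"anywhere"` variant credits a reference variable found anywhere in a
#' tree's top five rather than only at the same rank.
#'
#' @param reference Character vector, the reference (RF) predictor ranking,
#'   up to five used.
#' @param ensemble A `bagging_ensemble`.
#' @param match `"same_rank"` (default) or `"anywhere"`.
#' @return A number in `[0, 1]`.
#' @export
top5_stability <- function(reference, ensemble,
                           match = c("same_rank", "anywhere")) {
  match <- match.arg(match)
  stopifnot(inherits(ensemble, "bagging_ensemble"), length(reference) >= 1)
  ref <- utils::head(as.character(reference), 5)
  scores <- vapply(ensemble$top5, function(t5) {
    pts <- 0
    for (r in seq_along(ref)) {
      hit <- if (match == "same_rank") {
        r <= length(t5) && t5[r] == ref[r]
      } else {
        ref[r] %in% t5
      }
      if (hit) pts <- pts + (6 - r)
    }
    pts / 15
  }, numeric(1))
  mean(scores)
}

#' Deviance stability (CVdev) across a bagging ensemble
#'
#' Per tree, form the weighted sum of the deviance-explained shares of the
#' reference's top-five predictors, with inverse-rank weights
#' `(5, 4, 3, 2, 1) / 15` mirroring the Top5 point scheme; compute the
#' coefficient of variation of these sums across the trees, clip it to
#' `[0, 1]`, and subtract from one. Identical profiles give 1 (most
#' stable); a zero mean gives 0 (maximally unstable).
#'
#' @inheritParams top5_stability
#' @return A number in `[0, 1]`.
#' @export
cv_deviance_stability <- function(ensemble, reference) {
  stopifnot(inherits(ensemble, "bagging_ensemble"), length(reference) >= 1)
  ref <- utils::head(as.character(reference), 5)
  wts <- (6 - seq_along(ref)) / 15
  tot <- rowSums(ensemble$profiles)
  shares <- ensemble$profiles / ifelse(tot > 0, tot, 1)
  idx <- match(ref, ensemble$predictors)
  refshare <- matrix(0, nrow(shares), length(ref))
  refshare[, !is.na(idx)] <- shares[, idx[!is.na(idx)], drop = FALSE]
  w <- as.numeric(refshare %*% wts)
  m <- mean(w)
  if (m == 0) return(0)
  cvw <- stats::sd(w) / m
  1 - min(max(cvw, 0), 1)
}

#' Weighted ModRel composite from normalized components
#'
#' `ModRel = 0.33 nR2 + 0.33 nFK + 0.11 nTSS + 0.11 nCVdev + 0.11 nTop5`
#' by default, so a species maxing every normalized component scores 0.99.
#'
#' @param r2,fk,tss,cvdev,top5 Normalized (0-1) component vectors.
#' @param weights Numeric length-5 weights in that order.
#' @return Numeric ModRel scores.
#' @export
modrel_combine <- function(r2, fk, tss, cvdev, top5,
                           weights = c(0.33, 0.33, 0.11, 0.11, 0.11)) {
  stopifnot(length(weights) == 5)
  weights[1] * r2 + weights[2] * fk + weights[3] * tss +
    weights[4] * cvdev + weights[5] * top5
}

#' Model-reliability scores and classes across species
#'
#' Each raw component is min-max normalized to `[0, 1]` across the supplied
#' species set (a constant column maps to all ones; a missing component is
#' treated as the worst observed value and normalizes to 0), then combined
#' with [modrel_combine()]. Classes use half-open thresholds: high
#' (ModRel >= 0.70), medium ([0.55, 0.70)), low ([0.14, 0.55)), unreliable
#' (< 0.14). A species is withdrawn if its raw RF pseudo-R^2 is negative or
#' its ModRel falls below 0.14.
#'
#' @param components Data frame with columns `species`, `rf_r2`, `fk`,
#'   `tss`, `cvdev`, `top5` (raw component values).
#' @param weights Passed to [modrel_combine()].
#' @param thresholds Named vector `c(high, medium, low)` of lower class
#'   bounds.
#' @return Data frame `species`, normalized components (`n_rf_r2`, ...),
#'   `modrel`, `reliability_class`, `withdrawn`.
#' @export
model_reliability <- function(components,
                              weights = c(0.33, 0.33, 0.11, 0.11, 0.11),
                              thresholds = c(high = 0.70, medium = 0.55,
                                             low = 0.14)) {
  need <- c("species", "rf_r2", "fk", "tss", "cvdev", "top5")
  stopifnot(all(need %in% names(components)), nrow(components) >= 1)
  norm_col <- function(x) {
    if (all(is.na(x))) return(rep(0, length(x)))
    x[is.na(x)] <- min(x, na.rm = TRUE)
    minmax_unit(x)
  }
  n_r2 <- norm_col(components$rf_r2)
  n_fk <- norm_col(components$fk)
  n_tss <- norm_col(components$tss)
  n_cvdev <- norm_col(components$cvdev)
  n_top5 <- norm_col(components$top5)
  modrel <- modrel_combine(n_r2, n_fk, n_tss, n_cvdev, n_top5, weights)
  cls <- ifelse(modrel >= thresholds["high"], "high",
         ifelse(modrel >= thresholds["medium"], "medium",
         ifelse(modrel >= thresholds["low"], "low", "unreliable")))
  withdrawn <- components$rf_r2 < 0 | modrel < thresholds["low"]
  data.frame(species = components$species,
             n_rf_r2 = n_r2, n_fk = n_fk, n_tss = n_tss,
             n_cvdev = n_cvdev, n_top5 = n_top5,
             modrel = modrel, reliability_class = cls,
             withdrawn = withdrawn, stringsAsFactors = FALSE)
}

#' Species range, detection and abundance codes
#'
#' Three-letter code: breadth `N`(arrow) if the occupied area fraction is
#' below `area_threshold` (default 10% of the study area), else `W`(ide);
#' density `D`(ense) if at least `density_threshold` (default 40%) of the
#' inventory plots within occupied cells report the species, else
#' `S`(parse); abundance `H`(igh) if the mean IV where the species occurs
#' is at least `iv_threshold` (default 6.0), else `L`(ow). An `"X"` is
#' appended for species withdrawn from modeling.
#'
#' @param occupied_area_fraction Fraction of study area in cells with
#'   observed IV > 0 (true cell areas: fine 100 km^2, coarse 400 km^2).
#' @param presence_plot_fraction Fraction of plots in occupied cells that
#'   report the species.
#' @param mean_presence_iv Mean plot IV where the species is present.
#' @param withdrawn Logical.
#' @param area_threshold,density_threshold,iv_threshold Class cutoffs.
#' @return Character vector of codes, e.g. `"WDH"`, `"NSLX"`.
#' @export
classify_range <- function(occupied_area_fraction, presence_plot_fraction,
                           mean_presence_iv, withdrawn = FALSE,
                           area_threshold = 0.10, density_threshold = 0.40,
                           iv_threshold = 6.0) {
  stopifnot(all(occupied_area_fraction >= 0 & occupied_area_fraction <= 1),
            all(presence_plot_fraction >= 0 & presence_plot_fraction <= 1),
            all(mean_presence_iv >= 0))
  paste0(ifelse(occupied_area_fraction < area_threshold, "N", "W"),
         ifelse(presence_plot_fraction >= density_threshold, "D", "S"),
         ifelse(mean_presence_iv >= iv_threshold, "H", "L"),
         ifelse(rep_len(withdrawn, length(occupied_area_fraction)), "X", ""))
}

#' Cross-species predictor importance index
#'
#' Summarizes predictor importance across all modeled species with three
#' scores: the sum of importance scores (SumVarImp), the sum of reciprocal
#' importance ranks (SumRankRecip), and the frequency with which a
#' predictor falls in a species' top ten (FreqTop10). Each is min-max
#' normalized to 0-100 across predictors and the index (VarImpIndx) is
#' their mean. Ranks are per species, decreasing in score; tied scores
#' share their average rank, so predictors with identical importance
#' profiles receive identical indices.
#'
#' @param importance Numeric matrix of importance scores, one row per
#'   species, one named column per predictor.
#' @param top_n Rank cutoff of the frequency score (default 10).
#' @return Data frame `predictor`, `sum_var_imp`, `sum_rank_recip`,
#'   `freq_top10` (each normalized 0-100), `var_imp_indx`, plus the raw
#'   scores as `raw_*` columns, sorted by decreasing index.
#' @export
variable_importance_index <- function(importance, top_n = 10) {
  importance <- rbind(importance)
  stopifnot(!is.null(colnames(importance)))
  preds <- colnames(importance)
  ranks <- t(apply(importance, 1,
                   function(s) rank(-s, ties.method = "average")))
  raw_sum <- colSums(importance)
  raw_recip <- colSums(1 / ranks)
  raw_freq <- colSums(ranks <= top_n)
  n100 <- function(x) minmax_unit(x) * 100
  out <- data.frame(
    predictor = preds,
    sum_var_imp = n100(raw_sum),
    sum_rank_recip = n100(raw_recip),
    freq_top10 = n100(raw_freq),
    raw_sum_var_imp = raw_sum,
    raw_sum_rank_recip = raw_recip,
    raw_freq_top10 = raw_freq,
    stringsAsFactors = FALSE
  )
  out$var_imp_indx <- (out$sum_var_imp + out$sum_rank_recip +
                         out$freq_top10) / 3
  out <- out[order(-out$var_imp_indx, out$predictor), ]
  rownames(out) <- NULL
  out
}
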