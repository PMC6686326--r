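# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately re-derive quantities from first
# principles, without calling the implementation under test.

# Fuzzy-kappa oracle: explicit enumeration of observed and expected
# similarity-weighted agreement over all class pairs.
fk_bruteforce <- function(obs, pred, n_classes, sim) {
  n <- length(obs)
  po <- 0
  for (i in seq_len(n)) po <- po + sim(abs(obs[i] - pred[i]))
  po <- po / n
  pe <- 0
  for (a in 0:(n_classes - 1)) {
    for (b in 0:(n_classes - 1)) {
      pe <- pe + mean(obs == a) * mean(pred == b) * sim(abs(a - b))
    }
  }
  (po - pe) / (1 - pe)
}

# Refinement oracle: enumerate the four quadrants of each coarse cell
# directly from the plot coordinates and apply the threshold rule.
refine_bruteforce <- function(coarse, plots, min_plots = 2,
                              min_fraction = 0.5) {
  subdivided <- logical(nrow(coarse))
  for (i in seq_len(nrow(coarse))) {
    xm <- (coarse$xmin[i] + coarse$xmax[i]) / 2
    ym <- (coarse$ymin[i] + coarse$ymax[i]) / 2
    qs <- list(c(coarse$xmin[i], coarse$ymin[i], xm, ym),
               c(xm, coarse$ymin[i], coarse$xmax[i], ym),
               c(coarse$xmin[i], ym, xm, coarse$ymax[i]),
               c(xm, ym, coarse$xmax[i], coarse$ymax[i]))
    ok <- vapply(qs, function(q) {
      sum(plots$x >= q[1] & plots$x < q[3] &
            plots$y >= q[2] & plots$y < q[4]) >= min_plots
    }, logical(1))
    subdivided[i] <- mean(ok) >= min_fraction
  }
  stats::setNames(subdivided, coarse$cell_id)
}

# Variable-importance oracle: raw sums, reciprocal-rank sums and top-n
# frequencies computed with explicit loops, then min-max scaled to 0-100.
varimp_bruteforce <- function(scores, top_n = 10) {
  preds <- colnames(scores)
  raw_sum <- raw_recip <- raw_freq <- stats::setNames(
    numeric(length(preds)), preds)
  for (s in seq_len(nrow(scores))) {
    for (p in preds) {
      v <- scores[s, p]
      # average rank: strictly-better count plus the middle of the tie run
      better <- sum(scores[s, ] > v)
      ties <- sum(scores[s, ] == v)
      r <- better + (1 + ties) / 2
      raw_sum[p] <- raw_sum[p] + v
      raw_recip[p] <- raw_recip[p] + 1 / r
      if (r <= top_n) raw_freq[p] <- raw_freq[p] + 1
    }
  }
  scale100 <- function(x) {
    if (diff(range(x)) == 0) return(rep(100, length(x)))
    (x - min(x)) / diff(range(x)) * 100
  }
  list(raw_sum = raw_sum, raw_recip = raw_recip, raw_freq = raw_freq,
       index = (scale100(raw_sum) + scale100(raw_recip) +
                  scale100(raw_freq)) / 3)
}

# One-plot tally builder.
make_tally <- function(plot_id, species, stems, basal_area) {
  data.frame(plot_id = plot_id, species = species, stems = stems,
             basal_area = basal_area, stringsAsFactors = FALSE)
}

# Cell-sample builder for the filter tests.
make_samples <- function(mean_iv, plot_count = 2, forest_fraction = 0.5,
                         species = "sp") {
  n <- length(mean_iv)
  data.frame(cell_id = sprintf("c%02d", seq_len(n)), species = species,
             mean_iv = mean_iv, plot_count = rep_len(plot_count, n),
             forest_fraction = rep_len(forest_fraction, n),
             stringsAsFactors = FALSE)
}

# Small deterministic training set driven by a single covariate, used by
# the model-fitting tests: mean_iv responds to x1, x2/x3 are noise.
make_training <- function(n = 120, seed = 1, p = 3) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n,
                            dimnames = list(NULL, paste0("x", seq_len(p)))))
  y <- pmax(0, 40 * exp(-(x$x1 - 0.3)^2) + rnorm(n, sd = 2))
  structure(list(species = "sp",
                 data = cbind(data.frame(cell_id = sprintf("c%03d", 1:n),
                                         mean_iv = y), x),
                 excluded = data.frame(cell_id = character(0),
                                       reason = character(0))),
            class = "training_set")
}
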