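# IV classes, fuzzy kappa, TSS, stability metrics, ModRel, range codes and
# the cross-species variable importance index.

test_that("IV classes follow the binning after integer rounding", {
  expect_equal(iv_to_class(c(0, 2, 25)), c(0L, 1L, 5L))
  expect_equal(iv_to_class(c(0.4, 3.6, 100)), c(0L, 2L, 7L))
  expect_error(iv_to_class(101), "\\[0, 100\\]")
  expect_error(iv_to_class(-2), "\\[0, 100\\]")
})

test_that("fuzzy kappa is 1 for identical maps and matches the brute-force oracle", {
  scheme <- iv_class_scheme()
  obs <- iv_to_class(c(0, 2, 25, 60, 8, 14), scheme)
  expect_equal(fuzzy_kappa(obs, obs, scheme), 1)
  # 4-cell worked case, 3 classes, s(d) = 2^-d, against explicit enumeration
  sim <- function(d) 2^(-d)
  o4 <- c(0L, 1L, 2L, 2L); p4 <- c(0L, 2L, 2L, 1L)
  small <- iv_class_scheme(lower = c(0, 1, 11), upper = c(0, 10, 100),
                           similarity = sim)
  expect_equal(fuzzy_kappa(o4, p4, small),
               fk_bruteforce(o4, p4, 3, sim), tolerance = 1e-12)
  # random 30-cell maps over the full 8-class scheme
  set.seed(101)
  for (rep in 1:200) {
    o <- sample(0:7, 30, replace = TRUE)
    p <- sample(0:7, 30, replace = TRUE)
    expect_equal(fuzzy_kappa(o, p, scheme),
                 fk_bruteforce(o, p, 8, function(d) 2^(-d)),
                 tolerance = 1e-12)
  }
})

test_that("fuzzy kappa with identity similarity equals Cohen's kappa", {
  ident <- iv_class_scheme(similarity = function(d) as.numeric(d == 0))
  set.seed(55)
  for (rep in 1:20) {
    o <- sample(0:4, 60, replace = TRUE)
    p <- ifelse(runif(60) < 0.5, o, sample(0:4, 60, replace = TRUE))
    ck <- e1071::classAgreement(table(factor(o, 0:7), factor(p, 0:7)))$kappa
    expect_equal(fuzzy_kappa(o, p, ident), ck, tolerance = 1e-10)
  }
})

test_that("fuzzy kappa averages to chance level over cell permutations", {
  set.seed(77)
  obs <- sample(0:7, 60, replace = TRUE, prob = c(4, 3, 2, 2, 1, 1, 1, 1))
  fks <- replicate(400, fuzzy_kappa(obs, sample(obs)))
  expect_lt(abs(mean(fks)), 0.02)
})

test_that("agreement statistics ignore cell labels", {
  set.seed(60)
  o <- sample(0:7, 40, replace = TRUE)
  p <- sample(0:7, 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(fuzzy_kappa(o, p), fuzzy_kappa(o[perm], p[perm]))
  ob <- o > 2; pb <- p > 2
  expect_equal(tss(ob, pb), tss(ob[perm], pb[perm]))
})

test_that("TSS follows the 2x2 confusion table", {
  expect_equal(tss(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # all predicted present: sensitivity 1, specificity 0
  expect_equal(tss(c(TRUE, FALSE), c(TRUE, TRUE)), 0)
  # TP 40, FN 10, TN 30, FP 20 -> 0.8 + 0.6 - 1 = 0.4
  obs <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 30, 20))
  pred <- rep(c(TRUE, FALSE, FALSE, TRUE), c(40, 10, 30, 20))
  expect_equal(tss(obs, pred), 0.4)
  expect_warning(out <- tss(c(TRUE, TRUE), c(TRUE, FALSE)), "one class")
  expect_true(is.na(out))
})

test_that("Top5 awards inverse-rank points for same-rank matches", {
  ref <- c("a", "b", "c", "d", "e")
  perfect <- bagging_ensemble(matrix(rep(c(5, 4, 3, 2, 1), each = 30), 30, 5,
                                     dimnames = list(NULL, ref)))
  expect_equal(top5_stability(ref, perfect), 1)
  disjoint <- bagging_ensemble(matrix(rep(c(0, 0, 0, 0, 0, 3, 2, 1), each = 30),
                                      30, 8,
                                      dimnames = list(NULL, c(ref, "f", "g", "h"))))
  expect_equal(top5_stability(ref, disjoint), 0)
  # every tree matches only the rank-1 predictor: 5/15
  m <- matrix(rep(c(10, 0, 0, 0, 0, 3, 2, 1), each = 30), 30, 8,
              dimnames = list(NULL, c(ref, "f", "g", "h")))
  expect_equal(top5_stability(ref, bagging_ensemble(m)), 1 / 3)
  # a short reference keeps the /15 denominator
  short <- bagging_ensemble(matrix(rep(c(5, 4), each = 10), 10, 2,
                                   dimnames = list(NULL, c("a", "b"))))
  expect_equal(top5_stability(c("a", "b"), short), 9 / 15)
  # the "anywhere" variant credits off-rank membership
  swapped <- bagging_ensemble(matrix(rep(c(4, 5), each = 10), 10, 2,
                                     dimnames = list(NULL, c("a", "b"))))
  expect_equal(top5_stability(c("a", "b"), swapped), 0)
  expect_equal(top5_stability(c("a", "b"), swapped, match = "anywhere"), 9 / 15)
})

test_that("CVdev is one minus the clipped CV of weighted deviance shares", {
  ref <- c("a", "b")
  same <- matrix(rep(c(6, 3, 1), each = 30), 30, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(cv_deviance_stability(bagging_ensemble(same), ref), 1)
  # engineer share vectors with sd/mean exactly 0.25
  z <- as.numeric(scale(1:30))          # mean 0, sample sd 1
  sh <- 0.5 * (1 + 0.25 * z)
  prof <- cbind(a = sh, b = 1 - sh)     # totals are 1, share of "a" = sh
  expect_equal(cv_deviance_stability(bagging_ensemble(prof), "a"), 0.75)
  # sd/mean beyond 1 clips to CVdev 0
  sh2 <- c(rep(0.001, 28), 0.9, 0.95)
  prof2 <- cbind(a = sh2, b = 1 - sh2)
  expect_gt(sd(sh2) / mean(sh2), 1.8)
  expect_equal(cv_deviance_stability(bagging_ensemble(prof2), "a"), 0)
  # zero mean weight is maximally unstable
  prof3 <- cbind(a = rep(0, 5), b = rep(1, 5))
  expect_equal(cv_deviance_stability(bagging_ensemble(prof3), "a"), 0)
})

test_that("stability metrics are invariant to predictor renaming", {
  set.seed(91)
  prof <- matrix(rexp(30 * 6), 30, 6,
                 dimnames = list(NULL, paste0("v", 1:6)))
  ref <- c("v3", "v1", "v5")
  ren <- prof
  colnames(ren) <- paste0("w", 1:6)
  ref2 <- c("w3", "w1", "w5")
  expect_equal(top5_stability(ref, bagging_ensemble(prof)),
               top5_stability(ref2, bagging_ensemble(ren)))
  expect_equal(cv_deviance_stability(bagging_ensemble(prof), ref),
               cv_deviance_stability(bagging_ensemble(ren), ref2))
})

test_that("ModRel combines normalized components with the published weights", {
  expect_equal(modrel_combine(1, 1, 1, 1, 1), 0.99)
  expect_equal(modrel_combine(1, 0, 0, 0, 0), 0.33)
  expect_equal(modrel_combine(0, 0, 1, 0, 0), 0.11)
  # monotone in every component
  set.seed(14)
  base <- runif(5)
  for (j in 1:5) {
    up <- base; up[j] <- up[j] + 0.1
    expect_gt(do.call(modrel_combine, as.list(up)),
              do.call(modrel_combine, as.list(base)))
  }
})

test_that("model reliability normalizes, classifies, and withdraws", {
  comp <- data.frame(
    species = c("s1", "s2", "s3", "s4"),
    rf_r2 = c(0.8, 0.4, -0.05, 0.6),
    fk = c(0.9, 0.5, 0.3, 0.7),
    tss = c(0.9, 0.4, 0.2, 0.6),
    cvdev = c(0.95, 0.5, 0.2, 0.7),
    top5 = c(0.8, 0.3, 0.1, 0.5))
  rel <- model_reliability(comp)
  # best species maxes every normalized component
  expect_equal(rel$modrel[1], 0.99)
  expect_equal(rel$reliability_class[1], "high")
  # negative RF R2 forces withdrawal even before the ModRel threshold
  expect_true(rel$withdrawn[3])
  expect_false(any(rel$withdrawn[c(1, 2, 4)]))
  # worst species anchors the normalization at 0
  expect_equal(rel$modrel[3], 0)
  expect_equal(rel$reliability_class[3], "unreliable")
  # constant columns normalize to 1 for every species
  const <- comp; const$fk <- 0.5
  expect_true(all(model_reliability(const)$n_fk == 1))
  # class boundaries are half-open
  cls <- function(m) ifelse(m >= 0.7, "high", ifelse(m >= 0.55, "medium",
                     ifelse(m >= 0.14, "low", "unreliable")))
  for (m in c(0.7, 0.699, 0.55, 0.549, 0.14, 0.139)) {
    fake <- model_reliability(data.frame(species = "x", rf_r2 = 1, fk = 1,
                                         tss = 1, cvdev = 1, top5 = 1),
                              weights = c(m, 0, 0, 0, 0))
    expect_equal(fake$reliability_class, cls(m))
  }
})

test_that("range codes encode breadth, density and abundance", {
  expect_equal(classify_range(0.05, 0.50, 7.2), "NDH")
  expect_equal(classify_range(0.25, 0.30, 3.0), "WSL")
  expect_equal(classify_range(0.05, 0.30, 3.0, withdrawn = TRUE), "NSLX")
  # thresholds are inclusive on the stated sides
  expect_equal(classify_range(0.10, 0.40, 6.0), "WDH")
})

test_that("variable importance index matches the brute-force oracle", {
  # one dominant predictor scores 100 on all three components
  solo <- matrix(c(5, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c")))
  vit <- variable_importance_index(solo, top_n = 2)
  expect_equal(vit$var_imp_indx[vit$predictor == "a"], 100)
  # symmetric predictors tie
  sym <- matrix(c(3, 3, 1, 3, 3, 1), 2, 3, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
  vs <- variable_importance_index(sym, top_n = 2)
  expect_equal(vs$var_imp_indx[vs$predictor == "a"],
               vs$var_imp_indx[vs$predictor == "b"])
  # 3 species x 4 predictors toy table against the enumeration oracle
  toy <- matrix(c(4, 2, 1, 0.5,
                  0.2, 5, 1, 0,
                  3, 3, 0.1, 2), 3, 4, byrow = TRUE,
                dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
  got <- variable_importance_index(toy, top_n = 2)
  oracle <- varimp_bruteforce(toy, top_n = 2)
  expect_equal(stats::setNames(got$raw_sum_var_imp, got$predictor)[names(oracle$raw_sum)],
               oracle$raw_sum)
  expect_equal(stats::setNames(got$raw_sum_rank_recip, got$predictor)[names(oracle$raw_recip)],
               oracle$raw_recip)
  expect_equal(stats::setNames(got$raw_freq_top10, got$predictor)[names(oracle$raw_freq)],
               oracle$raw_freq)
  expect_equal(stats::setNames(got$var_imp_indx, got$predictor)[names(oracle$index)],
               oracle$index)
})
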