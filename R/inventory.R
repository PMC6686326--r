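# Plot-level species importance values, cell aggregation, and the
# training-cell filters applied before model fitting.

validate_tallies <- function(tallies) {
  need <- c("plot_id", "species", "stems", "basal_area")
  if (!all(need %in% names(tallies))) {
    stop("tallies need columns ", paste(need, collapse = ", "))
  }
  if (any(tallies$stems < 0) || any(tallies$basal_area < 0)) {
    stop("invalid-tally: stems and basal_area must be non-negative")
  }
  if (any(tallies$stems == 0 & tallies$basal_area > 0)) {
    stop("invalid-tally: a record with zero stems cannot carry basal area")
  }
  invisible(tallies)
}

#' Compute importance values for all species on all plots
#'
#' The importance value (IV) of a species on a plot is the equally weighted
#' sum of its relative stem density and relative basal-area dominance,
#' scaled to 0-100:
#' `IV = 50 * stems / total_stems + 50 * basal_area / total_basal_area`.
#' Per forested plot the species IVs therefore sum to 100. Plots with zero
#' total stems are non-forested: they receive no IV records (absence of
#' trees, not absence of a species) and are reported in the
#' `"non_forested"` attribute. If a forested plot has zero total basal area
#' the dominance term is dropped and IV is 100 times relative density.
#'
#' @param tallies Data frame with columns `plot_id`, `species`, `stems`,
#'   `basal_area` (m^2); duplicated plot/species rows are summed.
#' @return Data frame `plot_id`, `species`, `iv` covering every species
#'   present on each forested plot, with attribute `non_forested` (plot ids
#'   with zero stems overall).
#' @export
compute_plot_ivs <- function(tallies) {
  validate_tallies(tallies)
  agg <- stats::aggregate(cbind(stems, basal_area) ~ plot_id + species,
                          data = tallies, FUN = sum)
  tot_stems <- tapply(agg$stems, agg$plot_id, sum)
  tot_ba <- tapply(agg$basal_area, agg$plot_id, sum)
  non_forested <- names(tot_stems)[tot_stems == 0]
  agg <- agg[tot_stems[agg$plot_id] > 0, , drop = FALSE]
  ts <- as.numeric(tot_stems[agg$plot_id])
  tb <- as.numeric(tot_ba[agg$plot_id])
  iv <- ifelse(tb > 0,
               50 * agg$stems / ts + 50 * agg$basal_area / tb,
               100 * agg$stems / ts)
  out <- data.frame(plot_id = agg$plot_id, species = agg$species, iv = iv,
                    stringsAsFactors = FALSE)
  out <- out[order(out$plot_id, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "non_forested") <- non_forested
  out
}

#' Importance value of one species on one plot
#'
#' @param tallies Tree tallies for a single plot.
#' @param species Focal species name.
#' @return The IV in `[0, 100]`; 0 if the species is absent from a forested
#'   plot; `NA` (the non-forested marker) if the plot has no stems at all.
#' @examples
#' t1 <- data.frame(plot_id = "p", species = c("a", "b"),
#'                  stems = c(3, 7), basal_area = c(0.6, 0.4))
#' plot_importance_value(t1, "a")  # 50 * 0.3 + 50 * 0.6 = 45
#' @export
plot_importance_value <- function(tallies, species) {
  validate_tallies(tallies)
  if (length(unique(tallies$plot_id)) != 1) {
    stop("tallies must all share one plot_id")
  }
  if (sum(tallies$stems) == 0) return(NA_real_)  # non-forested plot marker
  ivs <- compute_plot_ivs(tallies)
  hit <- ivs$species == species
  if (!any(hit)) 0 else sum(ivs$iv[hit])
}

#' Aggregate plot importance values to lattice cells
#'
#' Per cell, the mean IV of the focal species over the forested plots
#' assigned to it, where a forested plot on which the species is absent
#' contributes 0 (observed absence). Non-forested plots never enter the
#' mean. A cell with no forested plots gets a missing mean and
#' `plot_count = 0`.
#'
#' @param plot_ivs Output of [compute_plot_ivs()] (its plots define the
#'   forested set).
#' @param assignment Data frame `plot_id`, `cell_id` (e.g. from
#'   [assign_plots()]).
#' @param species Focal species.
#' @param cells Optional character vector of cell ids to report (defaults to
#'   the cells present in `assignment`); include the full lattice to obtain
#'   empty cells.
#' @param forest_fraction Optional named numeric vector (by cell id) or data
#'   frame `cell_id`, `forest_fraction`.
#' @return Data frame `cell_id`, `species`, `mean_iv`, `plot_count`,
#'   `forest_fraction`.
#' @export
aggregate_cell_iv <- function(plot_ivs, assignment, species, cells = NULL,
                              forest_fraction = NULL) {
  stopifnot(all(c("plot_id", "cell_id") %in% names(assignment)))
  cells <- cells %||% sort(unique(assignment$cell_id))
  forested <- unique(plot_ivs$plot_id)
  asg <- assignment[assignment$plot_id %in% forested, , drop = FALSE]
  sp <- plot_ivs[plot_ivs$species == species, , drop = FALSE]
  iv_of <- stats::setNames(sp$iv, sp$plot_id)
  plot_iv <- iv_of[asg$plot_id]
  plot_iv[is.na(plot_iv)] <- 0  # forested, species absent
  f <- factor(asg$cell_id, levels = cells)
  n <- as.integer(table(f))
  total <- as.numeric(tapply(plot_iv, f, sum, default = 0))
  mean_iv <- ifelse(n > 0, total / n, NA_real_)
  ff <- rep(NA_real_, length(cells))
  if (!is.null(forest_fraction)) {
    if (is.data.frame(forest_fraction)) {
      forest_fraction <- stats::setNames(forest_fraction$forest_fraction,
                                         forest_fraction$cell_id)
    }
    ff <- as.numeric(forest_fraction[cells])
  }
  data.frame(cell_id = cells, species = species, mean_iv = mean_iv,
             plot_count = n, forest_fraction = ff, stringsAsFactors = FALSE)
}

#' Filter cells into a species training set
#'
#' Applies the three exclusion rules, in order: (a) cells with fewer than
#' `min_plots` inventory plots, (b) cells with forest-cover fraction below
#' `min_forest`, and (c) outlier cells whose mean IV exceeds a cutoff
#' derived from the interquartile range (IQR) of the occupied (mean IV > 0)
#' cells surviving (a) and (b). Each excluded cell is recorded once, with
#' the first rule that removed it. Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' Two readings of the outlier rule are available: `"literal"` (the
#' default) excludes cells with `mean_iv > iqr_mult * IQR`, while
#' `"tukey"` uses the conventional upper fence `Q3 + iqr_mult * IQR`. When
#' fewer than four occupied cells survive (a) and (b) the IQR is
#' ill-determined and rule (c) is skipped with a warning. Cells with an
#' unknown forest fraction (`NA`) are not excluded by rule (b).
#'
#' @param samples Cell samples for one species ([aggregate_cell_iv()]).
#' @param predictors Optional data frame keyed by `cell_id` whose remaining
#'   numeric columns are joined onto the surviving rows.
#' @param min_plots Minimum plots per training cell (default 2).
#' @param min_forest Minimum forest-cover fraction (default 0.05).
#' @param iqr_mult IQR multiplier of rule (c) (default 1.5).
#' @param outlier_rule `"literal"` or `"tukey"`.
#' @return An object of class `training_set`: list with `species`, `data`
#'   (data frame `cell_id`, `mean_iv` plus any predictor columns),
#'   `excluded` (data frame `cell_id`, `reason` in
#'   too_few_plots/low_forest/outlier), and `outlier_cutoff`.
#' @export
filter_training_cells <- function(samples, predictors = NULL, min_plots = 2,
                                  min_forest = 0.05, iqr_mult = 1.5,
                                  outlier_rule = c("literal", "tukey")) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(min_plots >= 1, min_forest >= 0, iqr_mult > 0)
  if (length(unique(samples$species)) > 1) {
    stop("samples must be for a single species")
  }
  reason <- rep(NA_character_, nrow(samples))
  a <- samples$plot_count < min_plots | is.na(samples$mean_iv)
  reason[a] <- "too_few_plots"
  b <- is.na(reason) & !is.na(samples$forest_fraction) &
    samples$forest_fraction < min_forest
  reason[b] <- "low_forest"

  surviving <- is.na(reason)
  occupied <- surviving & samples$mean_iv > 0
  cutoff <- NA_real_
  if (sum(occupied) < 4) {
    warning("fewer than 4 occupied cells survive filters (a)-(b); ",
            "IQR undefined, skipping outlier filter (c)")
  } else {
    q <- stats::quantile(samples$mean_iv[occupied], c(0.25, 0.75),
                         type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    cutoff <- if (outlier_rule == "literal") iqr_mult * iqr
              else q[2] + iqr_mult * iqr
    out <- surviving & samples$mean_iv > cutoff
    reason[out] <- "outlier"
  }

  keep <- is.na(reason)
  data <- data.frame(cell_id = samples$cell_id[keep],
                     mean_iv = samples$mean_iv[keep],
                     stringsAsFactors = FALSE)
  if (!is.null(predictors)) {
    m <- match(data$cell_id, predictors$cell_id)
    if (anyNA(m)) {
      stop("predictors missing for cell(s): ",
           paste(utils::head(data$cell_id[is.na(m)], 5), collapse = ", "))
    }
    data <- cbind(data, predictors[m, setdiff(names(predictors), "cell_id"),
                                   drop = FALSE])
    rownames(data) <- NULL
  }
  structure(list(
    species = samples$species[1],
    data = data,
    excluded = data.frame(cell_id = samples$cell_id[!keep],
                          reason = reason[!keep], stringsAsFactors = FALSE),
    outlier_cutoff = cutoff,
    params = list(min_plots = min_plots, min_forest = min_forest,
                  iqr_mult = iqr_mult, outlier_rule = outlier_rule)
  ), class = "training_set")
}

#' Is a species eligible for habitat-suitability modeling?
#'
#' A species is modeled only if it occupies (mean IV > 0) at least
#' `min_cells` grid cells over the full lattice.
#'
#' @param samples Cell samples for one species.
#' @param min_cells Minimum occupied cells (default 60).
#' @return Logical scalar.
#' @export
species_eligibility <- function(samples, min_cells = 60) {
  sum(!is.na(samples$mean_iv) & samples$mean_iv > 0) >= min_cells
}
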