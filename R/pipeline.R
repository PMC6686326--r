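# Configured end-to-end pipeline: lattice -> inventory -> per-species
# filter/fit/predict/combine -> evaluation -> range codes -> predictor
# importance, with stable file formats and a run manifest.

#' Pipeline configuration
#'
#' Collects the input paths and every tunable parameter, with the
#' standard defaults (fine/coarse cell sizes 10/20 km, refinement rule 2
#' plots in >= 50% of quadrants, exclusion filters 2 plots / 5% forest /
#' 1.5 IQR, 60-cell eligibility, random forest 1,001 trees / mtry 8 /
#' node size 10, mean-median CV threshold 2.75, 30 bagging trees, ModRel
#' weights 0.33/0.33/0.11/0.11/0.11 with class bounds 0.70/0.55/0.14).
#'
#' @param plots,tallies,covariates,forest_fraction Paths to the input CSV
#'   tables (see the package vignette for formats).
#' @param out_dir Output directory.
#' @param extent Path to a boundary-vertex CSV (columns x, y); or NULL to
#'   use the bounding box of the plots, snapped outward to whole coarse
#'   cells.
#' @param fine_size_m,coarse_size_m Lattice cell sizes (m).
#' @param min_plots,min_fraction Refinement rule.
#' @param min_forest,iqr_mult,outlier_rule Training-cell filters.
#' @param min_cells Species eligibility threshold.
#' @param n_trees,mtry,min_node Random-forest parameters.
#' @param cv_threshold Mean-median combination threshold.
#' @param n_bagging Bagging ensemble size.
#' @param weights ModRel weights (length 5).
#' @param class_thresholds Named vector `c(high, medium, low)`.
#' @param background_species Species name treated as the non-focal pool
#'   and never modeled.
#' @param species Optional character vector restricting the modeled
#'   species.
#' @param seed Base RNG seed; per-species fit seeds are derived from it.
#' @param write_geojson Also write GeoJSON mirrors of the lattice and
#'   prediction maps.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(plots, tallies, covariates, forest_fraction,
                            out_dir, extent = NULL,
                            fine_size_m = 10000, coarse_size_m = 20000,
                            min_plots = 2, min_fraction = 0.5,
                            min_forest = 0.05, iqr_mult = 1.5,
                            outlier_rule = "literal", min_cells = 60,
                            n_trees = 1001, mtry = 8, min_node = 10,
                            cv_threshold = 2.75, n_bagging = 30,
                            weights = c(0.33, 0.33, 0.11, 0.11, 0.11),
                            class_thresholds = c(high = 0.70, medium = 0.55,
                                                 low = 0.14),
                            background_species = "OTHER", species = NULL,
                            seed = 1, write_geojson = TRUE) {
  stopifnot(coarse_size_m == 2 * fine_size_m, length(weights) == 5)
  cfg <- as.list(environment())
  cfg <- cfg[order(names(cfg))]  # deterministic order for hashing
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected.
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$class_thresholds)) {
    raw$class_thresholds <- unlist(raw$class_thresholds)
  }
  do.call(pipeline_config, raw)
}

read_extent <- function(config, plots) {
  if (!is.null(config$extent)) {
    b <- utils::read.csv(config$extent)
    return(study_extent(as.matrix(b[, c("x", "y")])))
  }
  s <- config$coarse_size_m
  x0 <- floor(min(plots$x) / s) * s
  y0 <- floor(min(plots$y) / s) * s
  x1 <- ceiling(max(plots$x) / s) * s
  y1 <- ceiling(max(plots$y) / s) * s
  rectangular_extent(x1 - x0, y1 - y0, origin = c(x0, y0))
}

config_hash <- function(config) {
  # hash the scientific parameters only, not filesystem paths, so reruns of
  # the same configuration hash identically wherever they are staged
  params <- unclass(config)
  params <- params[setdiff(names(params),
                           c("plots", "tallies", "covariates",
                             "forest_fraction", "extent", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(params), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full modeling pipeline
#'
#' Executes, in order: lattice construction and density refinement, plot
#' IV computation and cell aggregation, per-species eligibility and
#' training filters, random-forest fitting, whole-lattice prediction with
#' the mean-median combination and confidence values, the five
#' reliability components and ModRel classes, species range codes, and
#' the cross-species predictor importance table. All tables are written
#' under `config$out_dir` together with a `manifest.json`; reruns with an
#' identical configuration and seed produce byte-identical outputs.
#' Withdrawn species get no prediction map. Any stage failure aborts with
#' a stage-named error and removes the partially written staging outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  staging <- file.path(config$out_dir, ".staging")
  unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(staging, recursive = TRUE))
  wcsv <- function(d, f) utils::write.csv(d, file.path(staging, f),
                                          row.names = FALSE, quote = FALSE)

  inp <- stage("read-inputs", {
    plots <- utils::read.csv(config$plots)
    tallies <- utils::read.csv(config$tallies)
    covariates <- utils::read.csv(config$covariates)
    ff <- utils::read.csv(config$forest_fraction)
    validate_tallies(tallies)
    stopifnot(all(c("plot_id", "x", "y") %in% names(plots)),
              "cell_id" %in% names(covariates),
              all(c("cell_id", "forest_fraction") %in% names(ff)))
    list(plots = plots, tallies = tallies, covariates = covariates,
         forest_fraction = stats::setNames(ff$forest_fraction, ff$cell_id))
  })
  pred_names <- setdiff(names(inp$covariates), "cell_id")
  if (config$mtry > length(pred_names)) {
    stop("stage validate-config: bad-predictor-count: mtry (", config$mtry,
         ") exceeds the number of covariates (", length(pred_names), ")",
         call. = FALSE)
  }

  lat <- stage("lattice", {
    extent <- read_extent(config, inp$plots)
    coarse <- build_uniform_lattice(extent, config$coarse_size_m, "coarse")
    lattice <- refine_lattice(coarse, inp$plots,
                              min_plots = config$min_plots,
                              min_fraction = config$min_fraction)
    asg <- assign_plots(lattice$cells, inp$plots)
    miss <- setdiff(lattice$cells$cell_id, inp$covariates$cell_id)
    if (length(miss)) {
      stop("covariates missing for cell(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    list(lattice = lattice, asg = asg)
  })
  lattice <- lat$lattice
  cell_ids <- lattice$cells$cell_id
  covs <- inp$covariates[match(cell_ids, inp$covariates$cell_id), ,
                         drop = FALSE]

  plot_ivs <- stage("inventory", compute_plot_ivs(inp$tallies))
  all_species <- setdiff(sort(unique(inp$tallies$species)),
                         config$background_species)
  modeled <- config$species %||% all_species

  per_species <- list()
  components <- list()
  importance_rows <- list()
  range_rows <- list()
  for (i in seq_along(modeled)) {
    sp <- modeled[i]
    res <- stage(paste0("species-", sp), {
      samples <- aggregate_cell_iv(plot_ivs, lat$asg$assignment, sp,
                                   cells = cell_ids,
                                   forest_fraction = inp$forest_fraction)
      eligible <- species_eligibility(samples, config$min_cells)
      if (!eligible) {
        list(species = sp, eligible = FALSE, samples = samples)
      } else {
        training <- filter_training_cells(
          samples, predictors = covs,
          min_plots = config$min_plots, min_forest = config$min_forest,
          iqr_mult = config$iqr_mult, outlier_rule = config$outlier_rule)
        model <- fit_rf(training, rf_config(config$n_trees, config$mtry,
                                            config$min_node,
                                            seed = config$seed + i))
        pred <- predict_combined(model, covs,
                                 cv_threshold = config$cv_threshold)
        bag <- fit_bagging(training, n_models = config$n_bagging,
                           seed = config$seed + 100000L + i,
                           min_node = config$min_node)
        ref <- top_predictors(model, 5, positive_only = TRUE)
        tr_cells <- training$data$cell_id
        obs_iv <- training$data$mean_iv
        pred_iv <- pred$iv[match(tr_cells, pred$cell_id)]
        comp <- data.frame(
          species = sp,
          rf_r2 = model$oob_r2,
          fk = fuzzy_kappa_iv(obs_iv, pred_iv),
          tss = suppressWarnings(tss(obs_iv > 0, pred_iv > 0)),
          cvdev = cv_deviance_stability(bag, ref),
          top5 = top5_stability(ref, bag),
          stringsAsFactors = FALSE)
        # range statistics from the observed (inventory) side
        observed <- samples[samples$plot_count > 0, , drop = FALSE]
        occ <- observed$cell_id[observed$mean_iv > 0]
        area <- sum(lattice$cells$area_km2[cell_ids %in% occ]) /
          sum(lattice$cells$area_km2)
        in_occ <- lat$asg$assignment$cell_id %in% occ
        occ_plots <- lat$asg$assignment$plot_id[in_occ]
        occ_plots <- occ_plots[occ_plots %in% unique(plot_ivs$plot_id)]
        sp_iv <- plot_ivs[plot_ivs$species == sp, , drop = FALSE]
        present <- sp_iv$plot_id[sp_iv$iv > 0]
        dens <- if (length(occ_plots)) {
          mean(occ_plots %in% present)
        } else 0
        mean_iv_pres <- if (length(present)) {
          mean(sp_iv$iv[sp_iv$iv > 0])
        } else 0
        list(species = sp, eligible = TRUE, samples = samples,
             training = training, model = model, pred = pred,
             comp = comp,
             range_stats = c(area = area, dens = dens,
                             mean_iv = mean_iv_pres))
      }
    })
    per_species[[sp]] <- res
    if (isTRUE(res$eligible)) {
      components[[sp]] <- res$comp
      importance_rows[[sp]] <- stats::setNames(res$model$importance$score,
                                               res$model$importance$predictor)
    }
  }

  fitted_sp <- names(components)
  if (!length(fitted_sp)) {
    stop("stage evaluation: no eligible species to model", call. = FALSE)
  }
  evalres <- stage("evaluation", {
    comp <- do.call(rbind, components)
    rel <- model_reliability(comp, weights = config$weights,
                             thresholds = config$class_thresholds)
    imp <- do.call(rbind, importance_rows)
    vit <- variable_importance_index(imp)
    codes <- vapply(fitted_sp, function(sp) {
      rs <- per_species[[sp]]$range_stats
      classify_range(rs["area"], rs["dens"], rs["mean_iv"],
                     withdrawn = rel$withdrawn[rel$species == sp])
    }, character(1))
    report <- cbind(comp[c("species", "rf_r2", "fk", "tss", "cvdev", "top5")],
                    rel[c("modrel", "reliability_class", "withdrawn")],
                    range_code = codes)
    list(rel = rel, vit = vit, report = report)
  })

  manifest <- stage("write-outputs", {
    counts <- lat$asg$counts
    lattice_tab <- cbind(lattice$cells,
                         plot_count = as.integer(counts[cell_ids]))
    wcsv(lattice_tab, "lattice.csv")
    if (config$write_geojson) {
      write_lattice_geojson(lattice, file.path(staging, "lattice.geojson"),
                            plot_counts = counts)
    }
    wcsv(evalres$report, "reliability.csv")
    wcsv(evalres$vit, "variable_importance.csv")
    entries <- list()
    for (sp in modeled) {
      res <- per_species[[sp]]
      if (!isTRUE(res$eligible)) {
        entries[[sp]] <- list(species = sp, eligible = FALSE)
        next
      }
      wcsv(res$samples, paste0("cell_samples_", sp, ".csv"))
      wcsv(res$training$excluded, paste0("excluded_", sp, ".csv"))
      row <- evalres$report[evalres$report$species == sp, ]
      entry <- list(species = sp, eligible = TRUE,
                    reliability_class = row$reliability_class,
                    withdrawn = row$withdrawn,
                    range_code = row$range_code,
                    files = list(
                      cell_samples = paste0("cell_samples_", sp, ".csv"),
                      excluded = paste0("excluded_", sp, ".csv")))
      if (!row$withdrawn) {
        pf <- paste0("predictions_", sp, ".csv")
        wcsv(res$pred, pf)
        entry$files$predictions <- pf
      }
      entries[[sp]] <- entry
    }
    manifest <- list(
      package = "hybridsdm",
      version = as.character(utils::packageVersion("hybridsdm")),
      config_hash = config_hash(config),
      n_cells = nrow(lattice$cells),
      n_fine = sum(lattice$cells$level == "fine"),
      n_coarse = sum(lattice$cells$level == "coarse"),
      n_plots_assigned = sum(counts),
      n_plots_unassigned = length(lat$asg$unassigned),
      species = unname(entries),
      files = list(lattice = "lattice.csv",
                   reliability = "reliability.csv",
                   variable_importance = "variable_importance.csv"))
    jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  })

  # promote staging to the output directory only on full success
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  }
  invisible(manifest)
}

#' Write a lattice as a GeoJSON FeatureCollection
#'
#' One rectangular polygon feature per cell with properties `cell_id`,
#' `level`, `parent_id` and optionally `plot_count`.
#'
#' @param lattice A `hybrid_lattice` (or a cell data frame).
#' @param path Output path.
#' @param plot_counts Optional named counts per cell id.
#' @return `path`, invisibly.
#' @export
write_lattice_geojson <- function(lattice, path, plot_counts = NULL) {
  cells <- if (inherits(lattice, "hybrid_lattice")) lattice$cells else lattice
  features <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    ring <- list(c(cl$xmin, cl$ymin), c(cl$xmax, cl$ymin),
                 c(cl$xmax, cl$ymax), c(cl$xmin, cl$ymax),
                 c(cl$xmin, cl$ymin))
    props <- list(cell_id = cl$cell_id, level = cl$level,
                  parent_id = if (is.na(cl$parent_id)) NULL else cl$parent_id)
    if (!is.null(plot_counts)) {
      props$plot_count <- as.integer(plot_counts[[cl$cell_id]] %||% 0L)
    }
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
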