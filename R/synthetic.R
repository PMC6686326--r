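# Synthetic landscapes with known ground truth: smooth standardized
# covariate surfaces, plot networks with region-dependent density, and
# species with Gaussian niche responses whose tree tallies reproduce the
# intended importance values. Everything is deterministic given its seed.

#' Landscape configuration
#'
#' @param width_km,height_km Extent dimensions (km).
#' @param n_covariates Number of covariate surfaces (>= 2, default 12).
#' @param corr_length_km Spatial correlation length of the surfaces (km).
#' @param seed RNG seed.
#' @param n_fourier Random Fourier features per surface (smoothness /
#'   fidelity trade-off).
#' @param trend_sd Standard deviation of the low-order trend coefficients
#'   (0 disables the trend).
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(width_km = 300, height_km = 300,
                             n_covariates = 12, corr_length_km = 50,
                             seed = 1, n_fourier = 256, trend_sd = 0.25) {
  stopifnot(width_km > 0, height_km > 0, n_covariates >= 2,
            corr_length_km > 0, n_fourier >= 16)
  structure(list(width_m = width_km * 1000, height_m = height_km * 1000,
                 n_covariates = as.integer(n_covariates),
                 corr_length_m = corr_length_km * 1000,
                 seed = as.integer(seed), n_fourier = as.integer(n_fourier),
                 trend_sd = trend_sd),
            class = "landscape_config")
}

#' Generate smooth covariate surfaces
#'
#' Each surface is a stationary Gaussian random field with a squared-
#' exponential covariance (approximated by random Fourier features at the
#' configured correlation length) plus a weak low-order polynomial trend,
#' standardized to mean 0 and SD 1 over a dense reference grid of the
#' extent. Surfaces can be sampled at arbitrary coordinates with
#' [predict.synthetic_environment()] and are deterministic per seed.
#'
#' @param config A [landscape_config()].
#' @return An object of class `synthetic_environment`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  covs <- lapply(seq_len(config$n_covariates), function(j) {
    list(
      omega = matrix(stats::rnorm(2 * config$n_fourier,
                                  sd = 1 / config$corr_length_m),
                     nrow = 2),
      phase = stats::runif(config$n_fourier, 0, 2 * pi),
      trend = stats::rnorm(3, sd = config$trend_sd)
    )
  })
  env <- structure(list(config = config, covs = covs,
                        mu = rep(0, config$n_covariates),
                        sigma = rep(1, config$n_covariates)),
                   class = "synthetic_environment")
  # standardize over a 60 x 60 reference grid
  gx <- seq(0, config$width_m, length.out = 60)
  gy <- seq(0, config$height_m, length.out = 60)
  ref <- env_sample_raw(env, as.matrix(expand.grid(x = gx, y = gy)))
  env$mu <- colMeans(ref)
  env$sigma <- apply(ref, 2, stats::sd)
  env
}

env_sample_raw <- function(env, xy) {
  cfg <- env$config
  u <- xy[, 1] / cfg$width_m - 0.5
  v <- xy[, 2] / cfg$height_m - 0.5
  vapply(env$covs, function(cv) {
    m <- ncol(cv$omega)
    f <- sqrt(2 / m) *
      rowSums(cos(xy %*% cv$omega +
                    matrix(cv$phase, nrow(xy), m, byrow = TRUE)))
    f + cv$trend[1] * u + cv$trend[2] * v + cv$trend[3] * u * v
  }, numeric(nrow(xy)))
}

#' Sample covariate surfaces at coordinates
#'
#' @param object A `synthetic_environment`.
#' @param xy Two-column matrix or data frame of coordinates (meters).
#' @param ... Unused.
#' @return Numeric matrix, one standardized column per covariate
#'   (`cov01`, `cov02`, ...).
#' @export
predict.synthetic_environment <- function(object, xy, ...) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  raw <- env_sample_raw(object, xy)
  z <- sweep(sweep(raw, 2, object$mu), 2, object$sigma, "/")
  colnames(z) <- sprintf("cov%02d", seq_len(ncol(z)))
  z
}

#' Generate an inventory plot network
#'
#' Plots are placed by a homogeneous Poisson point process within each
#' rectangular region, with intensity expressed as expected plots per fine
#' (10 x 10 km by default) cell. Contrasting intensities between regions
#' drive the mix of fine and coarse cells in the hybrid lattice.
#'
#' @param regions Data frame with columns `xmin`, `xmax`, `ymin`, `ymax`
#'   (meters) and `intensity` (expected plots per fine cell, >= 0).
#' @param seed RNG seed.
#' @param fine_size_m Fine cell size defining the intensity unit.
#' @return Plot data frame `plot_id`, `x`, `y`.
#' @export
generate_plots <- function(regions, seed = 1, fine_size_m = 10000) {
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax", "intensity")
                %in% names(regions)),
            all(regions$intensity >= 0))
  set.seed(seed)
  pts <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    lambda <- r$intensity * (r$xmax - r$xmin) * (r$ymax - r$ymin) /
      fine_size_m^2
    n <- stats::rpois(1, lambda)
    if (n == 0) return(NULL)
    cbind(stats::runif(n, r$xmin, r$xmax), stats::runif(n, r$ymin, r$ymax))
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts)) pts <- matrix(numeric(0), ncol = 2)
  data.frame(plot_id = sprintf("P%06d", seq_len(nrow(pts))),
             x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
}

#' Define a synthetic species
#'
#' The species' expected IV at a location is a product of Gaussian
#' responses to its driving covariates (on the standardized covariate
#' scale), peaking at `max_iv` at the niche optimum; expected IVs below
#' `occupancy_threshold` are zeroed (range boundary / zero inflation), and
#' Gaussian noise of SD `noise_sd` is added on the IV scale at occupied
#' plots, clipped to `[0, 100]`.
#'
#' @param name Species name.
#' @param optima Named numeric vector of niche optima, one per driving
#'   covariate (names must be covariate names).
#' @param breadths Niche breadths (SD of the Gaussian response), recycled.
#' @param max_iv Peak expected IV (0 < max_iv <= 100).
#' @param occupancy_threshold Expected-IV floor below which the species is
#'   absent (default 1).
#' @param noise_sd Plot-level IV noise SD (default 3).
#' @return An object of class `synthetic_species`.
#' @export
synthetic_species <- function(name, optima, breadths, max_iv = 60,
                              occupancy_threshold = 1, noise_sd = 3) {
  stopifnot(!is.null(names(optima)), length(optima) >= 1,
            all(breadths > 0), max_iv > 0, max_iv <= 100,
            occupancy_threshold >= 0, noise_sd >= 0)
  structure(list(name = name, optima = optima,
                 breadths = rep_len(breadths, length(optima)),
                 max_iv = max_iv, occupancy_threshold = occupancy_threshold,
                 noise_sd = noise_sd),
            class = "synthetic_species")
}

#' Expected IV of a species at sampled covariates
#'
#' @param species A `synthetic_species`.
#' @param z Covariate matrix from [predict.synthetic_environment()].
#' @return Expected IVs (threshold applied).
#' @export
expected_iv <- function(species, z) {
  miss <- setdiff(names(species$optima), colnames(z))
  if (length(miss)) stop("covariates missing: ", paste(miss, collapse = ", "))
  resp <- rep(species$max_iv, nrow(z))
  for (j in seq_along(species$optima)) {
    d <- z[, names(species$optima)[j]] - unname(species$optima[j])
    resp <- resp * exp(-d^2 / (2 * species$breadths[j]^2))
  }
  unname(ifelse(resp < species$occupancy_threshold, 0, resp))
}

#' Generate tree tallies realizing a species' intended IVs
#'
#' Draws the intended plot IV (expected IV plus noise, clipped), then
#' constructs stem and basal-area tallies against a fixed background
#' species pool (1,000 stems, 10 m^2 per plot) so that
#' [plot_importance_value()] recovers the intended IV to within stem
#' rounding (< 0.05 IV). Plots where the species is absent carry only the
#' background pool; per-plot IV closure holds by construction.
#'
#' @param env A `synthetic_environment`.
#' @param species A `synthetic_species`.
#' @param plots Plot data frame (`plot_id`, `x`, `y`).
#' @param seed RNG seed for the plot-level noise.
#' @param background Name of the background species pool.
#' @return List with `tallies` (data frame `plot_id`, `species`, `stems`,
#'   `basal_area`) and `intended_iv` (data frame `plot_id`, `iv`).
#' @export
generate_species_tallies <- function(env, species, plots, seed = 1,
                                     background = "OTHER") {
  z <- predict(env, plots[, c("x", "y")])
  e <- expected_iv(species, z)
  set.seed(seed)
  iv <- ifelse(e == 0, 0,
               pmin(100, pmax(0, e + stats::rnorm(length(e),
                                                  sd = species$noise_sd))))
  iv[round(iv * 10) == 0] <- 0  # too faint to carry a whole stem
  tallies <- species_tally_rows(plots$plot_id, iv, species$name, background)
  list(tallies = tallies,
       intended_iv = data.frame(plot_id = plots$plot_id, iv = iv,
                                stringsAsFactors = FALSE))
}

# Tallies for one focal species at given IVs: focal stems out of 1,000 and
# basal area out of 10 m^2, remainder assigned to the background pool.
species_tally_rows <- function(plot_id, iv, name, background) {
  stems <- round(iv * 10)
  ba <- iv / 100 * 10
  focal <- data.frame(plot_id = plot_id[iv > 0], species = name,
                      stems = stems[iv > 0], basal_area = ba[iv > 0],
                      stringsAsFactors = FALSE)
  rest <- data.frame(plot_id = plot_id, species = background,
                     stems = 1000 - stems, basal_area = 10 - ba,
                     stringsAsFactors = FALSE)
  rest <- rest[rest$stems > 0, , drop = FALSE]
  out <- rbind(focal, rest)
  out[order(out$plot_id, out$species), , drop = FALSE]
}

#' Generate a complete synthetic dataset
#'
#' Builds the full study system: covariate surfaces, a two-density plot
#' network (a densely inventoried and a sparsely inventoried half, so the
#' hybrid lattice mixes fine and coarse cells), the hybrid lattice itself,
#' per-cell covariates and forest-cover fractions, per-plot tree tallies
#' for each species against a shared background pool, and the ground-truth
#' niche parameters. When several species are present their intended IVs
#' are scaled down proportionally on any plot where they would sum above
#' 100, preserving per-plot closure.
#'
#' @param config A [landscape_config()].
#' @param species List of [synthetic_species()]; by default `n_species`
#'   are drawn with two driving covariates each, optima near the covariate
#'   center and moderate breadths.
#' @param n_species Number of auto-generated species when `species` is
#'   NULL.
#' @param intensity_high,intensity_low Expected plots per fine cell in the
#'   left (dense) and right (sparse) halves of the extent.
#' @param min_plots,min_fraction Refinement rule passed to
#'   [refine_lattice()].
#' @param background Background species name.
#' @return An object of class `synthetic_dataset`: list with `config`,
#'   `env`, `extent`, `plots`, `lattice`, `assignment` (plot-to-cell),
#'   `cell_covariates` (data frame `cell_id` + covariates at cell
#'   centers), `forest_fraction` (named vector), `tallies`, `intended_iv`
#'   (plot x species data frame), `species` (ground truth).
#' @export
generate_dataset <- function(config = landscape_config(), species = NULL,
                             n_species = 2, intensity_high = 4,
                             intensity_low = 0.3, min_plots = 2,
                             min_fraction = 0.5, background = "OTHER") {
  env <- generate_environment(config)
  if (is.null(species)) {
    set.seed(config$seed + 1000L)
    species <- lapply(seq_len(n_species), function(i) {
      drivers <- sample(sprintf("cov%02d", seq_len(config$n_covariates)), 2)
      synthetic_species(
        name = sprintf("SP%02d", i),
        optima = stats::setNames(stats::runif(2, -0.5, 0.5), drivers),
        breadths = stats::runif(2, 1.0, 1.8),
        max_iv = stats::runif(1, 40, 70),
        occupancy_threshold = 1, noise_sd = 3)
    })
  }
  extent <- rectangular_extent(config$width_m, config$height_m)
  xmid <- config$width_m / 2
  regions <- data.frame(
    xmin = c(0, xmid), xmax = c(xmid, config$width_m),
    ymin = 0, ymax = config$height_m,
    intensity = c(intensity_high, intensity_low))
  plots <- generate_plots(regions, seed = config$seed + 2000L)
  coarse <- build_uniform_lattice(extent, 20000, level = "coarse")
  lattice <- refine_lattice(coarse, plots, min_plots = min_plots,
                            min_fraction = min_fraction)
  asg <- assign_plots(lattice$cells, plots)

  centers <- cbind((lattice$cells$xmin + lattice$cells$xmax) / 2,
                   (lattice$cells$ymin + lattice$cells$ymax) / 2)
  zc <- predict(env, centers)
  cell_covariates <- data.frame(cell_id = lattice$cells$cell_id, zc,
                                stringsAsFactors = FALSE)

  # forest fraction from an extra smooth surface; most cells well forested,
  # a small tail below the 5% exclusion threshold
  set.seed(config$seed + 3000L)
  ffcov <- list(omega = matrix(stats::rnorm(2 * config$n_fourier,
                                            sd = 1 / config$corr_length_m),
                               nrow = 2),
                phase = stats::runif(config$n_fourier, 0, 2 * pi),
                trend = c(0, 0, 0))
  ffenv <- structure(list(config = config, covs = list(ffcov),
                          mu = 0, sigma = 1),
                     class = "synthetic_environment")
  g <- env_sample_raw(ffenv, centers)[, 1]
  g <- (g - mean(g)) / stats::sd(g)
  forest_fraction <- stats::setNames(stats::plogis(1.5 + 2.5 * g),
                                     lattice$cells$cell_id)

  # intended IVs per plot and species, scaled to respect closure
  intended <- matrix(0, nrow(plots), length(species),
                     dimnames = list(NULL,
                                     vapply(species, `[[`, "", "name")))
  for (i in seq_along(species)) {
    st <- generate_species_tallies(env, species[[i]], plots,
                                   seed = config$seed + 4000L + i,
                                   background = background)
    intended[, i] <- st$intended_iv$iv
  }
  tot <- rowSums(intended)
  over <- tot > 100
  if (any(over)) {
    intended[over, ] <- intended[over, ] * (100 / tot[over])
    intended[round(intended * 10) == 0] <- 0
  }
  tallies <- do.call(rbind, c(
    lapply(seq_along(species), function(i) {
      iv <- intended[, i]
      d <- data.frame(plot_id = plots$plot_id[iv > 0],
                      species = species[[i]]$name,
                      stems = round(iv[iv > 0] * 10),
                      basal_area = iv[iv > 0] / 100 * 10,
                      stringsAsFactors = FALSE)
      d
    }),
    list(data.frame(plot_id = plots$plot_id, species = background,
                    stems = 1000 - round(rowSums(intended) * 10),
                    basal_area = 10 - rowSums(intended) / 100 * 10,
                    stringsAsFactors = FALSE))
  ))
  tallies <- tallies[tallies$stems > 0, , drop = FALSE]
  tallies <- tallies[order(tallies$plot_id, tallies$species), , drop = FALSE]
  rownames(tallies) <- NULL

  structure(list(
    config = config, env = env, extent = extent, plots = plots,
    lattice = lattice, assignment = asg,
    cell_covariates = cell_covariates, forest_fraction = forest_fraction,
    tallies = tallies,
    intended_iv = data.frame(plot_id = plots$plot_id, intended,
                             stringsAsFactors = FALSE, check.names = FALSE),
    species = species
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `plots.csv`, `tallies.csv`, `covariates.csv`,
#' `forest_fraction.csv`, `extent.csv` (boundary vertices) and
#' `truth.json` (ground-truth niche parameters) into `dir`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE, quote = FALSE)
  w(dataset$plots, "plots.csv")
  w(dataset$tallies, "tallies.csv")
  w(dataset$cell_covariates, "covariates.csv")
  w(data.frame(cell_id = names(dataset$forest_fraction),
               forest_fraction = as.numeric(dataset$forest_fraction)),
    "forest_fraction.csv")
  w(as.data.frame(dataset$extent$boundary), "extent.csv")
  truth <- lapply(dataset$species, function(sp) {
    list(name = sp$name, optima = as.list(sp$optima),
         breadths = sp$breadths, max_iv = sp$max_iv,
         occupancy_threshold = sp$occupancy_threshold,
         noise_sd = sp$noise_sd)
  })
  jsonlite::write_json(list(seed = dataset$config$seed, species = truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
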