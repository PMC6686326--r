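# Density-adaptive hybrid lattice: uniform gridding of a study extent,
# point-in-cell plot counts, and refinement of coarse cells into four fine
# quadrants where plot density supports the finer grain.

#' Define a study extent
#'
#' A study extent is a planar polygon (projected coordinates, meters) plus a
#' lower-left origin that anchors all grids built over it, so that cell
#' boundaries are reproducible regardless of the polygon's exact vertices.
#'
#' @param boundary Two-column matrix or data frame of polygon vertices
#'   (x, y in meters). The ring need not be closed.
#' @param origin Optional numeric length-2 lower-left anchor `(x0, y0)`;
#'   defaults to the bounding-box minimum. Must lie at or below/left of every
#'   vertex.
#' @return An object of class `study_extent` with elements `boundary` and
#'   `origin`.
#' @examples
#' ext <- study_extent(cbind(c(0, 40000, 40000, 0), c(0, 0, 40000, 40000)))
#' @export
study_extent <- function(boundary, origin = NULL) {
  boundary <- as.matrix(boundary)
  if (!is.numeric(boundary) || ncol(boundary) != 2 || nrow(boundary) < 3 ||
      anyNA(boundary) || any(!is.finite(boundary))) {
    stop("empty-extent: boundary must be a finite numeric polygon with >= 3 vertices")
  }
  colnames(boundary) <- c("x", "y")
  if (polygon_area(boundary) <= 0) {
    stop("empty-extent: boundary polygon has zero area")
  }
  if (is.null(origin)) {
    origin <- c(min(boundary[, 1]), min(boundary[, 2]))
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2 || anyNA(origin) ||
      origin[1] > min(boundary[, 1]) || origin[2] > min(boundary[, 2])) {
    stop("origin must be a finite (x0, y0) at or below/left of the boundary")
  }
  structure(list(boundary = boundary, origin = origin), class = "study_extent")
}

#' Convenience rectangular extent
#'
#' @param width_m,height_m Extent dimensions in meters.
#' @param origin Lower-left corner, default `c(0, 0)`.
#' @return A `study_extent`.
#' @export
rectangular_extent <- function(width_m, height_m, origin = c(0, 0)) {
  stopifnot(width_m > 0, height_m > 0)
  x0 <- origin[1]; y0 <- origin[2]
  study_extent(cbind(c(x0, x0 + width_m, x0 + width_m, x0),
                     c(y0, y0, y0 + height_m, y0 + height_m)),
               origin = origin)
}

# Shoelace area of a polygon given as an (open or closed) vertex matrix.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of a polygon to an axis-aligned rectangle; returns
# the clipped vertex matrix (possibly 0 rows).
clip_polygon_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_half <- function(p, inside, intersect) {
    n <- nrow(p)
    if (n == 0) return(p)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- p[i, ]; prv <- p[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(a, b, val, axis) {
    # intersection of segment a-b with the line {axis coordinate == val}
    t <- (val - a[axis]) / (b[axis] - a[axis])
    a + t * (b - a)
  }
  p <- poly
  p <- clip_half(p, function(v) v[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip_half(p, function(v) v[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip_half(p, function(v) v[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip_half(p, function(v) v[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}

# Does the open rectangle share positive area with the polygon?
rect_intersects_polygon <- function(poly, xmin, ymin, xmax, ymax) {
  clipped <- clip_polygon_rect(poly, xmin, ymin, xmax, ymax)
  if (nrow(clipped) < 3) return(FALSE)
  polygon_area(clipped) > 1e-9 * (xmax - xmin) * (ymax - ymin)
}

lattice_cell_id <- function(level, row, col) {
  sprintf("L%s_%d_%d", level, row, col)
}

#' Build a uniform lattice over a study extent
#'
#' Grid cells are axis-aligned squares of side `cell_size_m`, anchored at the
#' extent origin and stepping by the cell size. Every cell whose rectangle
#' shares positive area with the extent polygon is retained whole (edge cells
#' are not clipped). Cell ids are deterministic functions of the row/column
#' indices, `L<level>_<row>_<col>`, rows and columns counted from the origin
#' starting at 1.
#'
#' @param extent A `study_extent`.
#' @param cell_size_m Cell side length in meters (> 0).
#' @param level Label for the cells, `"coarse"` or `"fine"`.
#' @return A data frame of cells with columns `cell_id`, `level`, `row`,
#'   `col`, `xmin`, `ymin`, `xmax`, `ymax`, `parent_id`, `area_km2`, carrying
#'   attributes `origin` and `cell_size` used for fast point-in-cell lookup.
#' @examples
#' ext <- rectangular_extent(40000, 40000)
#' nrow(build_uniform_lattice(ext, 20000))  # 4
#' @export
build_uniform_lattice <- function(extent, cell_size_m,
                                  level = c("coarse", "fine")) {
  stopifnot(inherits(extent, "study_extent"), cell_size_m > 0)
  level <- match.arg(level)
  b <- extent$boundary
  x0 <- extent$origin[1]; y0 <- extent$origin[2]
  s <- cell_size_m
  ncols <- ceiling((max(b[, 1]) - x0) / s)
  nrows <- ceiling((max(b[, 2]) - y0) / s)
  grid <- expand.grid(col = seq_len(ncols), row = seq_len(nrows))
  xmin <- x0 + (grid$col - 1) * s
  ymin <- y0 + (grid$row - 1) * s
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    rect_intersects_polygon(b, xmin[i], ymin[i], xmin[i] + s, ymin[i] + s)
  }, logical(1))
  if (!any(keep)) stop("empty-extent: no grid cell intersects the boundary")
  cells <- data.frame(
    cell_id = lattice_cell_id(level, grid$row[keep], grid$col[keep]),
    level = level,
    row = grid$row[keep],
    col = grid$col[keep],
    xmin = xmin[keep],
    ymin = ymin[keep],
    xmax = xmin[keep] + s,
    ymax = ymin[keep] + s,
    parent_id = NA_character_,
    area_km2 = s^2 / 1e6,
    stringsAsFactors = FALSE
  )
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "origin") <- c(x0, y0)
  attr(cells, "cell_size") <- s
  cells
}

#' Assign inventory plots to lattice cells
#'
#' Cell membership uses half-open bounds `[xmin, xmax) x [ymin, ymax)` so a
#' plot lying exactly on a shared edge is counted once, in the cell whose
#' half-open interval contains it. Plots falling outside every cell are
#' reported as unassigned, not counted.
#'
#' @param cells Cell data frame (from [build_uniform_lattice()] or the
#'   `cells` element of a [refine_lattice()] result); cells must not overlap.
#' @param plots Data frame with columns `plot_id`, `x`, `y` (meters);
#'   `plot_id` must be unique.
#' @return A list with `counts` (named integer vector over all cell ids),
#'   `assignment` (data frame `plot_id`, `cell_id` for assigned plots) and
#'   `unassigned` (character vector of plot ids outside the lattice).
#' @export
assign_plots <- function(cells, plots) {
  stopifnot(all(c("plot_id", "x", "y") %in% names(plots)))
  if (anyDuplicated(plots$plot_id)) {
    stop("duplicate-plot: plot_id values must be unique (",
         paste(unique(plots$plot_id[duplicated(plots$plot_id)]), collapse = ", "),
         ")")
  }
  if (anyNA(plots$x) || anyNA(plots$y) ||
      any(!is.finite(plots$x)) || any(!is.finite(plots$y))) {
    stop("plot coordinates must be finite")
  }
  n <- nrow(plots)
  cell_of <- rep(NA_character_, n)
  origin <- attr(cells, "origin")

  # Fast path for grid-aligned levels: derive the candidate id from indices.
  if (!is.null(origin) && all(c("level", "row", "col") %in% names(cells))) {
    for (lev in unique(cells$level)) {
      sub <- cells[cells$level == lev, , drop = FALSE]
      s <- unique(round(sub$xmax - sub$xmin, 6))
      if (length(s) != 1) next
      todo <- which(is.na(cell_of))
      if (!length(todo)) break
      col <- floor((plots$x[todo] - origin[1]) / s) + 1
      row <- floor((plots$y[todo] - origin[2]) / s) + 1
      cand <- lattice_cell_id(lev, row, col)
      hit <- cand %in% sub$cell_id
      cell_of[todo[hit]] <- cand[hit]
    }
  }

  # Generic fallback for arbitrary (non-indexed) cell collections.
  todo <- which(is.na(cell_of))
  if (length(todo)) {
    for (i in seq_len(nrow(cells))) {
      if (!length(todo)) break
      inside <- plots$x[todo] >= cells$xmin[i] & plots$x[todo] < cells$xmax[i] &
        plots$y[todo] >= cells$ymin[i] & plots$y[todo] < cells$ymax[i]
      cell_of[todo[inside]] <- cells$cell_id[i]
      todo <- todo[!inside]
    }
  }

  assigned <- !is.na(cell_of)
  counts <- table(factor(cell_of[assigned], levels = cells$cell_id))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(
    counts = counts,
    assignment = data.frame(plot_id = plots$plot_id[assigned],
                            cell_id = cell_of[assigned],
                            stringsAsFactors = FALSE),
    unassigned = plots$plot_id[!assigned]
  )
}

#' Refine a coarse lattice into a hybrid lattice by plot density
#'
#' Each coarse cell is inspected through its four fine quadrants: if the
#' fraction of quadrants holding at least `min_plots` plots reaches
#' `min_fraction`, the coarse cell is replaced by its four fine children;
#' otherwise it is retained whole. With the defaults (two or more plots in at
#' least 50% of the quadrants) this is the published acceptance rule for
#' 10-km cells inside a 20-km cell. With exactly two grid levels a single
#' pass over the coarse cells suffices; `depth` is reserved for deeper
#' nesting and only `depth = 1` is currently supported.
#'
#' @param coarse_cells Coarse cells from [build_uniform_lattice()].
#' @param plots Plot data frame (`plot_id`, `x`, `y`).
#' @param min_plots Minimum plots a quadrant needs to count as sampled
#'   (default 2).
#' @param min_fraction Minimum fraction of sampled quadrants required to
#'   subdivide (default 0.5).
#' @param depth Refinement depth; only 1 is supported.
#' @return An object of class `hybrid_lattice`: list with `cells` (data
#'   frame mixing retained coarse cells and fine children, each fine cell
#'   carrying its `parent_id`), `fine_size_m`, `coarse_size_m`, `origin`.
#' @export
refine_lattice <- function(coarse_cells, plots, min_plots = 2,
                           min_fraction = 0.5, depth = 1) {
  stopifnot(min_plots >= 1, min_fraction > 0, min_fraction <= 1)
  if (depth != 1) stop("unsupported-depth: only one level of refinement is implemented")
  origin <- attr(coarse_cells, "origin")
  if (is.null(origin)) stop("coarse_cells must come from build_uniform_lattice()")
  s <- attr(coarse_cells, "cell_size")
  fine_s <- s / 2

  asg <- assign_plots(coarse_cells, plots)
  by_cell <- split(asg$assignment$plot_id, asg$assignment$cell_id)
  px <- stats::setNames(plots$x, plots$plot_id)
  py <- stats::setNames(plots$y, plots$plot_id)

  keep <- list(); children <- list()
  for (i in seq_len(nrow(coarse_cells))) {
    cc <- coarse_cells[i, ]
    ids <- by_cell[[cc$cell_id]]
    xmid <- cc$xmin + fine_s
    ymid <- cc$ymin + fine_s
    if (length(ids)) {
      qx <- as.integer(px[ids] >= xmid)  # 0 = west, 1 = east
      qy <- as.integer(py[ids] >= ymid)  # 0 = south, 1 = north
      qcounts <- table(factor(qx + 2 * qy, levels = 0:3))
    } else {
      qcounts <- rep(0L, 4)
    }
    if (sum(qcounts >= min_plots) / 4 >= min_fraction) {
      # replace by the four fine children, indexed on the global fine grid
      frow <- 2 * (cc$row - 1) + rep(1:2, each = 2)
      fcol <- 2 * (cc$col - 1) + rep(1:2, times = 2)
      kid <- data.frame(
        cell_id = lattice_cell_id("fine", frow, fcol),
        level = "fine",
        row = frow,
        col = fcol,
        xmin = cc$xmin + (fcol - 2 * (cc$col - 1) - 1) * fine_s,
        ymin = cc$ymin + (frow - 2 * (cc$row - 1) - 1) * fine_s,
        xmax = NA_real_, ymax = NA_real_,
        parent_id = cc$cell_id,
        area_km2 = fine_s^2 / 1e6,
        stringsAsFactors = FALSE
      )
      kid$xmax <- kid$xmin + fine_s
      kid$ymax <- kid$ymin + fine_s
      children[[length(children) + 1]] <- kid
    } else {
      keep[[length(keep) + 1]] <- cc
    }
  }
  cells <- rbind(
    if (length(keep)) do.call(rbind, keep),
    if (length(children)) do.call(rbind, children)
  )
  cells <- cells[order(cells$level, cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "origin") <- origin
  attr(cells, "cell_size") <- NULL
  structure(list(cells = cells, fine_size_m = fine_s, coarse_size_m = s,
                 origin = origin),
            class = "hybrid_lattice")
}

#' @export
print.hybrid_lattice <- function(x, ...) {
  n_fine <- sum(x$cells$level == "fine")
  n_coarse <- sum(x$cells$level == "coarse")
  cat(sprintf(
    "Hybrid lattice: %d cells (%d fine %.0f km, %d coarse %.0f km), %.0f km2 total\n",
    nrow(x$cells), n_fine, x$fine_size_m / 1000, n_coarse,
    x$coarse_size_m / 1000, sum(x$cells$area_km2)))
  invisible(x)
}
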