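# Uniform gridding, plot assignment, and density-driven refinement.

test_that("uniform lattices tile rectangular extents and keep edge cells", {
  ext <- rectangular_extent(40000, 40000)
  expect_equal(nrow(build_uniform_lattice(ext, 20000)), 4)
  expect_equal(nrow(build_uniform_lattice(ext, 10000, "fine")), 16)
  # 25 x 25 km: edge cells partially outside are retained because they
  # share area with the extent
  expect_equal(nrow(build_uniform_lattice(rectangular_extent(25000, 25000),
                                          20000)), 4)
  cells <- build_uniform_lattice(ext, 20000)
  expect_equal(cells$cell_id,
               c("Lcoarse_1_1", "Lcoarse_1_2", "Lcoarse_2_1", "Lcoarse_2_2"))
  expect_true(all(cells$area_km2 == 400))
})

test_that("gridding a non-rectangular polygon keeps only intersecting cells", {
  # L-shape: full 40x40 square minus its upper-right 20x20 quadrant
  ell <- study_extent(cbind(c(0, 40000, 40000, 20000, 20000, 0),
                            c(0, 0, 20000, 20000, 40000, 40000)))
  cells <- build_uniform_lattice(ell, 20000)
  expect_equal(sort(cells$cell_id),
               c("Lcoarse_1_1", "Lcoarse_1_2", "Lcoarse_2_1"))
})

test_that("degenerate extents are rejected", {
  expect_error(study_extent(cbind(c(0, 1, 2), c(0, 0, 0))), "empty-extent")
  expect_error(study_extent(cbind(c(0, 1), c(0, 1))), "empty-extent")
})

test_that("plots are assigned once via half-open cell bounds", {
  ext <- rectangular_extent(40000, 40000)
  cells <- build_uniform_lattice(ext, 20000)
  plots <- data.frame(
    plot_id = c("edge", "in1", "in2", "in3", "out"),
    x = c(20000, 5000, 6000, 7000, 90000),  # "edge" on the shared boundary
    y = c(10000, 5000, 6000, 7000, 5000))
  res <- assign_plots(cells, plots)
  expect_equal(sum(res$counts), 4)                 # edge counted exactly once
  expect_equal(unname(res$counts["Lcoarse_1_2"]), 1)  # in the right-hand cell
  expect_equal(unname(res$counts["Lcoarse_1_1"]), 3)
  expect_equal(res$unassigned, "out")
  expect_error(assign_plots(cells, rbind(plots, plots[1, ])),
               "duplicate-plot")
})

test_that("refinement follows the quadrant threshold rule", {
  ext <- rectangular_extent(20000, 20000)
  coarse <- build_uniform_lattice(ext, 20000)
  quad_plot <- function(qx, qy, k) {
    data.frame(x = qx * 10000 + seq_len(k) * 100,
               y = qy * 10000 + seq_len(k) * 100)
  }
  mk <- function(counts) {
    pts <- do.call(rbind, lapply(0:3, function(q) {
      if (counts[q + 1] == 0) return(NULL)
      quad_plot(q %% 2, q %/% 2, counts[q + 1])
    }))
    cbind(plot_id = sprintf("p%d", seq_len(nrow(pts))), pts)
  }
  # 2/4 quadrants sampled -> exactly at the 50% threshold -> subdivide
  hy <- refine_lattice(coarse, mk(c(2, 2, 0, 0)))
  expect_equal(sum(hy$cells$level == "fine"), 4)
  expect_equal(unique(hy$cells$parent_id), "Lcoarse_1_1")
  # 1/4 quadrants sampled -> retain the coarse cell
  hy2 <- refine_lattice(coarse, mk(c(3, 1, 1, 1)))
  expect_equal(hy2$cells$level, "coarse")
  # all quadrants sampled -> four fine children replace the parent
  hy3 <- refine_lattice(coarse, mk(c(2, 2, 2, 2)))
  expect_equal(nrow(hy3$cells), 4)
  expect_true(all(hy3$cells$level == "fine"))
  expect_true(all(hy3$cells$area_km2 == 100))
})

test_that("hybrid lattices conserve area and plot counts", {
  set.seed(42)
  for (rep in 1:5) {
    ext <- rectangular_extent(120000, 120000)
    coarse <- build_uniform_lattice(ext, 20000)
    n <- sample(50:200, 1)
    plots <- data.frame(plot_id = sprintf("p%03d", 1:n),
                        x = runif(n, 0, 120000), y = runif(n, 0, 120000))
    hy <- refine_lattice(coarse, plots)
    # children exactly partition parents
    expect_equal(sum(hy$cells$area_km2), sum(coarse$area_km2))
    # every assigned plot is counted exactly once on the hybrid lattice
    res <- assign_plots(hy$cells, plots)
    expect_equal(sum(res$counts), n - length(res$unassigned))
    expect_equal(length(res$unassigned), 0)
  }
})

test_that("refinement is monotone in the plot set", {
  set.seed(7)
  ext <- rectangular_extent(60000, 60000)
  coarse <- build_uniform_lattice(ext, 20000)
  n <- 60
  plots <- data.frame(plot_id = sprintf("p%03d", 1:n),
                      x = runif(n, 0, 60000), y = runif(n, 0, 60000))
  hy1 <- refine_lattice(coarse, plots)
  sub1 <- unique(hy1$cells$parent_id[!is.na(hy1$cells$parent_id)])
  extra <- data.frame(plot_id = sprintf("q%03d", 1:40),
                      x = runif(40, 0, 60000), y = runif(40, 0, 60000))
  hy2 <- refine_lattice(coarse, rbind(plots, extra))
  sub2 <- unique(hy2$cells$parent_id[!is.na(hy2$cells$parent_id)])
  expect_true(all(sub1 %in% sub2))
  # with min_plots 1 and a vanishing fraction, any coarse cell holding a
  # plot subdivides
  hy3 <- refine_lattice(coarse, plots, min_plots = 1, min_fraction = 1e-9)
  occupied <- names(which(assign_plots(coarse, plots)$counts > 0))
  sub3 <- unique(hy3$cells$parent_id[!is.na(hy3$cells$parent_id)])
  expect_setequal(sub3, occupied)
})

test_that("refinement matches the quadrant-enumeration oracle", {
  set.seed(123)
  for (rep in 1:20) {
    ext <- rectangular_extent(120000, 120000)  # 6 x 6 coarse cells
    coarse <- build_uniform_lattice(ext, 20000)
    n <- sample(20:200, 1)
    plots <- data.frame(plot_id = sprintf("p%03d", 1:n),
                        x = runif(n, 0, 120000), y = runif(n, 0, 120000))
    hy <- refine_lattice(coarse, plots)
    oracle <- refine_bruteforce(coarse, plots)
    sub <- unique(hy$cells$parent_id[!is.na(hy$cells$parent_id)])
    expect_setequal(sub, names(which(oracle)))
    retained <- hy$cells$cell_id[hy$cells$level == "coarse"]
    expect_setequal(retained, names(which(!oracle)))
  }
})
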