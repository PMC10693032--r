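test_that("orthogonal two-type design projects exactly", {
  panel <- generate_reference_panel(K = 2, markers_per_type = 1, contrast = 1,
                                    jitter_sd = 0)
  bulk <- matrix(c(0.3, 0.7), 1, dimnames = list("s1", panel$cpg_ids))
  comp <- estimate_composition(bulk, panel, min_overlap = 2)
  expect_equal(unname(comp$values[1, ]), c(0.3, 0.7), tolerance = 1e-9)
})

test_that("noise-free mixtures are recovered and noisy ones nearly so", {
  panel <- generate_reference_panel(seed = 7)
  sim <- generate_cohort(40, seed = 7, noise_sd = 0)
  bulk <- mix_bulk(panel, sim$truth)
  comp <- estimate_composition(bulk, panel)
  expect_lt(max(abs(comp$values - sim$truth$compositions)), 1e-6)

  sim$truth$noise_sd <- 0.02
  bulk <- mix_bulk(panel, sim$truth)
  comp <- estimate_composition(bulk, panel)
  expect_lt(mean(abs(comp$values - sim$truth$compositions)), 0.02)
})

test_that("solutions stay on the simplex even off the mixing cone", {
  panel <- generate_reference_panel(K = 2, markers_per_type = 3,
                                    contrast = 0.6, seed = 3)
  b <- pmin(1.2 * panel$values[, 1], 1)
  bulk <- matrix(b, 1, dimnames = list("s1", panel$cpg_ids))
  comp <- estimate_composition(bulk, panel, min_overlap = 2)
  expect_true(all(comp$values >= 0))
  expect_equal(sum(comp$values), 1, tolerance = 1e-10)
})

test_that("constrained projection matches the simplex grid-search oracle", {
  set.seed(21)
  panel <- generate_reference_panel(K = 3, markers_per_type = 2,
                                    contrast = 0.7, seed = 21)
  R <- panel$values
  W <- runif_simplex(3, 3)
  Btrue <- W %*% t(R) + matrix(rnorm(3 * nrow(R), 0, 0.01), 3)
  Btrue <- pmin(pmax(Btrue, 0), 1)
  colnames(Btrue) <- panel$cpg_ids
  comp <- estimate_composition(Btrue, panel, constraint = "sum_to_one",
                               min_overlap = 3)
  for (i in 1:3) {
    oracle <- grid_search_simplex(R, Btrue[i, ], step = 1e-3)
    expect_lt(max(abs(comp$values[i, ] - oracle)), 2e-3)
  }
})

test_that("permuting panel columns permutes the output identically", {
  panel <- generate_reference_panel(K = 4, markers_per_type = 5,
                                    contrast = 0.6, seed = 9,
                                    cell_types = c("a", "b", "c", "d"))
  truth <- structure(list(compositions = runif_simplex(5, 4), noise_sd = 0.01,
                          seed = 2L), class = "ground_truth")
  bulk <- mix_bulk(panel, truth)
  c1 <- estimate_composition(bulk, panel, min_overlap = 4)
  perm <- c(3, 1, 4, 2)
  panel_p <- panel
  panel_p$values <- panel$values[, perm]
  panel_p$cell_types <- panel$cell_types[perm]
  c2 <- estimate_composition(bulk, panel_p, min_overlap = 4)
  expect_equal(c1$values[, perm], c2$values, tolerance = 1e-10)
})

test_that("CpG alignment is order-insensitive and guarded", {
  panel <- generate_reference_panel(K = 3, markers_per_type = 4,
                                    contrast = 0.6, seed = 5)
  truth <- structure(list(compositions = runif_simplex(4, 3), noise_sd = 0,
                          seed = 1L), class = "ground_truth")
  bulk <- mix_bulk(panel, truth)
  shuffled <- bulk$values[, sample(ncol(bulk$values)), drop = FALSE]
  c1 <- estimate_composition(bulk$values, panel, min_overlap = 3)
  c2 <- estimate_composition(shuffled, panel, min_overlap = 3)
  expect_equal(c1$values, c2$values, tolerance = 1e-12)
  # too few shared CpGs
  few <- bulk$values[, 1:2, drop = FALSE]
  expect_error(estimate_composition(few, panel, min_overlap = 3), "shared CpGs")
  # below the minimum-overlap threshold
  expect_error(estimate_composition(bulk$values[, 1:5], panel,
                                    min_overlap = 10), "minimum overlap")
})

test_that("multiplicative zero replacement follows the replacement formula", {
  expect_equal(drop(replace_zeros(matrix(c(0.5, 0.5, 0), 1), delta = 0.01)),
               c(0.495, 0.495, 0.01))
  out <- drop(replace_zeros(matrix(c(0.6, 0.4, 0, 0), 1), delta = 0.01))
  expect_equal(out, c(0.588, 0.392, 0.01, 0.01))
  expect_equal(out[1] / out[2], 0.6 / 0.4, tolerance = 1e-15)
  # rows without zeros come back identical
  x <- matrix(c(0.2, 0.3, 0.5), 1)
  expect_identical(replace_zeros(x, delta = 0.01), x)
})

test_that("zero replacement preserves ratios and exact unit sums", {
  set.seed(12)
  W <- runif_simplex(20, 5)
  W[cbind(1:20, sample(5, 20, replace = TRUE))] <- 0
  W <- W / rowSums(W)
  out <- replace_zeros(W, delta = 1e-3)
  expect_true(all(out >= 1e-3))
  expect_lt(max(abs(rowSums(out) - 1)), 1e-10)
  for (i in 1:20) {
    nz <- W[i, ] > 0
    r0 <- W[i, nz] / sum(W[i, nz])
    r1 <- out[i, nz] / sum(out[i, nz])
    expect_equal(r0, r1, tolerance = 1e-14)
  }
})

test_that("zero replacement rejects bad delta and degenerate rows", {
  x <- matrix(c(0.5, 0.5, 0), 1)
  expect_error(replace_zeros(x, delta = 0), "delta")
  expect_error(replace_zeros(x, delta = 0.4), "delta")
  expect_error(replace_zeros(matrix(0, 1, 3), delta = 0.01), "all-zero")
})
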