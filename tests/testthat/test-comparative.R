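# Matrix-form second-order Taylor moments, as an independent check of
# the closed-form implementation.
taylor_matrix_oracle <- function(mx, my, vx, vy, cv) {
  g <- c(1 / my, -mx / my^2)
  H <- matrix(c(0, -1 / my^2, -1 / my^2, 2 * mx / my^3), 2, 2)
  S <- matrix(c(vx, cv, cv, vy), 2, 2)
  HS <- H %*% S
  list(expected = mx / my + 0.5 * sum(diag(HS)),
       variance = drop(t(g) %*% S %*% g) + 0.5 * sum(diag(HS %*% HS)))
}

test_that("log2-difference propagation is exact", {
  pr <- taylor_propagate(3.2, 1.1, 0.4, 0.3, 0.1, "log2_difference")
  expect_equal(pr$expected, 2.1)
  expect_equal(pr$variance, 0.4 + 0.3 - 0.2)
  # zero uncertainty collapses to the plug-in value
  pr0 <- taylor_propagate(10, 5, 0, 0, 0, "linear_ratio")
  expect_equal(pr0$expected, 2)
  expect_equal(pr0$variance, 0)
  expect_error(taylor_propagate(1, 0, 1, 1, 0, "linear_ratio"),
               "nonzero")
  expect_error(taylor_propagate(1, 2, 1, 1, 5), "cov")
})

test_that("linear-ratio closed forms match the matrix formulas", {
  cases <- list(c(10, 5, 1, 0.25, 0),
                c(10, 5, 1, 0.25, 0.3),
                c(-4, 2, 0.2, 0.1, -0.05),
                c(7, -3, 0.5, 0.05, 0))
  for (cs in cases) {
    pr <- taylor_propagate(cs[1], cs[2], cs[3], cs[4], cs[5],
                           "linear_ratio")
    or <- taylor_matrix_oracle(cs[1], cs[2], cs[3], cs[4], cs[5])
    expect_equal(pr$expected, or$expected, tolerance = 1e-12)
    expect_equal(pr$variance, or$variance, tolerance = 1e-12)
  }
  # the spec'd worked example
  pr <- taylor_propagate(10, 5, 1, 0.25, 0, "linear_ratio")
  expect_equal(pr$expected, 2.02, tolerance = 1e-9)
  expect_equal(pr$variance, 0.0812, tolerance = 1e-9)
})

test_that("exact-moment draws have the requested sample statistics", {
  for (s in c(1, 7, 23)) {
    x <- empirical_mvn(3, mean = 0.7, sd = 0.31, seed = s)
    expect_equal(mean(x), 0.7, tolerance = 1e-12)
    expect_equal(sd(x), 0.31, tolerance = 1e-12)
    # the ordinary t of the draw is fully determined by the moments
    expect_equal(unname(t.test(x)$statistic), 0.7 / (0.31 / sqrt(3)),
                 tolerance = 1e-9)
  }
  expect_equal(empirical_mvn(3, 2, 0), c(2, 2, 2))
  # same property as MASS::mvrnorm(empirical = TRUE)
  y <- drop(MASS::mvrnorm(5, mu = 1.5, Sigma = matrix(0.25),
                          empirical = TRUE))
  expect_equal(mean(y), 1.5, tolerance = 1e-9)
  expect_equal(sd(y), 0.5, tolerance = 1e-9)
  x <- empirical_mvn(5, 1.5, 0.5, seed = 2)
  expect_equal(c(mean(x), sd(x)), c(mean(y), sd(y)), tolerance = 1e-9)
})

test_that("rescaling centers shifts over the crosslinked mask", {
  rs <- rescale_shifts(c(1, 2, 3), rep(TRUE, 3))
  expect_equal(rs$constant, -2)
  expect_equal(rs$shifts, c(-1, 0, 1))
  sub <- rescale_shifts(c(1, 2, 9), c(TRUE, TRUE, FALSE))
  expect_equal(sub$constant, -1.5)
  expect_equal(sub$shifts, c(-0.5, 0.5, 7.5))
  # idempotent, and a no-op when already centered
  again <- rescale_shifts(sub$shifts, c(TRUE, TRUE, FALSE))
  expect_equal(again$constant, 0)
  expect_equal(mean(sub$shifts[1:2]), 0, tolerance = 1e-12)
  expect_error(rescale_shifts(1:3, rep(FALSE, 3)), "crosslinked")
})

test_that("comparing a table with itself yields zero shifts and p = 1", {
  sim <- generate_experiment(sim_config(n_proteins = 60,
                                        batches = "B1",
                                        nocl_batches = character(0)),
                             seed = 3)
  tab <- median_normalize(impute_background(sim$table))
  mut <- tab
  mut$meta$genotype <- "mut"
  mut$meta$sample_id <- sub("WT", "mut", mut$meta$sample_id)
  colnames(mut$values) <- mut$meta$sample_id
  colnames(mut$imputed) <- mut$meta$sample_id
  sh <- compare_ric(tab, mut)
  expect_equal(sh$shift, rep(0, nrow(sh)))
  expect_equal(sh$p, rep(1, nrow(sh)))
  expect_true(all(sh$se_shift > 0))
})

test_that("comparative inference is invariant to the pseudo-replicate seed", {
  pair <- generate_mutant_pair(
    sim_config(n_proteins = 150, sigma_rep = 0.3),
    list(protein_ids = sprintf("P%05d", 1:10), delta = 1), seed = 4)
  wt <- median_normalize(impute_background(pair$wt))
  mut <- median_normalize(impute_background(pair$mut))
  ref <- compare_ric(wt, mut, seed = 101)
  for (s in c(1, 2, 3)) {
    alt <- compare_ric(wt, mut, seed = s)
    expect_equal(alt$p, ref$p, tolerance = 1e-9)
    expect_equal(alt$t_mod, ref$t_mod, tolerance = 1e-9)
    expect_equal(alt$shift, ref$shift, tolerance = 1e-12)
  }
})

test_that("same-complex proteins with equal delta co-shift more tightly as noise vanishes", {
  spread <- sapply(c(0.3, 0.05), function(sg) {
    cfg <- sim_config(n_proteins = 100, n_complexes = 10,
                      complex_size_mean = 6, sigma_rep = sg,
                      sigma_cplx = 0, detection_limit = -Inf)
    pair <- generate_mutant_pair(cfg, list(complex_ids = "C001",
                                           delta = 1), seed = 6)
    wt <- median_normalize(impute_background(pair$wt))
    mut <- median_normalize(impute_background(pair$mut))
    sh <- compare_ric(wt, mut)
    aff <- pair$truth$protein_id[!is.na(pair$truth$complex_id) &
                                   pair$truth$complex_id == "C001"]
    sd(sh$shift[sh$protein_id %in% aff])
  })
  expect_lt(spread[2], spread[1])
})

test_that("proteins absent from one table are aligned and flagged", {
  simA <- generate_experiment(sim_config(n_proteins = 30, batches = "B1",
                                         nocl_batches = character(0)),
                              seed = 9)
  tabA <- median_normalize(impute_background(simA$table))
  tabB <- tabA
  tabB$meta$genotype <- "mut"
  tabB$meta$sample_id <- sub("WT", "mut", tabB$meta$sample_id)
  colnames(tabB$values) <- tabB$meta$sample_id
  colnames(tabB$imputed) <- tabB$meta$sample_id
  tabB$values <- tabB$values[-(1:3), ]
  tabB$imputed <- tabB$imputed[-(1:3), ]
  sh <- compare_ric(tabA, tabB)
  expect_equal(nrow(sh), 30L)
  dropped <- rownames(tabA$values)[1:3]
  expect_true(all(!sh$detected_in_mutant[sh$protein_id %in% dropped]))
})
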