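noise_free <- function(...) {
  sim_config(n_proteins = 50, n_complexes = 5, sigma_rep = 0,
             sigma_cplx = 0, batch_effect_sd = 0,
             detection_limit = -Inf, ...)
}

test_that("the model collapses when phi = kappa = C = 1 and beta = 0", {
  cfg <- noise_free(phi_fixed = 1, kappa_fixed = 1, capture_eff = 1,
                    nocl_background = 0)
  sim <- generate_experiment(cfg, seed = 1)
  tab <- sim$table
  ric <- tab$values[, samples_for(tab, "RIC")]
  wce <- tab$values[, samples_for(tab, "WCE")]
  expect_equal(unname(ric), unname(wce))
  nocl <- tab$values[, samples_for(tab, "noCL")]
  expect_true(all(is.na(nocl)))
})

test_that("the generator is deterministic for a fixed config and seed", {
  cfg <- sim_config(n_proteins = 100)
  a <- generate_experiment(cfg, seed = 7)
  b <- generate_experiment(cfg, seed = 7)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth, b$truth)
  c <- generate_experiment(cfg, seed = 8)
  expect_false(identical(a$table$values, c$table$values))
})

test_that("no emitted value falls below the detection limit", {
  for (s in 1:5) {
    sim <- generate_experiment(sim_config(n_proteins = 200), seed = s)
    v <- sim$table$values
    expect_true(all(v[!is.na(v)] >= 18))
  }
  # a limit above everything censors the whole table
  hi <- generate_experiment(sim_config(n_proteins = 50,
                                       detection_limit = 1e6), seed = 1)
  expect_true(all(is.na(hi$table$values)))
})

test_that("raising phi raises RIC and leaves WCE unchanged", {
  lo <- generate_experiment(noise_free(phi_fixed = 0.25), seed = 3)
  hi <- generate_experiment(noise_free(phi_fixed = 0.5), seed = 3)
  ric_lo <- lo$table$values[, samples_for(lo$table, "RIC")]
  ric_hi <- hi$table$values[, samples_for(hi$table, "RIC")]
  expect_true(all(ric_hi > ric_lo))
  expect_equal(ric_hi - ric_lo,
               matrix(1, nrow(ric_lo), ncol(ric_lo),
                      dimnames = dimnames(ric_lo)))
  expect_identical(lo$table$values[, samples_for(lo$table, "WCE")],
                   hi$table$values[, samples_for(hi$table, "WCE")])
})

test_that("a mutant pair shares truth and applies delta multiplicatively", {
  cfg <- noise_free()
  pair0 <- generate_mutant_pair(cfg, list(delta = 0), seed = 2)
  expect_identical(unname(pair0$wt$values), unname(pair0$mut$values))
  # phi = 0.25 keeps 2^delta * phi below the clip at 1
  cfgf <- noise_free(phi_fixed = 0.25)
  pair0f <- generate_mutant_pair(cfgf, list(delta = 0), seed = 2)
  cplx <- unique(na.omit(pair0f$truth$complex_id))[1]
  pair <- generate_mutant_pair(cfgf,
                               list(complex_ids = cplx, delta = 1),
                               seed = 2)
  aff <- pair$truth$protein_id[!is.na(pair$truth$complex_id) &
                                 pair$truth$complex_id == cplx]
  dr <- pair$mut$values[, samples_for(pair$mut, "RIC")] -
    pair$wt$values[, samples_for(pair$wt, "RIC")]
  expect_equal(unique(as.vector(round(dr[aff, ], 10))), 1)
  expect_true(all(dr[setdiff(rownames(dr), aff), ] == 0))
  dw <- pair$mut$values[, samples_for(pair$mut, "WCE")] -
    pair$wt$values[, samples_for(pair$wt, "WCE")]
  expect_true(all(dw == 0))
  # phi is clipped at 1
  clip <- generate_mutant_pair(noise_free(phi_fixed = 0.9),
                               list(complex_ids = cplx, delta = 1),
                               seed = 2)
  expect_true(all(clip$truth$bound_fraction_mut <= 1))
  expect_true(all(pair$truth$bound_fraction_mut <= 1))
  expect_error(generate_mutant_pair(cfg, list(protein_ids = "nope",
                                              delta = 1), seed = 1),
               "unknown protein")
})

test_that("pipeline shifts on a zero-noise pair equal delta exactly", {
  cfg <- noise_free(phi_fixed = 0.25)
  cplx <- "C001"
  pair <- generate_mutant_pair(cfg, list(complex_ids = cplx, delta = 1),
                               seed = 5)
  wt <- median_normalize(impute_background(pair$wt))
  mut <- median_normalize(impute_background(pair$mut))
  sh <- compare_ric(wt, mut)
  aff <- pair$truth$protein_id[!is.na(pair$truth$complex_id) &
                                 pair$truth$complex_id == cplx]
  is_aff <- sh$protein_id %in% aff
  # unaffected proteins share one common (centering) offset; affected
  # ones sit exactly delta = 1 above it
  base <- sh$shift[!is_aff][1]
  expect_equal(sh$shift[!is_aff], rep(base, sum(!is_aff)),
               tolerance = 1e-9)
  expect_equal(sh$shift[is_aff], rep(base + 1, sum(is_aff)),
               tolerance = 1e-9)
  # corrected shifts average to zero over the crosslinked set
  expect_lt(abs(mean(sh$shift)), 1e-12)
})

test_that("titrations lie on the 4PL curve and honor the seed", {
  pars <- list(ymin = 0.05, ymax = 0.25, kd = 47, n = 1)
  ti <- generate_titration(pars)
  expect_equal(nrow(ti), 13L)
  expect_equal(max(ti$concentration_nM), 1240)
  expect_lt(min(ti$concentration_nM), 0.32)
  expect_equal(ti$anisotropy,
               predict_4pl(pars, ti$concentration_nM))
  # midpoint identity at x = Kd
  at_kd <- generate_titration(pars, concentrations = 47)
  expect_equal(at_kd$anisotropy, (0.05 + 0.25) / 2)
  n1 <- generate_titration(pars, noise_sd = 0.01, seed = 9)
  n2 <- generate_titration(pars, noise_sd = 0.01, seed = 9)
  expect_identical(n1, n2)
  expect_false(identical(n1$anisotropy, ti$anisotropy))
})

test_that("annotation fixtures plant the expected domain classes", {
  sim <- generate_experiment(sim_config(detection_limit = -Inf), seed = 1)
  ann <- generate_annotation_fixture(sim$truth, seed = 1)
  expected <- attr(ann, "expected_class")
  expect_setequal(unique(expected),
                  c("classical_like", "substoichiometric", "adaptive",
                    "unclassified"))
  # small domains have exactly 3 member proteins -> unclassified
  n_members <- function(dom) sum(vapply(ann$pfam_ids, function(p)
    dom %in% p, logical(1)))
  small <- names(expected)[expected == "unclassified"]
  expect_true(all(vapply(small, n_members, integer(1)) == 3L))
  # high-stratum domains only contain high-activity proteins
  act <- log2(sim$truth$bound_fraction * sim$truth$crosslink_eff)
  names(act) <- sim$truth$protein_id
  for (dom in names(expected)[expected == "classical_like"]) {
    members <- ann$protein_id[vapply(ann$pfam_ids, function(p)
      dom %in% p, logical(1))]
    expect_true(all(act[members] >= median(act) + 3))
  }
  # mixed-stratum domains span both sides
  for (dom in names(expected)[expected == "adaptive"]) {
    members <- ann$protein_id[vapply(ann$pfam_ids, function(p)
      dom %in% p, logical(1))]
    expect_true(any(act[members] >= median(act) + 3) &&
                  any(act[members] <= median(act) - 3))
  }
})
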