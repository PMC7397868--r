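# Synthetic RIC/WCE/noCL experiments with known ground truth. The
# generative model per protein g, sample i (all in log2 space):
#   WCE_gi  = log2(A_g)                 + b_i + u^WCE_c(g),i  + e_gi
#   RIC_gi  = log2(A_g phi_g kappa_g C) + b_i + u^RIC_c(g),i  + e_gi
#   noCL_gi = log2(A_g beta C)          + b_i                 + e_gi
# with abundance A log-normal, bound fraction phi and crosslink
# efficiency kappa on (0, 1], a per-sample offset b, complex-shared
# noise u ~ N(0, sigma_cplx^2) drawn per (complex, sample), independent
# replicate noise e ~ N(0, sigma_rep^2), and left-censoring: any value
# below the detection limit L becomes missing.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate a two-batch triplicate label-free MS design:
#' RIC and WCE in both batches, a noCL control only in the first.
#' Bound fractions follow a two-component mixture (a high-activity
#' stratum of professional RBPs and a low, substoichiometric stratum),
#' crosslink efficiencies are low on average, and intensities below
#' the detection limit (18 log2 units) are censored to missing.
#'
#' @param n_proteins Number of proteins.
#' @param n_complexes Number of protein complexes (0 disables complexes).
#' @param complex_size_mean Mean complex size (Poisson, minimum 2).
#' @param abundance_mean,abundance_sd Log2 mean and SD of protein
#'   abundance.
#' @param fraction_high Fraction of proteins in the high bound-fraction
#'   stratum.
#' @param phi_high_shape,phi_low_shape Beta shape pairs for the bound
#'   fraction phi in the high and low strata.
#' @param kappa_shape Beta shape pair for the UV-crosslink efficiency.
#' @param phi_fixed,kappa_fixed Optional constants overriding the phi
#'   and kappa draws (useful for controlled tests; e.g. `phi_fixed = 1`,
#'   `kappa_fixed = 1` collapses RIC onto WCE).
#' @param capture_eff Global linear capture efficiency C of the
#'   oligo(dT) step (a constant column effect; median normalization
#'   removes it).
#' @param nocl_background Background capture fraction beta in \[0, 1) of
#'   abundance recovered without crosslinking; 0 makes all noCL values
#'   missing.
#' @param detection_limit Log2 intensity L below which values are
#'   censored to missing.
#' @param sigma_rep Replicate noise SD (log2).
#' @param sigma_cplx Complex-shared noise SD (log2).
#' @param batch_effect_sd SD of the per-sample-column offset b (log2).
#' @param n_replicates Replicates per fraction/genotype/batch.
#' @param batches Batch labels.
#' @param nocl_batches Batches that include a noCL control.
#' @param seed Default seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000L,
                       n_complexes = 150L,
                       complex_size_mean = 5,
                       abundance_mean = 26,
                       abundance_sd = 3,
                       fraction_high = 0.3,
                       phi_high_shape = c(5, 2),
                       phi_low_shape = c(1.2, 25),
                       kappa_shape = c(1.5, 10),
                       phi_fixed = NULL,
                       kappa_fixed = NULL,
                       capture_eff = 1,
                       nocl_background = 0.005,
                       detection_limit = 18,
                       sigma_rep = 0.3,
                       sigma_cplx = 0.5,
                       batch_effect_sd = 0.2,
                       n_replicates = 3L,
                       batches = c("B1", "B2"),
                       nocl_batches = "B1",
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_complexes = as.integer(n_complexes),
              complex_size_mean = complex_size_mean,
              abundance_mean = abundance_mean,
              abundance_sd = abundance_sd,
              fraction_high = fraction_high,
              phi_high_shape = phi_high_shape,
              phi_low_shape = phi_low_shape,
              kappa_shape = kappa_shape,
              phi_fixed = phi_fixed,
              kappa_fixed = kappa_fixed,
              capture_eff = capture_eff,
              nocl_background = nocl_background,
              detection_limit = detection_limit,
              sigma_rep = sigma_rep,
              sigma_cplx = sigma_cplx,
              batch_effect_sd = batch_effect_sd,
              n_replicates = as.integer(n_replicates),
              batches = batches,
              nocl_batches = nocl_batches,
              seed = as.integer(seed))
  stopifnot(cfg$n_proteins >= 1,
            cfg$nocl_background >= 0, cfg$nocl_background < 1,
            cfg$sigma_rep >= 0, cfg$sigma_cplx >= 0,
            cfg$batch_effect_sd >= 0,
            cfg$capture_eff > 0, cfg$n_replicates >= 1)
  structure(cfg, class = "sim_config")
}

# Draw per-protein ground truth. Assumes the RNG state is set.
generate_truth <- function(config) {
  n <- config$n_proteins
  id <- sprintf("P%05d", seq_len(n))
  abundance <- 2^stats::rnorm(n, config$abundance_mean, config$abundance_sd)
  hi <- stats::runif(n) < config$fraction_high
  phi <- numeric(n)
  phi[hi] <- stats::rbeta(sum(hi), config$phi_high_shape[1],
                          config$phi_high_shape[2])
  phi[!hi] <- stats::rbeta(sum(!hi), config$phi_low_shape[1],
                           config$phi_low_shape[2])
  phi <- pmin(pmax(phi, 1e-6), 1)
  if (!is.null(config$phi_fixed)) phi <- rep(config$phi_fixed, n)
  kappa <- pmin(pmax(stats::rbeta(n, config$kappa_shape[1],
                                  config$kappa_shape[2]), 1e-6), 1)
  if (!is.null(config$kappa_fixed)) kappa <- rep(config$kappa_fixed, n)
  complex_id <- rep(NA_character_, n)
  if (config$n_complexes > 0) {
    sizes <- pmax(2L, stats::rpois(config$n_complexes,
                                   config$complex_size_mean))
    members <- sample.int(n, min(sum(sizes), n))
    complex_id[members] <-
      rep(sprintf("C%03d", seq_along(sizes)), sizes)[seq_along(members)]
  }
  data.frame(protein_id = id, abundance = abundance,
             bound_fraction = phi, crosslink_eff = kappa,
             complex_id = complex_id, mutant_effect = 0,
             stringsAsFactors = FALSE)
}

# Build one genotype's intensity table from truth. Assumes the RNG
# state is set; draws are column by column in a fixed order.
simulate_table <- function(truth, config, genotype = "WT",
                           phi = truth$bound_fraction,
                           include_nocl = TRUE) {
  n <- nrow(truth)
  L <- config$detection_limit
  base_wce <- log2(truth$abundance)
  base_ric <- log2(truth$abundance * phi * truth$crosslink_eff *
                     config$capture_eff)
  base_nocl <- log2(truth$abundance * config$nocl_background *
                      config$capture_eff)   # -Inf when beta = 0
  cplx <- truth$complex_id
  ucplx <- unique(cplx[!is.na(cplx)])
  cols <- list()
  meta <- list()
  for (b in config$batches) {
    fracs <- c("RIC", "WCE",
               if (include_nocl && b %in% config$nocl_batches) "noCL")
    for (fr in fracs) {
      for (r in seq_len(config$n_replicates)) {
        bi <- if (config$batch_effect_sd > 0)
          stats::rnorm(1, 0, config$batch_effect_sd) else 0
        u <- numeric(n)
        if (fr != "noCL" && length(ucplx) && config$sigma_cplx > 0) {
          uc <- stats::rnorm(length(ucplx), 0, config$sigma_cplx)
          names(uc) <- ucplx
          u[!is.na(cplx)] <- uc[cplx[!is.na(cplx)]]
        }
        eps <- if (config$sigma_rep > 0)
          stats::rnorm(n, 0, config$sigma_rep) else numeric(n)
        base <- switch(fr, WCE = base_wce, RIC = base_ric,
                       noCL = base_nocl)
        v <- base + bi + u + eps
        v[!is.finite(v) | v < L] <- NA_real_
        sid <- paste(fr, genotype, b, r, sep = "_")
        cols[[sid]] <- v
        meta[[sid]] <- data.frame(sample_id = sid, fraction = fr,
                                  genotype = genotype, replicate = r,
                                  batch = b, stringsAsFactors = FALSE)
      }
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- truth$protein_id
  intensity_table(vals, do.call(rbind, meta))
}

#' Generate one synthetic RIC experiment with ground truth
#'
#' @param config A [sim_config()].
#' @param seed Seed; the same config and seed reproduce the output
#'   exactly.
#' @return List with `table` (an [intensity_table()]) and `truth`
#'   (data frame: `protein_id`, `abundance`, `bound_fraction`,
#'   `crosslink_eff`, `complex_id`, `mutant_effect`).
#' @export
generate_experiment <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  truth <- generate_truth(config)
  table <- simulate_table(truth, config)
  list(table = table, truth = truth)
}

#' Generate a WT / mutant pair sharing ground truth
#'
#' WT and mutant share abundances, crosslink efficiencies and complex
#' structure; in the mutant the bound fraction of affected proteins is
#' multiplied by 2^delta and clipped at 1. Neither table includes a
#' noCL control (the comparative analysis uses RIC and WCE only).
#'
#' @param config A [sim_config()].
#' @param mutant_spec List with `delta` (log2 change of phi) and
#'   `protein_ids` and/or `complex_ids` naming the affected proteins.
#'   `delta` may be a scalar or one value per affected protein.
#' @param seed Seed.
#' @param genotype Mutant genotype label.
#' @return List with `wt`, `mut` (intensity tables) and `truth`
#'   (including `mutant_effect` and the realized `bound_fraction_mut`).
#' @export
generate_mutant_pair <- function(config = sim_config(),
                                 mutant_spec = list(delta = 0),
                                 seed = config$seed,
                                 genotype = "mut") {
  set.seed(seed)
  truth <- generate_truth(config)
  affected <- character(0)
  if (!is.null(mutant_spec$protein_ids)) {
    missing_ids <- setdiff(mutant_spec$protein_ids, truth$protein_id)
    if (length(missing_ids))
      stop("unknown protein id(s): ", paste(missing_ids, collapse = ", "))
    affected <- union(affected, mutant_spec$protein_ids)
  }
  if (!is.null(mutant_spec$complex_ids)) {
    known <- unique(truth$complex_id[!is.na(truth$complex_id)])
    missing_ids <- setdiff(mutant_spec$complex_ids, known)
    if (length(missing_ids))
      stop("unknown complex id(s): ", paste(missing_ids, collapse = ", "))
    affected <- union(affected,
                      truth$protein_id[!is.na(truth$complex_id) &
                                         truth$complex_id %in%
                                           mutant_spec$complex_ids])
  }
  delta <- mutant_spec$delta
  if (is.null(delta)) delta <- 0
  truth$mutant_effect <- 0
  truth$mutant_effect[match(affected, truth$protein_id)] <-
    rep_len(delta, length(affected))
  phi_mut <- pmin(1, truth$bound_fraction * 2^truth$mutant_effect)
  truth$bound_fraction_mut <- phi_mut
  wt <- simulate_table(truth, config, genotype = "WT",
                       include_nocl = FALSE)
  mut <- simulate_table(truth, config, genotype = genotype,
                        phi = phi_mut, include_nocl = FALSE)
  list(wt = wt, mut = mut, truth = truth)
}

#' Generate a synthetic anisotropy titration
#'
#' Points on a 4PL curve plus Gaussian noise. The default
#' concentration grid is a 13-point two-fold dilution series from
#' 1240 nM downward (to about 0.3 nM).
#'
#' @param params List with `ymin`, `ymax`, `kd` (nM), `n`.
#' @param concentrations Concentrations in nM (> 0).
#' @param noise_sd SD of additive anisotropy noise.
#' @param seed Optional seed.
#' @return Data frame with `concentration_nM` and `anisotropy`.
#' @export
generate_titration <- function(params,
                               concentrations = 1240 / 2^(0:12),
                               noise_sd = 0, seed = NULL) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (!is.null(seed)) set.seed(seed)
  y <- four_pl(concentrations, params$ymin, params$ymax, params$kd,
               params$n)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  data.frame(concentration_nM = concentrations, anisotropy = y)
}

#' Build an annotation fixture with planted domain classes
#'
#' Assigns synthetic Pfam-like domain ids to protein strata defined by
#' the true binding activity log2(phi * kappa), relative to its median:
#' high-stratum domains (members at least `margin` log2 units above
#' the median) are expected `classical_like`, low-stratum domains
#' `substoichiometric`, domains spanning both strata `adaptive`, and
#' domains with fewer than four members `unclassified`.
#'
#' @param truth Ground-truth data frame from the generator.
#' @param domains_per_stratum Number of domains per stratum.
#' @param proteins_per_domain Member proteins per classifiable domain.
#' @param n_small Number of under-populated (3-protein) domains.
#' @param margin Log2 separation of the strata from the median
#'   activity.
#' @param seed Optional seed for the membership sampling.
#' @return An [annotation_table()] covering all proteins, with the
#'   planted class of every synthetic domain in attribute
#'   `"expected_class"`.
#' @export
generate_annotation_fixture <- function(truth, domains_per_stratum = 4L,
                                        proteins_per_domain = 8L,
                                        n_small = 2L, margin = 3,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  act <- log2(truth$bound_fraction * truth$crosslink_eff)
  med <- stats::median(act)
  hi_pool <- truth$protein_id[act >= med + margin]
  lo_pool <- truth$protein_id[act <= med - margin]
  need_hi <- domains_per_stratum * proteins_per_domain +
    ceiling(domains_per_stratum * proteins_per_domain / 2) + 3 * n_small
  if (length(hi_pool) < need_hi ||
      length(lo_pool) < need_hi)
    stop("strata too small for the requested fixture; ",
         "increase margin separation or protein count")
  doms <- list()
  expected <- character(0)
  take <- function(pool, k) sample(pool, k)
  for (i in seq_len(domains_per_stratum)) {
    id <- sprintf("SYNH%02d", i)
    doms[[id]] <- take(hi_pool, proteins_per_domain)
    expected[id] <- "classical_like"
    id <- sprintf("SYNL%02d", i)
    doms[[id]] <- take(lo_pool, proteins_per_domain)
    expected[id] <- "substoichiometric"
    id <- sprintf("SYNM%02d", i)
    half <- ceiling(proteins_per_domain / 2)
    doms[[id]] <- c(take(hi_pool, half),
                    take(lo_pool, proteins_per_domain - half))
    expected[id] <- "adaptive"
  }
  for (i in seq_len(n_small)) {
    id <- sprintf("SYNS%02d", i)
    doms[[id]] <- take(hi_pool, 3L)
    expected[id] <- "unclassified"
  }
  pfam <- rep(list(character(0)), nrow(truth))
  names(pfam) <- truth$protein_id
  for (id in names(doms))
    for (p in doms[[id]]) pfam[[p]] <- c(pfam[[p]], id)
  ann <- annotation_table(truth$protein_id, pfam,
                          classical_ids = character(0),
                          nonclassical_ids = names(doms))
  attr(ann, "expected_class") <- expected
  ann
}
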