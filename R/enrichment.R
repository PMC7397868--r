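# Single-condition enrichment statistics: imputation, median
# normalization, RIC/WCE (paired) and CL/noCL (unpaired) fold changes,
# moderated t-tests and population flags.

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

#' Impute left-censored missing intensities at a background value
#'
#' Every missing cell is set to a fixed background log2 intensity
#' (default 18) and recorded in the imputed mask. Because the fill is a
#' constant, per-batch and global application give identical values;
#' the `scope` argument documents at which level of the design the
#' imputation is considered to act.
#'
#' @param table An [intensity_table()] in log2 space.
#' @param value Background log2 intensity to fill in.
#' @param scope `"batch"` (default) or `"global"`.
#' @return The table with no missing cells and an updated imputed mask.
#' @export
impute_background <- function(table, value = 18, scope = c("batch", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "intensity_table"), is.finite(value))
  miss <- is.na(table$values)
  table$values[miss] <- value
  table$imputed <- table$imputed | miss
  table
}

#' Median-center every sample column
#'
#' Subtracts each column's median (for an even count, the mean of the
#' two central values) so that every column has median exactly zero.
#' Imputed cells participate like any other value.
#'
#' @param table An [intensity_table()].
#' @return The normalized table.
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  meds <- apply(table$values, 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(meds)))
    stop("column(s) with no observed values: ",
         paste(colnames(table$values)[!is.finite(meds)], collapse = ", "))
  table$values <- sweep(table$values, 2L, meds)
  table
}

pair_key <- function(meta, ids) {
  m <- meta[match(ids, meta$sample_id), ]
  paste(m$genotype, m$batch, m$replicate, sep = "\r")
}

#' Per-protein log2 fold change between two sample groups
#'
#' Paired mode matches samples by (genotype, batch, replicate) and
#' returns the per-replicate differences d_i = A_i - B_i together with
#' their mean; unpaired mode returns the difference of group means.
#'
#' @param table An [intensity_table()] (imputed, so no missing cells).
#' @param group_a,group_b Sample ids of the two groups.
#' @param paired Match replicates pairwise?
#' @return Paired: list with `mean`, `diffs` (protein x pair matrix)
#'   and `n_pairs`. Unpaired: list with `mean`, `mean_a`, `mean_b`,
#'   `var_a`, `var_b`, `n_a`, `n_b`.
#' @export
mean_log2_fc <- function(table, group_a, group_b, paired = FALSE) {
  stopifnot(inherits(table, "intensity_table"),
            length(group_a) >= 1L, length(group_b) >= 1L)
  A <- table$values[, group_a, drop = FALSE]
  B <- table$values[, group_b, drop = FALSE]
  if (!paired) {
    return(list(mean = rowMeans(A) - rowMeans(B),
                mean_a = rowMeans(A), mean_b = rowMeans(B),
                var_a = row_vars(A), var_b = row_vars(B),
                n_a = ncol(A), n_b = ncol(B)))
  }
  if (length(group_a) != length(group_b))
    stop("paired groups must have equal size")
  ka <- pair_key(table$meta, group_a)
  kb <- pair_key(table$meta, group_b)
  idx <- match(ka, kb)
  if (anyNA(idx) || anyDuplicated(idx))
    stop("paired groups do not have matching (genotype, batch, replicate)")
  diffs <- A - B[, idx, drop = FALSE]
  colnames(diffs) <- paste(group_a, colnames(B)[idx], sep = "-")
  list(mean = rowMeans(diffs), diffs = diffs, n_pairs = ncol(diffs))
}

#' Classify proteins by where they were detected
#'
#' Detection is assessed on pre-imputation missingness (the imputed
#' mask): a protein is detected in a fraction if it was observed in at
#' least `min_detected` of that fraction's replicates. Returns the
#' volcano-plot population symbol encoding: `both` (full circle),
#' `ric_only` (empty circle), `wce_only` (cross); proteins detected in
#' neither group get `NA` and are dropped from downstream results.
#'
#' @param table An [intensity_table()].
#' @param ric_samples,wce_samples Sample ids of the pull-down group and
#'   the reference group (WCE, or noCL in CL/noCL mode).
#' @param min_detected Minimum observed replicates to count as detected.
#' @return Factor with levels `both`, `ric_only`, `wce_only`; `NA` for
#'   proteins observed in neither group.
#' @export
population_flags <- function(table, ric_samples, wce_samples,
                             min_detected = 1L) {
  det <- detected_matrix(table)
  n_ric <- rowSums(det[, ric_samples, drop = FALSE])
  n_wce <- rowSums(det[, wce_samples, drop = FALSE])
  in_ric <- n_ric >= min_detected
  in_wce <- n_wce >= min_detected
  flag <- rep(NA_character_, nrow(det))
  flag[in_ric & in_wce] <- "both"
  flag[in_ric & !in_wce] <- "ric_only"
  flag[!in_ric & in_wce] <- "wce_only"
  factor(flag, levels = c("both", "ric_only", "wce_only"))
}

#' Per-protein enrichment statistics (RIC/WCE or CL/noCL)
#'
#' The single-condition pipeline: population flags from pre-imputation
#' detection, per-protein fold changes (paired per-replicate RIC - WCE
#' differences in `"wce"` mode; unpaired pooled-variance CL vs noCL
#' contrast in `"nocl"` mode), an empirical-Bayes variance prior fitted
#' across proteins, moderated t-statistics, and BH plus Bonferroni
#' adjustment. Proteins detected in neither group are dropped.
#'
#' The table must already be imputed (and, for `"wce"` mode,
#' median-normalized).
#'
#' @param table An [intensity_table()].
#' @param mode `"wce"` for RIC/WCE ratios, `"nocl"` for crosslinked
#'   vs non-crosslinked enrichment.
#' @param config A [ric_config()].
#' @return Data frame with one row per retained protein: `protein_id`,
#'   `population`, `mean_log2fc`, `ratio_sd`, `n_pairs`, `t_mod`,
#'   `df_total`, `p`, `q_fdr`, `q_bonf`, `n_imputed_ric`,
#'   `n_imputed_wce`. The fitted prior is attached as attribute
#'   `"prior"`.
#' @export
enrichment_table <- function(table, mode = c("wce", "nocl"),
                             config = ric_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "intensity_table"))
  if (any(is.na(table$values)))
    stop("table still has missing cells; run impute_background() first")
  geno <- config$genotype
  ric <- samples_for(table, fraction = "RIC", genotype = geno)
  ref <- samples_for(table,
                     fraction = if (mode == "wce") "WCE" else "noCL",
                     genotype = if (mode == "wce") geno else NULL)
  if (!length(ric) || !length(ref))
    stop("table lacks RIC or reference samples for mode '", mode, "'")
  flag <- population_flags(table, ric, ref, config$min_detected)
  keep <- !is.na(flag)
  if (mode == "wce") {
    fc <- mean_log2_fc(table, ric, ref, paired = TRUE)
    s2 <- row_vars(fc$diffs)
    df <- fc$n_pairs - 1L
    n_eff <- fc$n_pairs
    n_pairs <- fc$n_pairs
    ratio_sd <- sqrt(s2)
  } else {
    fc <- mean_log2_fc(table, ric, ref, paired = FALSE)
    df <- fc$n_a + fc$n_b - 2L
    s2 <- ((fc$n_a - 1) * fc$var_a + (fc$n_b - 1) * fc$var_b) / df
    n_eff <- 1 / (1 / fc$n_a + 1 / fc$n_b)
    n_pairs <- min(fc$n_a, fc$n_b)
    ratio_sd <- sqrt(s2)
  }
  mean_fc <- fc$mean[keep]
  s2 <- s2[keep]
  # a degenerate experiment (e.g. noise-free synthetic data) has no
  # positive variances to fit a prior on; report fold changes with NA
  # statistics rather than failing
  prior <- tryCatch(fit_variance_prior(s2, df), error = function(e) NULL)
  if (is.null(prior)) {
    nv <- rep(NA_real_, length(mean_fc))
    mt <- list(t = nv, df_total = nv, p = nv)
  } else {
    mt <- moderated_t(mean_fc, s2, n = n_eff, prior, df = df)
  }
  imp <- table$imputed
  out <- data.frame(
    protein_id = rownames(table$values)[keep],
    population = flag[keep],
    mean_log2fc = mean_fc,
    ratio_sd = ratio_sd[keep],
    n_pairs = n_pairs,
    t_mod = mt$t,
    df_total = mt$df_total,
    p = mt$p,
    q_fdr = adjust_p(mt$p, "fdr"),
    q_bonf = adjust_p(mt$p, "bonferroni"),
    n_imputed_ric = rowSums(imp[keep, ric, drop = FALSE]),
    n_imputed_wce = rowSums(imp[keep, ref, drop = FALSE]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  out
}
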