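#' Analysis configuration
#'
#' Central tunables of the pipeline with their defaults. Key choices:
#'
#' * `impute_value = 18`: background log2 intensity used to fill
#'   left-censored missing cells.
#' * `min_detected = 1`: a protein counts as detected in a fraction if
#'   it was observed (pre-imputation) in at least this many replicates.
#' * `lfc_enriched = 2`, `lfc_underrepresented = -2`, `p_cutoff = 0.01`:
#'   selection thresholds for high/low RNA-binding-activity sets
#'   (a 4-fold RIC/WCE ratio is 2 log2 units).
#' * `propagation`: `"log2_difference"` (exact, Hessian-free) or
#'   `"linear_ratio"` (second-order Taylor on the linear-scale ratio).
#' * `pseudo_sd_scale`: `"none"` uses the propagated shift SE directly
#'   as the pseudo-replicate sample SD; `"sqrt_n"` multiplies it by
#'   sqrt(n_pseudo), which makes the ordinary t of the pseudo-replicates
#'   equal shift/SE (the calibrated statistic).
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `ric_config`.
#' @export
ric_config <- function(...) {
  defaults <- list(
    impute_value = 18,
    impute_scope = "batch",
    min_detected = 1L,
    genotype = NULL,
    lfc_enriched = 2,
    lfc_underrepresented = -2,
    p_cutoff = 0.01,
    min_proteins = 4L,
    class_hi = 2,
    class_lo = -2,
    ribosome_go = "GO:0022626",
    propagation = "log2_difference",
    pseudo_sd_scale = "none",
    n_pseudo = 3L,
    cov_mode = "zero",
    seed = 1L)
  args <- list(...)
  if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args))))
      stop("config overrides must be named")
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    defaults[names(args)] <- args
  }
  stopifnot(defaults$propagation %in% c("log2_difference", "linear_ratio"),
            defaults$pseudo_sd_scale %in% c("none", "sqrt_n"),
            defaults$cov_mode %in% c("zero", "paired"),
            defaults$n_pseudo >= 2)
  structure(defaults, class = "ric_config")
}

#' Read a YAML key-value configuration file
#'
#' @param path Path to a YAML file whose keys match [ric_config()]
#'   arguments.
#' @return A `ric_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(ric_config, vals)
}
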