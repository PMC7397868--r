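# Downstream classification: enriched/underrepresented protein sets,
# per-Pfam-domain RNA-binding-activity classes, and descriptive GO-term
# fraction comparisons between sets.

#' Select high- and low-activity protein sets
#'
#' Enriched proteins have a RIC/WCE ratio above `lfc_enriched` log2
#' units (default +2, i.e. more than 4-fold) at `p < p_cutoff`;
#' underrepresented proteins fall below `lfc_underrepresented`
#' (default -2, less than 0.25-fold) at the same p threshold. The two
#' sets are disjoint by construction.
#'
#' @param rows An enrichment table from [enrichment_table()] with
#'   `mode = "wce"`.
#' @param config A [ric_config()].
#' @return List with character vectors `enriched` and
#'   `underrepresented`.
#' @export
select_sets <- function(rows, config = ric_config()) {
  stopifnot(all(c("protein_id", "mean_log2fc", "p") %in% names(rows)))
  enr <- rows$mean_log2fc > config$lfc_enriched & rows$p < config$p_cutoff
  und <- rows$mean_log2fc < config$lfc_underrepresented &
    rows$p < config$p_cutoff
  list(enriched = rows$protein_id[enr],
       underrepresented = rows$protein_id[und])
}

classify_one <- function(ratios, min_proteins, hi, lo) {
  if (length(ratios) < min_proteins) return("unclassified")
  med <- stats::median(ratios)
  if (med >= hi) return("classical_like")
  if (med <= lo) return("substoichiometric")
  if (min(ratios) <= lo && max(ratios) >= hi) return("adaptive")
  iqr <- stats::IQR(ratios)
  if (iqr > (hi - lo) / 2) return("adaptive")
  if (med > 0) "classical_like" else "substoichiometric"
}

#' Classify nonclassical RNA-binding domains by member activity
#'
#' For each nonclassical Pfam domain, the RIC/WCE ratios of its
#' RIC-detected member proteins determine a class: `classical_like`
#' (median at or above `class_hi`; professional, near-constant RNA
#' association), `substoichiometric` (median at or below `class_lo`;
#' only a small fraction of the protein pool is RNA-bound), `adaptive`
#' (member ratios span both thresholds, or are unusually dispersed),
#' or `unclassified` when fewer than `min_proteins` member proteins
#' were detected. Member proteins that also harbor a classical RBD, or
#' are annotated with the cytosolic-ribosome GO term, are excluded
#' from the domain statistics.
#'
#' @param rows Enrichment table (`mode = "wce"`); only rows with
#'   population `both` or `ric_only` (RIC-detected) are used.
#' @param annotations An [annotation_table()].
#' @param config A [ric_config()] (`min_proteins`, `class_hi`,
#'   `class_lo`, `ribosome_go`).
#' @param nonclassical_ids Pfam ids eligible for classification;
#'   defaults to every annotated domain that is not classical for any
#'   protein (so synthetic vocabularies work without registration).
#' @return Data frame with `pfam_id`, `n_proteins_detected`,
#'   `median_ratio`, `iqr_ratio`, `klass`.
#' @export
classify_domains <- function(rows, annotations, config = ric_config(),
                             nonclassical_ids = NULL) {
  stopifnot(inherits(annotations, "annotation_table"))
  detected <- rows$population %in% c("both", "ric_only")
  ratios <- rows$mean_log2fc[detected]
  names(ratios) <- rows$protein_id[detected]
  idx <- match(names(ratios), annotations$protein_id)
  classical <- annotations$has_classical_rbd[idx]
  classical[is.na(classical)] <- FALSE
  ribo <- vapply(annotations$go_terms[idx], function(g)
    !is.null(g) && config$ribosome_go %in% g, logical(1))
  ribo[is.na(idx)] <- FALSE
  eligible <- !classical & !ribo & !is.na(idx)
  ratios <- ratios[eligible]
  idx <- idx[eligible]
  if (is.null(nonclassical_ids)) {
    all_pfam <- unique(unlist(annotations$pfam_ids))
    classical_vocab <- attr(annotations, "classical_ids")
    if (is.null(classical_vocab)) classical_vocab <- character(0)
    nonclassical_ids <- setdiff(all_pfam, classical_vocab)
  }
  member_of <- function(dom) {
    has <- vapply(annotations$pfam_ids[idx], function(p) dom %in% p,
                  logical(1))
    ratios[has]
  }
  res <- lapply(nonclassical_ids, function(dom) {
    r <- member_of(dom)
    data.frame(
      pfam_id = dom,
      n_proteins_detected = length(r),
      median_ratio = if (length(r)) stats::median(r) else NA_real_,
      iqr_ratio = if (length(r) > 1) stats::IQR(r) else NA_real_,
      klass = classify_one(r, config$min_proteins, config$class_hi,
                           config$class_lo),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of set members carrying an annotation term
#'
#' Descriptive set statistic: the fraction of proteins in a set that
#' carry a given GO term, side by side with the same fraction in a
#' reference set (e.g. the whole detected proteome). No enrichment
#' test is performed.
#'
#' @param set_ids,reference_ids Protein id vectors (non-empty).
#' @param term The GO term to count.
#' @param annotations An [annotation_table()].
#' @return One-row data frame: `term`, `frac_in_set`,
#'   `frac_in_reference`, `k_set`, `n_set`, `k_ref`, `n_ref`.
#' @export
term_fractions <- function(set_ids, reference_ids, term, annotations) {
  if (!length(set_ids) || !length(reference_ids))
    stop("sets must be non-empty")
  has_term <- function(ids) {
    idx <- match(ids, annotations$protein_id)
    vapply(seq_along(ids), function(i) {
      if (is.na(idx[i])) return(FALSE)
      term %in% annotations$go_terms[[idx[i]]]
    }, logical(1))
  }
  k_set <- sum(has_term(set_ids))
  k_ref <- sum(has_term(reference_ids))
  data.frame(term = term,
             frac_in_set = k_set / length(set_ids),
             frac_in_reference = k_ref / length(reference_ids),
             k_set = k_set, n_set = length(set_ids),
             k_ref = k_ref, n_ref = length(reference_ids),
             stringsAsFactors = FALSE)
}
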