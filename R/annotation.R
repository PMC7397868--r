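#' Bundled RNA-binding-domain Pfam id lists
#'
#' The split of Pfam domains into "classical" RBDs (RRM, KH, dsRBD and
#' friends, with dedicated RNA-binding folds) and "nonclassical" RBDs
#' (domains recurrently recovered by crosslinking studies without a
#' canonical RNA-binding surface) drives annotation flags and domain
#' classification. The lists ship as editable plain-text files under
#' `inst/extdata/` so users can substitute their own vocabulary.
#'
#' @param type `"classical"` or `"nonclassical"`.
#' @return Character vector of Pfam identifiers.
#' @export
rbd_pfam_ids <- function(type = c("classical", "nonclassical")) {
  type <- match.arg(type)
  path <- system.file("extdata", paste0(type, "_rbd_pfam.txt"),
                      package = "ricactivity")
  if (!nzchar(path)) stop("bundled domain list not found")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

split_terms <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) unique(trimws(v[nzchar(trimws(v))])))
}

#' Build an annotation table
#'
#' Associates each protein with its Pfam domains and GO terms and
#' derives classical/nonclassical RBD flags from the configured domain
#' id lists.
#'
#' @param protein_id Character vector of unique protein ids.
#' @param pfam_ids List of character vectors (one per protein) or a
#'   character vector of `;`-separated ids.
#' @param go_terms Same shape as `pfam_ids`, for GO terms.
#' @param classical_ids,nonclassical_ids Pfam id vocabularies; default
#'   to the bundled lists.
#' @return A data frame of class `annotation_table` with list columns
#'   `pfam_ids` and `go_terms` and logical flags `has_classical_rbd`,
#'   `has_nonclassical_rbd`.
#' @export
annotation_table <- function(protein_id, pfam_ids = NULL, go_terms = NULL,
                             classical_ids = rbd_pfam_ids("classical"),
                             nonclassical_ids = rbd_pfam_ids("nonclassical")) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id))
    stop("duplicate protein ids in annotation")
  n <- length(protein_id)
  norm_list <- function(x) {
    if (is.null(x)) return(rep(list(character(0)), n))
    if (is.character(x)) x <- split_terms(x)
    if (length(x) != n) stop("annotation column length mismatch")
    lapply(x, as.character)
  }
  pfam_ids <- norm_list(pfam_ids)
  go_terms <- norm_list(go_terms)
  ann <- data.frame(protein_id = protein_id, stringsAsFactors = FALSE)
  ann$pfam_ids <- pfam_ids
  ann$go_terms <- go_terms
  ann$has_classical_rbd <-
    vapply(pfam_ids, function(p) any(p %in% classical_ids), logical(1))
  ann$has_nonclassical_rbd <-
    vapply(pfam_ids, function(p) any(p %in% nonclassical_ids), logical(1))
  attr(ann, "classical_ids") <- classical_ids
  attr(ann, "nonclassical_ids") <- nonclassical_ids
  class(ann) <- c("annotation_table", "data.frame")
  ann
}

#' Read an annotation TSV
#'
#' Expects columns `protein_id`, `pfam_ids` and `go_terms`, the latter
#' two `;`-separated.
#'
#' @inheritParams annotation_table
#' @param path Path to the TSV.
#' @return An [annotation_table()].
#' @export
read_annotation_table <- function(path,
                                  classical_ids = rbd_pfam_ids("classical"),
                                  nonclassical_ids = rbd_pfam_ids("nonclassical")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("protein_id", "pfam_ids", "go_terms")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("annotation file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  annotation_table(raw$protein_id, raw$pfam_ids, raw$go_terms,
                   classical_ids, nonclassical_ids)
}

#' Write an annotation table as a flat TSV
#'
#' @param ann An [annotation_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(ann, path) {
  flat <- data.frame(
    protein_id = ann$protein_id,
    pfam_ids = vapply(ann$pfam_ids, paste, character(1), collapse = ";"),
    go_terms = vapply(ann$go_terms, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
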