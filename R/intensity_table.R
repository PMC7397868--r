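#' Construct a protein x sample intensity table
#'
#' The container used by every processing step: a numeric matrix of
#' log2 MS intensities (proteins in rows, samples in columns), sample
#' metadata, and a logical mask recording which cells were imputed.
#' Missing (non-detected) intensities are `NA`; they are distinct from
#' zero, which for label-free MS would denote a measured value.
#'
#' @param values Numeric matrix of log2 intensities with unique protein
#'   ids as rownames. `NA` marks a missing (censored) measurement.
#' @param meta Data frame with one row per sample column and columns
#'   `sample_id`, `fraction` (one of `"RIC"`, `"WCE"`, `"noCL"`),
#'   `genotype`, `replicate` (integer >= 1) and `batch`.
#' @param imputed Optional logical matrix of the same shape marking
#'   imputed cells; defaults to all `FALSE`.
#'
#' @return An object of class `intensity_table`: a list with elements
#'   `values`, `meta` and `imputed`.
#' @export
intensity_table <- function(values, meta, imputed = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must carry protein ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("sample_id", "fraction", "genotype", "replicate", "batch")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$fraction <- as.character(meta$fraction)
  meta$genotype <- as.character(meta$genotype)
  meta$batch <- as.character(meta$batch)
  meta$replicate <- as.integer(meta$replicate)
  if (nrow(meta) != ncol(values))
    stop("metadata has ", nrow(meta), " rows but the matrix has ",
         ncol(values), " sample columns")
  if (is.null(colnames(values))) colnames(values) <- meta$sample_id
  if (!identical(colnames(values), meta$sample_id))
    stop("sample columns and metadata sample_id disagree (order matters)")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  bad_frac <- setdiff(unique(meta$fraction), c("RIC", "WCE", "noCL"))
  if (length(bad_frac))
    stop("unknown fraction label(s): ", paste(bad_frac, collapse = ", "))
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1L))
    stop("`replicate` must be a positive integer")
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs)))
    stop("non-missing intensities must be finite")
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  } else {
    if (!is.logical(imputed) || !identical(dim(imputed), dim(values)))
      stop("`imputed` must be a logical matrix with the shape of `values`")
    dimnames(imputed) <- dimnames(values)
  }
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, imputed = imputed),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table: ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples\n", sep = "")
  tab <- table(x$meta$fraction, x$meta$batch)
  cat("samples per fraction/batch:\n")
  print(tab)
  cat(sum(is.na(x$values)), " missing cells, ",
      sum(x$imputed), " imputed\n", sep = "")
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' Which cells hold a genuinely observed (non-imputed) intensity
#'
#' @param table An [intensity_table()].
#' @return Logical matrix; `TRUE` where a value was measured (neither
#'   missing nor filled by imputation).
#' @export
detected_matrix <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  !is.na(table$values) & !table$imputed
}

#' Select sample ids by metadata
#'
#' @param table An [intensity_table()].
#' @param fraction,genotype,batch Optional filters; `NULL` means any.
#' @return Character vector of sample ids in metadata order.
#' @export
samples_for <- function(table, fraction = NULL, genotype = NULL, batch = NULL) {
  m <- table$meta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(fraction)) keep <- keep & m$fraction %in% fraction
  if (!is.null(genotype)) keep <- keep & m$genotype %in% genotype
  if (!is.null(batch)) keep <- keep & m$batch %in% batch
  m$sample_id[keep]
}

#' Read a wide intensity TSV plus its sample metadata
#'
#' The intensity file must have a first column `protein_id` and one
#' numeric column per sample; empty cells and the literal string "NA"
#' are treated as missing. Linear-scale input is log2-transformed;
#' non-positive linear values are censored to missing (the log of a
#' label-free MS zero is not a measurement).
#'
#' @param path Path to the intensity TSV.
#' @param meta_path Path to the metadata TSV (columns `sample_id`,
#'   `fraction`, `genotype`, `replicate`, `batch`), one row per sample
#'   column. Columns are reordered to metadata order.
#' @param scale `"log2"` (default) if values are already log2, or
#'   `"linear"` to transform.
#' @return An [intensity_table()] with an all-`FALSE` imputed mask.
#' @export
read_intensity_table <- function(path, meta_path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L || names(raw)[1L] != "protein_id")
    stop("intensity file must start with a `protein_id` column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sample_ids <- names(raw)[-1L]
  vals <- matrix(NA_real_, length(ids), length(sample_ids),
                 dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- raw[[j + 1L]]
    cell[cell == "" | cell == "NA"] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", cell[bad[1L]], "' for protein ",
           ids[bad[1L]], " in sample column ", sample_ids[j])
    vals[, j] <- num
  }
  if (scale == "linear") {
    vals[!is.na(vals) & vals <= 0] <- NA_real_
    vals <- log2(vals)
  }
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("metadata file lacks a `sample_id` column")
  meta$sample_id <- as.character(meta$sample_id)
  extra <- setdiff(sample_ids, meta$sample_id)
  if (length(extra))
    stop("sample column(s) without metadata: ", paste(extra, collapse = ", "))
  orphan <- setdiff(meta$sample_id, sample_ids)
  if (length(orphan))
    stop("metadata row(s) without a sample column: ",
         paste(orphan, collapse = ", "))
  vals <- vals[, meta$sample_id, drop = FALSE]
  intensity_table(vals, meta)
}

#' Merge intensity tables from different batches
#'
#' Column-wise concatenation over the union of proteins; a protein
#' absent from one batch gets missing cells in that batch's columns.
#' Batch ids and sample ids must be distinct across inputs. Merging is
#' order-insensitive up to column/row ordering.
#'
#' @param tables List of [intensity_table()] objects.
#' @return A single merged [intensity_table()] with imputed masks
#'   preserved.
#' @export
merge_batches <- function(tables) {
  if (!length(tables)) stop("nothing to merge")
  ok <- vapply(tables, inherits, logical(1), "intensity_table")
  if (!all(ok)) stop("all inputs must be intensity tables")
  batch_sets <- lapply(tables, function(t) unique(t$meta$batch))
  all_batches <- unlist(batch_sets)
  if (anyDuplicated(all_batches))
    stop("batch ids clash across inputs: ",
         paste(unique(all_batches[duplicated(all_batches)]), collapse = ", "))
  all_samples <- unlist(lapply(tables, function(t) t$meta$sample_id))
  if (anyDuplicated(all_samples))
    stop("duplicate sample ids across inputs: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  prots <- Reduce(union, lapply(tables, function(t) rownames(t$values)))
  expand <- function(t, fill, mat) {
    out <- matrix(fill, length(prots), ncol(mat),
                  dimnames = list(prots, colnames(mat)))
    out[rownames(mat), ] <- mat
    out
  }
  vals <- do.call(cbind, lapply(tables, function(t) expand(t, NA_real_, t$values)))
  imp <- do.call(cbind, lapply(tables, function(t) expand(t, FALSE, t$imputed)))
  meta <- do.call(rbind, lapply(tables, function(t) t$meta))
  intensity_table(vals, meta, imp)
}

#' Write a result table to TSV
#'
#' One row per protein (or domain); floats are serialized at full
#' double precision, missing values as the string "NA".
#'
#' @param rows A data frame of results (e.g. from [enrichment_table()],
#'   [compare_ric()] or [classify_domains()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data frame")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
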