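# Builders for small in-code fixtures.

# A table with explicit values; fractions/replicates derived from the
# column layout: one batch, `n_rep` replicates per listed fraction.
make_table <- function(values, fractions, genotype = "WT", batch = "B1",
                       replicates = NULL) {
  n_samp <- ncol(values)
  stopifnot(length(fractions) == n_samp)
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_len(n_samp), fractions,
                             FUN = seq_along)
  }
  meta <- data.frame(
    sample_id = paste(fractions, genotype, batch, replicates, sep = "_"),
    fraction = fractions, genotype = genotype,
    replicate = replicates, batch = batch,
    stringsAsFactors = FALSE)
  colnames(values) <- meta$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  intensity_table(values, meta)
}

# Paired RIC/WCE table from a matrix of per-replicate differences:
# WCE is flat at `base`, RIC = base + diffs.
table_from_diffs <- function(diffs, base = 20) {
  n <- nrow(diffs)
  k <- ncol(diffs)
  wce <- matrix(base, n, k)
  vals <- cbind(base + diffs, wce)
  make_table(vals, rep(c("RIC", "WCE"), each = k),
             replicates = rep(seq_len(k), 2))
}

write_tsv_text <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
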