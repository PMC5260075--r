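#' Sample-level quality metrics
#'
#' Computes, for one mapped sample: the mapped read count and percentage,
#' the ambiguous (multi-mapping) and unmapped tallies, the UP/DN tag
#' correlation for pair-tag libraries (the two barcodes of a deletion
#' strain should receive similar counts, so a low correlation signals a
#' problem with the sample or the library), and the distribution of
#' per-barcode count ratios within the sample.
#'
#' @param result a [MappingResult-class].
#' @param library the [BarcodeLibrary-class] it was mapped against (tag
#'   structure; optional for single-tag results).
#' @param method correlation estimator for UP vs DN per-gene counts,
#'   computed on `log2(count + 1)`: `"pearson"` (default) or
#'   `"spearman"`.
#' @return list with `summary` (one-row data.frame: `sample_id`,
#'   `input_reads`, `mapped_count`, `mapped_pct`, `ambiguous_count`,
#'   `unmapped_count`, `filtered_count`, `updn_correlation` — `NA` for
#'   single-tag), `ratio_quantiles` (0/25/50/75/100% quantiles of barcode
#'   count / total mapped) and `ratios` (full per-barcode ratio table).
#' @export
sampleQC <- function(result, library = NULL,
                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(result, "MappingResult"))
  tot <- result@totals
  cts <- mappingCounts(result)
  mapped <- tot[["mapped"]]
  ratios <- data.frame(barcode_id = cts$barcode_id,
                       ratio = if (mapped > 0) cts$total / mapped
                               else rep(0, nrow(cts)),
                       stringsAsFactors = FALSE)
  updn <- NA_real_
  if (any(cts$tag %in% c("UP", "DN"))) {
    up <- cts[cts$tag == "UP", c("gene_id", "total")]
    dn <- cts[cts$tag == "DN", c("gene_id", "total")]
    up_g <- rowsum(up$total, up$gene_id)
    dn_g <- rowsum(dn$total, dn$gene_id)
    genes <- intersect(rownames(up_g), rownames(dn_g))
    miss <- setdiff(union(rownames(up_g), rownames(dn_g)), genes)
    if (length(miss))
      warning("gene(s) missing one tag excluded from UP/DN correlation: ",
              paste(miss, collapse = ", "))
    if (length(genes) >= 2L)
      updn <- cor(log2(up_g[genes, 1L] + 1), log2(dn_g[genes, 1L] + 1),
                  method = method)
  }
  summary <- data.frame(
    sample_id = result@sampleId,
    input_reads = tot[["input"]],
    mapped_count = mapped,
    mapped_pct = if (tot[["input"]] > 0) 100 * mapped / tot[["input"]] else 0,
    ambiguous_count = tot[["ambiguous"]],
    unmapped_count = tot[["unmapped"]],
    filtered_count = tot[["filtered"]],
    updn_correlation = updn,
    stringsAsFactors = FALSE)
  list(summary = summary,
       ratio_quantiles = quantile(ratios$ratio, c(0, 0.25, 0.5, 0.75, 1)),
       ratios = ratios)
}

#' Combine per-sample QC summaries
#'
#' @param qcs list of [sampleQC()] results.
#' @return one data.frame, one row per sample.
#' @export
combineQC <- function(qcs) {
  do.call(rbind, lapply(qcs, `[[`, "summary"))
}

#' Write sample QC to TSV
#'
#' @param qc a [sampleQC()] result or a [combineQC()] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeQC <- function(qc, path) {
  df <- if (is.data.frame(qc)) qc else qc$summary
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
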