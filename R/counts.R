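#' Assemble a barcodes x samples count matrix
#'
#' Builds a [SummarizedExperiment::SummarizedExperiment] holding the raw
#' counts with the library annotations as row data (`gene_id`, `tag`) and
#' the sample design as column data (`condition`, `replicate`,
#' `time_point`). This is the container every analysis step operates on.
#'
#' @param counts numeric matrix, barcodes in rows (rownames = barcode ids),
#'   samples in columns (colnames = sample ids); or a named list of
#'   [MappingResult-class] objects, one per design row (matched by
#'   `sample_id`), whose `total` counts become the columns.
#' @param library a [BarcodeLibrary-class]; rows are kept in library order.
#' @param design a sample design data.frame (see [readSampleDesign()]).
#' @return a `SummarizedExperiment` with assay `"counts"`.
#' @export
screenCounts <- function(counts, library, design) {
  design <- validateSampleDesign(design)
  if (is.list(counts) && !is.matrix(counts)) {
    ids <- vapply(counts, mappingSampleId, "")
    if (is.null(names(counts))) names(counts) <- ids
    miss <- setdiff(design$sample_id, names(counts))
    if (length(miss))
      stop("no mapping result for design sample(s): ",
           paste(miss, collapse = ", "))
    counts <- vapply(design$sample_id, function(s) {
      ct <- mappingCounts(counts[[s]])
      setNames(ct$total, ct$barcode_id)[barcodeIds(library)]
    }, numeric(length(library)))
    rownames(counts) <- barcodeIds(library)
  }
  counts <- as.matrix(counts)
  if (!setequal(colnames(counts), design$sample_id))
    stop("count matrix columns must match design sample_ids")
  counts <- counts[, design$sample_id, drop = FALSE]
  if (is.null(rownames(counts)) || !setequal(rownames(counts),
                                             barcodeIds(library)))
    stop("count matrix rows must match library barcode_ids")
  counts <- counts[barcodeIds(library), , drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      gene_id = unname(geneIds(library)),
      tag = unname(libraryTags(library)),
      row.names = barcodeIds(library)),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
}

#' Write a count table as TSV
#'
#' Columns: `barcode_id`, `gene_id`, `tag`, then one column per sample id;
#' rows in library (row) order.
#'
#' @param se a `SummarizedExperiment` from [screenCounts()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(se, path) {
  cts <- SummarizedExperiment::assay(se, "counts")
  rd <- SummarizedExperiment::rowData(se)
  df <- data.frame(barcode_id = rownames(se), gene_id = rd$gene_id,
                   tag = rd$tag, stringsAsFactors = FALSE,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(cts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [writeCountTable()]
#'
#' @param path count-table TSV.
#' @param design a sample design data.frame naming the sample columns.
#' @return a `SummarizedExperiment`.
#' @export
readCountTable <- function(path, design) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = c(barcode_id = "character",
                                  gene_id = "character", tag = "character"))
  design <- validateSampleDesign(design)
  miss <- setdiff(design$sample_id, names(df))
  if (length(miss))
    stop("count table lacks sample column(s): ", paste(miss, collapse = ", "))
  cts <- as.matrix(df[, design$sample_id, drop = FALSE])
  rownames(cts) <- df$barcode_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cts),
    rowData = S4Vectors::DataFrame(gene_id = df$gene_id, tag = df$tag,
                                   row.names = df$barcode_id),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
}

#' Collapse pair-tag UP/DN counts per strain
#'
#' For pair-tag libraries each gene carries an UP and a DN barcode whose
#' counts measure the same strain; before scoring they are summed into one
#' row per gene (configurable to the mean). Single-tag input is returned
#' unchanged.
#'
#' @param se a `SummarizedExperiment` from [screenCounts()].
#' @param fun `"sum"` (default) or `"mean"`.
#' @return a `SummarizedExperiment` with one row per gene (tag `"SINGLE"`),
#'   or `se` itself when no UP/DN tags are present.
#' @export
collapsePairTags <- function(se, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  rd <- SummarizedExperiment::rowData(se)
  if (!any(rd$tag %in% c("UP", "DN"))) return(se)
  cts <- SummarizedExperiment::assay(se, "counts")
  agg <- rowsum(cts, group = rd$gene_id)
  if (fun == "mean")
    agg <- agg / as.vector(table(rd$gene_id)[rownames(agg)])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = agg),
    rowData = S4Vectors::DataFrame(gene_id = rownames(agg),
                                   tag = "SINGLE", row.names = rownames(agg)),
    colData = SummarizedExperiment::colData(se))
}
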