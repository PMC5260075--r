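#' Construct a BarcodeLibrary
#'
#' @param barcode_id unique barcode identifiers.
#' @param gene_id target gene per barcode.
#' @param barcode_seq designed barcode sequences over {A,C,G,T} (uppercased
#'   at ingest; typically 18-25 nt).
#' @param tag `"SINGLE"` (shRNA/sgRNA-style), or `"UP"`/`"DN"` (pair-tag
#'   yeast deletion libraries). SINGLE never mixes with UP/DN.
#' @param primer_seq universal primer preceding the barcode in a read;
#'   empty string if the layout has no primer.
#' @param mid_seq multiplex ID (sample index) sequence; usually empty, MIDs
#'   are normally handled by [demultiplex()].
#' @return a [BarcodeLibrary-class].
#' @examples
#' barcodeLibrary(c("b1", "b2"), c("g1", "g1"), c("ACGTACGT", "TTGGCCAA"))
#' @export
barcodeLibrary <- function(barcode_id, gene_id, barcode_seq,
                           tag = "SINGLE", primer_seq = "", mid_seq = "") {
  n <- length(barcode_id)
  df <- data.frame(
    barcode_id = as.character(barcode_id),
    gene_id = as.character(gene_id),
    tag = rep_len(as.character(tag), n),
    barcode_seq = toupper(as.character(barcode_seq)),
    primer_seq = toupper(rep_len(as.character(primer_seq), n)),
    mid_seq = toupper(rep_len(as.character(mid_seq), n)),
    stringsAsFactors = FALSE)
  new("BarcodeLibrary", records = df)
}

#' Accessors for BarcodeLibrary
#'
#' @param x a [BarcodeLibrary-class].
#' @return `libraryRecords()` the full record data.frame; `barcodeIds()`,
#'   `geneIds()`, `barcodeSeqs()` (named by id), `libraryTags()` the
#'   respective columns; `isPairTag()` whether the library uses UP/DN tags;
#'   `libraryPrimer()` the unique universal primer (`""` if none, error if
#'   records disagree).
#' @export
libraryRecords <- function(x) x@records

#' @rdname libraryRecords
#' @export
barcodeIds <- function(x) x@records$barcode_id

#' @rdname libraryRecords
#' @export
geneIds <- function(x) setNames(x@records$gene_id, x@records$barcode_id)

#' @rdname libraryRecords
#' @export
barcodeSeqs <- function(x) setNames(x@records$barcode_seq, x@records$barcode_id)

#' @rdname libraryRecords
#' @export
libraryTags <- function(x) setNames(x@records$tag, x@records$barcode_id)

#' @rdname libraryRecords
#' @export
isPairTag <- function(x) any(x@records$tag %in% c("UP", "DN"))

#' @rdname libraryRecords
#' @export
libraryPrimer <- function(x) {
  p <- unique(x@records$primer_seq)
  p <- p[!is.na(p)]
  if (length(p) == 0L) return("")
  if (length(p) > 1L)
    stop("library has more than one distinct primer sequence: ",
         paste(p, collapse = ", "))
  p
}

#' @describeIn barcodeLibrary number of barcode records.
#' @param x a BarcodeLibrary.
#' @export
setMethod("length", "BarcodeLibrary", function(x) nrow(x@records))

#' @export
setMethod("show", "BarcodeLibrary", function(object) {
  df <- object@records
  cat("BarcodeLibrary:", nrow(df), "barcodes,",
      length(unique(df$gene_id)), "genes,",
      if (isPairTag(object)) "pair-tag (UP/DN)" else "single-tag", "\n")
  if (nrow(df)) {
    cat("  barcode length:", paste(range(nchar(df$barcode_seq)),
                                   collapse = "-"), "nt")
    if (any(df$primer_seq != "")) cat("; primer:", libraryPrimer(object))
    cat("\n")
  }
})

#' @export
#' @describeIn barcodeLibrary subset records by a logical or index vector.
#' @param i row index.
#' @param j,drop,... ignored.
setMethod("[", "BarcodeLibrary", function(x, i, j, ..., drop = FALSE) {
  df <- x@records[i, , drop = FALSE]
  rownames(df) <- NULL
  new("BarcodeLibrary", records = df)
})

#' Read a barcode library from a tab-delimited file
#'
#' The file must have a header naming at least `barcode_id`, `gene_id` and
#' `barcode_seq`; optional columns `tag` (UP/DN/SINGLE, default SINGLE),
#' `primer_seq` and `mid_seq`. Records are validated: duplicate ids,
#' non-ACGT barcode bases and mixed SINGLE/UP/DN tags are rejected with the
#' offending rows named.
#'
#' @param path library TSV.
#' @return a [BarcodeLibrary-class].
#' @export
readBarcodeLibrary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("barcode_id", "gene_id", "barcode_seq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("library file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  barcodeLibrary(df$barcode_id, df$gene_id, df$barcode_seq,
                 tag = if ("tag" %in% names(df)) df$tag else "SINGLE",
                 primer_seq = if ("primer_seq" %in% names(df)) df$primer_seq else "",
                 mid_seq = if ("mid_seq" %in% names(df)) df$mid_seq else "")
}

#' Write a barcode library in the library TSV schema
#'
#' @param x a [BarcodeLibrary-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBarcodeLibrary <- function(x, path) {
  stopifnot(is(x, "BarcodeLibrary"))
  write.table(x@records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Tab-delimited with header: `sample_id`, `condition` (case/control),
#' `replicate` (positive integer); optional `time_point` and `source_path`.
#' The combination (condition, replicate, time_point) must be unique.
#'
#' @param path design TSV.
#' @return a validated data.frame.
#' @export
readSampleDesign <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validateSampleDesign(df)
}

#' Validate a sample design data.frame
#'
#' @param df data.frame with at least `sample_id`, `condition`, `replicate`.
#' @return the design, with `time_point`/`source_path` filled with NA when
#'   absent.
#' @export
validateSampleDesign <- function(df) {
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design lacks required column(s): ", paste(miss, collapse = ", "))
  if (!all(df$condition %in% c("case", "control")))
    stop("condition must be 'case' or 'control'")
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  if (!"time_point" %in% names(df)) df$time_point <- NA
  if (!"source_path" %in% names(df)) df$source_path <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design")
  key <- paste(df$condition, df$replicate, df$time_point)
  if (anyDuplicated(key))
    stop("(condition, replicate, time_point) must be unique; duplicated: ",
         key[duplicated(key)][1L])
  df
}
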