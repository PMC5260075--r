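#' Construct a SeqMap from sequences and counts
#'
#' Duplicate sequences are collapsed by summing their counts; sequences are
#' uppercased at ingest so downstream comparisons are case-insensitive.
#'
#' @param sequences character vector of DNA sequences (need not be unique).
#' @param counts integer counts, one per sequence; defaults to 1 each, i.e.
#'   raw reads.
#' @return a [SeqMap-class] object.
#' @examples
#' seqMap(c("acgt", "ACGT", "ACGA"))
#' @export
seqMap <- function(sequences, counts = rep(1L, length(sequences))) {
  stopifnot(length(sequences) == length(counts))
  sequences <- toupper(as.character(sequences))
  counts <- as.integer(counts)
  if (length(sequences)) {
    agg <- rowsum(counts, group = sequences, reorder = FALSE)
    sequences <- rownames(agg)
    counts <- as.integer(agg[, 1L])
  }
  new("SeqMap", sequences = sequences, counts = counts)
}

#' @describeIn seqMap number of unique sequences.
#' @param x a SeqMap.
#' @export
setMethod("length", "SeqMap", function(x) length(x@sequences))

#' Accessors for SeqMap
#'
#' @param x a [SeqMap-class].
#' @return `seqMapSequences()` the unique sequences; `seqMapCounts()` their
#'   counts, named by sequence; `totalReads()` the number of raw reads
#'   collapsed (sum of counts).
#' @export
seqMapSequences <- function(x) x@sequences

#' @rdname seqMapSequences
#' @export
seqMapCounts <- function(x) setNames(x@counts, x@sequences)

#' @rdname seqMapSequences
#' @export
totalReads <- function(x) sum(as.numeric(x@counts))

#' @export
setMethod("show", "SeqMap", function(object) {
  cat("SeqMap with", length(object@sequences), "unique sequences,",
      format(totalReads(object), big.mark = ","), "reads\n")
  n <- min(3L, length(object@sequences))
  if (n > 0L)
    cat(paste0("  ", head(object@sequences, n), "\t",
               head(object@counts, n), collapse = "\n"), "\n")
})

#' @export
#' @describeIn seqMap coerce to a two-column data.frame.
#' @param row.names,optional,... passed on conventionally; unused.
as.data.frame.SeqMap <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(sequence = x@sequences, count = x@counts,
             stringsAsFactors = FALSE)
}

.read_fastq <- function(path) {
  lines <- readLines(path)
  # tolerate a trailing blank line
  if (length(lines) && lines[length(lines)] == "") lines <- lines[-length(lines)]
  if (length(lines) == 0L) return(character())
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record at line ",
         (length(lines) %/% 4L) * 4L + 1L)
  hdr <- seq(1L, length(lines), by = 4L)
  badh <- hdr[!startsWith(lines[hdr], "@")]
  if (length(badh))
    stop("malformed FASTQ '", path, "': expected '@' header at line ", badh[1L])
  plus <- hdr + 2L
  badp <- plus[!startsWith(lines[plus], "+")]
  if (length(badp))
    stop("malformed FASTQ '", path, "': expected '+' separator at line ",
         badp[1L])
  lines[hdr + 1L]  # quality strings discarded
}

.read_seqmap_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0L)
    return(data.frame(sequence = character(), count = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed seqmap '", path, "': expected two tab-separated fields ",
         "at line ", bad[1L])
  cnt <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(cnt))
    stop("malformed seqmap '", path, "': non-integer count at line ",
         which(is.na(cnt))[1L])
  data.frame(sequence = vapply(parts, `[`, "", 1L), count = cnt,
             stringsAsFactors = FALSE)
}

#' Read sequencing reads and collapse them into a SeqMap
#'
#' FASTQ and FASTA inputs are collapsed into unique sequences with counts;
#' a seqmap file (two tab-separated columns: sequence, count; no header) is
#' loaded directly. Quality strings are discarded and sequences uppercased.
#' The total count always equals the number of input records.
#'
#' @param path input file.
#' @param format `"fastq"`, `"fasta"`, `"seqmap"`, or `"auto"` (by file
#'   extension: `.fq`/`.fastq` -> fastq, `.fa`/`.fasta`/`.fna` -> fasta,
#'   anything else -> seqmap).
#' @return a [SeqMap-class]; an empty file yields an empty SeqMap.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "IIII"), f)
#' readReads(f)
#' @export
readReads <- function(path, format = c("auto", "fastq", "fasta", "seqmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("fq", "fastq")) "fastq"
      else if (ext %in% c("fa", "fasta", "fna")) "fasta"
      else "seqmap"
  }
  if (format == "fastq") {
    seqMap(.read_fastq(path))
  } else if (format == "fasta") {
    if (file.size(path) == 0L) return(seqMap(character()))
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    seqMap(as.character(ss))
  } else {
    df <- .read_seqmap_file(path)
    seqMap(df$sequence, df$count)
  }
}

#' Write a SeqMap as a two-column tab-delimited file
#'
#' The seqmap dialect: `sequence<TAB>count`, one entry per line, no header,
#' Unix line endings. `readReads(writeSeqMap(x), format = "seqmap")`
#' reproduces `x`.
#'
#' @param x a [SeqMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSeqMap <- function(x, path) {
  stopifnot(is(x, "SeqMap"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(x@sequences))
    writeLines(paste0(x@sequences, "\t", x@counts), con, sep = "\n")
  invisible(path)
}
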