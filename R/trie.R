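#' Build a trie index over barcode sequences
#'
#' Constructs a prefix tree whose root-to-terminal paths spell the library
#' barcode sequences. Identical sequences carrying different ids share one
#' terminal, so an exact search returns all of their ids. The trie supports
#' fast approximate search ([searchTrie()]) with mismatches, insertions and
#' deletions.
#'
#' @param x a [BarcodeLibrary-class], or a character vector of ACGT
#'   sequences (named with ids, otherwise ids `seq1`, `seq2`, ... are
#'   assigned).
#' @return a [BarcodeTrie-class].
#' @examples
#' tr <- buildTrie(c(b1 = "ACGT", b2 = "ACGA"))
#' searchTrie(tr, "ACGG", maxErrors = 1)
#' @export
buildTrie <- function(x) {
  if (is(x, "BarcodeLibrary")) {
    seqs <- x@records$barcode_seq
    ids <- x@records$barcode_id
  } else {
    seqs <- toupper(as.character(x))
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  }
  if (length(seqs) == 0L) stop("cannot build a trie over zero sequences")
  ptr <- .trie_build(seqs, ids)
  new("BarcodeTrie", ptr = ptr, ids = ids, sequences = seqs)
}

# external pointers do not survive serialization; rebuild transparently
.trie_ptr <- function(trie) {
  info <- tryCatch(.trie_size(trie@ptr), error = function(e) NULL)
  if (is.null(info) || info[["sequences"]] != length(trie@ids))
    return(.trie_build(trie@sequences, trie@ids))
  trie@ptr
}

#' @export
setMethod("show", "BarcodeTrie", function(object) {
  info <- .trie_size(.trie_ptr(object))
  cat("BarcodeTrie:", info[["sequences"]], "sequences,",
      info[["nodes"]], "nodes, max depth", info[["max_depth"]], "\n")
})

#' @describeIn buildTrie number of indexed sequences.
#' @export
setMethod("length", "BarcodeTrie", function(x) length(x@ids))

.MAX_BUDGET <- 5L

#' Search a trie for approximate prefix matches
#'
#' Returns every library sequence whose edit distance to a *prefix* of
#' `segment` is at most `maxErrors`, with its minimal distance and an
#' operation breakdown. Query bases beyond the end of a matched library
#' sequence are never penalized (dynamic-length end semantics), so reads
#' may run past the barcode freely; a library sequence may also hang over
#' the end of a short query via deletions, provided the total stays within
#' budget. Non-ACGT query bases (e.g. N) match nothing and always count as
#' mismatches.
#'
#' Hits are reported at the minimal error count per barcode; among equal-cost
#' alignments the one with fewest indels, then fewest insertions, then the
#' longest consumed query span is kept, which makes results deterministic.
#'
#' @param trie a [BarcodeTrie-class].
#' @param segment DNA string to search (read segment starting at the
#'   expected barcode position).
#' @param maxErrors error budget, 0-5. Budget 0 is exact matching.
#' @return data.frame with columns `barcode_id`, `errors`, `mismatches`,
#'   `insertions`, `deletions` (relative to the library sequence) and
#'   `consumed` (query bases covered by the alignment), ordered by
#'   (`errors`, `barcode_id`). Zero rows when nothing is within budget.
#' @export
searchTrie <- function(trie, segment, maxErrors = 0L) {
  stopifnot(is(trie, "BarcodeTrie"))
  maxErrors <- as.integer(maxErrors)
  if (maxErrors < 0L) stop("maxErrors must be >= 0")
  if (maxErrors > .MAX_BUDGET)
    stop("maxErrors capped at ", .MAX_BUDGET, " (trie recursion bound)")
  segment <- toupper(as.character(segment))
  if (length(segment) != 1L || nchar(segment) < 1L)
    stop("segment must be a single non-empty string")
  hits <- .trie_search(.trie_ptr(trie), segment, maxErrors)
  hits[order(hits$errors, hits$barcode_id), , drop = FALSE]
}

#' Pairwise barcode distance under static or dynamic comparison
#'
#' Static mode is the full global edit distance, every gap column counted.
#' Dynamic mode treats gap columns after the end of the first (reference)
#' sequence as free — "the sequence already finished" — i.e. the minimal
#' edit distance between `a` and any prefix of `b`; it is directional
#' (reference first) and never exceeds the static distance. This dynamic
#' comparison is what read mapping itself uses, with the library sequence
#' as the reference.
#'
#' @param a reference sequence.
#' @param b second sequence.
#' @param mode `"static"` or `"dynamic"`.
#' @return integer distance.
#' @examples
#' pairwiseDistance("AGCT", "ACTA", mode = "static")   # 2
#' pairwiseDistance("AGCT", "ACTA", mode = "dynamic")  # 1
#' @export
pairwiseDistance <- function(a, b, mode = c("static", "dynamic")) {
  mode <- match.arg(mode)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  if (mode == "static") .edit_static(a, b)
  else .prefix_align(a, b)[["errors"]]
}

#' Align a reference against the start of a query
#'
#' Minimal edit distance between `ref` and a prefix of `query`, with the
#' chosen alignment's operation breakdown and the number of query bases
#' consumed. Used for primer and MID matching: the consumed length marks
#' where the next read segment starts, so indels in the primer shift the
#' barcode start position by their net balance.
#'
#' @param ref reference sequence (primer or MID).
#' @param query read sequence (aligned from its first base).
#' @return named integer vector: `errors`, `mismatches`, `insertions`,
#'   `deletions`, `consumed`.
#' @export
prefixAlign <- function(ref, query) {
  .prefix_align(toupper(as.character(ref)), toupper(as.character(query)))
}
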