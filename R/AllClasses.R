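#' SeqMap: collapsed unique read sequences with counts
#'
#' The seqmap representation collapses raw reads into unique sequences and
#' their occurrence counts; barcode-seq data contain many identical short
#' reads, so mapping unique sequences once is much cheaper than mapping every
#' read.
#'
#' @slot sequences character vector of unique, uppercase DNA sequences
#'   (IUPAC ambiguity codes such as N are allowed and treated as mismatches
#'   downstream).
#' @slot counts integer vector of occurrence counts, parallel to
#'   `sequences`; the sum equals the number of raw reads collapsed.
#' @seealso [readReads()], [writeSeqMap()], [seqMap()]
#' @exportClass SeqMap
setClass("SeqMap", representation(sequences = "character", counts = "integer"))

setValidity("SeqMap", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@counts))
    msg <- c(msg, "sequences and counts must have equal length")
  if (anyDuplicated(object@sequences))
    msg <- c(msg, "sequences must be unique")
  if (length(object@counts) && any(object@counts < 1L))
    msg <- c(msg, "counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BarcodeLibrary: a validated table of designed barcodes
#'
#' One record per designed barcode: its id, target gene, tag role
#' (`SINGLE` for shRNA/sgRNA-style libraries, `UP`/`DN` for pair-tag yeast
#' deletion libraries), the barcode sequence, and optional universal primer
#' and multiplex-ID (MID) sequences.
#'
#' @slot records data.frame with columns `barcode_id`, `gene_id`, `tag`,
#'   `barcode_seq`, `primer_seq`, `mid_seq`.
#' @seealso [readBarcodeLibrary()], [barcodeLibrary()]
#' @exportClass BarcodeLibrary
setClass("BarcodeLibrary", representation(records = "data.frame"))

.LIB_COLS <- c("barcode_id", "gene_id", "tag", "barcode_seq", "primer_seq",
               "mid_seq")

setValidity("BarcodeLibrary", function(object) {
  df <- object@records
  msg <- character()
  if (!all(.LIB_COLS %in% names(df)))
    return(paste("records must have columns:", paste(.LIB_COLS, collapse = ", ")))
  if (anyDuplicated(df$barcode_id)) {
    dup <- unique(df$barcode_id[duplicated(df$barcode_id)])
    msg <- c(msg, paste0("duplicate barcode_id: ", paste(dup, collapse = ", ")))
  }
  bad <- which(is.na(df$barcode_seq) | df$barcode_seq == "" |
                 grepl("[^ACGT]", df$barcode_seq))
  if (length(bad))
    msg <- c(msg, paste0("barcode_seq must be non-empty over {A,C,G,T}; ",
                         "offending rows: ", paste(bad, collapse = ", ")))
  if (!all(df$tag %in% c("UP", "DN", "SINGLE")))
    msg <- c(msg, "tag must be one of UP, DN, SINGLE")
  if (any(df$tag == "SINGLE") && any(df$tag %in% c("UP", "DN")))
    msg <- c(msg, "tag SINGLE must not be mixed with UP/DN in one library")
  if (length(msg)) msg else TRUE
})

#' BarcodeTrie: trie index over library barcode sequences
#'
#' A trie (prefix tree) whose root-to-terminal paths spell the library
#' barcode sequences; terminals carry the ids of the barcodes ending there
#' (identical sequences under different ids share one terminal). Searching
#' walks the trie with a banded edit-distance row, so every barcode within
#' the error budget of a prefix of the query is found in one pass.
#'
#' The index lives in native memory (external pointer) and is rebuilt from
#' `sequences`/`ids` if the pointer is invalid, e.g. after serialization.
#'
#' @slot ptr external pointer to the native trie.
#' @slot ids character vector of barcode ids, insertion order.
#' @slot sequences character vector of the indexed sequences.
#' @seealso [buildTrie()], [searchTrie()]
#' @exportClass BarcodeTrie
setClass("BarcodeTrie",
         representation(ptr = "externalptr", ids = "character",
                        sequences = "character"))

#' MappingResult: per-barcode counts for one mapped sample
#'
#' Holds the outcome of mapping one sample's reads against a barcode
#' library: per-barcode exact (0-error) and mutated (>= 1 error) counts,
#' per-variant-sequence counts for mutated hits, and the sample-level
#' mapped/ambiguous/unmapped/filtered tallies. Reads with more than one
#' minimal-error hit are ambiguous and never assigned.
#'
#' @slot sampleId sample identifier (may be `NA`).
#' @slot counts data.frame: `barcode_id`, `gene_id`, `tag`, `exact_count`,
#'   `mutated_count` (library row order).
#' @slot variants data.frame: `barcode_id`, `variant_seq`, `errors`, `count`
#'   — the read barcode-segment sequence of every mutated unique hit.
#' @slot totals named numeric: `input`, `mapped`, `ambiguous`, `unmapped`,
#'   `filtered`; `mapped + ambiguous + unmapped + filtered == input`.
#' @slot barcodeMaxErrors the barcode error budget the result was mapped
#'   with (0 for perfect-only runs).
#' @seealso [mapSample()], [detectErroneous()]
#' @exportClass MappingResult
setClass("MappingResult",
         representation(sampleId = "character", counts = "data.frame",
                        variants = "data.frame", totals = "numeric",
                        barcodeMaxErrors = "integer"))

setValidity("MappingResult", function(object) {
  msg <- character()
  tot <- object@totals
  need <- c("input", "mapped", "ambiguous", "unmapped", "filtered")
  if (!all(need %in% names(tot)))
    return(paste("totals must contain:", paste(need, collapse = ", ")))
  if (abs(tot[["mapped"]] + tot[["ambiguous"]] + tot[["unmapped"]] +
            tot[["filtered"]] - tot[["input"]]) > 1e-9)
    msg <- c(msg, "mapped + ambiguous + unmapped + filtered must equal input")
  cts <- object@counts
  if (abs(sum(cts$exact_count + cts$mutated_count) - tot[["mapped"]]) > 1e-9)
    msg <- c(msg, "per-barcode counts must sum to the mapped total")
  if (length(msg)) msg else TRUE
})
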