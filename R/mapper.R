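#' Mapper configuration
#'
#' Controls the per-read layout walk: optional MID, optional universal
#' primer, then the barcode. Budgets are maximum edit errors per segment.
#' Indels in the primer alignment shift the barcode start by their net
#' balance, correcting barcode position shifts.
#'
#' @param barcodeMaxErrors barcode error budget (default 2, the usual
#'   imperfect-matching setting).
#' @param primerMaxErrors primer error budget (default 2).
#' @param midMaxErrors MID error budget (default 0; MIDs are short, and a
#'   miscalled index costs a whole sample).
#' @param barcodeStart `"auto"` (barcode starts where the primer alignment
#'   ends, or at position 1 when the library has no primer) or a 1-based
#'   integer overriding the start, in which case primer matching is skipped.
#' @param perfectOnly force all budgets to 0 (perfect matching).
#' @return a `MapperConfig` list.
#' @export
mapperConfig <- function(barcodeMaxErrors = 2L, primerMaxErrors = 2L,
                         midMaxErrors = 0L, barcodeStart = "auto",
                         perfectOnly = FALSE) {
  cfg <- list(barcodeMaxErrors = as.integer(barcodeMaxErrors),
              primerMaxErrors = as.integer(primerMaxErrors),
              midMaxErrors = as.integer(midMaxErrors),
              barcodeStart = barcodeStart,
              perfectOnly = isTRUE(perfectOnly))
  if (cfg$perfectOnly)
    cfg$barcodeMaxErrors <- cfg$primerMaxErrors <- cfg$midMaxErrors <- 0L
  if (any(c(cfg$barcodeMaxErrors, cfg$primerMaxErrors, cfg$midMaxErrors) < 0L))
    stop("error budgets must be >= 0")
  if (!identical(cfg$barcodeStart, "auto")) {
    cfg$barcodeStart <- as.integer(cfg$barcodeStart)
    if (is.na(cfg$barcodeStart) || cfg$barcodeStart < 1L)
      stop("barcodeStart must be 'auto' or a positive integer")
  }
  class(cfg) <- "MapperConfig"
  cfg
}

# Decide the fate of one read: locate the barcode segment (primer-adjusted
# start), search the trie, and classify as unique / ambiguous / unmapped.
.map_one <- function(read, trie, primer, config) {
  start <- 1L
  if (identical(config$barcodeStart, "auto")) {
    if (nzchar(primer)) {
      al <- .prefix_align(primer, read)
      if (al[["errors"]] > config$primerMaxErrors)
        return(list(status = "unmapped"))
      start <- al[["consumed"]] + 1L
    }
  } else {
    start <- config$barcodeStart
  }
  if (start > nchar(read)) return(list(status = "unmapped"))
  seg <- substr(read, start, nchar(read))
  hits <- .trie_search(.trie_ptr(trie), seg, config$barcodeMaxErrors)
  if (nrow(hits) == 0L) return(list(status = "unmapped"))
  minimal <- hits[hits$errors == min(hits$errors), , drop = FALSE]
  if (nrow(minimal) > 1L)
    return(list(status = "ambiguous", ids = sort(minimal$barcode_id)))
  list(status = "unique", barcode_id = minimal$barcode_id[1L],
       errors = minimal$errors[1L],
       variant_seq = substr(read, start, start + minimal$consumed[1L] - 1L))
}

#' Map a single read
#'
#' Walks one read through the configured layout: primer alignment fixes the
#' barcode start (net primer indels shift it), then the barcode segment is
#' searched in the trie. Exactly one minimal-error hit is a unique
#' assignment; several minimal-error hits are ambiguous, never arbitrarily
#' resolved; no hit within budget is unmapped.
#'
#' @param read read sequence (MID already stripped, see [demultiplex()]).
#' @param library the [BarcodeLibrary-class] (supplies the primer).
#' @param trie [BarcodeTrie-class] over the library (built if `NULL`).
#' @param config a [mapperConfig()].
#' @return a list with `status` (`"unique"`, `"ambiguous"`, `"unmapped"`)
#'   and, for unique hits, `barcode_id`, `errors` and `variant_seq` (the
#'   consumed read segment); for ambiguous, the tied `ids`.
#' @export
mapRead <- function(read, library, trie = NULL, config = mapperConfig()) {
  if (is.null(trie)) trie <- buildTrie(library)
  .map_one(toupper(as.character(read)), trie, libraryPrimer(library), config)
}

#' Map a sample's reads against a barcode library
#'
#' Applies [mapRead()] to every unique sequence of the seqmap, weighting
#' outcomes by the sequence counts. Per barcode, reads mapped with 0 errors
#' accumulate `exact_count` and reads mapped with >= 1 error accumulate
#' `mutated_count`; the read barcode-segment string of every mutated unique
#' hit is recorded in the variants table (the evidence used by
#' [detectErroneous()]). Ambiguous and unmapped reads are tallied;
#' `mapped + ambiguous + unmapped` always equals the input read count.
#'
#' @param seqmap a [SeqMap-class] of the sample's reads.
#' @param library a [BarcodeLibrary-class].
#' @param config a [mapperConfig()].
#' @param tag restrict mapping to a sub-library: `"UP"`, `"DN"`, or `NULL`
#'   (all records). Pair-tag samples sequenced per tag should be mapped as
#'   two independent runs.
#' @param sampleId identifier stored in the result.
#' @return a [MappingResult-class].
#' @examples
#' lib <- barcodeLibrary("b1", "g1", "ACGTACGTACGT", primer_seq = "TTAACC")
#' sm <- seqMap(c("TTAACCACGTACGTACGT", "TTAACCACGTACGAACGT"))
#' mapSample(sm, lib)
#' @export
mapSample <- function(seqmap, library, config = mapperConfig(), tag = NULL,
                      sampleId = NA_character_) {
  stopifnot(is(seqmap, "SeqMap"), is(library, "BarcodeLibrary"))
  if (!is.null(tag)) {
    keep <- libraryRecords(library)$tag == tag
    if (!any(keep)) stop("no library records with tag '", tag, "'")
    library <- library[keep]
  }
  trie <- buildTrie(library)
  primer <- libraryPrimer(library)
  ids <- barcodeIds(library)
  exact <- mutated <- setNames(numeric(length(ids)), ids)
  seqs <- seqmap@sequences
  cnts <- as.numeric(seqmap@counts)
  start0 <- if (identical(config$barcodeStart, "auto")) -1L
            else config$barcodeStart - 1L
  mb <- .map_batch(.trie_ptr(trie), seqs, primer, config$primerMaxErrors,
                   config$barcodeMaxErrors, start0)
  uniq <- mb$status == 0L
  ex <- uniq & mb$errors == 0L
  mu <- uniq & mb$errors > 0L
  if (any(ex)) {
    agg <- rowsum(cnts[ex], group = mb$hit[ex])
    exact[as.integer(rownames(agg))] <- agg[, 1L]
  }
  if (any(mu)) {
    agg <- rowsum(cnts[mu], group = mb$hit[mu])
    mutated[as.integer(rownames(agg))] <- agg[, 1L]
  }
  ambiguous <- sum(cnts[mb$status == 1L])
  unmapped <- sum(cnts[mb$status == 2L])
  variants <- data.frame(barcode_id = ids[mb$hit[mu]],
                         variant_seq = mb$variant[mu],
                         errors = as.numeric(mb$errors[mu]),
                         count = cnts[mu],
                         stringsAsFactors = FALSE)
  if (nrow(variants)) {
    key <- paste(variants$barcode_id, variants$variant_seq, sep = "\r")
    agg <- rowsum(variants$count, key, reorder = FALSE)
    first <- !duplicated(key)
    variants <- variants[first, , drop = FALSE]
    variants$count <- as.numeric(agg[match(key[first], rownames(agg)), 1L])
    variants <- variants[order(variants$barcode_id, -variants$count,
                               variants$variant_seq), , drop = FALSE]
    rownames(variants) <- NULL
  }
  counts <- data.frame(barcode_id = ids,
                       gene_id = unname(geneIds(library)),
                       tag = unname(libraryTags(library)),
                       exact_count = unname(exact),
                       mutated_count = unname(mutated),
                       stringsAsFactors = FALSE)
  new("MappingResult", sampleId = as.character(sampleId), counts = counts,
      variants = variants,
      totals = c(input = sum(cnts), mapped = sum(exact) + sum(mutated),
                 ambiguous = ambiguous, unmapped = unmapped, filtered = 0),
      barcodeMaxErrors = config$barcodeMaxErrors)
}

#' Accessors for MappingResult
#'
#' @param x a [MappingResult-class].
#' @return `mappingCounts()` the per-barcode count table (with a `total`
#'   column added); `mappingVariants()` the mutated-hit variant table;
#'   `mappingTotals()` the named tallies (`input`, `mapped`, `ambiguous`,
#'   `unmapped`, `filtered`); `mappingSampleId()` the sample identifier.
#' @export
mappingCounts <- function(x) {
  df <- x@counts
  df$total <- df$exact_count + df$mutated_count
  df
}

#' @rdname mappingCounts
#' @export
mappingVariants <- function(x) x@variants

#' @rdname mappingCounts
#' @export
mappingTotals <- function(x) x@totals

#' @rdname mappingCounts
#' @export
mappingSampleId <- function(x) x@sampleId

#' @export
setMethod("show", "MappingResult", function(object) {
  tot <- object@totals
  pct <- function(v) sprintf("%.2f%%", if (tot[["input"]] > 0)
    100 * v / tot[["input"]] else 0)
  cat("MappingResult", if (!is.na(object@sampleId))
    paste0("[", object@sampleId, "]"), "\n")
  cat("  input reads:", format(tot[["input"]], big.mark = ","), "\n")
  cat("  mapped:     ", format(tot[["mapped"]], big.mark = ","),
      paste0("(", pct(tot[["mapped"]]), ")"), "\n")
  cat("  ambiguous:  ", format(tot[["ambiguous"]], big.mark = ","),
      paste0("(", pct(tot[["ambiguous"]]), ")"), "\n")
  cat("  unmapped:   ", format(tot[["unmapped"]], big.mark = ","),
      paste0("(", pct(tot[["unmapped"]]), ")"), "\n")
  if (tot[["filtered"]] > 0)
    cat("  filtered:   ", format(tot[["filtered"]], big.mark = ","), "\n")
})

#' Demultiplex a seqmap by 5' multiplex IDs (MIDs)
#'
#' Each read is assigned to the unique MID matching its 5' prefix within
#' the MID error budget; reads matching no MID or tied between several go
#' to the `"unassigned"` bin. With exact matching and nested MIDs of
#' unequal length (e.g. 9-17 nt indices) the longest match wins. The
#' matched MID prefix is stripped from assigned reads, so downstream
#' mapping starts at the primer; unassigned reads are kept verbatim. The
#' bins partition the input counts.
#'
#' @param seqmap a [SeqMap-class].
#' @param mids character vector of MID sequences, optionally named with
#'   sample ids (sequences used as names otherwise). Must be distinct.
#'   Empty vector: the input is returned as a single `"all"` bin.
#' @param config a [mapperConfig()]; only `midMaxErrors` is used.
#' @return named list of [SeqMap-class] bins, one per MID plus
#'   `"unassigned"`.
#' @export
demultiplex <- function(seqmap, mids, config = mapperConfig()) {
  stopifnot(is(seqmap, "SeqMap"))
  mids <- setNames(toupper(as.character(mids)), names(mids))
  if (length(mids) == 0L) return(list(all = seqmap))
  if (anyDuplicated(mids))
    stop("duplicate MID sequences: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))
  bin_names <- names(mids)
  if (is.null(bin_names) || any(!nzchar(bin_names))) bin_names <- mids
  budget <- config$midMaxErrors
  seqs <- seqmap@sequences
  assign_bin <- integer(length(seqs))  # 0 = unassigned
  strip <- integer(length(seqs))
  for (k in seq_along(seqs)) {
    s <- seqs[k]
    if (budget == 0L) {
      hit <- which(startsWith(s, mids))
      cost <- rep(0L, length(hit))
      cons <- nchar(mids)[hit]
    } else {
      al <- vapply(mids, function(m) .prefix_align(m, s),
                   integer(5))
      ok <- which(al["errors", ] <= budget)
      hit <- ok
      cost <- al["errors", ok]
      cons <- al["consumed", ok]
    }
    if (length(hit) == 0L) next
    best <- which(cost == min(cost))
    if (length(best) > 1L) {
      # longest-match-first; a length tie stays unassigned
      len <- nchar(mids)[hit[best]]
      best <- best[len == max(len)]
      if (length(best) > 1L) next
    }
    assign_bin[k] <- hit[best]
    strip[k] <- cons[best]
  }
  out <- vector("list", length(mids) + 1L)
  names(out) <- c(bin_names, "unassigned")
  for (b in seq_along(mids)) {
    sel <- assign_bin == b
    out[[b]] <- seqMap(substring(seqs[sel], strip[sel] + 1L),
                       seqmap@counts[sel])
  }
  sel <- assign_bin == 0L
  out[["unassigned"]] <- seqMap(seqs[sel], seqmap@counts[sel])
  out
}

#' Write mapping outputs as tab-delimited text
#'
#' Three files under `dir`: `<prefix>.counts.tsv` (barcode_id, gene_id,
#' tag, exact_count, mutated_count, total), `<prefix>.variants.tsv`
#' (barcode_id, variant_seq, errors, count) and `<prefix>.summary.tsv`
#' (metric/value rows with mapped/ambiguous/unmapped counts and
#' percentages).
#'
#' @param x a [MappingResult-class].
#' @param dir output directory (created if needed).
#' @param prefix file prefix; defaults to the sample id or `"sample"`.
#' @return the three paths, invisibly.
#' @export
writeMappingResult <- function(x, dir, prefix = NULL) {
  stopifnot(is(x, "MappingResult"))
  if (is.null(prefix))
    prefix <- if (!is.na(x@sampleId)) x@sampleId else "sample"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".counts.tsv", ".variants.tsv",
                                           ".summary.tsv")))
  write.table(mappingCounts(x), paths[1L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x@variants, paths[2L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tot <- x@totals
  pct <- function(v) if (tot[["input"]] > 0) 100 * v / tot[["input"]] else 0
  sm <- data.frame(
    metric = c("sample_id", "input", "mapped", "mapped_pct", "ambiguous",
               "ambiguous_pct", "unmapped", "unmapped_pct", "filtered",
               "barcode_max_errors"),
    value = c(x@sampleId, tot[["input"]], tot[["mapped"]],
              sprintf("%.4f", pct(tot[["mapped"]])), tot[["ambiguous"]],
              sprintf("%.4f", pct(tot[["ambiguous"]])), tot[["unmapped"]],
              sprintf("%.4f", pct(tot[["unmapped"]])), tot[["filtered"]],
              x@barcodeMaxErrors),
    stringsAsFactors = FALSE)
  write.table(sm, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Re-load mapping outputs written by [writeMappingResult()]
#'
#' @param dir directory holding the three TSVs.
#' @param prefix the file prefix used when writing.
#' @return a [MappingResult-class].
#' @export
readMappingResult <- function(dir, prefix) {
  counts <- read.delim(file.path(dir, paste0(prefix, ".counts.tsv")),
                       stringsAsFactors = FALSE,
                       colClasses = c(barcode_id = "character",
                                      gene_id = "character",
                                      tag = "character"))
  counts$total <- NULL
  variants <- read.delim(file.path(dir, paste0(prefix, ".variants.tsv")),
                         stringsAsFactors = FALSE,
                         colClasses = c(barcode_id = "character",
                                        variant_seq = "character"))
  sm <- read.delim(file.path(dir, paste0(prefix, ".summary.tsv")),
                   stringsAsFactors = FALSE)
  val <- setNames(sm$value, sm$metric)
  new("MappingResult", sampleId = val[["sample_id"]], counts = counts,
      variants = variants,
      totals = c(input = as.numeric(val[["input"]]),
                 mapped = as.numeric(val[["mapped"]]),
                 ambiguous = as.numeric(val[["ambiguous"]]),
                 unmapped = as.numeric(val[["unmapped"]]),
                 filtered = as.numeric(val[["filtered"]])),
      barcodeMaxErrors = as.integer(val[["barcode_max_errors"]]))
}
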