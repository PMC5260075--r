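#' Report all pairwise barcode similarities in a library
#'
#' Computes, for every unordered pair of barcodes, the static distance
#' (full global edit distance) and the dynamic distance (end gaps after the
#' reference sequence are free; the minimum over both directions is
#' reported) and returns the pairs within `maxDistance` under either mode.
#' Each pair is labeled `intra` (same gene) or `inter` (different genes):
#' inter pairs are the dangerous ones, since a one-base sequencing or
#' synthesis error can move reads to the wrong gene (off-target).
#'
#' The summary counts, per comparison mode, the barcodes having at least
#' one similar partner, split by whether all partners are intra, all inter,
#' or both.
#'
#' @param library a [BarcodeLibrary-class].
#' @param maxDistance similarity threshold (default 1 base).
#' @return list with `pairs` (data.frame: `barcode_id_a`, `barcode_id_b`,
#'   `distance_static`, `distance_dynamic`, `relation`) and `summary`
#'   (data.frame: one row per mode with barcode counts having similar
#'   partners, split intra / intra&inter / inter, plus percentages).
#' @export
similarityReport <- function(library, maxDistance = 1L) {
  stopifnot(is(library, "BarcodeLibrary"))
  df <- libraryRecords(library)
  rep <- .pair_report(df$barcode_seq, as.integer(maxDistance))
  pairs <- data.frame(
    barcode_id_a = df$barcode_id[rep$i],
    barcode_id_b = df$barcode_id[rep$j],
    distance_static = rep$distance_static,
    distance_dynamic = rep$distance_dynamic,
    relation = ifelse(df$gene_id[rep$i] == df$gene_id[rep$j],
                      "intra", "inter"),
    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c("static", "dynamic"), function(mode) {
    d <- if (mode == "static") pairs$distance_static else pairs$distance_dynamic
    p <- pairs[d <= maxDistance, , drop = FALSE]
    ids <- c(p$barcode_id_a, p$barcode_id_b)
    rel <- c(p$relation, p$relation)
    has_intra <- unique(ids[rel == "intra"])
    has_inter <- unique(ids[rel == "inter"])
    both <- intersect(has_intra, has_inter)
    n <- length(unique(ids))
    pctf <- function(k) if (nrow(df)) 100 * k / nrow(df) else 0
    data.frame(mode = mode, count = n,
               intra = length(setdiff(has_intra, both)),
               intra_and_inter = length(both),
               inter = length(setdiff(has_inter, both)),
               pct = pctf(n), stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, summary = summ)
}

#' Detect erroneous barcodes from a mapping result
#'
#' An erroneous barcode is one whose physical sequence in the pool differs
#' from its design (synthesis, strain-maintenance or integration error):
#' under imperfect matching its mapped counts are dominated by one mutant
#' variant and vastly exceed its exact-design counts, unlike ordinary
#' sequencing/PCR errors which spread thinly over many variants. A barcode
#' is flagged iff all three hold:
#' \itemize{
#'   \item total (exact + mutated) count >= `minImperfectCount`;
#'   \item pseudocounted ratio `(mutated + 1) / (exact + 1)` >=
#'     `ratioThreshold`;
#'   \item a single variant sequence holds more than `dominantFraction` of
#'     the mutated reads (the putative true pool sequence).
#' }
#'
#' @param result a [MappingResult-class] mapped with `barcodeMaxErrors >= 1`
#'   (a perfect-only run has no mutated counts and is rejected).
#' @param minImperfectCount minimum total count (default 100).
#' @param ratioThreshold minimum mutated/exact pseudocounted ratio
#'   (default 10).
#' @param dominantFraction fraction of mutated reads one variant must
#'   exceed (default 0.5).
#' @return data.frame (all barcodes with a candidate dominant variant, plus
#'   every flagged barcode): `barcode_id`, `perfect_count`,
#'   `imperfect_count`, `dominant_variant_seq`, `dominant_variant_count`,
#'   `ratio`, `flagged`.
#' @export
detectErroneous <- function(result, minImperfectCount = 100,
                            ratioThreshold = 10, dominantFraction = 0.5) {
  stopifnot(is(result, "MappingResult"))
  if (result@barcodeMaxErrors < 1L)
    stop("result was mapped perfect-only; erroneous-barcode detection ",
         "needs both exact and mutated counts (barcodeMaxErrors >= 1)")
  cts <- result@counts
  vars <- result@variants
  dom_seq <- rep(NA_character_, nrow(cts))
  dom_cnt <- numeric(nrow(cts))
  if (nrow(vars)) {
    # variants are sorted by count within barcode; the first row per
    # barcode is its dominant variant
    first <- vars[!duplicated(vars$barcode_id), , drop = FALSE]
    m <- match(cts$barcode_id, first$barcode_id)
    dom_seq <- first$variant_seq[m]
    dom_cnt <- ifelse(is.na(m), 0, first$count[m])
  }
  imperfect <- cts$exact_count + cts$mutated_count
  ratio <- (cts$mutated_count + 1) / (cts$exact_count + 1)
  flagged <- imperfect >= minImperfectCount &
    ratio >= ratioThreshold &
    cts$mutated_count > 0 & dom_cnt > dominantFraction * cts$mutated_count
  out <- data.frame(barcode_id = cts$barcode_id,
                    perfect_count = cts$exact_count,
                    imperfect_count = imperfect,
                    dominant_variant_seq = dom_seq,
                    dominant_variant_count = dom_cnt,
                    ratio = ratio, flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove or repair erroneous barcodes in a mapping result
#'
#' `policy = "remove"` zeroes the flagged barcodes' counts and moves them
#' into the `filtered` tally (conservation is re-established against it),
#' excluding them from analysis — the right treatment for shRNA/sgRNA
#' screens where a mutant construct no longer silences its target.
#' `policy = "replace"` keeps the counts but re-attributes each flagged
#' barcode's dominant-variant reads from mutated to exact, treating the
#' dominant variant as the true pool sequence; use [applyFixes()] to obtain
#' the corresponding fixed library for re-mapping.
#'
#' @param result a [MappingResult-class].
#' @param calls output of [detectErroneous()] on the same result.
#' @param policy `"remove"` or `"replace"`.
#' @param library the [BarcodeLibrary-class] the result was mapped against;
#'   required for `"replace"` (collision check).
#' @return a modified [MappingResult-class]. With no flagged calls the
#'   result is returned unchanged.
#' @export
filterErroneous <- function(result, calls, policy = c("remove", "replace"),
                            library = NULL) {
  policy <- match.arg(policy)
  stopifnot(is(result, "MappingResult"))
  bad <- calls$barcode_id[calls$flagged]
  if (length(bad) == 0L) return(result)
  cts <- result@counts
  if (!all(bad %in% cts$barcode_id))
    stop("calls do not match this result: unknown barcode_id ",
         paste(setdiff(bad, cts$barcode_id), collapse = ", "))
  if (policy == "remove") {
    sel <- cts$barcode_id %in% bad
    removed <- sum(cts$exact_count[sel] + cts$mutated_count[sel])
    cts$exact_count[sel] <- 0
    cts$mutated_count[sel] <- 0
    tot <- result@totals
    tot[["mapped"]] <- tot[["mapped"]] - removed
    tot[["filtered"]] <- tot[["filtered"]] + removed
    vars <- result@variants
    vars <- vars[!(vars$barcode_id %in% bad), , drop = FALSE]
    return(new("MappingResult", sampleId = result@sampleId, counts = cts,
               variants = vars, totals = tot,
               barcodeMaxErrors = result@barcodeMaxErrors))
  }
  # replace: dominant variant becomes the accepted sequence
  if (is.null(library))
    stop("policy 'replace' needs the library for the collision check")
  .check_fix_collisions(library, calls)
  vars <- result@variants
  for (b in bad) {
    dom <- calls$dominant_variant_seq[calls$barcode_id == b]
    sel_v <- vars$barcode_id == b & vars$variant_seq == dom
    moved <- sum(vars$count[sel_v])
    vars <- vars[!sel_v, , drop = FALSE]
    i <- which(cts$barcode_id == b)
    cts$exact_count[i] <- cts$exact_count[i] + moved
    cts$mutated_count[i] <- cts$mutated_count[i] - moved
  }
  new("MappingResult", sampleId = result@sampleId, counts = cts,
      variants = vars, totals = result@totals,
      barcodeMaxErrors = result@barcodeMaxErrors)
}

.check_fix_collisions <- function(library, calls) {
  df <- libraryRecords(library)
  bad <- calls[calls$flagged, , drop = FALSE]
  for (k in seq_len(nrow(bad))) {
    hit <- df$barcode_id[df$barcode_seq == bad$dominant_variant_seq[k] &
                           df$barcode_id != bad$barcode_id[k]]
    if (length(hit))
      stop("replacement sequence for ", bad$barcode_id[k],
           " collides with existing barcode ", hit[1L])
  }
  invisible(TRUE)
}

#' Fix a library by swapping flagged barcodes to their dominant variants
#'
#' Produces the "error-free" library implied by [detectErroneous()] calls:
#' each flagged barcode's designed sequence is replaced by its dominant
#' observed variant. Re-mapping the same reads against the fixed library
#' moves the variant's reads into the exact counts.
#'
#' @param library a [BarcodeLibrary-class].
#' @param calls output of [detectErroneous()].
#' @return a fixed [BarcodeLibrary-class].
#' @export
applyFixes <- function(library, calls) {
  stopifnot(is(library, "BarcodeLibrary"))
  .check_fix_collisions(library, calls)
  df <- libraryRecords(library)
  bad <- calls[calls$flagged, , drop = FALSE]
  m <- match(bad$barcode_id, df$barcode_id)
  if (anyNA(m))
    stop("calls name barcodes absent from the library: ",
         paste(bad$barcode_id[is.na(m)], collapse = ", "))
  df$barcode_seq[m] <- bad$dominant_variant_seq
  new("BarcodeLibrary", records = df)
}
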