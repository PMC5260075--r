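#' Pseudocounted ratio normalization and condition means
#'
#' Each barcode count is incremented by 1 (so every barcode is positive)
#' and divided by the sample's total of incremented counts, giving
#' per-sample ratios that sum to 1. Condition means are arithmetic means of
#' the ratios over that condition's replicates; raw-count condition means
#' are also returned for the low-count filter, which operates on counts,
#' not ratios.
#'
#' @param se a `SummarizedExperiment` from [screenCounts()] with at least
#'   one case and one control sample.
#' @return list: `ratios` (matrix, same shape as counts), `case_ratio` /
#'   `control_ratio` (per-barcode mean ratios), `case_raw` / `control_raw`
#'   (per-barcode mean raw counts).
#' @export
normalizeCounts <- function(se) {
  cts <- SummarizedExperiment::assay(se, "counts")
  cond <- SummarizedExperiment::colData(se)$condition
  if (!any(cond == "case") || !any(cond == "control"))
    stop("need at least one case and one control sample")
  if (any(colSums(cts) == 0))
    warning("all-zero sample(s): ",
            paste(colnames(cts)[colSums(cts) == 0], collapse = ", "),
            " (ratios are uniform)")
  plus <- cts + 1
  ratios <- sweep(plus, 2L, colSums(plus), `/`)
  list(ratios = ratios,
       case_ratio = rowMeans(ratios[, cond == "case", drop = FALSE]),
       control_ratio = rowMeans(ratios[, cond == "control", drop = FALSE]),
       case_raw = rowMeans(cts[, cond == "case", drop = FALSE]),
       control_raw = rowMeans(cts[, cond == "control", drop = FALSE]))
}

#' Low-count filter
#'
#' A barcode is filtered iff *both* its case and control mean raw counts
#' fall below `minCount` — barcodes measured adequately in either
#' condition are kept, since complete depletion in the case arm is exactly
#' the signal of interest.
#'
#' @param se a `SummarizedExperiment` from [screenCounts()].
#' @param minCount threshold (default 100).
#' @return logical vector, `TRUE` for filtered barcodes, named by barcode.
#' @export
filterLowCount <- function(se, minCount = 100) {
  nm <- normalizeCounts(se)
  setNames(nm$case_raw < minCount & nm$control_raw < minCount, rownames(se))
}

#' Per-barcode fold-change and z-scores
#'
#' For every unfiltered barcode the fc-score is the log2 quotient of
#' pseudocounted mean case and control ratios (negative = depleted in the
#' case arm), and the z-score standardizes the fc-scores across all
#' unfiltered barcodes: `z = (x - mean) / sd`. Ranks are ascending in z
#' (most depleted first), ties broken by barcode id.
#'
#' @param se a `SummarizedExperiment` from [screenCounts()].
#' @param minCount low-count filter threshold (see [filterLowCount()]).
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`.
#' @return data.frame: `barcode_id`, `gene_id`, `mean_case_ratio`,
#'   `mean_control_ratio`, `fc_score`, `z_score`, `rank`, `filtered`,
#'   `filter_reason` (`NA`, `"low_count"`, or later
#'   `"off_target_cluster"`). Filtered barcodes carry `NA` scores.
#' @export
scoreBarcodes <- function(se, minCount = 100, sdType = c("sample",
                                                         "population")) {
  sdType <- match.arg(sdType)
  nm <- normalizeCounts(se)
  low <- filterLowCount(se, minCount)
  keep <- !low
  if (sum(keep) < 2L)
    stop("fewer than 2 unfiltered barcodes; cannot standardize")
  fc <- log2(nm$case_ratio / nm$control_ratio)
  x <- fc[keep]
  s <- if (sdType == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0)
    stop("fc-scores have zero spread; z-scores undefined")
  z <- rep(NA_real_, length(fc))
  z[keep] <- (x - mean(x)) / s
  rk <- rep(NA_integer_, length(fc))
  ids <- rownames(se)
  ord <- order(z[keep], ids[keep])
  rk[keep][ord] <- seq_len(sum(keep))
  out <- data.frame(
    barcode_id = ids,
    gene_id = SummarizedExperiment::rowData(se)$gene_id,
    mean_case_ratio = unname(nm$case_ratio),
    mean_control_ratio = unname(nm$control_ratio),
    fc_score = ifelse(keep, fc, NA_real_),
    z_score = z, rank = rk,
    filtered = low,
    filter_reason = ifelse(low, "low_count", NA_character_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# 1D single-linkage: sort, cut where the gap between neighbours exceeds
# `gap`; returns cluster index per input element (original order).
.cluster1d <- function(z, gap) {
  ord <- order(z)
  cl <- integer(length(z))
  cl[ord] <- cumsum(c(1L, diff(z[ord]) > gap))
  cl
}

#' Cluster one gene's barcodes and apply the quarter rule
#'
#' The barcodes of a gene should agree: discordant members are suspected
#' off-target signal. Members are clustered by 1D single-linkage on the
#' z-score (cut where the sorted gap exceeds `gap`); a cluster is removed
#' iff its member count is strictly less than a quarter of the gene's
#' unfiltered barcode total.
#'
#' @param records data.frame with columns `barcode_id`, `fc_score`,
#'   `z_score` for one gene's unfiltered barcodes.
#' @param gap single-linkage cut threshold in z units (default 1).
#' @return data.frame, one row per cluster: `cluster`, `n_members`,
#'   `members` (comma-separated ids), `cluster_fc` (mean member fc),
#'   `cluster_z_local` (mean member z), `kept`.
#' @export
clusterGene <- function(records, gap = 1) {
  stopifnot(nrow(records) >= 1L)
  cl <- .cluster1d(records$z_score, gap)
  total <- nrow(records)
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sel <- cl == k
    data.frame(cluster = k, n_members = sum(sel),
               members = paste(sort(records$barcode_id[sel]),
                               collapse = ","),
               cluster_fc = mean(records$fc_score[sel]),
               cluster_z_local = mean(records$z_score[sel]),
               kept = !(sum(sel) < total / 4),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gene-level clustering, off-target removal and cluster scores
#'
#' Applies [clusterGene()] to every gene of a barcode score table, flags
#' the members of removed clusters as `off_target_cluster` in the returned
#' score table, and standardizes the kept clusters' mean fc-scores across
#' all genes into cluster z-scores, ranked ascending (most depleted
#' first).
#'
#' @param scores a [scoreBarcodes()] table.
#' @param gap single-linkage cut threshold (default 1 z unit).
#' @return list: `clusters` (data.frame: `gene_id`, `cluster`,
#'   `n_members`, `members`, `cluster_fc`, `cluster_z`, `kept`, `rank`)
#'   and `scores` (the input with off-target members flagged).
#' @export
clusterScores <- function(scores, gap = 1) {
  act <- scores[!scores$filtered, , drop = FALSE]
  cl <- do.call(rbind, lapply(split(act, act$gene_id), function(g) {
    cbind(gene_id = g$gene_id[1L], clusterGene(g, gap))
  }))
  rownames(cl) <- NULL
  off <- unlist(strsplit(cl$members[!cl$kept], ",", fixed = TRUE))
  scores$filtered <- scores$filtered | scores$barcode_id %in% off
  scores$filter_reason[scores$barcode_id %in% off] <- "off_target_cluster"
  cl$cluster_z <- NA_real_
  kept <- cl$kept
  if (sum(kept) >= 2L && sd(cl$cluster_fc[kept]) > 0)
    cl$cluster_z[kept] <- (cl$cluster_fc[kept] - mean(cl$cluster_fc[kept])) /
      sd(cl$cluster_fc[kept])
  cl$rank <- NA_integer_
  ord <- order(cl$cluster_z[kept], cl$gene_id[kept])
  cl$rank[kept][ord] <- seq_len(sum(kept))
  list(clusters = cl, scores = scores)
}

#' Time-series fold-change scores
#'
#' At every time point with at least one case and one control sample the
#' per-barcode fc-score is computed against that time point's own
#' controls; time points missing a condition are skipped with a warning.
#'
#' @param se a `SummarizedExperiment` from [screenCounts()] whose design
#'   has `time_point` set.
#' @return long-format data.frame: `barcode_id`, `gene_id`, `time_point`,
#'   `fc_score` — ready for heat-map rendering ([plotTimeHeatmap()]).
#' @export
timeseriesFC <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (all(is.na(cd$time_point)))
    stop("design has no time_point information")
  tps <- sort(unique(cd$time_point[!is.na(cd$time_point)]))
  out <- list()
  for (tp in tps) {
    sel <- !is.na(cd$time_point) & cd$time_point == tp
    sub <- se[, sel]
    cond <- SummarizedExperiment::colData(sub)$condition
    if (!any(cond == "case") || !any(cond == "control")) {
      warning("time point ", tp, " lacks a matched case/control; skipped")
      next
    }
    nm <- normalizeCounts(sub)
    out[[length(out) + 1L]] <- data.frame(
      barcode_id = rownames(sub),
      gene_id = SummarizedExperiment::rowData(sub)$gene_id,
      time_point = tp,
      fc_score = unname(log2(nm$case_ratio / nm$control_ratio)),
      stringsAsFactors = FALSE)
  }
  if (length(out) < 2L)
    stop("need at least 2 time points with matched case and control samples")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full case-vs-control screen analysis
#'
#' Normalization, low-count filtering, barcode fc/z scoring and ranking,
#' gene-level clustering with quarter-rule off-target removal and cluster
#' scores — the complete statistics pass in one call. Pair-tag counts are
#' collapsed per strain first (see [collapsePairTags()]).
#'
#' @param se a `SummarizedExperiment` from [screenCounts()].
#' @param minCount low-count filter threshold (default 100).
#' @param gap clustering gap in z units (default 1).
#' @param sdType `"sample"` or `"population"` standard deviation.
#' @param pairTagFun how UP/DN counts merge: `"sum"` (default) or
#'   `"mean"`.
#' @return list: `scores` (barcode-level, off-target flags applied),
#'   `clusters` (gene-level), `counts` (the analyzed
#'   `SummarizedExperiment`).
#' @export
screenAnalysis <- function(se, minCount = 100, gap = 1,
                           sdType = c("sample", "population"),
                           pairTagFun = c("sum", "mean")) {
  se <- collapsePairTags(se, match.arg(pairTagFun))
  scores <- scoreBarcodes(se, minCount, match.arg(sdType))
  cl <- clusterScores(scores, gap)
  list(scores = cl$scores, clusters = cl$clusters, counts = se)
}

#' Write score and cluster tables
#'
#' @param x a [scoreBarcodes()] or `clusters` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
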