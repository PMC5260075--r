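simpleSE <- function(case, control, genes = NULL,
                     ids = paste0("b", seq_len(nrow(as.matrix(case))))) {
  if (is.null(genes)) genes <- ids
  lib <- barcodeLibrary(ids, genes, strrep("ACGT", 5L)[rep(1, length(ids))],
                        tag = "SINGLE")
  # sequences are irrelevant here; make them unique to satisfy validity
  lib@records$barcode_seq <- randomDNA(length(ids), 20L)
  case <- as.matrix(case); control <- as.matrix(control)
  cts <- cbind(case, control)
  colnames(cts) <- c(paste0("case", seq_len(ncol(case))),
                     paste0("control", seq_len(ncol(control))))
  rownames(cts) <- ids
  design <- data.frame(sample_id = colnames(cts),
                       condition = rep(c("case", "control"),
                                       c(ncol(case), ncol(control))),
                       replicate = c(seq_len(ncol(case)),
                                     seq_len(ncol(control))))
  screenCounts(cts, lib, design)
}

test_that("pseudocounted ratios follow the stated formula and sum to 1", {
  se <- simpleSE(case = c(5, 5, 5), control = c(0, 9, 90))
  nm <- normalizeCounts(se)
  expect_equal(unname(nm$ratios[, "control1"]), c(1, 10, 91) / 102)
  expect_equal(colSums(nm$ratios), c(case1 = 1, control1 = 1),
               tolerance = 1e-12)

  # identical replicates: the mean equals either replicate
  se2 <- simpleSE(case = cbind(c(3, 7), c(3, 7)), control = cbind(c(5, 5)))
  nm2 <- normalizeCounts(se2)
  expect_equal(nm2$case_ratio, nm2$ratios[, "case1"])

  set.seed(901)
  se3 <- simpleSE(case = matrix(rpois(60, 50), 20),
                  control = matrix(rpois(60, 50), 20))
  expect_true(all(abs(colSums(normalizeCounts(se3)$ratios) - 1) < 1e-12))

  expect_warning(normalizeCounts(simpleSE(case = c(0, 0), control = c(1, 2))),
                 "all-zero")
})

test_that("low-count filter requires both conditions below threshold", {
  se <- simpleSE(case = c(50, 50, 500), control = c(60, 500, 60))
  f <- filterLowCount(se, 100)
  expect_equal(unname(f), c(TRUE, FALSE, FALSE))
  expect_false(any(filterLowCount(se, 0)))
})

test_that("z-scores standardize fc exactly: an fc ladder maps to [-1,0,1]", {
  # counts+1 double per step, so fc is an arithmetic progression and the
  # z-scores are forced to -1, 0, 1 by z = (x - mean)/sd
  se <- simpleSE(case = c(99, 199, 399), control = c(99, 99, 99))
  sc <- scoreBarcodes(se, minCount = 0)
  expect_equal(sc$z_score, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(diff(sc$fc_score), c(1, 1), tolerance = 1e-12)
  expect_equal(sc$rank, c(1L, 2L, 3L))
  expect_equal(mean(sc$z_score), 0, tolerance = 1e-12)
  expect_equal(sd(sc$z_score), 1, tolerance = 1e-12)
})

test_that("z-score mean/sd contract holds on random screens", {
  set.seed(902)
  se <- simpleSE(case = matrix(rpois(400, 300), 100),
                 control = matrix(rpois(400, 300), 100))
  sc <- scoreBarcodes(se, minCount = 50)
  z <- sc$z_score[!sc$filtered]
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  # z equals a direct standardization of the fc values
  fc <- sc$fc_score[!sc$filtered]
  expect_equal(z, (fc - mean(fc)) / sd(fc))
})

test_that("degenerate scoring inputs error cleanly", {
  se <- simpleSE(case = c(10, 20), control = c(10, 20))
  expect_error(scoreBarcodes(se, minCount = 0), "zero spread")
  se2 <- simpleSE(case = c(10, 20), control = c(11, 19))
  expect_error(scoreBarcodes(se2, minCount = 1000), "fewer than 2")
})

test_that("swapping case and control negates fc and z", {
  set.seed(903)
  case <- matrix(rpois(100, 200), 50)
  control <- matrix(rpois(100, 200), 50)
  a <- scoreBarcodes(simpleSE(case, control), minCount = 0)
  b <- scoreBarcodes(simpleSE(control, case), minCount = 0)
  expect_equal(a$fc_score, -b$fc_score, tolerance = 1e-12)
  expect_equal(a$z_score, -b$z_score, tolerance = 1e-9)
})

test_that("scores are invariant under per-sample scaling at large counts", {
  set.seed(904)
  case <- matrix(rpois(60, 5000), 30)
  control <- matrix(rpois(60, 5000), 30)
  a <- scoreBarcodes(simpleSE(case, control), minCount = 0)
  b <- scoreBarcodes(simpleSE(case * 10, control * 10), minCount = 0)
  expect_equal(a$fc_score, b$fc_score, tolerance = 1e-2)
})

test_that("single-linkage clustering and the quarter rule behave as stated", {
  rec <- function(z) data.frame(barcode_id = paste0("b", seq_along(z)),
                                fc_score = z, z_score = z)
  # 8 barcodes, singleton outlier: 1 < 8/4 = 2 -> removed
  cl <- clusterGene(rec(c(-2, -2.1, -1.9, -2.05, -1.95, -2.2, -1.8, 3)), 1)
  expect_equal(cl$kept, c(TRUE, FALSE))
  expect_equal(cl$n_members, c(7L, 1L))

  # 4 concordant barcodes: one kept cluster
  cl2 <- clusterGene(rec(c(0.1, 0.2, 0.3, 0.15)), 1)
  expect_equal(nrow(cl2), 1L)
  expect_true(cl2$kept)

  # strict inequality: quarter of 4 is 1, singleton 1 < 1 is FALSE -> kept
  cl3 <- clusterGene(rec(c(-2.0, -1.9, -1.8, 1.5)), 1)
  expect_equal(cl3$n_members, c(3L, 1L))
  expect_true(all(cl3$kept))
})

test_that("quarter rule matches enumeration over all cluster partitions", {
  # all ordered partitions (compositions) of group sizes 1..12, realized as
  # z-values with within-cluster spread << gap << between-cluster spread
  compositions <- function(n) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (first in seq_len(n))
      for (rest in compositions(n - first))
        out[[length(out) + 1L]] <- c(first, rest)
    out
  }
  gap <- 1
  for (n in 1:9) {
    for (comp in compositions(n)) {
      z <- unlist(lapply(seq_along(comp), function(k)
        k * 10 + seq_len(comp[k]) * 0.01))
      rec <- data.frame(barcode_id = paste0("b", seq_along(z)),
                        fc_score = z, z_score = z)
      cl <- clusterGene(rec, gap)
      expect_equal(cl$n_members, comp)
      expect_equal(cl$kept, !(comp < n / 4))
    }
  }
})

test_that("off-target members are flagged and cluster z standardized", {
  set.seed(905)
  genes <- rep(paste0("g", 1:10), each = 5)
  case <- matrix(rpois(100, 400), 50, 2)
  control <- matrix(rpois(100, 400), 50, 2)
  case[1, ] <- 4000  # one wild outlier barcode in g1
  se <- simpleSE(case, control, genes = genes)
  sc <- scoreBarcodes(se, minCount = 0)
  res <- clusterScores(sc, gap = 1)
  out <- res$scores
  expect_true(out$filtered[1])
  expect_equal(out$filter_reason[1], "off_target_cluster")
  kept <- res$clusters[res$clusters$kept, ]
  expect_equal(mean(kept$cluster_z), 0, tolerance = 1e-9)
  expect_equal(sd(kept$cluster_z), 1, tolerance = 1e-9)
  expect_equal(sort(kept$rank), seq_len(nrow(kept)))
})

test_that("time-series fc tracks per-time-point depletion", {
  # many constant barcodes keep the sample totals (the normalization
  # denominator) nearly unchanged while b1 is depleted
  nb <- 50L
  ids <- paste0("b", seq_len(nb))
  lib <- barcodeLibrary(ids, ids, randomDNA(nb, 20))
  tps <- 1:3
  design <- expand.grid(condition = c("case", "control"), time_point = tps,
                        stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$condition, "_t", design$time_point)
  design$replicate <- 1L
  cts <- sapply(seq_len(nrow(design)), function(k) {
    base <- rep(1000, nb)
    if (design$condition[k] == "case")
      base[1] <- 1000 / 2^design$time_point[k]  # b1 halves per unit time
    base
  })
  dimnames(cts) <- list(ids, design$sample_id)
  se <- screenCounts(cts, lib, design)
  ts <- timeseriesFC(se)
  b1 <- ts[ts$barcode_id == "b1", ]
  expect_equal(nrow(b1), 3L)
  expect_equal(diff(b1$fc_score), c(-1, -1), tolerance = 0.05)
  # constant barcodes: fc 0 at every time point
  expect_equal(ts$fc_score[ts$barcode_id == "b2"], rep(0, 3),
               tolerance = 0.05)

  # a single time point is an error
  expect_error(timeseriesFC(se[, se$time_point == 1]), "2 time points")
  # a time point missing its control is skipped with a warning
  keep <- !(design$sample_id == "control_t3")
  expect_warning(ts2 <- timeseriesFC(se[, keep]), "skipped")
  expect_equal(sort(unique(ts2$time_point)), 1:2)
})

test_that("a simulated screen recovers its truly depleted genes", {
  spec <- generatorSpec(nGenes = 100L, barcodesPerGene = 5L,
                        depletedGenes = 20L, effectLog2 = -2,
                        replicates = 2L, seed = 41L)
  sim <- generateScreen(spec)
  res <- screenAnalysis(sim$counts, minCount = 100)
  truth <- sim$truth$gene_id[sim$truth$effect_log2 < 0]
  kept <- res$clusters[res$clusters$kept, ]
  top <- kept$gene_id[order(kept$rank)][seq_along(truth)]
  expect_gte(length(intersect(top, truth)) / length(truth), 0.9)
  # depleted genes' barcodes sit clearly below zero
  depleted_z <- res$scores$z_score[res$scores$gene_id %in% truth &
                                     !res$scores$filtered]
  expect_lt(mean(depleted_z), -1)
})

test_that("pair-tag counts collapse per strain before scoring", {
  ids <- paste0("g", rep(1:4, each = 2), "_", c("UP", "DN"))
  genes <- paste0("g", rep(1:4, each = 2))
  lib <- barcodeLibrary(ids, genes, randomDNA(8, 20),
                        tag = rep(c("UP", "DN"), 4))
  cts <- matrix(rep(c(100, 120, 200, 240, 300, 360, 400, 480), 2), ncol = 2,
                dimnames = list(ids, c("s1", "s2")))
  design <- data.frame(sample_id = c("s1", "s2"),
                       condition = c("case", "control"), replicate = 1L)
  se <- screenCounts(cts, lib, design)
  cse <- collapsePairTags(se)
  expect_equal(nrow(cse), 4L)
  expect_equal(unname(SummarizedExperiment::assay(cse)["g1", "s1"]), 220)
  # single-tag input passes through untouched
  lib2 <- barcodeLibrary(paste0("b", 1:3), paste0("b", 1:3),
                         randomDNA(3, 20))
  cts2 <- matrix(1:6, 3, dimnames = list(paste0("b", 1:3), c("s1", "s2")))
  expect_identical(collapsePairTags(screenCounts(cts2, lib2, design)),
                   screenCounts(cts2, lib2, design))
})
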