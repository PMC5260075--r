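# hand-build a MappingResult with consistent tallies
makeResult <- function(ids, exact, mutated, variants = NULL,
                       budget = 2L, unmapped = 0) {
  counts <- data.frame(barcode_id = ids, gene_id = ids, tag = "SINGLE",
                       exact_count = exact, mutated_count = mutated,
                       stringsAsFactors = FALSE)
  if (is.null(variants))
    variants <- data.frame(barcode_id = character(), variant_seq = character(),
                           errors = numeric(), count = numeric())
  new("MappingResult", sampleId = "t", counts = counts, variants = variants,
      totals = c(input = sum(exact) + sum(mutated) + unmapped,
                 mapped = sum(exact) + sum(mutated), ambiguous = 0,
                 unmapped = unmapped, filtered = 0),
      barcodeMaxErrors = budget)
}

test_that("similarity report labels intra/inter pairs", {
  lib <- barcodeLibrary(c("b1", "b2"), c("g1", "g2"), c("ACGT", "ACGA"))
  rep <- similarityReport(lib, 1)
  expect_equal(nrow(rep$pairs), 1L)
  expect_equal(rep$pairs$relation, "inter")
  expect_equal(rep$pairs$distance_static, 1L)

  lib2 <- barcodeLibrary(c("b1", "b2"), c("g1", "g1"), c("ACGTACGT", "ACGTACGA"))
  expect_equal(similarityReport(lib2, 1)$pairs$relation, "intra")
})

test_that("a well-separated library reports no similar pairs", {
  lib <- makeFixtureLibrary(n = 40L, len = 18L, seed = 31L)  # min distance 5
  rep <- similarityReport(lib, 1)
  expect_equal(nrow(rep$pairs), 0L)
  expect_true(all(rep$summary$count == 0))
  expect_true(all(rep$summary$pct == 0))
})

test_that("similarity report equals the brute-force all-pairs oracle", {
  set.seed(701)
  base <- randomDNA(80L, 20L)
  near <- vapply(sample(base, 20L), mutateSeq, "", n_sub = 1L,
                 USE.NAMES = FALSE)
  seqs <- unique(c(base, near))
  lib <- barcodeLibrary(paste0("b", seq_along(seqs)),
                        paste0("g", (seq_along(seqs) - 1L) %/% 4L), seqs)
  got <- similarityReport(lib, 2)$pairs
  # oracle: O(n^2) scan with adist-based static and prefix-min dynamic
  want <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    if (i == length(seqs)) return(NULL)
    do.call(rbind, lapply((i + 1L):length(seqs), function(j) {
      st <- oracleStatic(seqs[i], seqs[j])
      dy <- min(oraclePrefixDist(seqs[i], seqs[j]),
                oraclePrefixDist(seqs[j], seqs[i]))
      if (st <= 2L || dy <= 2L)
        data.frame(i = i, j = j, st = st, dy = dy)
    }))
  }))
  expect_gte(nrow(want), 20L)  # the fixture must actually contain close pairs
  key_got <- paste(got$barcode_id_a, got$barcode_id_b)
  key_want <- paste0("b", want$i, " b", want$j)
  expect_setequal(key_got, key_want)
  m <- match(key_want, key_got)
  expect_equal(got$distance_static[m], want$st)
  expect_equal(got$distance_dynamic[m], want$dy)
  expect_true(all(got$distance_dynamic <= got$distance_static))
})

test_that("summary counts barcodes by intra/inter partner mix", {
  lib <- barcodeLibrary(c("b1", "b2", "b3", "b4"),
                        c("g1", "g1", "g2", "g3"),
                        c("AAAAAAAA", "AAAAAAAT", "AAAAAATT", "GGGGGGGG"))
  s <- similarityReport(lib, 1)$summary
  st <- s[s$mode == "static", ]
  # b1-b2 intra (d1), b2-b3 inter (d1): b1 intra-only, b3 inter-only, b2 both
  expect_equal(st$count, 3L)
  expect_equal(st$intra, 1L)
  expect_equal(st$intra_and_inter, 1L)
  expect_equal(st$inter, 1L)
  expect_equal(st$pct, 75)
})

test_that("erroneous-barcode rule flags dominant-variant excess only", {
  vars <- data.frame(barcode_id = "b1", variant_seq = "TTTTACGT",
                     errors = 1, count = 5000)
  res <- makeResult(c("b1", "b2"), exact = c(10, 8000),
                    mutated = c(5000, 0), variants = vars)
  calls <- detectErroneous(res, minImperfectCount = 100, ratioThreshold = 10)
  expect_true(calls$flagged[calls$barcode_id == "b1"])
  expect_false(calls$flagged[calls$barcode_id == "b2"])
  expect_equal(calls$dominant_variant_seq[calls$barcode_id == "b1"],
               "TTTTACGT")
  expect_equal(calls$imperfect_count[calls$barcode_id == "b1"], 5010)

  # ordinary sequencing error: mutated reads spread over many variants
  vars2 <- data.frame(barcode_id = "b1",
                      variant_seq = paste0("V", 1:50),
                      errors = 1, count = rep(6, 50))
  res2 <- makeResult("b1", exact = 10000, mutated = 300, variants = vars2)
  expect_false(any(detectErroneous(res2)$flagged))

  # high ratio but too few reads
  res3 <- makeResult("b1", exact = 1, mutated = 50,
                     variants = data.frame(barcode_id = "b1",
                                           variant_seq = "X", errors = 1,
                                           count = 50))
  expect_false(any(detectErroneous(res3)$flagged))

  expect_error(detectErroneous(makeResult("b1", 10, 0, budget = 0L)),
               "perfect-only")
})

test_that("remove policy zeroes flagged counts against a filtered tally", {
  vars <- data.frame(barcode_id = "b2", variant_seq = "GGGG", errors = 1,
                     count = 2000)
  res <- makeResult(c("b1", "b2", "b3"), exact = c(500, 5, 800),
                    mutated = c(10, 2000, 20), variants = vars)
  calls <- detectErroneous(res)
  expect_equal(calls$barcode_id[calls$flagged], "b2")
  filt <- filterErroneous(res, calls, "remove")
  cts <- mappingCounts(filt)
  expect_equal(cts$total[cts$barcode_id == "b2"], 0)
  expect_equal(sum(cts$total > 0), 2L)
  tot <- mappingTotals(filt)
  expect_equal(tot[["filtered"]], 2005)
  expect_equal(tot[["mapped"]] + tot[["filtered"]], 3335)
  # validity (conservation) still holds
  expect_true(validObject(filt))

  # no flags -> identity
  res2 <- makeResult("b1", 100, 5)
  calls2 <- detectErroneous(res2)
  expect_identical(filterErroneous(res2, calls2, "remove"), res2)
})

test_that("replace policy moves dominant-variant reads to exact on re-map", {
  lib <- makeFixtureLibrary(n = 12L, len = 16L, seed = 32L)
  set.seed(702)
  df <- libraryRecords(lib)
  pool <- df$barcode_seq
  pool[3] <- mutateSeq(pool[3], n_sub = 1L)  # erroneous barcode in the pool
  reads <- paste0(libraryPrimer(lib),
                  rep(pool, times = c(rep(300L, 2L), 400L, rep(300L, 9L))))
  res <- mapSample(seqMap(reads), lib, mapperConfig(barcodeMaxErrors = 2))
  calls <- detectErroneous(res)
  expect_equal(calls$barcode_id[calls$flagged], df$barcode_id[3])

  fixedres <- filterErroneous(res, calls, "replace", library = lib)
  cts <- mappingCounts(fixedres)
  expect_equal(cts$exact_count[3], 400)
  expect_equal(cts$mutated_count[3], 0)

  # re-mapping against the fixed library gives the same exact counts
  fixedlib <- applyFixes(lib, calls)
  expect_equal(barcodeSeqs(fixedlib)[[3]], pool[3])
  res2 <- mapSample(seqMap(reads), fixedlib, mapperConfig(barcodeMaxErrors = 2))
  expect_equal(mappingCounts(res2)$exact_count[3], 400)

  # collision: dominant variant equals another library sequence
  calls$dominant_variant_seq[calls$flagged] <- df$barcode_seq[5]
  expect_error(filterErroneous(res, calls, "replace", library = lib),
               df$barcode_id[5])
})

test_that("injected pool-level mutants are detected without false positives", {
  spec <- generatorSpec(nGenes = 25L, barcodesPerGene = 4L,
                        readsPerSample = 5e4, nErroneous = 3L, seed = 33L)
  lib <- generateLibrary(spec)$library
  gr <- generateReads(lib, spec)
  res <- mapSample(gr$seqmap, lib, mapperConfig(barcodeMaxErrors = 2))
  calls <- detectErroneous(res)
  truth <- gr$truth$barcode_id[gr$truth$erroneous]
  expect_setequal(calls$barcode_id[calls$flagged], truth)
  # reported variants are the true pool sequences
  m <- match(truth, calls$barcode_id)
  expect_equal(calls$dominant_variant_seq[m],
               gr$truth$pool_seq[gr$truth$erroneous])
})
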