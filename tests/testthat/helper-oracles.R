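# Independent oracles, deliberately naive: utils::adist provides the
# textbook Levenshtein distance, against which the package's C++ engine is
# checked; nothing here calls the package's distance code.

randomDNA <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

# full global edit distance (static comparison)
oracleStatic <- function(a, b) as.integer(adist(a, b))

# minimal edit distance between ref and any prefix of query
# (dynamic comparison / the mapper's end semantics)
oraclePrefixDist <- function(ref, query) {
  prefixes <- substring(query, 1L, 0:nchar(query))
  as.integer(min(adist(ref, prefixes)))
}

# brute-force prefix-tolerant scan over a library: the reference behaviour
# of searchTrie (ids and minimal error counts)
oracleSearch <- function(seqs, ids, query, budget) {
  d <- vapply(seqs, oraclePrefixDist, 0L, query = query, USE.NAMES = FALSE)
  keep <- d <= budget
  data.frame(barcode_id = ids[keep], errors = as.integer(d[keep]),
             stringsAsFactors = FALSE)
}

# inject point errors into a read at given positions
mutateSeq <- function(seq, n_sub = 0L, n_ins = 0L, n_del = 0L) {
  s <- strsplit(seq, "")[[1]]
  if (n_sub > 0L)
    for (p in sample(length(s), n_sub))
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  if (n_ins > 0L)
    for (q in seq_len(n_ins))
      s <- append(s, sample(c("A", "C", "G", "T"), 1L),
                  after = sample(0:length(s), 1L))
  if (n_del > 0L) s <- s[-sample(length(s), n_del)]
  paste(s, collapse = "")
}

# a small well-separated library + reads fixture used across tests
makeFixtureLibrary <- function(n = 20L, len = 16L, primer = "TTGACC",
                               pairTag = FALSE, seed = 11L) {
  spec <- generatorSpec(nGenes = n %/% ifelse(pairTag, 2L, 4L),
                        barcodesPerGene = if (pairTag) 1L else 4L,
                        barcodeLength = len, minPairwiseDistance = 5L,
                        pairTag = pairTag, primerSeq = primer, seed = seed)
  generateLibrary(spec)$library
}
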