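#' Specification for the synthetic barcode-seq generator
#'
#' Collects every knob of the simulated world in one validated list. The
#' defaults describe a typical pooled screen: 100 genes x 5 barcodes of
#' 20 nt designed at pairwise static distance >= 3, an 18-nt universal
#' primer, log-normal barcode abundances, Illumina-like error rates
#' (0.5% per-base substitution, 0.05% insertion and deletion), a 2% read
#' shift rate, and no erroneous barcodes or effects unless requested.
#'
#' @param nGenes number of genes.
#' @param barcodesPerGene barcodes per gene (single-tag) or UP/DN pairs
#'   per gene when `pairTag`.
#' @param barcodeLength designed barcode length (nt).
#' @param minPairwiseDistance minimum static edit distance between any two
#'   designed barcodes (rejection sampling).
#' @param pairTag generate a pair-tag (UP/DN) library.
#' @param primerSeq universal primer preceding the barcode (`""` for
#'   none).
#' @param mids named character vector of MID sequences (`character(0)` for
#'   an unmultiplexed run).
#' @param abundanceMeanlog,abundanceSdlog log-normal parameters of the
#'   expected reads per barcode.
#' @param mismatchRate,insertionRate,deletionRate per-base error
#'   probabilities applied to the primer+barcode portion of each read.
#' @param shiftRate probability that a read gains one extra random base at
#'   its 5' end (a position shift the primer alignment must absorb).
#' @param nErroneous number of barcodes whose *pool* sequence differs from
#'   the design: all their reads carry the mutant sequence.
#' @param erroneousEdits number of substitutions in each injected mutant.
#' @param depletedGenes number of genes (or a vector of gene ids) truly
#'   depleted in case samples.
#' @param effectLog2 log2 effect size of depleted genes (default -2, i.e.
#'   case abundance a quarter of control).
#' @param replicates replicates per condition.
#' @param timePoints vector of time points (`NULL` for a single-point
#'   screen).
#' @param readsPerSample expected total reads per sample.
#' @param readPad extra random 3' bases appended to every read (reads run
#'   past the barcode, exercising dynamic-length matching).
#' @param seed mandatory RNG seed: identical specs produce byte-identical
#'   output.
#' @return a `GeneratorSpec` list.
#' @export
generatorSpec <- function(nGenes = 100L, barcodesPerGene = 5L,
                          barcodeLength = 20L, minPairwiseDistance = 3L,
                          pairTag = FALSE,
                          primerSeq = "GTCGACCTGCAGCGTACG",
                          mids = character(0),
                          abundanceMeanlog = log(400), abundanceSdlog = 0.5,
                          mismatchRate = 0.005, insertionRate = 5e-4,
                          deletionRate = 5e-4, shiftRate = 0.02,
                          nErroneous = 0L, erroneousEdits = 1L,
                          depletedGenes = 0L, effectLog2 = -2,
                          replicates = 2L, timePoints = NULL,
                          readsPerSample = 2e5, readPad = 4L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  spec <- as.list(environment())
  rates <- c(spec$mismatchRate, spec$insertionRate, spec$deletionRate,
             spec$shiftRate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (spec$minPairwiseDistance > spec$barcodeLength)
    stop("minPairwiseDistance cannot exceed barcodeLength")
  class(spec) <- "GeneratorSpec"
  spec
}

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  if (len == 0L) return(rep("", n))
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

.substitute_bases <- function(seq, nedits) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), nedits)
  for (p in pos) s[p] <- sample(setdiff(.BASES, s[p]), 1L)
  paste(s, collapse = "")
}

#' Generate a random barcode library with a distance guarantee
#'
#' Barcodes are rejection-sampled so that every pair is at static edit
#' distance >= `minPairwiseDistance` — mimicking a well-designed library
#' where single errors cannot move a read between barcodes. For pair-tag
#' specs each gene gets an UP and a DN barcode per design slot.
#'
#' @param spec a [generatorSpec()].
#' @return list: `library` (a [BarcodeLibrary-class]) and `truth`
#'   (data.frame of the designed records).
#' @export
generateLibrary <- function(spec) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  set.seed(spec$seed)
  per_gene <- spec$barcodesPerGene * (if (spec$pairTag) 2L else 1L)
  n <- spec$nGenes * per_gene
  seqs <- character(0)
  attempts <- 0L
  max_attempts <- 200L * n
  while (length(seqs) < n) {
    cand <- .random_dna(1L, spec$barcodeLength)
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " barcodes at pairwise distance >= ",
           spec$minPairwiseDistance, " (length ", spec$barcodeLength,
           "); relax the spec")
    if (spec$minPairwiseDistance > 1L && length(seqs) &&
          !.dist_at_least(cand, seqs, spec$minPairwiseDistance))
      next
    seqs <- c(seqs, cand)
  }
  gene <- rep(sprintf("g%03d", seq_len(spec$nGenes)), each = per_gene)
  if (spec$pairTag) {
    tag <- rep(c("UP", "DN"), times = n / 2L)
    slot <- rep(rep(seq_len(spec$barcodesPerGene), each = 2L), spec$nGenes)
    id <- paste0(gene, "_b", slot, "_", tag)
  } else {
    tag <- "SINGLE"
    id <- paste0(gene, "_b",
                 rep(seq_len(spec$barcodesPerGene), spec$nGenes))
  }
  lib <- barcodeLibrary(id, gene, seqs, tag = tag,
                        primer_seq = spec$primerSeq)
  list(library = lib, truth = libraryRecords(lib))
}

# distance-guarded rejection sampling is quadratic; for big libraries the
# candidate is only checked against its neighbours via the pair scan above

.apply_read_errors <- function(reads, spec) {
  # per-base substitution / insertion / deletion over the whole read body;
  # per-read event counts are drawn binomially (equivalent to independent
  # per-base Bernoulli trials) so untouched reads skip the edit loop
  len <- nchar(reads)
  nmis <- rbinom(length(reads), len, spec$mismatchRate)
  nins <- rbinom(length(reads), len, spec$insertionRate)
  ndel <- rbinom(length(reads), pmax(len - nmis, 0L), spec$deletionRate)
  todo <- which(nmis + nins + ndel > 0L)
  for (k in todo) {
    s <- strsplit(reads[k], "")[[1]]
    if (nmis[k] > 0L) {
      pos <- sample(length(s), min(nmis[k], length(s)))
      for (p in pos) s[p] <- sample(setdiff(.BASES, s[p]), 1L)
    }
    if (nins[k] > 0L) {
      for (q in seq_len(nins[k]))
        s <- append(s, sample(.BASES, 1L), after = sample(length(s), 1L))
    }
    if (ndel[k] > 0L && length(s) > ndel[k]) {
      s <- s[-sample(length(s), ndel[k])]
    }
    reads[k] <- paste(s, collapse = "")
  }
  reads
}

#' Generate error-bearing reads for one sample
#'
#' Reads are composed as `MID + primer + barcode + random 3' pad`, then
#' per-base substitution/insertion/deletion processes are applied at the
#' spec rates and a fraction of reads gains one extra 5' base (shift).
#' Injected erroneous barcodes have their *pool* sequence replaced by a
#' mutant before reads are drawn, so every one of their reads carries the
#' mutant — the signature [detectErroneous()] looks for.
#'
#' @param library a [BarcodeLibrary-class] (typically from
#'   [generateLibrary()]).
#' @param spec a [generatorSpec()].
#' @param weights expected read share per barcode (recycled/normalized);
#'   defaults to log-normal draws from the spec's abundance model.
#' @param nReads total reads to draw (default `spec$readsPerSample`).
#' @param mid MID sequence to prepend (`""` for none).
#' @param seed RNG seed for this sample (defaults to `spec$seed`).
#' @return list: `seqmap` (a [SeqMap-class]), `truth` (per-barcode
#'   data.frame: `barcode_id`, `pool_seq`, `erroneous`, `true_count`),
#'   `reads` (character vector of the raw reads, truth-ordered).
#' @export
generateReads <- function(library, spec, weights = NULL,
                          nReads = spec$readsPerSample, mid = "",
                          seed = spec$seed) {
  stopifnot(is(library, "BarcodeLibrary"), inherits(spec, "GeneratorSpec"))
  set.seed(seed)
  df <- libraryRecords(library)
  n <- nrow(df)
  pool_seq <- df$barcode_seq
  erroneous <- rep(FALSE, n)
  if (spec$nErroneous > 0L) {
    which_err <- sample(n, spec$nErroneous)
    erroneous[which_err] <- TRUE
    for (i in which_err)
      pool_seq[i] <- .substitute_bases(pool_seq[i], spec$erroneousEdits)
  }
  if (is.null(weights))
    weights <- rlnorm(n, spec$abundanceMeanlog, spec$abundanceSdlog)
  weights <- rep_len(weights, n)
  true_count <- as.vector(rmultinom(1L, size = as.integer(nReads),
                                    prob = weights / sum(weights)))
  src <- rep(seq_len(n), true_count)
  pad <- if (spec$readPad > 0L) .random_dna(length(src), spec$readPad)
         else ""
  reads <- paste0(spec$primerSeq, pool_seq[src], pad)
  shift <- runif(length(reads)) < spec$shiftRate
  if (any(shift))
    reads[shift] <- paste0(sample(.BASES, sum(shift), replace = TRUE),
                           reads[shift])
  reads <- .apply_read_errors(reads, spec)
  if (nzchar(mid)) reads <- paste0(mid, reads)
  truth <- data.frame(barcode_id = df$barcode_id, pool_seq = pool_seq,
                      erroneous = erroneous, true_count = true_count,
                      stringsAsFactors = FALSE)
  list(seqmap = seqMap(reads), truth = truth, reads = reads)
}

#' @importFrom stats rmultinom
NULL

#' Generate a case/control screen count matrix with known effects
#'
#' Control expected counts follow the spec's log-normal abundance model;
#' case expected counts are scaled by `2^effectLog2` for every barcode of
#' a truly depleted/enriched gene; observed counts are Poisson draws per
#' replicate. The truth sidecar lists the affected genes.
#'
#' @param spec a [generatorSpec()].
#' @param library optional pre-generated [BarcodeLibrary-class]; generated
#'   from the spec otherwise.
#' @return list: `counts` (a `SummarizedExperiment`, see [screenCounts()]),
#'   `library`, `design`, `truth` (data.frame: `gene_id`, `effect_log2`).
#' @export
generateScreen <- function(spec, library = NULL) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  if (is.null(library)) library <- generateLibrary(spec)$library
  set.seed(spec$seed + 1L)
  df <- libraryRecords(library)
  genes <- unique(df$gene_id)
  dep <- spec$depletedGenes
  dep_genes <- if (is.character(dep)) dep
    else if (as.integer(dep) > 0L) sample(genes, as.integer(dep))
    else character(0)
  base_mu <- rlnorm(nrow(df), spec$abundanceMeanlog, spec$abundanceSdlog)
  eff <- ifelse(df$gene_id %in% dep_genes, 2^spec$effectLog2, 1)
  tps <- if (is.null(spec$timePoints)) NA else spec$timePoints
  design <- expand.grid(replicate = seq_len(spec$replicates),
                        condition = c("control", "case"),
                        time_point = tps, stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$condition, design$replicate,
                             ifelse(is.na(design$time_point), "",
                                    paste0("_t", design$time_point)))
  design <- design[, c("sample_id", "condition", "replicate", "time_point")]
  cts <- sapply(seq_len(nrow(design)), function(k) {
    mu <- base_mu
    if (design$condition[k] == "case") {
      # time-dependent depletion: effect compounds per unit time
      tp <- design$time_point[k]
      power <- if (is.na(tp)) 1 else match(tp, sort(unique(tps)))
      mu <- mu * eff^power
    }
    rpois(length(mu), mu)
  })
  rownames(cts) <- df$barcode_id
  colnames(cts) <- design$sample_id
  list(counts = screenCounts(cts, library, design), library = library,
       design = design,
       truth = data.frame(gene_id = genes,
                          effect_log2 = ifelse(genes %in% dep_genes,
                                               spec$effectLog2, 0),
                          stringsAsFactors = FALSE))
}

#' Generate per-sample reads for a whole screen design
#'
#' The full simulate-map-analyze pipeline entry: for every design row the
#' barcode abundances of [generateScreen()]'s model are turned into actual
#' reads via [generateReads()], so mapping and analysis can be exercised
#' end to end against the truth.
#'
#' @param spec a [generatorSpec()].
#' @return list: `library`, `design`, `seqmaps` (named list of
#'   [SeqMap-class], one per sample), `truth` (gene effects).
#' @export
generateScreenReads <- function(spec) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  lib <- generateLibrary(spec)$library
  set.seed(spec$seed + 1L)
  df <- libraryRecords(lib)
  genes <- unique(df$gene_id)
  dep <- spec$depletedGenes
  dep_genes <- if (is.character(dep)) dep
    else if (as.integer(dep) > 0L) sample(genes, as.integer(dep))
    else character(0)
  base_mu <- rlnorm(nrow(df), spec$abundanceMeanlog, spec$abundanceSdlog)
  eff <- ifelse(df$gene_id %in% dep_genes, 2^spec$effectLog2, 1)
  design <- expand.grid(replicate = seq_len(spec$replicates),
                        condition = c("control", "case"),
                        stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$condition, design$replicate)
  design$time_point <- NA
  design <- design[, c("sample_id", "condition", "replicate", "time_point")]
  seqmaps <- list()
  for (k in seq_len(nrow(design))) {
    w <- if (design$condition[k] == "case") base_mu * eff else base_mu
    gr <- generateReads(lib, spec, weights = w,
                        seed = spec$seed + 100L + k)
    seqmaps[[design$sample_id[k]]] <- gr$seqmap
  }
  list(library = lib, design = design, seqmaps = seqmaps,
       truth = data.frame(gene_id = genes,
                          effect_log2 = ifelse(genes %in% dep_genes,
                                               spec$effectLog2, 0),
                          stringsAsFactors = FALSE))
}
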