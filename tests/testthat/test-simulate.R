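cfgSmall <- function(seed = 3, ...) {
  args <- list(seed = seed, n_families = 6,
               consensus_length_range = c(500L, 800L), n_clusters = 3,
               cluster_fragments = 3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

test_that("the generator is fully deterministic under its seed", {
  cfg <- cfgSmall(seed = 42)
  f1 <- simulateTELibrary(cfg); f2 <- simulateTELibrary(cfg)
  expect_identical(as.character(consensusSeqs(f1)),
                   as.character(consensusSeqs(f2)))
  expect_identical(as.data.frame(familyInfo(f1)), as.data.frame(familyInfo(f2)))
  g1 <- simulateParentalGenomes(cfg, f1)
  g2 <- simulateParentalGenomes(cfg, f1)
  expect_identical(as.character(genomeSeqs(g1$parentA)),
                   as.character(genomeSeqs(g2$parentA)))
  s1 <- simulateSmallRNALibrary(cfg, f1, g1, "parentA")
  s2 <- simulateSmallRNALibrary(cfg, f1, g1, "parentA")
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  m1 <- simulateMRNACounts(cfg); m2 <- simulateMRNACounts(cfg)
  expect_identical(m1$counts, m2$counts)
})

test_that("TE library respects size and length settings", {
  cfg0 <- simConfig(seed = 1, n_families = 0)
  expect_length(simulateTELibrary(cfg0), 0)
  cfgF <- simConfig(seed = 1, n_families = 4,
                    consensus_length_range = c(500L, 500L))
  fam <- simulateTELibrary(cfgF)
  expect_true(all(Biostrings::width(consensusSeqs(fam)) == 500))
  expect_equal(sum(familyInfo(fam)$abundance_weight), 1)
})

test_that("genome divergence plants the expected substitutions and diagnostic sites", {
  cfg <- cfgSmall(seed = 5, divergence = 0.02,
                  consensus_length_range = c(1000L, 1000L))
  fam <- simulateTELibrary(cfg)
  g <- simulateParentalGenomes(cfg, fam)
  # ~20 substitutions per 1000-nt allele, within 3 binomial sigma pooled
  nsub <- vapply(familyNames(fam), function(f) {
    a <- strsplit(g$alleles$A[f], "")[[1]]
    cns <- strsplit(as.character(consensusSeqs(fam)[[f]]), "")[[1]]
    sum(a != cns)
  }, 0)
  n <- length(nsub) * 1000
  expect_lt(abs(sum(nsub) - 0.02 * n), 3 * sqrt(n * 0.02 * 0.98))
  # every family distinguishes the genomes somewhere
  expect_true(all(familyNames(fam) %in% g$diagnosticSites$family))

  # divergence 0: alleles identical to consensus, no diagnostic sites
  cfg0 <- cfgSmall(seed = 5, divergence = 0)
  fam0 <- simulateTELibrary(cfg0)
  g0 <- simulateParentalGenomes(cfg0, fam0)
  expect_identical(unname(g0$alleles$A), unname(as.character(consensusSeqs(fam0))))
  expect_identical(g0$alleles$A, g0$alleles$B)
  expect_equal(nrow(g0$diagnosticSites), 0)
})

test_that("genome-A-only families get no insertions in genome B", {
  cfg <- cfgSmall(seed = 6)
  fam <- simulateTELibrary(cfg)
  g <- simulateParentalGenomes(cfg, fam)
  info <- familyInfo(fam)
  melOnly <- familyNames(fam)[info$full_length_presence == "mel_only"]
  neither <- familyNames(fam)[info$full_length_presence == "neither"]
  famB <- unique(teInsertions(g$parentB)$family)
  famA <- unique(teInsertions(g$parentA)$family)
  expect_length(intersect(melOnly, famB), 0)
  expect_length(intersect(neither, c(famA, famB)), 0)
})

test_that("small-RNA truth table honors the pairing and length contracts", {
  cfg <- cfgSmall(seed = 9)
  cfg$smallrna$parentA$n_reads <- 4000L
  fam <- simulateTELibrary(cfg)
  s <- simulateSmallRNALibrary(cfg, fam, genomes = NULL, "parentA")
  len <- nchar(s$reads$seq)
  expect_true(all(len >= 18 & len <= 30))
  expect_equal(nrow(s$reads), 4000)
  # every read appears exactly once
  expect_false(anyDuplicated(s$truth$read_id) > 0)
  # every pair id maps to exactly two reads with a verified 10-nt 5'-5' overlap
  prs <- split(s$truth[!is.na(s$truth$pair_id), ],
               s$truth$pair_id[!is.na(s$truth$pair_id)])
  expect_true(all(vapply(prs, nrow, 1L) == 2L))
  for (p in prs[seq_len(min(50, length(prs)))]) {
    sp <- p$five_prime[p$strand == "sense"]
    ap <- p$five_prime[p$strand == "antisense"]
    expect_equal(ap - sp + 1L, 10L)
  }
  # background class is confined to 18-22 nt, piRNA class to 23-29
  expect_true(all(s$truth$length[s$truth$class == "background"] <= 22))
  expect_true(all(s$truth$length[s$truth$class == "pirna"] >= 23))
})

test_that("degenerate small-RNA settings behave: pi = 1 and pirna_fraction = 0", {
  cfg <- cfgSmall(seed = 10)
  cfg$smallrna$parentA <- libraryParams(n_reads = 1000L, pingpong_prob = 1,
                                        antisense_fraction = 0.5)
  fam <- simulateTELibrary(cfg)
  s <- simulateSmallRNALibrary(cfg, fam, NULL, "parentA")
  pir <- s$truth[s$truth$class == "pirna", ]
  # all piRNA reads paired up to the odd leftover per family
  unpaired <- sum(is.na(pir$pair_id))
  expect_lte(unpaired, length(unique(pir$family)))

  cfg$smallrna$parentA <- libraryParams(n_reads = 500L, pirna_fraction = 0)
  s0 <- simulateSmallRNALibrary(cfg, fam, NULL, "parentA")
  expect_true(all(nchar(s0$reads$seq) <= 22))
})

test_that("configured antisense fraction is recovered within binomial tolerance", {
  cfg <- cfgSmall(seed = 11, n_families = 2)
  cfg$smallrna$parentA <- libraryParams(n_reads = 8000L, pirna_fraction = 1,
                                        antisense_fraction = 0.8,
                                        pingpong_prob = 0.2)
  fam <- simulateTELibrary(cfg)
  s <- simulateSmallRNALibrary(cfg, fam, NULL, "parentA")
  af <- mean(s$truth$strand == "antisense")
  expect_lt(abs(af - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(s$truth)))
})

test_that("mRNA counts: planted fold change, Poisson limit, library scaling", {
  cfg <- cfgSmall(seed = 12)
  cfg$mrna$dispersion <- 0
  cfg$mrna$base_mean_range <- c(5000, 5000)
  cfg$mrna$planted_log2fc <- c(TE01 = 1)
  m <- simulateMRNACounts(cfg)
  expect_identical(rownames(m$counts), sprintf("TE%02d", 1:6))
  # dispersion -> 0, FC = 1: hybrid ~ parental mean within Poisson noise
  nullF <- rownames(m$counts) != "TE01"
  mid <- (m$counts[nullF, "parentA"] + m$counts[nullF, "parentB"]) / 2
  expect_true(all(abs(m$counts[nullF, "hybrid"] - mid) <
                    5 * sqrt(pmax(mid, 1))))
  # planted family doubled
  expect_lt(abs(m$counts["TE01", "hybrid"] - 2 * 5000), 5 * sqrt(10000))
  expect_true(m$truth$derepressed[m$truth$family == "TE01"])
  expect_false(any(m$truth$derepressed[m$truth$family != "TE01"]))
})

test_that("mRNA reads carry their true genome and family", {
  cfg <- cfgSmall(seed = 13, divergence = 0.02)
  fam <- simulateTELibrary(cfg)
  g <- simulateParentalGenomes(cfg, fam)
  r <- simulateMRNAReads(cfg, fam, g, "parentA", nReads = 200L)
  expect_true(all(r$truth$genome == "A"))
  # sequences really come from the named allele at the named position
  i <- sample(nrow(r$truth), 20)
  ok <- vapply(i, function(k) {
    al <- g$alleles[[r$truth$genome[k]]][r$truth$family[k]]
    substr(al, r$truth$five_prime[k] + 1,
           r$truth$five_prime[k] + r$truth$length[k]) == r$reads$seq[k]
  }, TRUE)
  expect_true(all(ok))
})
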