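test_that("ping-pong fraction is forced by its definition on small cases", {
  # sense 5'@100 with antisense 5'@109: both participate
  h <- makeHits(c(100L, 109L), c("sense", "antisense"))
  r <- pingPongFraction(h)
  expect_equal(r$fraction, 1.0)
  expect_equal(r$total_weight, 2)

  # all sense: zero
  expect_equal(pingPongFraction(makeHits(c(1L, 50L, 90L), "sense"))$fraction, 0)

  # pair plus a lone sense read: 2 of 3
  h3 <- makeHits(c(100L, 109L, 500L), c("sense", "antisense", "sense"))
  expect_equal(pingPongFraction(h3)$fraction, 2 / 3)
  expect_equal(oraclePingPong(h3), 2 / 3)

  # zero reads in window: missing
  expect_true(is.na(pingPongFraction(
    makeHits(integer(0), character(0)), family = "TE01")$fraction))

  # weighting by copies: the paired side dominating
  h4 <- makeHits(c(100L, 109L, 500L), c("sense", "antisense", "sense"),
                 copies = c(4L, 4L, 2L))
  expect_equal(pingPongFraction(h4)$fraction, 8 / 10)
  expect_equal(pingPongFraction(h4, distinct = TRUE)$fraction, 2 / 3)
})

test_that("ping-pong fraction is symmetric under strand swap and order permutation", {
  set.seed(41)
  fp <- sample(0:500, 60)
  st <- sample(c("sense", "antisense"), 60, TRUE)
  cp <- sample(1:5, 60, TRUE)
  h <- makeHits(fp, st, copies = cp)
  f0 <- pingPongFraction(h)$fraction
  # swap labels and mirror coordinates so the pair geometry is preserved
  hs <- h
  hs$strand <- ifelse(h$strand == "sense", "antisense", "sense")
  hs$five_prime <- 600L - h$five_prime
  expect_equal(pingPongFraction(hs)$fraction, f0)
  # permuting rows changes nothing
  hp <- h[sample(nrow(h)), ]
  expect_equal(pingPongFraction(hp)$fraction, f0)
})

test_that("fraction recovers the planted pairing probability and matches the brute-force oracle", {
  cfg <- simConfig(seed = 44, n_families = 3,
                   consensus_length_range = c(2000L, 3000L))
  for (pi0 in c(0.2, 0.8)) {
    cfg$smallrna$test <- libraryParams(n_reads = 3000L, pirna_fraction = 1,
                                       antisense_fraction = 0.5,
                                       pingpong_prob = pi0)
    fam <- simulateTELibrary(cfg)
    s <- simulateSmallRNALibrary(cfg, fam, NULL, "test")
    h <- assignReads(s$reads, buildConsensusIndex(fam, 0L))
    wtot <- 0; wpart <- 0
    for (f in familyNames(fam)) {
      r <- pingPongFraction(h, f)
      if (is.na(r$fraction)) next
      wtot <- wtot + r$total_weight
      wpart <- wpart + r$participating_weight
      # brute-force O(n^2) agreement on families <= 500 reads
      hf <- h$hits[h$hits$target == f, ]
      if (nrow(hf) <= 500)
        expect_equal(r$fraction, oraclePingPong(hf), tolerance = 1e-12)
    }
    est <- wpart / wtot
    expect_lt(abs(est - pi0), 3 * sqrt(pi0 * (1 - pi0) / wtot))
  }
})

test_that("the reporting filter keeps families passing in at least one library", {
  mk <- function(n, frac, fam = "TEx") {
    npair <- round(n * frac / 2)
    fp <- seq(0, by = 60L, length.out = n - npair)
    h <- makeHits(fp, "sense", family = fam)
    if (npair > 0) {
      pr <- makeHits(c(fp[seq_len(npair)] + 1000L, fp[seq_len(npair)] + 1009L),
                     rep(c("sense", "antisense"), each = npair), family = fam)
      pr$seq <- paste0("P", seq_len(nrow(pr)))
      h <- rbind(h[seq_len(n - 2 * npair), ], pr)
    }
    h$seq <- paste0(fam, "_", seq_len(nrow(h)))
    h
  }
  hits <- list(
    lib1 = rbind(mk(40, 0.5, "few"), mk(60, 0.04, "flat"), mk(80, 0.5, "good")),
    lib2 = rbind(mk(40, 0.5, "few"), mk(60, 0.04, "flat"), mk(30, 0, "good")),
    lib3 = rbind(mk(40, 0.5, "few"), mk(60, 0.04, "flat"), mk(30, 0, "good")))
  tab <- pingPongTable(hits, families = c("few", "flat", "good"))
  # 40 reads everywhere: dropped; fraction 0.04 everywhere: dropped;
  # passing in one library: retained with all three libraries' values
  expect_false("few" %in% tab$family)
  expect_false("flat" %in% tab$family)
  expect_equal(sum(tab$family == "good"), 3)
  expect_equal(sum(tab$passes_filter[tab$family == "good"]), 1)
  un <- attr(tab, "unfiltered")
  expect_equal(nrow(un), 9)
})

test_that("overlap spectrum concentrates at the pair offset", {
  h <- makeHits(c(100L, 109L), c("sense", "antisense"))
  sp <- overlapSpectrum(h)
  expect_equal(unname(sp[["10"]]), 2)
  expect_equal(sum(sp), 2)  # all weight at overlap 10
  expect_equal(sum(overlapSpectrum(makeHits(c(1L, 30L), "sense"))), 0)

  cfg <- simConfig(seed = 46, n_families = 1,
                   consensus_length_range = c(3000L, 3000L))
  cfg$smallrna$t <- libraryParams(n_reads = 2000L, pirna_fraction = 1,
                                  antisense_fraction = 0.5,
                                  pingpong_prob = 0.6)
  fam <- simulateTELibrary(cfg)
  s <- simulateSmallRNALibrary(cfg, fam, NULL, "t")
  h2 <- assignReads(s$reads, buildConsensusIndex(fam, 0L))
  sp2 <- overlapSpectrum(h2, familyNames(fam)[1])
  expect_equal(which.max(sp2), 10, ignore_attr = TRUE)
  r <- pingPongFraction(h2, familyNames(fam)[1])
  expect_equal(unname(sp2[["10"]]), r$participating_weight)
})
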