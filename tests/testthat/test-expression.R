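test_that("quantification applies the tie policy and fixed universes", {
  h <- makeHits(rep(1L, 3), "sense", copies = c(50L, 30L, 20L))
  h$seq <- paste0("S", 1:3)
  expect_equal(unname(quantifyFamilies(h)), 100)
  h2 <- rbind(makeHits(10L, "sense", family = "TE01", n_locations = 2L),
              makeHits(20L, "sense", family = "TE02", n_locations = 2L))
  h2$seq <- "X"; h2$read_id <- "r"
  q <- quantifyFamilies(h2, targets = c("TE01", "TE02", "TE03"))
  expect_equal(unname(q), c(0.5, 0.5, 0))
})

test_that("normalization is the per-kilobase-per-million formula", {
  expect_equal(unname(normalizeRPKM(c(f = 100), 1e6, c(f = 1000))), 100)
  expect_equal(unname(normalizeRPKM(c(f = 100), 2e6, c(f = 1000))), 50)
  expect_equal(unname(normalizeRPKM(c(f = 100), 1e6, c(f = 2000))), 50)
  expect_error(normalizeRPKM(c(f = 1), 0, c(f = 10)), "positive")
})

test_that("derepression calling follows the dual-parent fold and q rules", {
  libs <- c(parentA = 1e6, parentB = 1e6, hybrid = 1e6)
  counts <- rbind(TEa = c(1000, 1500, 4000),   # 4x and ~2.7x: derepressed
                  TEb = c(2000, 2500, 3000),   # < 2-fold vs B: unchanged
                  TEc = c(4000, 4000, 1000))   # 4x down: underexpressed
  colnames(counts) <- names(libs)
  r <- callExpressionStatus(counts, libs)
  expect_identical(r$status, c("derepressed", "unchanged", "underexpressed"))
  expect_equal(r$log2fc_vs_A[1], log2(4000.5 / 1000.5), tolerance = 1e-12)
  # the significance gate can only remove derepressed calls
  expect_true(all(r$family[r$status == "derepressed"] %in%
                    r$family[r$status_fold_only == "derepressed"]))
  # normalized-abundance example: hybrid 40 vs parents 10 and 15 passes fold
  expect_true(log2(40 / 10) >= 1 && log2(40 / 15) >= 1)
})

test_that("increasing only the hybrid count never revokes a derepression call", {
  libs <- c(parentA = 1e6, parentB = 1e6, hybrid = 1e6)
  grid <- seq(500, 8000, by = 500)
  st <- vapply(grid, function(h) {
    counts <- rbind(TEa = c(1000, 1200, h))
    colnames(counts) <- names(libs)
    callExpressionStatus(counts, libs)$status
  }, "")
  firstDr <- match("derepressed", st)
  expect_false(is.na(firstDr))
  expect_true(all(st[firstDr:length(st)] == "derepressed"))
})

test_that("null q-values are calibrated at the Poisson limit", {
  set.seed(51)
  nfam <- 250; reps <- 6
  hits <- 0
  for (i in seq_len(reps)) {
    mu <- exp(runif(nfam, log(100), log(1000)))
    counts <- cbind(parentA = rpois(nfam, mu), parentB = rpois(nfam, mu),
                    hybrid = rpois(nfam, mu))
    rownames(counts) <- sprintf("f%03d", seq_len(nfam))
    r <- callExpressionStatus(counts, c(parentA = 1e6, parentB = 1e6,
                                        hybrid = 1e6))
    hits <- hits + sum(r$q_vs_A < 0.05 | r$q_vs_B < 0.05)
  }
  n <- nfam * reps
  expect_lte(hits / n, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("the negative-binomial test option runs and agrees directionally", {
  libs <- c(parentA = 1e6, parentB = 1e6, hybrid = 1e6)
  counts <- rbind(TEa = c(1000, 1100, 4200), TEb = c(2000, 2100, 2050))
  colnames(counts) <- names(libs)
  r <- callExpressionStatus(counts, libs, test = "nb", nbDispersion = 0.01)
  expect_lt(r$q_vs_A[1], 0.05)
  expect_identical(r$status[1], "derepressed")
  expect_identical(r$status[2], "unchanged")
})

test_that("origin partition separates diagnostic reads and matches truth", {
  cfg <- simConfig(seed = 53, n_families = 6, divergence = 0.02,
                   consensus_length_range = c(600L, 900L), n_clusters = 0)
  fam <- simulateTELibrary(cfg)
  g <- simulateParentalGenomes(cfg, fam)
  r <- simulateMRNAReads(cfg, fam, g, "hybrid", nReads = 400L)
  part <- originPartition(r$reads, g$parentA, g$parentB)
  # join truth by sequence
  tr <- r$truth$genome[match(part$reads$seq, r$reads$seq)]
  expect_true(all(tr[part$reads$origin == "A_only"] == "A"))
  expect_true(all(tr[part$reads$origin == "B_only"] == "B"))
  expect_true(all(part$reads$origin != "unplaced"))
  # a read covering a diagnostic site of genome A is A-only
  ds <- g$diagnosticSites[1, ]
  al <- g$alleles$A[ds$family]
  fp <- max(0, ds$pos0 - 12)
  probe <- substr(al, fp + 1, fp + 25)
  p2 <- originPartition(data.frame(read_id = "d", seq = probe),
                        g$parentA, g$parentB)
  expect_identical(p2$reads$origin, "A_only")
})

test_that("per-origin fold changes recover planted biallelic derepression", {
  mkPart <- function(A, B, S) {
    fams <- names(A)
    tab <- cbind(A_only = A, B_only = B, shared = S)
    structure(list(reads = data.frame(), families = tab),
              class = "OriginPartition")
  }
  libs <- c(parentA = 1e4, parentB = 1e4, hybrid = 1e4)
  hyb <- mkPart(c(f1 = 20), c(f1 = 24), c(f1 = 100))
  pA <- mkPart(c(f1 = 5), c(f1 = 0), c(f1 = 80))
  pB <- mkPart(c(f1 = 0), c(f1 = 6), c(f1 = 80))
  fc <- perOriginFoldChange(hyb, pA, pB, libs)
  expect_equal(fc$log2fc_A_origin, log2(20.5 / 5.5), tolerance = 1e-12)
  expect_equal(fc$log2fc_B_origin, log2(24.5 / 6.5), tolerance = 1e-12)
  expect_false(fc$flag_zero_A)
  # no origin-specific reads anywhere: missing and flagged
  hyb0 <- mkPart(c(f2 = 0), c(f2 = 10), c(f2 = 5))
  pA0 <- mkPart(c(f2 = 0), c(f2 = 0), c(f2 = 5))
  pB0 <- mkPart(c(f2 = 0), c(f2 = 8), c(f2 = 5))
  fc0 <- perOriginFoldChange(hyb0, pA0, pB0, libs)
  expect_true(is.na(fc0$log2fc_A_origin))
  expect_true(fc0$flag_zero_A)
})
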