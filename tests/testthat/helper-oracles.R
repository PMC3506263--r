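# Independent oracles used across the suite. Each re-derives the target
# quantity from first principles (exhaustive scan, enumeration, direct
# formula) without touching the implementation path it checks.

# exhaustive sliding-window placement of one read on every target, both
# strands, zero mismatches; returns rows (target, strand, five_prime)
oracleSlidingWindow <- function(read, targets) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- nchar(read)
  rows <- list()
  for (tn in names(targets)) {
    S <- as.character(targets[[tn]])
    if (L > nchar(S)) next
    for (st in seq_len(nchar(S) - L + 1L)) {
      win <- substr(S, st, st + L - 1L)
      if (win == read)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tn, strand = "sense", five_prime = st - 1L)
      if (win == rc(read))
        rows[[length(rows) + 1L]] <- data.frame(
          target = tn, strand = "antisense", five_prime = st + L - 2L)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(), strand = character(),
               five_prime = integer())
}

# exhaustive k-mismatch variant (small inputs only)
oracleSlidingWindowK <- function(read, targets, k) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  mm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  L <- nchar(read)
  rows <- list()
  for (tn in names(targets)) {
    S <- as.character(targets[[tn]])
    if (L > nchar(S)) next
    for (st in seq_len(nchar(S) - L + 1L)) {
      win <- substr(S, st, st + L - 1L)
      dS <- mm(win, read); dA <- mm(win, rc(read))
      if (dS <= k)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tn, strand = "sense", five_prime = st - 1L, mismatches = dS)
      if (dA <= k)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tn, strand = "antisense", five_prime = st + L - 2L,
          mismatches = dA)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(), strand = character(),
               five_prime = integer(), mismatches = integer())
}

# O(n^2) ping-pong oracle over one family's hit rows: a sequence
# participates iff any of its placements has an opposite-strand partner
# at the exact 5'-5' offset; weights are collapsed copy counts per
# distinct sequence
oraclePingPong <- function(hits, offset = 10L, minLen = 23L, maxLen = 29L) {
  h <- hits[hits$length >= minLen & hits$length <= maxLen, , drop = FALSE]
  if (!nrow(h)) return(NA_real_)
  seqs <- unique(h$seq)
  part <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    ri <- h[h$seq == seqs[i], , drop = FALSE]
    found <- FALSE
    for (a in seq_len(nrow(ri))) {
      for (b in seq_len(nrow(h))) {
        if (ri$strand[a] == h$strand[b]) next
        s5 <- if (ri$strand[a] == "sense") ri$five_prime[a] else h$five_prime[b]
        a5 <- if (ri$strand[a] == "sense") h$five_prime[b] else ri$five_prime[a]
        if (a5 - s5 + 1L == offset) { found <- TRUE; break }
      }
      if (found) break
    }
    part[i] <- found
  }
  w <- h$copies[match(seqs, h$seq)]
  sum(w[part]) / sum(w)
}

# direct-formula G-test, evaluated cell by cell
oracleG <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
}

# direct-formula Pearson chi-square
oracleChisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# partial correlation via residual regression: correlate the residuals of
# each focal variable regressed on all the others
oraclePartial <- function(X, i, j) {
  rest <- setdiff(seq_len(ncol(X)), c(i, j))
  ri <- stats::resid(stats::lm(X[, i] ~ X[, rest]))
  rj <- stats::resid(stats::lm(X[, j] ~ X[, rest]))
  stats::cor(ri, rj)
}

# exact two-sided Wilcoxon p by full enumeration of group assignments
oracleWilcoxonExact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  r <- rank(v)
  combos <- utils::combn(nx + ny, nx)
  U <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  pLe <- mean(U <= uObs); pGe <- mean(U >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# small deterministic hit-table builder: rows are distinct sequences
makeHits <- function(five_prime, strand, copies = 1L, family = "TE01",
                     length = 25L, n_locations = 1L) {
  n <- length(five_prime)
  data.frame(read_id = sprintf("r%d", seq_len(n)),
             seq = sprintf("S%d", seq_len(n)),
             target = rep_len(family, n), strand = rep_len(strand, n),
             five_prime = five_prime, length = rep_len(length, n),
             mismatches = rep_len(0L, n), n_locations = rep_len(n_locations, n),
             copies = rep_len(copies, n))
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
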