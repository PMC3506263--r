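#' G-test of independence on a 2x2 table
#'
#' Likelihood-ratio chi-square: `G = 2 * sum(O * ln(O/E))` over the four
#' cells with independence-expected counts, df = 1, p from the
#' chi-square tail. No Williams or continuity correction is applied.
#'
#' @param a,b First row (e.g. derepressed / not derepressed TE families).
#' @param c,d Second row (e.g. derepressed / not derepressed genes).
#' @return A [StatResult-class] with statistic `"G"`.
#' @examples
#' gTest2x2(32, 233, 38, 8404)  # TE families vs protein-coding genes
#' @export
gTest2x2 <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(O < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("zero margin in 2x2 table", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  nz <- O > 0  # lim x->0 of x*ln(x/e) = 0
  G <- 2 * sum(O[nz] * log(O[nz] / E[nz]))
  statResult("G", G, df = 1, p = stats::pchisq(G, 1, lower.tail = FALSE),
             n = sum(O), details = list(observed = O, expected = E))
}

#' Pearson chi-square test on an R x C table
#'
#' `X^2 = sum((O-E)^2/E)`, df = (R-1)(C-1), no continuity correction.
#'
#' @param table Matrix of non-negative counts.
#' @return A [StatResult-class] with statistic `"X2"`.
#' @export
chiSquareRxC <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  statResult("X2", unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, n = sum(table),
             details = list(observed = table, expected = ct$expected))
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p for `min(n) <= 8` without ties, normal
#' approximation (with tie correction) otherwise. Two-sided by default.
#'
#' @param x,y Numeric samples.
#' @param alternative As in [stats::wilcox.test()].
#' @return A [StatResult-class] with statistic `"W"`.
#' @export
wilcoxonRankSum <- function(x, y, alternative = "two.sided") {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = !exact))
  statResult("W", unname(wt$statistic), p = wt$p.value,
             n = length(x) + length(y),
             details = list(nx = length(x), ny = length(y), exact = exact))
}

#' Pooled-variance two-sample t-test
#'
#' Pooled (not Welch) variance, df = nx + ny - 2 — the df accounting
#' under which 40 + 33 observations give df = 71.
#'
#' @param x,y Numeric samples.
#' @param alternative As in [stats::t.test()].
#' @return A [StatResult-class] with statistic `"t"`.
#' @export
twoSampleT <- function(x, y, alternative = "two.sided") {
  if (length(x) + length(y) < 3) stop("need nx + ny >= 3", call. = FALSE)
  if (stats::var(c(x - mean(x), y - mean(y))) == 0)
    stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE, alternative = alternative)
  statResult("t", unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, n = length(x) + length(y),
             details = list(nx = length(x), ny = length(y),
                            meanx = mean(x), meany = mean(y)))
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @return A [StatResult-class] with statistic `"r"` and t-based p.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  statResult("r", unname(ct$estimate), df = unname(ct$parameter),
             p = ct$p.value, n = length(x))
}

#' Partial correlation matrix
#'
#' Partial correlation between every pair of variables controlling for
#' all remaining variables, via the normalized inverse of the
#' correlation matrix: `p_ij = -s_ij / sqrt(s_ii * s_jj)` with `S = R^-1`.
#'
#' @param X Numeric matrix or data.frame, columns = variables, complete
#'   rows, >= 3 variables.
#' @return Symmetric matrix of partial correlations (unit diagonal).
#' @export
partialCorrelation <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 3) stop("need >= 3 variables", call. = FALSE)
  if (anyNA(X)) stop("rows must be complete", call. = FALSE)
  R <- stats::cor(X)
  S <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix", call. = FALSE))
  D <- sqrt(diag(S))
  P <- -S / outer(D, D)
  diag(P) <- 1
  dimnames(P) <- dimnames(R)
  P
}

#' Permutation significance for partial correlations
#'
#' Builds an empirical null by repeatedly destroying all dependence
#' among the variables while keeping each variable's marginal
#' distribution: every permutation independently shuffles the row order
#' of each column except a fixed reference column, and the partial
#' correlations are recomputed. A focal observed partial correlation is
#' flagged significant iff it exceeds the 95th percentile (one-sided,
#' `probs` configurable) of its own permuted distribution.
#'
#' @param X Numeric matrix/data.frame, columns = variables.
#' @param focal Two-column matrix (or list of length-2 vectors) of
#'   column index pairs to test; default all pairs.
#' @param nPerm Number of permutations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @param refColumn Column left unshuffled (default 1).
#' @param probs Quantile defining the threshold (default 0.95).
#' @return data.frame: `var1`, `var2`, `observed`, `threshold`
#'   (empirical `probs` quantile), `significant`.
#' @export
permutationPartialTest <- function(X, focal = NULL, nPerm = 10000L,
                                   seed = 1L, refColumn = 1L, probs = 0.95) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(focal)) {
    focal <- t(utils::combn(p, 2))
  } else if (is.list(focal)) focal <- do.call(rbind, focal)
  set.seed(seed)
  obs <- partialCorrelation(X)
  nf <- nrow(focal)
  perm <- matrix(NA_real_, nPerm, nf)
  n <- nrow(X)
  shuffleCols <- setdiff(seq_len(p), refColumn)
  Xp <- X
  for (b in seq_len(nPerm)) {
    for (j in shuffleCols) Xp[, j] <- X[sample.int(n), j]
    Pb <- tryCatch(partialCorrelation(Xp), error = function(e) NULL)
    if (is.null(Pb)) next
    perm[b, ] <- Pb[focal]
  }
  thr <- apply(perm, 2, stats::quantile, probs = probs, na.rm = TRUE)
  obsv <- obs[focal]
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  data.frame(var1 = nm[focal[, 1]], var2 = nm[focal[, 2]],
             observed = obsv, threshold = as.numeric(thr),
             significant = obsv > thr, row.names = NULL)
}

#' Derepression incidence by piRNA-abundance category
#'
#' Given each family's interspecific piRNA differential-abundance
#' category and its derepression flag: per-category derepression
#' proportions, an overall R x 2 chi-square of independence, and a
#' two-proportion score z test (pooled variance, no continuity
#' correction) for each pairwise contrast.
#'
#' @param categories Factor/character of per-family categories.
#' @param derepressed Logical flags, same length.
#' @return A list of class `CategoryDerepression`: `proportions`
#'   (data.frame `category`, `n`, `n_derepressed`, `proportion`),
#'   `chisq` ([StatResult-class], `NULL` if < 2 non-empty categories),
#'   `pairwise` (data.frame `cat1`, `cat2`, `z`, `df`, `p`).
#' @export
derepressionByCategory <- function(categories, derepressed) {
  stopifnot(length(categories) == length(derepressed))
  keep <- !is.na(categories)
  levAll <- if (is.factor(categories)) levels(categories) else
    sort(unique(as.character(categories[keep])))
  categories <- as.character(categories[keep])
  derepressed <- derepressed[keep]
  lev <- sort(unique(categories))
  empty <- setdiff(levAll, lev)
  if (length(empty)) warning("empty categor(ies) excluded: ",
                             paste(empty, collapse = ", "))
  n <- vapply(lev, function(l) sum(categories == l), 0)
  k <- vapply(lev, function(l) sum(derepressed[categories == l]), 0)
  props <- data.frame(category = lev, n = n, n_derepressed = k,
                      proportion = k / n, row.names = NULL)
  # chi-square is undefined when every family (or none) is derepressed
  chis <- if (length(lev) >= 2 && sum(k) > 0 && sum(n - k) > 0)
    chiSquareRxC(cbind(derepressed = k, not = n - k)) else NULL
  pairs <- if (length(lev) >= 2) t(utils::combn(length(lev), 2)) else
    matrix(integer(), 0, 2)
  pw <- lapply(seq_len(nrow(pairs)), function(i) {
    i1 <- pairs[i, 1]; i2 <- pairs[i, 2]
    phat <- (k[i1] + k[i2]) / (n[i1] + n[i2])
    se <- sqrt(phat * (1 - phat) * (1 / n[i1] + 1 / n[i2]))
    z <- if (se > 0) (k[i1] / n[i1] - k[i2] / n[i2]) / se else 0
    data.frame(cat1 = lev[i1], cat2 = lev[i2], z = z,
               df = n[i1] + n[i2] - 2,
               p = 2 * stats::pnorm(-abs(z)))
  })
  structure(list(proportions = props, chisq = chis,
                 pairwise = if (length(pw)) do.call(rbind, pw) else
                   data.frame(cat1 = character(), cat2 = character(),
                              z = numeric(), df = numeric(), p = numeric())),
            class = "CategoryDerepression")
}

#' @export
print.CategoryDerepression <- function(x, ...) {
  cat("Derepression by category:\n")
  print(x$proportions)
  if (!is.null(x$chisq)) show(x$chisq)
  invisible(x)
}
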