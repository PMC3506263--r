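#' Quantify mRNA reads per TE family (or gene)
#'
#' Weighted raw counts per target from a consensus-database mapping,
#' under the standard tie policy: a read hitting k distinct targets
#' contributes `copies/k` to each. Genes are quantified identically
#' against transcript sequences.
#'
#' @param hits `ReadHits` (or hits data.frame) from [assignReads()].
#' @param targets Optional character vector fixing the output universe
#'   (families absent from the hits get count 0).
#' @return Named numeric vector of weighted counts.
#' @export
quantifyFamilies <- function(hits, targets = NULL) {
  h <- .hitFrame(hits)
  w <- .familyWeights(h, minLen = 0L, maxLen = .Machine$integer.max)
  out <- tapply(w$weight, w$family, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  if (!is.null(targets)) {
    full <- stats::setNames(rep(0, length(targets)), targets)
    full[names(out)[names(out) %in% targets]] <-
      out[names(out) %in% targets]
    out <- full
  }
  out
}

#' Length- and depth-normalized abundance
#'
#' `count * 1e9 / (librarySize * length)`: reads per kilobase of
#' consensus per million library reads.
#'
#' @param counts Named numeric vector of raw counts.
#' @param librarySize Total mapped library size (> 0).
#' @param lengths Named numeric vector of consensus lengths (> 0),
#'   matched by name to `counts`.
#' @return Numeric vector of normalized abundances.
#' @export
normalizeRPKM <- function(counts, librarySize, lengths) {
  if (librarySize <= 0) stop("librarySize must be positive", call. = FALSE)
  L <- if (!is.null(names(counts)) && !is.null(names(lengths)))
    lengths[names(counts)] else rep_len(lengths, length(counts))
  if (any(is.na(L)) || any(L <= 0))
    stop("every count needs a positive length", call. = FALSE)
  counts * 1e9 / (librarySize * L)
}

# exact conditional binomial test for two single-library counts: given
# x + y, x ~ Binomial(x + y, N1/(N1+N2)) under equal underlying abundance
.countTest <- function(x, y, n1, n2) {
  tot <- round(x + y)
  if (tot == 0) return(1)
  stats::binom.test(round(x), tot, p = n1 / (n1 + n2))$p.value
}

#' Dual-parent derepression calling
#'
#' For each family, the hybrid library is compared against each parent:
#' fold changes are formed on depth-normalized counts with a 0.5
#' pseudocount on the raw counts, and significance comes from an exact
#' conditional binomial test on the raw weighted counts (total-count
#' conditioned; `test = "nb"` substitutes a negative-binomial exact test
#' with a supplied dispersion, via edgeR), BH-adjusted across families
#' separately per comparison. A family is `derepressed` iff its log2
#' fold change is >= 1 against BOTH parents and both q-values are below
#' `alpha`; `underexpressed` is symmetric at <= -1. A significance-free
#' fold-only call is emitted alongside (`status_fold_only`), since the
#' abundance analyses are run on both variants.
#'
#' @param counts Matrix or data.frame, families x libraries, with
#'   columns `parentA`, `parentB`, `hybrid` of raw weighted counts.
#' @param librarySizes Named numeric: total reads per library.
#' @param lengths Named numeric consensus lengths per family (only used
#'   for reporting normalized abundances; fold changes are depth-scaled
#'   so lengths cancel).
#' @param fold Fold-change threshold (default 2; inclusive unless
#'   `strictGreater`).
#' @param alpha q-value threshold (default 0.05).
#' @param strictGreater Use strict `>` instead of `>=` on the fold rule.
#' @param test `"binomial"` (default) or `"nb"`.
#' @param nbDispersion Dispersion for `test = "nb"`.
#' @return data.frame with per-family counts, normalized abundances,
#'   `log2fc_vs_A`, `log2fc_vs_B`, `q_vs_A`, `q_vs_B`, `status`,
#'   `status_fold_only`.
#' @export
callExpressionStatus <- function(counts, librarySizes, lengths = NULL,
                                 fold = 2, alpha = 0.05,
                                 strictGreater = FALSE,
                                 test = c("binomial", "nb"),
                                 nbDispersion = 0.01) {
  test <- match.arg(test)
  counts <- as.matrix(counts)
  stopifnot(all(c("parentA", "parentB", "hybrid") %in% colnames(counts)))
  fams <- rownames(counts)
  nA <- librarySizes[["parentA"]]; nB <- librarySizes[["parentB"]]
  nH <- librarySizes[["hybrid"]]
  fc <- function(xH, xP, nP) ((xH + 0.5) / nH) / ((xP + 0.5) / nP)
  l2A <- log2(fc(counts[, "hybrid"], counts[, "parentA"], nA))
  l2B <- log2(fc(counts[, "hybrid"], counts[, "parentB"], nB))
  if (test == "binomial") {
    pA <- mapply(.countTest, counts[, "hybrid"], counts[, "parentA"],
                 MoreArgs = list(n1 = nH, n2 = nA))
    pB <- mapply(.countTest, counts[, "hybrid"], counts[, "parentB"],
                 MoreArgs = list(n1 = nH, n2 = nB))
  } else {
    if (!requireNamespace("edgeR", quietly = TRUE))
      stop("test = 'nb' requires the edgeR package", call. = FALSE)
    pA <- .nbTest(counts[, "hybrid"], counts[, "parentA"], nH, nA,
                  nbDispersion)
    pB <- .nbTest(counts[, "hybrid"], counts[, "parentB"], nH, nB,
                  nbDispersion)
  }
  qA <- stats::p.adjust(pA, "BH")
  qB <- stats::p.adjust(pB, "BH")
  lfcThr <- log2(fold)
  up <- if (strictGreater) function(x) x > lfcThr else function(x) x >= lfcThr
  dn <- if (strictGreater) function(x) x < -lfcThr else function(x) x <= -lfcThr
  foldUp <- up(l2A) & up(l2B)
  foldDn <- dn(l2A) & dn(l2B)
  sig <- qA < alpha & qB < alpha
  status <- ifelse(foldUp & sig, "derepressed",
                   ifelse(foldDn & sig, "underexpressed", "unchanged"))
  statusF <- ifelse(foldUp, "derepressed",
                    ifelse(foldDn, "underexpressed", "unchanged"))
  out <- data.frame(
    family = fams,
    count_parentA = counts[, "parentA"], count_parentB = counts[, "parentB"],
    count_hybrid = counts[, "hybrid"],
    log2fc_vs_A = l2A, log2fc_vs_B = l2B,
    q_vs_A = qA, q_vs_B = qB,
    status = status, status_fold_only = statusF, row.names = NULL)
  if (!is.null(lengths)) {
    out$norm_parentA <- normalizeRPKM(stats::setNames(counts[, "parentA"], fams), nA, lengths)
    out$norm_parentB <- normalizeRPKM(stats::setNames(counts[, "parentB"], fams), nB, lengths)
    out$norm_hybrid <- normalizeRPKM(stats::setNames(counts[, "hybrid"], fams), nH, lengths)
  }
  out
}

.nbTest <- function(x, y, n1, n2, dispersion) {
  d <- edgeR::DGEList(counts = cbind(a = round(x), b = round(y)),
                      lib.size = c(n1, n2), group = factor(c("a", "b")))
  et <- edgeR::exactTest(d, pair = c("b", "a"), dispersion = dispersion)
  et$table$PValue
}

#' Species-of-origin partition of reads
#'
#' Classifies each read by zero-mismatch placement on the two parental
#' genomes: unique to genome A, unique to genome B, shared (placed on
#' both), or unplaced. Family attribution goes through the annotated TE
#' insertion a placement overlaps; reads overlapping no insertion are
#' tallied under `"(unassigned)"`.
#'
#' @param reads data.frame with `read_id`, `seq` (and optional `copies`).
#' @param genomeA,genomeB [GenomeAnnotation-class] objects.
#' @return A list of class `OriginPartition`: `reads` (per collapsed
#'   sequence: `seq`, `copies`, `origin` in
#'   `c("A_only","B_only","shared","unplaced")`, `family`) and `families`
#'   (per family x origin count matrix).
#' @export
originPartition <- function(reads, genomeA, genomeB) {
  idxA <- buildConsensusIndex(genomeA, 0L)
  idxB <- buildConsensusIndex(genomeB, 0L)
  hA <- assignReads(reads, idxA)
  hB <- assignReads(reads, idxB)
  allSeq <- unique(toupper(reads$seq))
  if (!"copies" %in% names(reads)) reads$copies <- 1L
  cp <- tapply(reads$copies, toupper(reads$seq), sum)
  inA <- allSeq %in% hA$hits$seq
  inB <- allSeq %in% hB$hits$seq
  origin <- ifelse(inA & inB, "shared",
                   ifelse(inA, "A_only", ifelse(inB, "B_only", "unplaced")))
  attrib <- function(seq, hits, ann) {
    h <- hits$hits[hits$hits$seq == seq, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    gr <- GenomicRanges::GRanges(h$target,
                                 IRanges::IRanges(h$five_prime + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(gr, teInsertions(ann))
    if (!length(ov)) return("(unassigned)")
    fams <- teInsertions(ann)$family[S4Vectors::subjectHits(ov)]
    names(sort(table(fams), decreasing = TRUE))[1L]
  }
  fam <- vapply(seq_along(allSeq), function(i) {
    switch(origin[i],
           A_only = attrib(allSeq[i], hA, genomeA),
           B_only = attrib(allSeq[i], hB, genomeB),
           shared = attrib(allSeq[i], hA, genomeA),
           unplaced = NA_character_)
  }, "")
  perRead <- data.frame(seq = allSeq, copies = as.numeric(cp[allSeq]),
                        origin = origin, family = fam)
  mapped <- perRead[perRead$origin != "unplaced", , drop = FALSE]
  famLev <- sort(unique(stats::na.omit(mapped$family)))
  tab <- matrix(0, nrow = length(famLev), ncol = 3L,
                dimnames = list(famLev, c("A_only", "B_only", "shared")))
  for (o in colnames(tab)) {
    s <- mapped[mapped$origin == o & !is.na(mapped$family), , drop = FALSE]
    if (nrow(s)) {
      t0 <- tapply(s$copies, s$family, sum)
      tab[names(t0), o] <- as.numeric(t0)
    }
  }
  structure(list(reads = perRead, families = tab), class = "OriginPartition")
}

#' @export
print.OriginPartition <- function(x, ...) {
  cat("OriginPartition:", nrow(x$reads), "sequences;",
      paste(names(table(x$reads$origin)), table(x$reads$origin),
            sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Per-origin fold change
#'
#' Compares genome-A-unique hybrid reads against the corresponding
#' parent-A reads (and B against B) in RPM, with a 0.5 pseudocount;
#' increased abundance of both maternal- and paternal-origin transcripts
#' in the hybrid indicates biallelic derepression rather than a failure
#' specific to one parent's piRNA complement.
#'
#' @param hybridPart [originPartition()] of the hybrid library.
#' @param parentAPart,parentBPart Partitions of the parental libraries.
#' @param librarySizes Named numeric: `parentA`, `parentB`, `hybrid`.
#' @return data.frame: `family`, `log2fc_A_origin`, `log2fc_B_origin`,
#'   `flag_zero_A`, `flag_zero_B` (families with no origin-specific
#'   reads in the corresponding parent are flagged; with none anywhere
#'   the value is `NA`).
#' @export
perOriginFoldChange <- function(hybridPart, parentAPart, parentBPart,
                                librarySizes) {
  fams <- sort(Reduce(union, list(rownames(hybridPart$families),
                                  rownames(parentAPart$families),
                                  rownames(parentBPart$families))))
  get <- function(part, fam, col) {
    if (fam %in% rownames(part$families)) part$families[fam, col] else 0
  }
  rows <- lapply(fams, function(f) {
    hA <- get(hybridPart, f, "A_only"); pA <- get(parentAPart, f, "A_only")
    hB <- get(hybridPart, f, "B_only"); pB <- get(parentBPart, f, "B_only")
    lfc <- function(x, y, nx, ny) {
      if (x == 0 && y == 0) return(NA_real_)
      log2(((x + 0.5) / nx) / ((y + 0.5) / ny))
    }
    data.frame(family = f,
               log2fc_A_origin = lfc(hA, pA, librarySizes[["hybrid"]],
                                     librarySizes[["parentA"]]),
               log2fc_B_origin = lfc(hB, pB, librarySizes[["hybrid"]],
                                     librarySizes[["parentB"]]),
               flag_zero_A = pA == 0, flag_zero_B = pB == 0)
  })
  do.call(rbind, rows)
}
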