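#' Small-RNA size distribution
#'
#' Histogram of read lengths over `range`, normalized fractions, and the
#' piRNA share: the fraction of reads at least `pirnaMin` nt long. In
#' wild-type ovaries the >=23 nt class dominates; in piRNA-pathway
#' mutants (and, per this analysis, in interspecific hybrids) the
#' distribution shifts towards the 18-22 nt miRNA/endo-siRNA background.
#'
#' @param reads data.frame with a `seq` column (and optional `copies`),
#'   or a character vector of sequences.
#' @param range Length window, inclusive; reads outside are dropped.
#' @param pirnaMin Minimum piRNA length (default 23 nt).
#' @param libraryId Identifier carried into the output.
#' @return A list of class `SizeDistribution`: `library_id`, `counts`
#'   (named per length), `fractions` (sum to 1), `pirna_share`.
#' @export
sizeDistribution <- function(reads, range = c(18L, 30L), pirnaMin = 23L,
                             libraryId = "library") {
  if (is.character(reads)) reads <- data.frame(seq = reads)
  if (!"copies" %in% names(reads)) reads$copies <- 1L
  len <- nchar(reads$seq)
  keep <- len >= range[1] & len <= range[2]
  if (!any(keep)) stop("no reads in range [", range[1], ",", range[2], "]",
                       call. = FALSE)
  lens <- range[1]:range[2]
  counts <- vapply(lens, function(L) sum(reads$copies[keep][len[keep] == L]), 0)
  names(counts) <- lens
  fr <- counts / sum(counts)
  structure(list(library_id = libraryId, counts = counts, fractions = fr,
                 pirna_share = sum(fr[lens >= pirnaMin])),
            class = "SizeDistribution")
}

#' @export
print.SizeDistribution <- function(x, ...) {
  cat("SizeDistribution [", x$library_id, "]: ", sum(x$counts),
      " reads, piRNA share ", sprintf("%.3f", x$pirna_share), "\n", sep = "")
  invisible(x)
}

# tie policy: a read hitting k distinct families contributes copies/k to
# each; returns per (seq, family) weight rows for reads in [minLen, maxLen]
.familyWeights <- function(hits, minLen = 23L, maxLen = 29L) {
  h <- .hitFrame(hits)
  h <- h[h$length >= minLen & h$length <= maxLen, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(seq = character(), family = character(),
                      strand = character(), weight = numeric()))
  # one row per (seq, family, strand): a read placed several times in one
  # family still contributes once to that family's tally
  key <- paste(h$seq, h$target, h$strand, sep = "\r")
  u <- h[!duplicated(key), c("seq", "target", "strand", "copies")]
  nfam <- tapply(u$target, u$seq, function(t) length(unique(t)))
  # strand of a read within a family: if placed on both strands of the same
  # family, split its weight between them
  key2 <- paste(u$seq, u$target, sep = "\r")
  nstr <- table(key2)
  u$weight <- u$copies / as.integer(nfam[u$seq]) / as.integer(nstr[key2])
  data.frame(seq = u$seq, family = u$target, strand = u$strand,
             weight = u$weight)
}

#' Per-family piRNA abundance
#'
#' Weighted read counts per TE family for reads in the piRNA length
#' window, with reads hitting k families contributing `copies/k` to each
#' (set `uniqueOnly = TRUE` to count single-family reads only), and
#' reads-per-million normalization against the library size.
#'
#' @param hits `ReadHits` (or hits data.frame) from consensus mapping.
#' @param librarySize Total reads in the library (for RPM).
#' @param minLen,maxLen piRNA length window, inclusive (defaults 23/29).
#' @param uniqueOnly Count only reads mapping to a single family.
#' @param libraryId Identifier carried into the output.
#' @param excludeSeqs Optional character vector of read sequences to drop
#'   before tallying (see [clusterUniqueSeqs()] for the cluster-filter
#'   variant of the analysis).
#' @return data.frame: `family`, `library_id`, `weight`, `rpm`,
#'   `antisense_fraction` (NA for zero-weight families).
#' @export
familyAbundance <- function(hits, librarySize, minLen = 23L, maxLen = 29L,
                            uniqueOnly = FALSE, libraryId = "library",
                            excludeSeqs = NULL) {
  if (librarySize <= 0) stop("librarySize must be positive", call. = FALSE)
  h <- .hitFrame(hits)
  if (!is.null(excludeSeqs)) h <- h[!(h$seq %in% excludeSeqs), , drop = FALSE]
  w <- .familyWeights(h, minLen, maxLen)
  if (uniqueOnly) {
    nfam <- tapply(w$family, w$seq, function(t) length(unique(t)))
    w <- w[as.integer(nfam[w$seq]) == 1L, , drop = FALSE]
  }
  fams <- sort(unique(w$family))
  if (!length(fams))
    return(data.frame(family = character(), library_id = character(),
                      weight = numeric(), rpm = numeric(),
                      antisense_fraction = numeric()))
  tot <- vapply(fams, function(f) sum(w$weight[w$family == f]), 0)
  anti <- vapply(fams, function(f)
    sum(w$weight[w$family == f & w$strand == "antisense"]), 0)
  data.frame(family = fams, library_id = libraryId, weight = tot,
             rpm = tot * 1e6 / librarySize,
             antisense_fraction = ifelse(tot > 0, anti / tot, NA_real_),
             row.names = NULL)
}

#' Antisense fraction of one family's piRNAs
#'
#' Antisense weight over total weight for reads of one family in the
#' piRNA window. Families with zero weighted reads yield `NA` (missing,
#' not 0).
#'
#' @inheritParams familyAbundance
#' @param family Family name.
#' @return A single numeric fraction, or `NA` if the family has no reads.
#' @export
antisenseFraction <- function(hits, family, minLen = 23L, maxLen = 29L) {
  w <- .familyWeights(hits, minLen, maxLen)
  w <- w[w$family == family, , drop = FALSE]
  if (!nrow(w) || sum(w$weight) == 0) return(NA_real_)
  sum(w$weight[w$strand == "antisense"]) / sum(w$weight)
}

#' Sequences mapping uniquely inside piRNA clusters
#'
#' Identifies read sequences whose genome placements are unique
#' (`n_locations == 1`) and fall inside an annotated cluster; removing
#' them before family tallies reproduces the cluster-excluded variant of
#' the differential-abundance analysis.
#'
#' @param genomeHits `ReadHits` from mapping the library to the annotated
#'   genome.
#' @param annotation The [GenomeAnnotation-class] carrying the clusters.
#' @return Character vector of read sequences.
#' @export
clusterUniqueSeqs <- function(genomeHits, annotation) {
  h <- .hitFrame(genomeHits)
  h <- h[h$n_locations == 1L, , drop = FALSE]
  if (!nrow(h)) return(character(0))
  gr <- GenomicRanges::GRanges(h$target,
                               IRanges::IRanges(h$five_prime + 1L, width = 1L))
  inside <- IRanges::overlapsAny(gr, piClusters(annotation))
  unique(h$seq[inside])
}

#' Interspecific differential piRNA abundance categories
#'
#' Classifies each family by the ratio of its piRNA abundance (RPM)
#' between two libraries: `A_biased` iff `RPM_A >= fold * RPM_B`
#' (inclusive), symmetrically `B_biased`, otherwise `nondifferential`.
#' Zero RPM values are floored at the RPM of half a read
#' (`0.5e6/librarySize`) for ratio formation only; reported RPM columns
#' stay raw.
#'
#' @param tableA,tableB Outputs of [familyAbundance()] for the two
#'   libraries (same family universe not required; missing families get
#'   RPM 0).
#' @param fold Ratio threshold (default 2, inclusive).
#' @param librarySizeA,librarySizeB Library sizes backing the floor.
#' @return data.frame: `family`, `rpm_A`, `rpm_B`, `category`.
#' @export
differentialAbundance <- function(tableA, tableB, fold = 2,
                                  librarySizeA = 1e6, librarySizeB = 1e6) {
  fams <- sort(union(tableA$family, tableB$family))
  rA <- stats::setNames(rep(0, length(fams)), fams)
  rB <- rA
  rA[tableA$family] <- tableA$rpm
  rB[tableB$family] <- tableB$rpm
  fA <- ifelse(rA > 0, rA, 0.5e6 / librarySizeA)
  fB <- ifelse(rB > 0, rB, 0.5e6 / librarySizeB)
  cat_ <- ifelse(fA >= fold * fB, "A_biased",
                 ifelse(fB >= fold * fA, "B_biased", "nondifferential"))
  data.frame(family = fams, rpm_A = as.numeric(rA), rpm_B = as.numeric(rB),
             category = cat_, row.names = NULL)
}
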