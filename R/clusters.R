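#' Cluster-derived piRNA tallies under three mapping schemes
#'
#' Tallies piRNA reads whose genomic 5' end falls inside each annotated
#' cluster interval (half-open membership, so edge-straddling reads are
#' assigned unambiguously), under the three standard multimapper
#' schemes: `unique` counts only reads with a single genomic placement;
#' `weighted` gives every read weight `copies/n_locations` per in-cluster
#' placement; `all` counts every read with any in-cluster placement at
#' its full copy weight. Frequencies denominate over the total mappable
#' piRNA-class read copies of the library.
#'
#' @param hits `ReadHits` from mapping the library to the annotated
#'   genome.
#' @param clusters [GenomicRanges::GRanges] of cluster intervals with
#'   mcol `cluster_id`, or a [GenomeAnnotation-class].
#' @param scheme `"unique"`, `"weighted"`, or `"all"`.
#' @param minLen,maxLen piRNA window, inclusive (defaults 23/29).
#' @param libraryId Identifier carried into the output.
#' @return data.frame: `cluster_id`, `library_id`, `scheme`, `tally`,
#'   `frequency`, plus attributes `"denominator"` (total mappable piRNA
#'   copies) and `"remainder"` (denominator minus the clusters' total).
#' @export
clusterTally <- function(hits, clusters, scheme = c("unique", "weighted", "all"),
                         minLen = 23L, maxLen = 29L, libraryId = "library") {
  scheme <- match.arg(scheme)
  if (methods::is(clusters, "GenomeAnnotation")) clusters <- piClusters(clusters)
  h <- .hitFrame(hits)
  h <- h[h$length >= minLen & h$length <= maxLen, , drop = FALSE]
  known <- unique(h$target)
  badCtg <- setdiff(unique(as.character(GenomicRanges::seqnames(clusters))),
                    known)
  if (length(badCtg) && nrow(h))
    stop("cluster interval(s) on unknown contig(s): ",
         paste(badCtg, collapse = ", "), call. = FALSE)
  denom <- sum(h$copies[!duplicated(h$seq)])
  ids <- clusters$cluster_id
  tall <- stats::setNames(rep(0, length(ids)), ids)
  if (nrow(h)) {
    gr <- GenomicRanges::GRanges(h$target,
                                 IRanges::IRanges(h$five_prime + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(gr, clusters)
    if (length(ov)) {
      hi <- S4Vectors::queryHits(ov)
      cj <- S4Vectors::subjectHits(ov)
      # per (sequence, cluster): number of in-cluster placements
      key <- paste(h$seq[hi], cj, sep = "\r")
      inCl <- tapply(seq_along(hi), key, length)
      firstRow <- tapply(hi, key, `[`, 1L)
      seqs <- h$seq[firstRow]
      cls <- as.integer(vapply(strsplit(names(inCl), "\r"), `[`, "", 2L))
      cp <- h$copies[firstRow]
      nl <- h$n_locations[firstRow]
      w <- switch(scheme,
                  unique = ifelse(nl == 1L, cp, 0),
                  weighted = cp * as.numeric(inCl) / nl,
                  all = cp)
      t0 <- tapply(w, ids[cls], sum)
      tall[names(t0)] <- tall[names(t0)] + as.numeric(t0)
    }
  }
  out <- data.frame(cluster_id = ids, library_id = libraryId, scheme = scheme,
                    tally = as.numeric(tall),
                    frequency = if (denom > 0) as.numeric(tall) / denom else
                      NA_real_,
                    row.names = NULL)
  attr(out, "denominator") <- denom
  attr(out, "remainder") <- denom - sum(tall)
  out
}

#' Inheritance classification of cluster activity
#'
#' The additive expectation for a cluster's activity in the hybrid is
#' the mean of the two parental frequencies; relative expression is the
#' hybrid frequency over that expectation. A cluster is `overexpressed`
#' (overdominant) iff relative expression >= 2, `underexpressed`
#' (underdominant) iff <= 0.5, `additive` otherwise; a zero expectation
#' leaves the class undefined (`NA`, flagged).
#'
#' @param parentAFreq,parentBFreq,hybridFreq Frequencies (scalars or
#'   equal-length vectors, e.g. the `frequency` columns of
#'   [clusterTally()] outputs aligned by cluster).
#' @param clusterIds Optional ids carried into the output.
#' @return data.frame: `cluster_id`, `parentA_freq`, `parentB_freq`,
#'   `hybrid_freq`, `expectation`, `relative_expression`, `inheritance`,
#'   `flag_zero_expectation`.
#' @export
inheritanceClass <- function(parentAFreq, parentBFreq, hybridFreq,
                             clusterIds = NULL) {
  n <- length(hybridFreq)
  if (is.null(clusterIds)) clusterIds <- paste0("cl", seq_len(n))
  expectation <- (parentAFreq + parentBFreq) / 2
  rel <- ifelse(expectation > 0, hybridFreq / expectation, NA_real_)
  inh <- ifelse(is.na(rel), NA_character_,
                ifelse(rel >= 2, "overexpressed",
                       ifelse(rel <= 0.5, "underexpressed", "additive")))
  data.frame(cluster_id = clusterIds,
             parentA_freq = parentAFreq, parentB_freq = parentBFreq,
             hybrid_freq = hybridFreq, expectation = expectation,
             relative_expression = rel, inheritance = inh,
             flag_zero_expectation = expectation == 0, row.names = NULL)
}

#' Single-parent additive expectation
#'
#' When the second parent's contribution cannot be measured (its
#' clusters unassembled, or its transcript unamplifiable) and is taken
#' as zero, the additive expectation reduces to half the measured
#' parent's level.
#'
#' @param parentFreq Measured parental frequency (vector ok).
#' @return Numeric expectation(s), `parentFreq / 2`; zeros are returned
#'   as zero with a warning (expectation undefined for classification).
#' @export
singleParentExpectation <- function(parentFreq) {
  if (any(parentFreq == 0))
    warning("zero parental frequency: additive expectation is 0 and ",
            "relative expression is undefined")
  parentFreq / 2
}
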