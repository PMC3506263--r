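#' Ping-pong fraction of one family
#'
#' The ping-pong amplification loop cleaves a target 10 nt from the 5'
#' end of the guide piRNA, so reciprocal rounds of Aub/Ago3 cleavage
#' leave pairs of opposite-strand piRNAs whose 5' ends overlap by
#' exactly 10 nt. The ping-pong fraction is the probability that a
#' randomly sampled piRNA of a family has at least one such partner:
#' a sense read with 5' end at `p` (0-based) pairs with any antisense
#' read whose 5' end (the highest plus-strand coordinate it covers) is
#' at `p + offset - 1`. Reads are weighted by their collapsed copy
#' number (sampling by abundance); `distinct = TRUE` weights each
#' distinct sequence once instead. Reads mapping to several families
#' contribute fully to each family they hit (no fractional split inside
#' this statistic: the pair search is per family and self-contained).
#'
#' @param hits `ReadHits` or hits data.frame on the consensus database.
#' @param family Family to score; `NULL` with a single-target hits table
#'   scores that target.
#' @param minLen,maxLen piRNA window, inclusive (defaults 23/29).
#' @param offset 5'-5' overlap defining a pair (default 10 nt).
#' @param distinct Weight by distinct sequences instead of abundance.
#' @param libraryId Identifier carried into the result.
#' @return A list of class `PingPongResult`: `family`, `library_id`,
#'   `fraction`, `total_weight`, `participating_weight`. With zero reads
#'   in the window the fraction is `NA`.
#' @export
pingPongFraction <- function(hits, family = NULL, minLen = 23L, maxLen = 29L,
                             offset = 10L, distinct = FALSE,
                             libraryId = "library") {
  h <- .hitFrame(hits)
  if (is.null(family)) {
    family <- unique(h$target)
    if (length(family) > 1L)
      stop("hits cover several families; give `family`", call. = FALSE)
    if (!length(family)) family <- NA_character_
  }
  h <- h[!is.na(h$target) & h$target == family &
           h$length >= minLen & h$length <= maxLen, , drop = FALSE]
  if (!nrow(h)) {
    return(structure(list(family = family, library_id = libraryId,
                          fraction = NA_real_, total_weight = 0,
                          participating_weight = 0),
                     class = "PingPongResult"))
  }
  # one row per (seq, strand, five_prime) within the family
  key <- paste(h$seq, h$strand, h$five_prime, sep = "\r")
  u <- h[!duplicated(key), , drop = FALSE]
  # a sequence placed at several positions in the family participates if
  # any placement has a partner; weight each sequence once
  sense5 <- unique(u$five_prime[u$strand == "sense"])
  anti5 <- unique(u$five_prime[u$strand == "antisense"])
  paired <- ifelse(u$strand == "sense",
                   (u$five_prime + offset - 1L) %in% anti5,
                   (u$five_prime - offset + 1L) %in% sense5)
  perSeq <- tapply(paired, u$seq, any)
  seqW <- if (distinct) rep(1, length(perSeq)) else
    u$copies[match(names(perSeq), u$seq)]
  total <- sum(seqW)
  part <- sum(seqW[perSeq])
  structure(list(family = family, library_id = libraryId,
                 fraction = part / total, total_weight = total,
                 participating_weight = part),
            class = "PingPongResult")
}

#' @export
print.PingPongResult <- function(x, ...) {
  cat(sprintf("PingPong [%s | %s]: fraction %.3f of weight %g\n",
              x$family, x$library_id,
              ifelse(is.na(x$fraction), NaN, x$fraction), x$total_weight))
  invisible(x)
}

#' Ping-pong table across families and libraries
#'
#' Computes the ping-pong fraction for every family in every library and
#' applies the reporting filter: a family is retained iff in at least
#' one library it has more than `minReads` weighted reads AND a fraction
#' above `minFraction`; retained families report all libraries' values.
#'
#' @param hitsList Named list (by library) of `ReadHits` on the consensus
#'   database.
#' @param families Character vector of families to score (default: all
#'   targets seen).
#' @param minReads,minFraction Filter thresholds (defaults 50 reads,
#'   fraction 0.1, both strict `>`).
#' @inheritParams pingPongFraction
#' @return data.frame: `family`, `library_id`, `fraction`,
#'   `total_weight`, `passes_filter` (per family x library), restricted
#'   to families passing the filter in >= 1 library. The unfiltered
#'   table is attached as attribute `"unfiltered"`.
#' @export
pingPongTable <- function(hitsList, families = NULL, minLen = 23L,
                          maxLen = 29L, offset = 10L, distinct = FALSE,
                          minReads = 50, minFraction = 0.1) {
  if (is.null(families))
    families <- sort(unique(unlist(lapply(hitsList,
                                          function(h) .hitFrame(h)$target))))
  rows <- list()
  for (lib in names(hitsList)) {
    for (fam in families) {
      r <- pingPongFraction(hitsList[[lib]], fam, minLen, maxLen, offset,
                            distinct, libraryId = lib)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, library_id = lib, fraction = r$fraction,
        total_weight = r$total_weight,
        passes_filter = !is.na(r$fraction) &&
          r$total_weight > minReads && r$fraction > minFraction)
    }
  }
  tab <- do.call(rbind, rows)
  keep <- unique(tab$family[tab$passes_filter])
  out <- tab[tab$family %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unfiltered") <- tab
  out
}

#' 5'-5' overlap spectrum
#'
#' Diagnostic generalization of the ping-pong rule: for every
#' sense/antisense read pair of one family, tallies the weight at each
#' 5'-5' overlap length from 1 to `maxOverlap`. A ping-pong-active
#' family shows a mode at 10.
#'
#' The entry at overlap `o` is the total weight of reads (both strands)
#' participating in at least one pair with 5'-5' overlap exactly `o`, so
#' the entry at the configured ping-pong offset equals the participating
#' weight reported by [pingPongFraction()].
#'
#' @inheritParams pingPongFraction
#' @param maxOverlap Largest overlap length tallied.
#' @return Named numeric vector of weights per overlap length
#'   `1..maxOverlap` (all zeros when either strand has no reads).
#' @export
overlapSpectrum <- function(hits, family = NULL, minLen = 23L, maxLen = 29L,
                            maxOverlap = 25L, distinct = FALSE) {
  h <- .hitFrame(hits)
  if (is.null(family)) {
    family <- unique(h$target)
    if (length(family) > 1L)
      stop("hits cover several families; give `family`", call. = FALSE)
  }
  h <- h[h$target %in% family & h$length >= minLen & h$length <= maxLen, ,
         drop = FALSE]
  spec <- stats::setNames(rep(0, maxOverlap), seq_len(maxOverlap))
  if (!nrow(h)) return(spec)
  key <- paste(h$seq, h$strand, h$five_prime, sep = "\r")
  u <- h[!duplicated(key), , drop = FALSE]
  s <- u$strand == "sense"
  if (!any(s) || all(s)) return(spec)
  sense5 <- unique(u$five_prime[s])
  anti5 <- unique(u$five_prime[!s])
  for (o in seq_len(maxOverlap)) {
    partS <- u$strand == "sense" & (u$five_prime + o - 1L) %in% anti5
    partA <- u$strand == "antisense" & (u$five_prime - o + 1L) %in% sense5
    part <- tapply(partS | partA, u$seq, any)
    wt <- if (distinct) rep(1, length(part)) else
      u$copies[match(names(part), u$seq)]
    spec[o] <- sum(wt[part])
  }
  spec
}
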