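#' Build a searchable index over consensus or genome sequences
#'
#' The pipeline places reads by exact and k-mismatch substring search on
#' both strands of a target database, always keeping only the
#' best-stratum hits (all placements at the lowest achievable mismatch
#' count). The search is self-contained rather than delegated to an
#' external aligner so that it can be verified against an exhaustive
#' sliding-window oracle at test scale. Default mismatch ceiling is 0,
#' the setting used for species-of-origin assignment ("zero mismatches").
#'
#' @param x A [TEFamilySet-class], [GenomeAnnotation-class], or named
#'   [Biostrings::DNAStringSet] of target sequences.
#' @param maxMismatch Integer in 0..3; ceiling on mismatches searched.
#' @return An object of class `SeqIndex`.
#' @seealso [assignReads()]
#' @export
buildConsensusIndex <- function(x, maxMismatch = 0L) {
  stopifnot(maxMismatch %in% 0:3)
  targets <- if (methods::is(x, "TEFamilySet")) consensusSeqs(x)
    else if (methods::is(x, "GenomeAnnotation")) genomeSeqs(x)
    else if (methods::is(x, "DNAStringSet")) x
    else Biostrings::DNAStringSet(toupper(x))
  if (is.null(names(targets))) stop("index targets must be named")
  structure(list(targets = targets, maxMismatch = as.integer(maxMismatch),
                 annotation = if (methods::is(x, "GenomeAnnotation")) x else NULL),
            class = "SeqIndex")
}

#' @export
print.SeqIndex <- function(x, ...) {
  cat("SeqIndex:", length(x$targets), "target(s),",
      sum(Biostrings::width(x$targets)), "bp, max mismatch", x$maxMismatch, "\n")
  invisible(x)
}

# exact (0-mismatch) placements of unique sequences on both strands of
# every target; hash-join of the read set against all target substrings
# of each read length (every occurrence is kept: one row per placement)
.exactHits <- function(seqs, targets) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  lens <- nchar(seqs)
  tchr <- as.character(targets)
  rows <- list()
  for (ti in seq_along(targets)) {
    S <- tchr[ti]
    Tn <- nchar(S)
    for (L in unique(lens)) {
      if (L > Tn) next
      inL <- which(lens == L)
      st <- seq_len(Tn - L + 1L)
      subs <- substring(S, st, st + L - 1L)
      mS <- match(subs, seqs[inL])       # sense placements
      mA <- match(subs, rc[inL])         # antisense (read revcomp on plus)
      hS <- which(!is.na(mS))
      hA <- which(!is.na(mA))
      if (length(hS))
        rows[[length(rows) + 1L]] <- data.frame(
          qidx = inL[mS[hS]], target = names(targets)[ti],
          start1 = hS, len = L, strand = "sense")
      if (length(hA))
        rows[[length(rows) + 1L]] <- data.frame(
          qidx = inL[mA[hA]], target = names(targets)[ti],
          start1 = hA, len = L, strand = "antisense")
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(qidx = integer(), target = character(), start1 = integer(),
               len = integer(), strand = character())
}

# <=k-mismatch placements for a (small) set of sequences, per-read scan
.kHits <- function(seqs, targets, k) {
  rows <- list()
  for (qi in seq_along(seqs)) {
    for (strand in c("sense", "antisense")) {
      pat <- if (strand == "sense") seqs[qi] else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[qi])))
      for (ti in seq_along(targets)) {
        if (nchar(pat) > Biostrings::width(targets)[ti]) next
        m <- Biostrings::matchPattern(pat, targets[[ti]], max.mismatch = k,
                                      with.indels = FALSE, fixed = TRUE)
        if (length(m))
          rows[[length(rows) + 1L]] <- data.frame(
            qidx = qi, target = names(targets)[ti],
            start1 = Biostrings::start(m), len = nchar(pat), strand = strand)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(qidx = integer(), target = character(), start1 = integer(),
               len = integer(), strand = character())
}

#' Place reads on an indexed target database
#'
#' Identical read sequences are collapsed first, with their multiplicity
#' carried in `copies`. Each collapsed read is searched on both strands
#' of every target at increasing mismatch count and keeps all placements
#' of the lowest mismatch stratum it achieves (ties across targets are
#' kept; `n_locations` records the total number of placements). Reads
#' with no placement within the mismatch ceiling are routed to the
#' unmapped bucket with their copy count.
#'
#' The reported `five_prime` coordinate is 0-based on the target's
#' plus-strand axis. For an antisense placement it is the *highest*
#' plus-strand coordinate covered by the read — the biological 5' end of
#' a minus-strand read — so that the 10-nt ping-pong overlap rule can be
#' expressed on a single axis.
#'
#' @param reads A data.frame with columns `read_id`, `seq` (and
#'   optionally `copies`), or a character vector of sequences.
#' @param index A `SeqIndex` from [buildConsensusIndex()].
#' @param maxMismatch Mismatch ceiling override (defaults to the index's).
#' @return A list of class `ReadHits` with elements `hits` (data.frame:
#'   `read_id`, `seq`, `target`, `strand`, `five_prime`, `length`,
#'   `mismatches`, `n_locations`, `copies`), `unmapped` (data.frame:
#'   `seq`, `copies`), and `totalCopies`.
#' @export
assignReads <- function(reads, index, maxMismatch = NULL) {
  if (is.character(reads))
    reads <- data.frame(read_id = paste0("r", seq_along(reads)), seq = reads)
  if (is.null(maxMismatch)) maxMismatch <- index$maxMismatch
  stopifnot(maxMismatch %in% 0:3)
  if (!"copies" %in% names(reads)) reads$copies <- 1L
  reads$seq <- toupper(reads$seq)
  # collapse identical sequences
  agg <- stats::aggregate(copies ~ seq, data = reads, FUN = sum)
  agg$read_id <- reads$read_id[match(agg$seq, reads$seq)]
  targets <- index$targets

  remaining <- seq_len(nrow(agg))
  hitList <- list()
  for (k in 0:maxMismatch) {
    if (!length(remaining)) break
    h <- if (k == 0L) .exactHits(agg$seq[remaining], targets)
         else .kHits(agg$seq[remaining], targets, k)
    if (nrow(h)) {
      h$qidx <- remaining[h$qidx]
      h$mismatches <- k
      hitList[[length(hitList) + 1L]] <- h
      remaining <- setdiff(remaining, unique(h$qidx))
    }
  }
  if (length(hitList)) {
    h <- do.call(rbind, hitList)
    nl <- table(h$qidx)
    hits <- data.frame(
      read_id = agg$read_id[h$qidx],
      seq = agg$seq[h$qidx],
      target = h$target,
      strand = h$strand,
      five_prime = ifelse(h$strand == "sense", h$start1 - 1L,
                          h$start1 + h$len - 2L),
      length = h$len,
      mismatches = h$mismatches,
      n_locations = as.integer(nl[as.character(h$qidx)]),
      copies = agg$copies[h$qidx])
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(read_id = character(), seq = character(),
                       target = character(), strand = character(),
                       five_prime = integer(), length = integer(),
                       mismatches = integer(), n_locations = integer(),
                       copies = integer())
  }
  unmapped <- agg[remaining, c("seq", "copies")]
  rownames(unmapped) <- NULL
  structure(list(hits = hits, unmapped = unmapped,
                 totalCopies = sum(agg$copies)),
            class = "ReadHits")
}

#' @export
print.ReadHits <- function(x, ...) {
  nm <- length(unique(x$hits$seq))
  cat("ReadHits:", nm, "mapped sequence(s) (",
      sum(x$hits$copies[!duplicated(x$hits$seq)]), "copies ) in",
      nrow(x$hits), "placements;", nrow(x$unmapped), "unmapped sequence(s)\n")
  invisible(x)
}

# per-read (collapsed sequence) view of a hits table: one row per unique
# sequence with its distinct target families and tie-split weight
.readLevel <- function(hits) {
  if (!nrow(hits))
    return(data.frame(seq = character(), copies = integer(),
                      n_families = integer()))
  sp <- split(hits$target, hits$seq)
  data.frame(seq = names(sp),
             copies = hits$copies[match(names(sp), hits$seq)],
             n_families = vapply(sp, function(t) length(unique(t)), 1L))
}

.hitFrame <- function(hits) {
  if (inherits(hits, "ReadHits")) hits$hits else hits
}
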