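#' Per-library small-RNA simulation parameters
#'
#' Defaults describe a wild-type ovarian library: ~60% of reads in the
#' piRNA size class (>=23 nt, lengths centred on 26 nt), the remainder an
#' 18-22 nt miRNA/endo-siRNA background, a family-level antisense
#' fraction of 0.7, and a ping-pong pairing probability of 0.5 (the
#' probability that a piRNA participates in an exact 10-nt 5'-5' overlap
#' pair). `genome` selects which parental genome(s) TE-derived reads are
#' drawn from: `"A"`, `"B"`, or `"both"` (hybrid).
#'
#' @param n_reads Total reads in the library.
#' @param pirna_fraction Fraction of reads in the >=23 nt class.
#' @param pirna_length_mean,pirna_length_sd Length distribution of piRNA
#'   reads, truncated to 23..29 nt.
#' @param bg_length_mean,bg_length_sd Background length distribution,
#'   truncated to 18..22 nt.
#' @param antisense_fraction Target per-family antisense fraction.
#' @param pingpong_prob Per-family ping-pong pairing probability (scalar
#'   or named per-family vector).
#' @param cluster_weights Named numeric vector: expected share of the
#'   library's piRNA-class reads derived from each annotated cluster
#'   (sum < 1; remainder comes from dispersed TE copies). `NULL` means
#'   no cluster-derived reads.
#' @param abundance_multiplier Scalar or named per-family multiplier on
#'   the family abundance weights, letting libraries differ in their
#'   per-family piRNA pools (the basis of the interspecific
#'   differential-abundance categories).
#' @param genome `"A"`, `"B"` or `"both"`.
#' @return A list of class `smallRNAParams`.
#' @export
libraryParams <- function(n_reads = 20000L,
                          pirna_fraction = 0.6,
                          pirna_length_mean = 26, pirna_length_sd = 1.5,
                          bg_length_mean = 20.5, bg_length_sd = 1.2,
                          antisense_fraction = 0.7,
                          pingpong_prob = 0.5,
                          cluster_weights = NULL,
                          abundance_multiplier = 1,
                          genome = "A") {
  stopifnot(pirna_fraction >= 0, pirna_fraction <= 1,
            antisense_fraction >= 0, antisense_fraction <= 1,
            all(pingpong_prob >= 0), all(pingpong_prob <= 1),
            genome %in% c("A", "B", "both"))
  structure(as.list(environment()), class = "smallRNAParams")
}

#' Mutant-like library preset
#'
#' Reshapes wild-type library parameters into the regime observed in
#' piRNA-effector-protein mutants and, per this analysis, in
#' interspecific hybrids: the piRNA-class share of reads drops (default
#' 0.6 -> 0.2), ping-pong pairing collapses (scaled by
#' `pingpong_scale`), and cluster contributions are reweighted by
#' `cluster_multipliers` (relative to the supplied base weights, which
#' for a hybrid should be the parental average).
#'
#' @param params A `smallRNAParams` base (typically a parent's).
#' @param pirna_fraction Replacement piRNA-class share.
#' @param pingpong_scale Multiplier on the pairing probability.
#' @param cluster_multipliers Numeric vector (recycled over clusters)
#'   multiplying `params$cluster_weights`.
#' @return A modified `smallRNAParams`.
#' @export
mutantLikeParams <- function(params, pirna_fraction = 0.2,
                             pingpong_scale = 0.3,
                             cluster_multipliers = NULL) {
  params$pirna_fraction <- pirna_fraction
  params$pingpong_prob <- params$pingpong_prob * pingpong_scale
  if (!is.null(cluster_multipliers) && !is.null(params$cluster_weights)) {
    m <- rep_len(cluster_multipliers, length(params$cluster_weights))
    params$cluster_weights <- params$cluster_weights * m
  }
  params
}

#' Simulation configuration
#'
#' One seeded configuration drives every generator; the seed fully
#' determines all outputs. Two diverged parental genomes are built from
#' one consensus library: each genome carries its own allele of every
#' family (substituted at rate `divergence` per site), full-length copies
#' of that allele, and (genome A only, mirroring the asymmetry of real
#' cluster annotation) piRNA clusters assembled from fragmented antisense
#' TE copies.
#'
#' @param seed Integer seed.
#' @param n_families Number of TE families.
#' @param consensus_length_range Min/max consensus length (nt).
#' @param insertions_per_family Mean full-length copies per family per
#'   genome (Poisson, minimum 1 where the family is present).
#' @param divergence Per-site substitution probability of each genome's
#'   family allele relative to the consensus (so two alleles differ at
#'   ~`2*divergence` of sites); every family is guaranteed at least one
#'   diagnostic substitution when `divergence > 0`.
#' @param copy_divergence Additional per-copy substitution rate (default
#'   0: copies within a genome share the genome allele, which is what
#'   makes species-diagnostic sites well defined).
#' @param presence_probs Probabilities that a family has full-length
#'   copies in both genomes, genome A only, or neither.
#' @param n_clusters Number of piRNA clusters (annotated on genome A).
#' @param cluster_fragments Fragmented TE copies per cluster.
#' @param cluster_fragment_range Fragment length range (nt).
#' @param abundance_range Range of the log-uniform per-family abundance
#'   weights.
#' @param smallrna Named list of `smallRNAParams`, one per library
#'   (default `parentA`, `parentB`, `hybrid`).
#' @param mrna List: `base_mean_range` (log-uniform per-family mean),
#'   `dispersion` (NB dispersion; 0 = Poisson), `library_sizes` (named),
#'   `planted_log2fc` (named per-family vector for the hybrid),
#'   `read_length` (for optional mRNA read emission).
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L,
                      n_families = 25L,
                      consensus_length_range = c(1000L, 2500L),
                      insertions_per_family = 3,
                      divergence = 0.02,
                      copy_divergence = 0,
                      presence_probs = c(both_genomes = 0.6, mel_only = 0.25,
                                         neither = 0.15),
                      n_clusters = 15L,
                      cluster_fragments = 8L,
                      cluster_fragment_range = c(300L, 800L),
                      abundance_range = c(1, 100),
                      smallrna = NULL,
                      mrna = NULL) {
  stopifnot(divergence >= 0, divergence <= 1, n_families >= 0)
  if (is.null(smallrna))
    smallrna <- list(parentA = libraryParams(genome = "A"),
                     parentB = libraryParams(genome = "B"),
                     hybrid = libraryParams(genome = "both"))
  mdef <- list(base_mean_range = c(100, 1000), dispersion = 0.01,
               library_sizes = c(parentA = 1e6, parentB = 1e6, hybrid = 1e6),
               planted_log2fc = numeric(), read_length = 50L)
  if (!is.null(mrna)) mdef[names(mrna)] <- mrna
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 consensus_length_range = consensus_length_range,
                 insertions_per_family = insertions_per_family,
                 divergence = divergence, copy_divergence = copy_divergence,
                 presence_probs = presence_probs,
                 n_clusters = as.integer(n_clusters),
                 cluster_fragments = as.integer(cluster_fragments),
                 cluster_fragment_range = cluster_fragment_range,
                 abundance_range = abundance_range,
                 smallrna = smallrna, mrna = mdef),
            class = "simConfig")
}

#' Default Zipf-profile cluster weights
#'
#' Parent A's cluster contributions follow a 1/rank profile over the
#' annotated clusters (a few prolific clusters dominate); parent B the
#' reversed profile, so the parents differ per cluster while sharing the
#' same total cluster-derived share.
#'
#' @param n_clusters Number of clusters.
#' @param total Total share of piRNA-class reads drawn from clusters.
#' @param reverse Use the reversed profile (parent B).
#' @return Named numeric vector of weights summing to `total`.
#' @export
defaultClusterWeights <- function(n_clusters = 15L, total = 0.35,
                                  reverse = FALSE) {
  w <- 1 / seq_len(n_clusters)
  if (reverse) w <- rev(w)
  stats::setNames(total * w / sum(w), paste0("cl", seq_len(n_clusters)))
}

.seedFor <- function(config, offset) {
  set.seed((config$seed %% 1000003L) * 101L + offset)
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# uniform integer draw on [lo, hi] that is safe when lo == hi (unlike
# sample(lo:hi, 1), which degenerates to sample.int(lo))
.runifInt <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

.mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  }
  paste(x, collapse = "")
}

.truncNormLen <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    cand <- as.integer(round(stats::rnorm(n, mean, sd)))
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a TE family library
#'
#' Draws `n_families` random consensus sequences with lengths uniform in
#' `consensus_length_range` and assigns family metadata: structural
#' class, tissue of regulation, Aub/Ago3 dependency group,
#' horizontal-transfer candidacy, full-length genomic presence, and a
#' log-uniform abundance weight (the expected share of TE-derived reads,
#' stored in `familyInfo()` as `abundance_weight`).
#'
#' @param config A [simConfig()].
#' @return A [TEFamilySet-class].
#' @export
simulateTELibrary <- function(config) {
  .seedFor(config, 1L)
  n <- config$n_families
  if (n == 0L)
    return(TEFamilySet(stats::setNames(character(0), character(0))))
  lens <- .runifInt(n, config$consensus_length_range[1],
                    config$consensus_length_range[2])
  seqs <- vapply(lens, .randSeq, "")
  names(seqs) <- sprintf("TE%02d", seq_len(n))
  fam <- TEFamilySet(
    seqs,
    te_class = sample(.TE_CLASSES, n, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
    tissue = sample(c("germline", "somatic", "intermediate"), n, replace = TRUE,
                    prob = c(0.6, 0.25, 0.15)),
    dependency_group = sample(.DEP_GROUPS[1:3], n, replace = TRUE),
    ht_candidate = stats::runif(n) < 0.3,
    full_length_presence = sample(names(config$presence_probs), n,
                                  replace = TRUE, prob = config$presence_probs))
  w <- exp(stats::runif(n, log(config$abundance_range[1]),
                        log(config$abundance_range[2])))
  fam@info$abundance_weight <- w / sum(w)
  fam
}

#' Simulate two diverged parental genomes
#'
#' Each genome gets its own allele of every family (substitution rate
#' `divergence` per site, with at least one diagnostic substitution
#' forced per family when `divergence > 0`), full-length copies of the
#' allele planted between random background segments, and - on genome A
#' only - piRNA clusters built by concatenating fragmented antisense
#' copies of randomly chosen family alleles.
#'
#' @param config A [simConfig()].
#' @param families A [TEFamilySet-class] from [simulateTELibrary()].
#' @return A list with elements `parentA`, `parentB`
#'   ([GenomeAnnotation-class]), `alleles` (list `A`/`B` of named allele
#'   sequences), `copies` (data.frame `family`, `genome`, `contig`,
#'   `start0` of every planted full-length copy), and `diagnosticSites`
#'   (data.frame `family`, `pos0`, `baseA`, `baseB`).
#' @export
simulateParentalGenomes <- function(config, families) {
  .seedFor(config, 2L)
  fams <- familyNames(families)
  cons <- as.character(consensusSeqs(families))
  presence <- familyInfo(families)$full_length_presence

  alleles <- list(A = character(0), B = character(0))
  diag <- list()
  for (i in seq_along(fams)) {
    aA <- .mutateSeq(cons[i], config$divergence)
    aB <- .mutateSeq(cons[i], config$divergence)
    if (config$divergence > 0 && identical(aA, aB)) {
      # force one diagnostic substitution
      pos <- sample(nchar(aA), 1L)
      ref <- substr(aA, pos, pos)
      substr(aB, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    }
    alleles$A[fams[i]] <- aA
    alleles$B[fams[i]] <- aB
    xa <- strsplit(aA, "")[[1]]; xb <- strsplit(aB, "")[[1]]
    d <- which(xa != xb)
    if (length(d))
      diag[[fams[i]]] <- data.frame(family = fams[i], pos0 = d - 1L,
                                    baseA = xa[d], baseB = xb[d])
  }
  diagnosticSites <- if (length(diag)) do.call(rbind, diag) else
    data.frame(family = character(), pos0 = integer(),
               baseA = character(), baseB = character())
  rownames(diagnosticSites) <- NULL

  buildGenome <- function(gid, gkey) {
    present <- if (gkey == "A") presence %in% c("both_genomes", "mel_only")
               else presence == "both_genomes"
    segs <- character(0)
    pos <- 0L
    ins <- list(); cls <- list(); cps <- list()
    addBg <- function() {
      b <- .randSeq(sample(200:1000, 1L))
      segs[[length(segs) + 1L]] <<- b
      pos <<- pos + nchar(b)
    }
    addBg()
    idx_f <- which(present)
    order_f <- idx_f[sample.int(length(idx_f))]
    for (i in order_f) {
      ncp <- max(1L, stats::rpois(1L, config$insertions_per_family))
      for (k in seq_len(ncp)) {
        cp <- .mutateSeq(alleles[[gkey]][fams[i]], config$copy_divergence)
        segs[[length(segs) + 1L]] <- cp
        ins[[length(ins) + 1L]] <- data.frame(
          contig = "chr1", start = pos, end = pos + nchar(cp),
          family = fams[i], strand = "+")
        cps[[length(cps) + 1L]] <- data.frame(
          family = fams[i], genome = gkey, contig = "chr1", start0 = pos)
        pos <- pos + nchar(cp)
        addBg()
      }
    }
    if (gkey == "A" && config$n_clusters > 0L) {
      for (j in seq_len(config$n_clusters)) {
        cstart <- pos
        for (frag in seq_len(config$cluster_fragments)) {
          fi <- sample(length(fams), 1L)
          al <- alleles$A[fams[fi]]
          flen <- .runifInt(1L, config$cluster_fragment_range[1],
                            config$cluster_fragment_range[2])
          flen <- min(flen, nchar(al))
          fstart <- sample(nchar(al) - flen + 1L, 1L)
          piece <- .revcomp(substr(al, fstart, fstart + flen - 1L))
          spacer <- .randSeq(sample(20:80, 1L))
          segs[[length(segs) + 1L]] <- paste0(piece, spacer)
          pos <- pos + flen + nchar(spacer)
        }
        cls[[length(cls) + 1L]] <- data.frame(
          contig = "chr1", start = cstart, end = pos,
          cluster_id = paste0("cl", j))
        addBg()
      }
    }
    seq <- stats::setNames(paste(unlist(segs), collapse = ""), "chr1")
    list(ann = GenomeAnnotation(
           gid, seq,
           insertions = if (length(ins)) do.call(rbind, ins) else NULL,
           clusters = if (length(cls)) do.call(rbind, cls) else NULL),
         copies = if (length(cps)) do.call(rbind, cps) else
           data.frame(family = character(), genome = character(),
                      contig = character(), start0 = integer()))
  }
  gA <- buildGenome("parentA", "A")
  gB <- buildGenome("parentB", "B")
  list(parentA = gA$ann, parentB = gB$ann, alleles = alleles,
       copies = rbind(gA$copies, gB$copies),
       diagnosticSites = diagnosticSites)
}

#' Simulate one small-RNA library with known ground truth
#'
#' Reads come in three classes. piRNA-class reads (>=23 nt) derive
#' either from dispersed TE copies - placed on the family's consensus
#' axis and lifted to a randomly chosen copy of the genotype's
#' genome(s), so the emitted sequence carries that genome's allele - or,
#' when `cluster_weights` are set, from the annotated piRNA clusters of
#' genome A. A configured fraction of each family's TE-derived piRNAs is
#' planted as exact ping-pong pairs: two opposite-strand reads whose 5'
#' ends overlap by exactly 10 nt. Unpaired reads are rejection-sampled
#' away from accidental 10-nt overlaps so the planted pairing fraction
#' is the truth; pairs whose partner would fall outside the consensus
#' are resampled (and counted in `resampled`). Background reads (18-22
#' nt) fill the remainder. Singleton strand choice is adjusted so the
#' family's overall antisense fraction matches the configured target
#' where feasible (pairs are always one sense + one antisense).
#'
#' @param config A [simConfig()].
#' @param families A [TEFamilySet-class].
#' @param genomes Output of [simulateParentalGenomes()], or `NULL` to
#'   draw sequences directly from the consensus (no cluster reads, no
#'   genome-of-origin truth).
#' @param libraryId Name of the library in `config$smallrna`.
#' @param params Optional `smallRNAParams` override.
#' @return A list with `reads` (data.frame `read_id`, `seq`) and `truth`
#'   (data.frame per read: `read_id`, `family`, `genome`, `cluster`,
#'   `class`, `strand`, `five_prime`, `length`, `pair_id`), plus
#'   `resampled`, the count of resampled pair placements.
#' @export
simulateSmallRNALibrary <- function(config, families, genomes = NULL,
                                    libraryId = "parentA", params = NULL) {
  if (is.null(params)) params <- config$smallrna[[libraryId]]
  if (is.null(params)) stop("no smallrna params for library ", libraryId)
  .seedFor(config, 10L + match(libraryId, names(config$smallrna),
                               nomatch = length(config$smallrna) + 1L))
  fams <- familyNames(families)
  fw <- familyInfo(families)$abundance_weight
  if (is.null(fw)) fw <- rep(1 / length(fams), length(fams))
  cons <- as.character(consensusSeqs(families))
  names(fw) <- names(cons) <- fams
  am <- params$abundance_multiplier
  if (length(am) == 1L && is.null(names(am))) {
    fw <- fw * am
  } else {
    m <- stats::setNames(rep(1, length(fams)), fams)
    m[names(am)[names(am) %in% fams]] <- am[names(am) %in% fams]
    fw <- fw * m
  }
  if (sum(fw) > 0) fw <- fw / sum(fw)

  pp <- params$pingpong_prob
  if (length(pp) == 1L) pp <- stats::setNames(rep(pp, length(fams)), fams)
  af <- params$antisense_fraction
  if (length(af) == 1L) af <- stats::setNames(rep(af, length(fams)), fams)

  n <- params$n_reads
  nPirna <- stats::rbinom(1L, n, params$pirna_fraction)
  nBg <- n - nPirna

  cw <- if (!is.null(genomes)) params$cluster_weights else NULL
  clShare <- if (is.null(cw)) 0 else sum(cw)
  nCluster <- stats::rbinom(1L, nPirna, clShare)
  nFamilial <- nPirna - nCluster

  # which genome's allele does each TE-derived read carry?
  pickGenome <- function(m) {
    if (is.null(genomes)) return(rep(NA_character_, m))
    switch(params$genome,
           A = rep("A", m), B = rep("B", m),
           both = sample(c("A", "B"), m, replace = TRUE))
  }
  axisSeq <- function(fam, gkey) {
    if (is.null(genomes) || is.na(gkey)) cons[fam]
    else genomes$alleles[[gkey]][fam]
  }
  # a family with no planted copy in a genome cannot source reads from it;
  # fall back to the genome that carries it, or to the bare consensus when
  # neither genome has full-length copies
  hasCopy <- if (is.null(genomes)) NULL else
    with(genomes$copies, table(factor(family, levels = fams),
                               factor(genome, levels = c("A", "B"))))
  fixGenome <- function(fam, gkey) {
    if (is.null(genomes) || is.na(gkey)) return(NA_character_)
    if (hasCopy[fam, gkey] > 0L) return(gkey)
    other <- setdiff(c("A", "B"), gkey)
    if (hasCopy[fam, other] > 0L) other else NA_character_
  }

  # preallocated accumulators; antisense sequences are stored as their
  # plus-strand substring and reverse-complemented in one vectorized pass
  resampled <- 0L
  rid <- 0L
  fam_v <- gen_v <- clu_v <- cls_v <- str_v <- pair_v <- rep(NA_character_, n)
  fp_v <- len_v <- rep(NA_integer_, n)
  raw_v <- rep(NA_character_, n)
  emit <- function(fam, gkey, cluster, class, strand, fp, len, pair, axis) {
    rid <<- rid + 1L
    fam_v[rid] <<- fam; gen_v[rid] <<- gkey; clu_v[rid] <<- cluster
    cls_v[rid] <<- class; str_v[rid] <<- strand; pair_v[rid] <<- pair
    fp_v[rid] <<- fp; len_v[rid] <<- len
    raw_v[rid] <<- if (strand == "sense") substr(axis, fp + 1L, fp + len)
      else substr(axis, fp - len + 2L, fp + 1L)
  }

  if (nFamilial > 0L) {
    famIdx <- sample(length(fams), nFamilial, replace = TRUE, prob = fw)
    cnt <- tabulate(famIdx, nbins = length(fams))
    pairCounter <- 0L
    for (i in which(cnt > 0L)) {
      fam <- fams[i]
      nf <- cnt[i]
      nPart <- stats::rbinom(1L, nf, pp[fam])
      nPairs <- nPart %/% 2L
      nSing <- nf - nPairs * 2L
      senseSet <- integer(0)   # occupied sense 5' positions, consensus axis
      antiSet <- integer(0)
      conlen <- nchar(cons[fam])
      # pairs first
      for (p in seq_len(nPairs)) {
        repeat {
          L1 <- .truncNormLen(1L, params$pirna_length_mean,
                              params$pirna_length_sd, 23L, 29L)
          L2 <- .truncNormLen(1L, params$pirna_length_mean,
                              params$pirna_length_sd, 23L, 29L)
          lo <- max(0L, L2 - 10L)
          hi <- conlen - max(L1, 10L)
          if (lo > hi) { resampled <- resampled + 1L; next }
          sp <- .runifInt(1L, lo, hi)       # sense 5', 0-based
          ap <- sp + 9L                     # antisense 5'
          break
        }
        gkey <- fixGenome(fam, pickGenome(1L))
        axis <- axisSeq(fam, gkey)
        pairCounter <- pairCounter + 1L
        pid <- sprintf("%s_%s_p%05d", libraryId, fam, pairCounter)
        emit(fam, gkey, NA, "pirna", "sense", sp, L1, pid, axis)
        emit(fam, gkey, NA, "pirna", "antisense", ap, L2, pid, axis)
        senseSet <- c(senseSet, sp); antiSet <- c(antiSet, ap)
      }
      # singletons, rejection-sampled away from accidental 10-nt overlaps
      afS <- if (pp[fam] >= 1) 0.5 else
        min(1, max(0, (af[fam] - pp[fam] / 2) / (1 - pp[fam])))
      for (s in seq_len(nSing)) {
        L <- .truncNormLen(1L, params$pirna_length_mean,
                           params$pirna_length_sd, 23L, 29L)
        anti <- stats::runif(1L) < afS
        ok <- FALSE
        for (attempt in 1:50) {
          if (anti) {
            fp <- sample((L - 1L):(conlen - 1L), 1L)
            if (!((fp - 9L) %in% senseSet)) { ok <- TRUE; break }
          } else {
            fp <- sample(0:(conlen - L), 1L)
            if (!((fp + 9L) %in% antiSet)) { ok <- TRUE; break }
          }
          resampled <- resampled + 1L
        }
        gkey <- fixGenome(fam, pickGenome(1L))
        axis <- axisSeq(fam, gkey)
        if (anti) {
          emit(fam, gkey, NA, "pirna", "antisense", fp, L, NA, axis)
          antiSet <- c(antiSet, fp)
        } else {
          emit(fam, gkey, NA, "pirna", "sense", fp, L, NA, axis)
          senseSet <- c(senseSet, fp)
        }
      }
    }
  }

  if (nCluster > 0L) {
    ann <- genomes$parentA
    cl <- piClusters(ann)
    gseq <- as.character(genomeSeqs(ann))
    ids <- cl$cluster_id
    pickCl <- sample(length(ids), nCluster, replace = TRUE, prob = cw[ids] / sum(cw[ids]))
    for (x in seq_len(nCluster)) {
      j <- pickCl[x]
      L <- .truncNormLen(1L, params$pirna_length_mean,
                         params$pirna_length_sd, 23L, 29L)
      s1 <- GenomicRanges::start(cl)[j]
      e1 <- GenomicRanges::end(cl)[j]
      st <- sample(s1:(e1 - L + 1L), 1L)          # 1-based on contig
      ctg <- as.character(GenomicRanges::seqnames(cl))[j]
      minus <- stats::runif(1L) < 0.5
      if (minus)
        emit(NA, "A", ids[j], "cluster", "antisense", st + L - 2L, L, NA,
             gseq[[ctg]])
      else
        emit(NA, "A", ids[j], "cluster", "sense", st - 1L, L, NA, gseq[[ctg]])
    }
  }

  if (nBg > 0L) {
    famIdx <- sample(length(fams), nBg, replace = TRUE, prob = fw)
    for (i in famIdx) {
      fam <- fams[i]
      L <- .truncNormLen(1L, params$bg_length_mean, params$bg_length_sd,
                         18L, 22L)
      gkey <- fixGenome(fam, pickGenome(1L))
      axis <- axisSeq(fam, gkey)
      anti <- stats::runif(1L) < af[fam]
      if (anti) {
        fp <- sample((L - 1L):(nchar(axis) - 1L), 1L)
        emit(fam, gkey, NA, "background", "antisense", fp, L, NA, axis)
      } else {
        fp <- sample(0:(nchar(axis) - L), 1L)
        emit(fam, gkey, NA, "background", "sense", fp, L, NA, axis)
      }
    }
  }

  keep <- seq_len(rid)
  ids_out <- sprintf("%s_r%06d", libraryId, keep)
  seqs_out <- raw_v[keep]
  rc <- which(str_v[keep] == "antisense")
  if (length(rc)) seqs_out[rc] <- .revcomp(seqs_out[rc])
  truth <- data.frame(read_id = ids_out, family = fam_v[keep],
                      genome = gen_v[keep], cluster = clu_v[keep],
                      class = cls_v[keep], strand = str_v[keep],
                      five_prime = fp_v[keep], length = len_v[keep],
                      pair_id = pair_v[keep])
  reads <- data.frame(read_id = ids_out, seq = seqs_out)
  list(reads = reads, truth = truth, resampled = resampled)
}

#' Simulate mRNA count tables with planted fold changes
#'
#' Per-family counts are drawn negative-binomially (dispersion 0 gives
#' the Poisson limit) with a log-uniform base mean per family; both
#' parents share a family's base mean, and the hybrid mean is the
#' parental average times `2^planted_log2fc`. Means scale with the
#' configured library sizes.
#'
#' @param config A [simConfig()].
#' @param families Optional [TEFamilySet-class]; defaults to the family
#'   names implied by `config`.
#' @return A list with `counts` (matrix families x libraries),
#'   `librarySizes`, and `truth` (data.frame `family`, `base_mean`,
#'   `planted_log2fc`, `derepressed` label for plantings >= 1).
#' @export
simulateMRNACounts <- function(config, families = NULL) {
  .seedFor(config, 30L)
  fams <- if (!is.null(families)) familyNames(families) else
    sprintf("TE%02d", seq_len(config$n_families))
  m <- config$mrna
  mu <- exp(stats::runif(length(fams), log(m$base_mean_range[1]),
                         log(m$base_mean_range[2])))
  lfc <- stats::setNames(rep(0, length(fams)), fams)
  pl <- m$planted_log2fc
  lfc[names(pl)[names(pl) %in% fams]] <- pl[names(pl) %in% fams]
  libs <- m$library_sizes
  sc <- libs / 1e6
  draw <- function(mean) {
    if (m$dispersion <= 0) stats::rpois(length(mean), mean)
    else stats::rnbinom(length(mean), mu = mean, size = 1 / m$dispersion)
  }
  cA <- draw(mu * sc[["parentA"]])
  cB <- draw(mu * sc[["parentB"]])
  cH <- draw((mu * sc[["parentA"]] + mu * sc[["parentB"]]) / 2 * 2^lfc)
  counts <- cbind(parentA = cA, parentB = cB, hybrid = cH)
  rownames(counts) <- fams
  list(counts = counts, librarySizes = libs,
       truth = data.frame(family = fams, base_mean = mu,
                          planted_log2fc = as.numeric(lfc),
                          derepressed = as.numeric(lfc) >= 1))
}

#' Simulate mRNA reads from the parental genomes
#'
#' Emits sense-strand TE-derived mRNA reads for the origin-partition
#' analysis: parents draw from their own genome's copies, the hybrid
#' from both genomes equally, with per-family totals proportional to the
#' library's expected expression (`counts` column if given, else the
#' family abundance weights).
#'
#' @param config A [simConfig()].
#' @param families A [TEFamilySet-class].
#' @param genomes Output of [simulateParentalGenomes()].
#' @param libraryId One of the mRNA library names.
#' @param nReads Number of reads to emit.
#' @param expected Optional named per-family expected expression.
#' @return list(reads, truth) as in [simulateSmallRNALibrary()].
#' @export
simulateMRNAReads <- function(config, families, genomes,
                              libraryId = "hybrid", nReads = 10000L,
                              expected = NULL) {
  .seedFor(config, 40L + nchar(libraryId))
  fams <- familyNames(families)
  w <- if (!is.null(expected)) expected[fams] else
    familyInfo(families)$abundance_weight
  w[is.na(w)] <- 0
  gmode <- switch(libraryId, parentA = "A", parentB = "B", "both")
  L <- config$mrna$read_length
  hasCopy <- with(genomes$copies, table(factor(family, levels = fams),
                                        factor(genome, levels = c("A", "B"))))
  fam <- fams[sample(length(fams), nReads, replace = TRUE, prob = w)]
  g <- if (gmode == "both") sample(c("A", "B"), nReads, replace = TRUE) else
    rep(gmode, nReads)
  # reroute reads of families absent from the drawn genome
  miss <- hasCopy[cbind(fam, g)] == 0L
  other <- ifelse(g == "A", "B", "A")
  g[miss] <- ifelse(hasCopy[cbind(fam[miss], other[miss])] > 0L,
                    other[miss], NA)
  keep <- !is.na(g)
  fam <- fam[keep]; g <- g[keep]
  axis <- ifelse(g == "A", genomes$alleles$A[fam], genomes$alleles$B[fam])
  keep2 <- nchar(axis) >= L
  fam <- fam[keep2]; g <- g[keep2]; axis <- axis[keep2]
  fp <- floor(stats::runif(length(axis)) * (nchar(axis) - L + 1))
  ids <- sprintf("%s_m%06d", libraryId, seq_along(fam))
  list(reads = data.frame(read_id = ids,
                          seq = substr(axis, fp + 1L, fp + L)),
       truth = data.frame(read_id = ids, family = fam, genome = g,
                          five_prime = as.integer(fp), length = L))
}
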