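#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom Biostrings DNAStringSet width
NULL

.TE_CLASSES <- c("LTR", "non_LTR", "TIR")
.TISSUES <- c("germline", "somatic", "intermediate", "unknown")
.DEP_GROUPS <- c("I", "II", "III", "unknown")
.PRESENCE <- c("both_genomes", "mel_only", "neither", "unknown")

#' TEFamilySet: transposable-element family consensus library
#'
#' Holds one consensus sequence per TE family together with the family
#' annotations used throughout the analysis: structural class (LTR,
#' non-LTR retrotransposon, or terminal-inverted-repeat DNA element), the
#' tissue whose piRNA pathway regulates the family (germline vs somatic),
#' the Aub/Ago3 dependency group of its piRNA production, whether the
#' family is a candidate for recent horizontal transfer between species,
#' and whether full-length copies are present in both parental genomes,
#' only the annotated (maternal) genome, or neither.
#'
#' @slot consensus A [Biostrings::DNAStringSet] of consensus sequences,
#'   one per family, named by family; alphabet restricted to ACGTN and
#'   each at least 50 nt.
#' @slot info A [S4Vectors::DataFrame] with one row per family and columns
#'   `te_class`, `tissue`, `dependency_group`, `ht_candidate`,
#'   `full_length_presence`.
#'
#' @seealso [TEFamilySet()] for construction, [consensusSeqs()],
#'   [familyInfo()], [familyNames()] for access.
#' @export
setClass("TEFamilySet",
  representation(consensus = "DNAStringSet", info = "DataFrame"))

setValidity("TEFamilySet", function(object) {
  msg <- character()
  nm <- names(object@consensus)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "every consensus sequence must be named by its family")
  if (anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicate family name(s): %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(Biostrings::width(object@consensus) < 50))
    msg <- c(msg, "consensus sequences must be at least 50 nt")
  bad <- grepl("[^ACGTN]", as.character(object@consensus))
  if (any(bad))
    msg <- c(msg, sprintf("non-ACGTN characters in consensus of: %s",
                          paste(nm[bad], collapse = ", ")))
  if (nrow(object@info) != length(object@consensus))
    msg <- c(msg, "info must have one row per family")
  need <- c("te_class", "tissue", "dependency_group", "ht_candidate",
            "full_length_presence")
  miss <- setdiff(need, colnames(object@info))
  if (length(miss))
    msg <- c(msg, sprintf("info lacks column(s): %s", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a TEFamilySet
#'
#' @param consensus Named character vector or [Biostrings::DNAStringSet]
#'   of consensus sequences (uppercased on input).
#' @param te_class,tissue,dependency_group Per-family annotation vectors,
#'   recycled if length 1. Allowed values: `te_class` in
#'   `c("LTR","non_LTR","TIR")`; `tissue` in
#'   `c("germline","somatic","intermediate","unknown")`;
#'   `dependency_group` in `c("I","II","III","unknown")`.
#' @param ht_candidate Logical, candidate for recent horizontal transfer.
#' @param full_length_presence One of
#'   `c("both_genomes","mel_only","neither","unknown")`.
#' @return A [TEFamilySet-class] object.
#' @examples
#' fam <- TEFamilySet(c(jockey = paste(rep("ACGT", 30), collapse = "")))
#' familyNames(fam)
#' @export
TEFamilySet <- function(consensus,
                        te_class = "unknown_class_default",
                        tissue = "unknown",
                        dependency_group = "unknown",
                        ht_candidate = FALSE,
                        full_length_presence = "unknown") {
  if (is.character(consensus))
    consensus <- Biostrings::DNAStringSet(toupper(consensus))
  n <- length(consensus)
  if (identical(te_class, "unknown_class_default")) te_class <- rep("LTR", n)
  if (n == 0L) {
    info <- S4Vectors::DataFrame(
      te_class = character(), tissue = character(),
      dependency_group = character(), ht_candidate = logical(),
      full_length_presence = character())
    return(new("TEFamilySet", consensus = consensus, info = info))
  }
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  te_class <- match.arg(rec(te_class), .TE_CLASSES, several.ok = TRUE)
  tissue <- match.arg(rec(tissue), .TISSUES, several.ok = TRUE)
  dependency_group <- match.arg(rec(dependency_group), .DEP_GROUPS, several.ok = TRUE)
  full_length_presence <- match.arg(rec(full_length_presence), .PRESENCE,
                                    several.ok = TRUE)
  info <- S4Vectors::DataFrame(
    te_class = te_class, tissue = tissue,
    dependency_group = dependency_group,
    ht_candidate = rec(as.logical(ht_candidate)),
    full_length_presence = full_length_presence,
    row.names = names(consensus))
  new("TEFamilySet", consensus = consensus, info = info)
}

#' GenomeAnnotation: one parental genome with TE and cluster annotation
#'
#' A parental genome sequence together with the 0-based half-open
#' intervals of its annotated TE insertions (each carrying the family it
#' derives from and its orientation) and of its piRNA clusters, the
#' TE-dense loci whose precursor transcripts feed mature piRNA
#' production.
#'
#' @slot genomeId Identifier, e.g. `"parentA"`.
#' @slot seq [Biostrings::DNAStringSet] of contigs.
#' @slot insertions [GenomicRanges::GRanges] with mcol `family`.
#' @slot clusters [GenomicRanges::GRanges] with mcol `cluster_id` (unique).
#'
#' @seealso [GenomeAnnotation()], [teInsertions()], [piClusters()],
#'   [genomeSeqs()].
#' @export
setClass("GenomeAnnotation",
  representation(genomeId = "character", seq = "DNAStringSet",
                 insertions = "GRanges", clusters = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  lens <- stats::setNames(Biostrings::width(object@seq), names(object@seq))
  chk <- function(gr, what) {
    m <- character()
    if (length(gr) == 0L) return(m)
    sq <- as.character(GenomicRanges::seqnames(gr))
    if (!all(sq %in% names(lens)))
      m <- c(m, sprintf("%s on unknown contig(s): %s", what,
                        paste(setdiff(unique(sq), names(lens)), collapse = ", ")))
    else if (any(GenomicRanges::end(gr) > lens[sq]))
      m <- c(m, sprintf("%s extend beyond contig bounds", what))
    if (any(GenomicRanges::width(gr) < 1L))
      m <- c(m, sprintf("%s with start >= end (empty interval)", what))
    m
  }
  msg <- c(msg, chk(object@insertions, "insertions"), chk(object@clusters, "clusters"))
  if (length(object@insertions) && is.null(object@insertions$family))
    msg <- c(msg, "insertions must carry a 'family' mcol")
  if (length(object@clusters)) {
    if (is.null(object@clusters$cluster_id))
      msg <- c(msg, "clusters must carry a 'cluster_id' mcol")
    else if (anyDuplicated(object@clusters$cluster_id))
      msg <- c(msg, "cluster ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' Intervals are supplied in 0-based half-open coordinates (BED
#' convention) and stored internally as GRanges (1-based closed); all
#' exported coordinate output converts back at the boundary.
#'
#' @param genomeId Identifier for the genome, e.g. `"parentA"`.
#' @param seq Named character vector or [Biostrings::DNAStringSet] of contigs.
#' @param insertions `data.frame` with columns `contig`, `start`, `end`
#'   (0-based half-open), `family`, `strand`; or a ready-made GRanges.
#' @param clusters `data.frame` with columns `contig`, `start`, `end`,
#'   `cluster_id`; or a GRanges.
#' @return A [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(genomeId, seq,
                             insertions = NULL, clusters = NULL) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(toupper(seq))
  asGR <- function(df, idcol) {
    if (is.null(df))
      return(GenomicRanges::GRanges())
    if (methods::is(df, "GRanges")) return(df)
    stopifnot(all(c("contig", "start", "end") %in% names(df)))
    if (any(df$start >= df$end))
      stop("interval with start >= end in ", idcol, " table", call. = FALSE)
    gr <- GenomicRanges::GRanges(
      seqnames = df$contig,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = if ("strand" %in% names(df)) df$strand else "*")
    extra <- setdiff(names(df), c("contig", "start", "end", "strand"))
    for (cn in extra) S4Vectors::mcols(gr)[[cn]] <- df[[cn]]
    gr
  }
  new("GenomeAnnotation", genomeId = genomeId, seq = seq,
      insertions = asGR(insertions, "insertions"),
      clusters = asGR(clusters, "clusters"))
}

#' StatResult: a named test statistic with its provenance
#'
#' Container for the comparative-statistics layer: the statistic's name
#' and value, degrees of freedom where defined, an asymptotic or exact
#' p-value or an empirical permutation threshold, the sample size, and a
#' free-form details list recording the exact inputs used.
#'
#' @slot statistic Name of the statistic (e.g. `"G"`, `"X2"`, `"t"`).
#' @slot value Numeric value of the statistic.
#' @slot df Degrees of freedom (`NA` when undefined).
#' @slot p p-value (`NA` for purely empirical results).
#' @slot n Problem size (number of observations/cells).
#' @slot details List of inputs and auxiliary output.
#' @export
setClass("StatResult",
  representation(statistic = "character", value = "numeric", df = "numeric",
                 p = "numeric", n = "numeric", details = "list"),
  prototype(df = NA_real_, p = NA_real_, n = NA_real_, details = list()))

setValidity("StatResult", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    "p must lie in [0, 1]" else TRUE
})

statResult <- function(statistic, value, df = NA_real_, p = NA_real_,
                       n = NA_real_, details = list()) {
  new("StatResult", statistic = statistic, value = as.numeric(value),
      df = as.numeric(df), p = as.numeric(p), n = as.numeric(n),
      details = details)
}
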