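#' @include AllClasses.R
NULL

#' Accessors for TEFamilySet and GenomeAnnotation
#'
#' @param x A [TEFamilySet-class] or [GenomeAnnotation-class] object.
#' @return `consensusSeqs()` the DNAStringSet of consensus sequences;
#'   `familyInfo()` the per-family annotation DataFrame; `familyNames()`
#'   the family identifiers; `genomeSeqs()` the contig DNAStringSet;
#'   `teInsertions()` / `piClusters()` the annotation GRanges;
#'   `genomeId()` the genome identifier.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("consensusSeqs", function(x) standardGeneric("consensusSeqs"))
#' @rdname accessors
#' @export
setGeneric("familyInfo", function(x) standardGeneric("familyInfo"))
#' @rdname accessors
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))
#' @rdname accessors
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))
#' @rdname accessors
#' @export
setGeneric("teInsertions", function(x) standardGeneric("teInsertions"))
#' @rdname accessors
#' @export
setGeneric("piClusters", function(x) standardGeneric("piClusters"))
#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname accessors
#' @export
setMethod("consensusSeqs", "TEFamilySet", function(x) x@consensus)
#' @rdname accessors
#' @export
setMethod("familyInfo", "TEFamilySet", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("familyNames", "TEFamilySet", function(x) names(x@consensus))
#' @rdname accessors
#' @export
setMethod("genomeSeqs", "GenomeAnnotation", function(x) x@seq)
#' @rdname accessors
#' @export
setMethod("teInsertions", "GenomeAnnotation", function(x) x@insertions)
#' @rdname accessors
#' @export
setMethod("piClusters", "GenomeAnnotation", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)

setMethod("length", "TEFamilySet", function(x) length(x@consensus))

setMethod("show", "TEFamilySet", function(object) {
  cat("TEFamilySet with", length(object@consensus), "families\n")
  cat("  consensus length:", paste(range(Biostrings::width(object@consensus)),
                                   collapse = "-"), "nt\n")
  tab <- table(object@info$te_class)
  cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation", object@genomeId, "\n")
  cat(" ", length(object@seq), "contig(s),",
      sum(Biostrings::width(object@seq)), "bp total\n")
  cat(" ", length(object@insertions), "TE insertions,",
      length(object@clusters), "piRNA clusters\n")
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult: %s = %.6g", object@statistic, object@value))
  if (!is.na(object@df)) cat(sprintf(", df = %g", object@df))
  if (!is.na(object@p)) cat(sprintf(", p = %.4g", object@p))
  if (!is.na(object@n)) cat(sprintf(", n = %g", object@n))
  cat("\n")
})
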