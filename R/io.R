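#' Read a FASTA file of nucleotide sequences
#'
#' Thin validating wrapper around [Biostrings::readDNAStringSet()]:
#' sequences are uppercased, duplicate identifiers are rejected, and any
#' record containing characters outside ACGTN raises a format error
#' naming the offending record. Coordinates elsewhere in the package are
#' 0-based half-open; FASTA's 1-based convention is converted at this
#' boundary only.
#'
#' @param path Path to a FASTA file (gzip accepted).
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # Biostrings silently drops invalid letters; enforce the ACGTN alphabet
  # up front so the offending record can be named
  lines <- readLines(gzfile(path))
  hdr <- startsWith(lines, ">")
  bad <- !hdr & grepl("[^ACGTNacgtn]", lines)
  if (any(bad)) {
    rec <- sub("^>", "", sub("\\s.*$", "",
                             lines[hdr][findInterval(which(bad)[1L], which(hdr))]))
    stop("non-ACGTN characters in record: ", rec, call. = FALSE)
  }
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e)
                     stop("malformed FASTA in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
  # uppercase without round-tripping ambiguity codes
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  seqs
}

#' Read a small-RNA FASTQ file
#'
#' Reads 4-line FASTQ records (gzip accepted, transparently); qualities
#' are ignored, as small-RNA analyses here operate on sequence identity
#' only. A truncated file raises a format error giving the index of the
#' incomplete record.
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `read_id` and `seq`.
#' @export
readSmallRNAFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at record ", length(lines) %/% 4L + 1L,
         " in ", path, call. = FALSE)
  n <- length(lines) %/% 4L
  if (n == 0L) return(data.frame(read_id = character(), seq = character()))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  badh <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(badh))
    stop("malformed FASTQ record at record ", badh[1L], " in ", path,
         call. = FALSE)
  data.frame(read_id = sub("\\s.*$", "", sub("^@", "", hdr)), seq = sq)
}

#' Write reads to FASTQ
#'
#' Emits constant maximum-confidence qualities ("I"); the package never
#' consumes quality values.
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param path Output path (".gz" suffix triggers gzip).
#' @return `path`, invisibly.
#' @export
writeSmallRNAFastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read BED3+ intervals
#'
#' Reads a BED file via [rtracklayer::import()] and validates the
#' half-open interval contract: zero- or negative-width intervals are a
#' format error. Overlapping intervals are retained as given (no
#' merging).
#'
#' @param path Path to a BED3+ file.
#' @return A [GenomicRanges::GRanges]; the BED name column, if present,
#'   is kept in mcol `name`.
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED in ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  if (length(gr) && any(GenomicRanges::width(gr) < 1L))
    stop("BED interval with start >= end at line ",
         which(GenomicRanges::width(gr) < 1L)[1L], " in ", path, call. = FALSE)
  gr
}

#' Write intervals as BED
#'
#' @param gr A GRanges; mcol `name` or `cluster_id` or `family` (first
#'   found) becomes the BED name column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedIntervals <- function(gr, path) {
  nm <- NULL
  for (cand in c("name", "cluster_id", "family"))
    if (!is.null(S4Vectors::mcols(gr)[[cand]])) { nm <- S4Vectors::mcols(gr)[[cand]]; break }
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(nm)) "." else nm,
    score = 0L,
    strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "+"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a TSV table with header row
#'
#' All tabular side data (family metadata, Ks values, fold-change
#' vectors, count tables) travel as TSV with a header row.
#'
#' @param path File path.
#' @param x data.frame to write.
#' @return `readTsvTable()` a data.frame; `writeTsvTable()` `path`,
#'   invisibly.
#' @export
readTsvTable <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname readTsvTable
#' @export
writeTsvTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
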