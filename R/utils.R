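# Internal helpers shared across modules.

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All simulators route their randomness through
# this so seeds are explicit parameters with no global state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Cheap genome fingerprint: contig names, widths and base composition.
# Enough to detect that a FragmentMap is being annotated against a
# different genome than it was digested from.
.genome_checksum <- function(genome) {
  seqs <- sequences(genome)
  if (length(seqs) == 0L) return("empty")
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  paste(sprintf("%s:%d:%s:%d", names(seqs), Biostrings::width(seqs),
                apply(freq, 1L, paste, collapse = ","),
                round(origins(genome))),
        collapse = ";")
}

#' Write sequences as FASTQ with constant quality
#'
#' Minimal FASTQ emitter for simulated reads (constant quality `I`; the
#' simulators make no claim to quality-score realism).
#'
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(seqs, path) {
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- sprintf("read%06d", seq_along(seqs))
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(seqs), function(w)
    strrep("I", w), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ file.
#' @return A named [Biostrings::DNAStringSet] (qualities are dropped; the
#'   4C pipeline works on sequence only).
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

# ---- SAM plumbing -----------------------------------------------------------
# SAM records travel internally as a data.frame with the 11 mandatory
# columns. Writing is a plain text emitter (minimal @SQ header); reading
# goes through Rsamtools (asBam + scanBam) so the parsing is not hand-rolled.

.sam_columns <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                  "rnext", "pnext", "tlen", "seq", "qual")

#' Write SAM records
#'
#' Emits a minimal valid SAM file: `@HD`, one `@SQ` line per contig, then
#' the records. Declared contig lengths are origin + contig length so that
#' origin-shifted 1-based positions are in range.
#'
#' @param records `data.frame` with the 11 mandatory SAM columns
#'   (`qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`,
#'   `tlen`, `seq`, `qual`).
#' @param seqLengths Named numeric vector of declared contig lengths.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(records, seqLengths, path) {
  stopifnot(all(.sam_columns %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths),
                     as.integer(seqLengths)), con)
  if (nrow(records))
    writeLines(do.call(paste, c(records[.sam_columns], sep = "\t")), con)
  invisible(path)
}

# Read a SAM file into the internal record data.frame via Rsamtools.
.read_sam <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "mrnm", "mpos",
                                        "isize", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(qname = x$qname, flag = x$flag,
             rname = as.character(x$rname), pos = x$pos, mapq = x$mapq,
             cigar = x$cigar, rnext = as.character(x$mrnm), pnext = x$mpos,
             tlen = x$isize, seq = as.character(x$seq),
             stringsAsFactors = FALSE)
}

# Reference-space width of a CIGAR string.
.cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}
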