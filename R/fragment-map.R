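#' In-silico digestion with the primary restriction enzyme
#'
#' Partitions each contig into primary restriction fragments. Cut positions
#' are `occurrence start + cutOffset` on the forward strand (both default
#' enzymes are palindromic, so one strand suffices); fragments are the
#' intervals between consecutive cuts plus the contig ends. Zero-length
#' fragments (a cut at position 0 or the contig end, or adjacent cuts) are
#' suppressed. Fragment ids are consecutive in coordinate order across the
#' whole map.
#'
#' @param genome A [ToyGenome-class], or the path to a FASTA file
#'   (origins 0).
#' @param primary Primary [RestrictionEnzyme-class] (default [DpnII()]).
#' @return A [FragmentMap-class] without secondary annotation.
#' @examples
#' g <- toyGenomeFromSeq("AAGATCTTTTGTACTTGATCAA")
#' fragmentTable(digest(g))  # fragments [0,2), [2,16), [16,22)
#' @export
digest <- function(genome, primary = DpnII()) {
  genome <- .as_toy_genome(genome)
  seqs <- sequences(genome)
  if (length(seqs) == 0L) stop("cannot digest an empty genome")
  bad <- Biostrings::alphabetFrequency(seqs)
  nonacgtn <- rowSums(bad[, !colnames(bad) %in% c("A", "C", "G", "T", "N"),
                          drop = FALSE])
  if (any(nonacgtn > 0)) {
    i <- which(nonacgtn > 0)[1]
    ch <- strsplit(as.character(seqs[[i]]), "")[[1]]
    p <- which(!ch %in% c("A", "C", "G", "T", "N"))[1]
    stop(sprintf("contig %s has a non-ACGTN character at position %d",
                 names(seqs)[i], p - 1L))
  }
  rows <- list()
  for (i in seq_along(seqs)) {
    L <- Biostrings::width(seqs)[i]
    occ <- Biostrings::start(Biostrings::matchPattern(primary@recognition,
                                                      seqs[[i]])) - 1L
    cuts <- sort(unique(c(0L, occ + primary@cutOffset, L)))
    cuts <- cuts[cuts >= 0L & cuts <= L]
    s0 <- cuts[-length(cuts)]; e0 <- cuts[-1]
    keep <- e0 > s0  # empty-interval suppression
    rows[[i]] <- data.frame(contig = names(seqs)[i], start = s0[keep],
                            end = e0[keep],
                            origin = unname(origins(genome)[i]),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  gr <- GRanges(tab$contig,
                IRanges(tab$origin + tab$start + 1, tab$origin + tab$end))
  mcols(gr)$id <- seq_along(gr)
  mcols(gr)$blind <- rep(NA, length(gr))
  mcols(gr)$firstCut <- rep(NA_real_, length(gr))
  mcols(gr)$lastCut <- rep(NA_real_, length(gr))
  new("FragmentMap", fragments = gr, primary = primary, secondary = NULL,
      checksum = .genome_checksum(genome))
}

#' Annotate a fragment map with secondary restriction cuts
#'
#' For each primary fragment, the nearest secondary cut strictly inside the
#' fragment defines the two end regions `[start, firstCut)` and
#' `[lastCut, end)`; a fragment with no internal secondary cut is flagged
#' `blind` (its end regions collapse to the whole fragment). Annotation is
#' idempotent.
#'
#' @param map A [FragmentMap-class] produced by [digest()] on `genome`.
#' @param genome The same genome (checksum-verified).
#' @param secondary Secondary [RestrictionEnzyme-class] (default [Csp6I()]).
#' @return The annotated [FragmentMap-class].
#' @export
annotateSecondary <- function(map, genome, secondary = Csp6I()) {
  genome <- .as_toy_genome(genome)
  if (!identical(map@checksum, .genome_checksum(genome)))
    stop("genome does not match the one this FragmentMap was digested from (checksum mismatch)")
  gr <- map@fragments
  seqs <- sequences(genome)
  if (length(gr)) {
    orig <- origins(genome)
    blind <- logical(length(gr)); fc <- rep(NA_real_, length(gr))
    lc <- rep(NA_real_, length(gr))
    for (ct in unique(as.character(seqnames(gr)))) {
      occ <- Biostrings::start(Biostrings::matchPattern(
        secondary@recognition, seqs[[ct]])) - 1L
      cuts <- orig[ct] + occ + secondary@cutOffset  # origin-shifted 0-based
      sel <- which(as.character(seqnames(gr)) == ct)
      for (j in sel) {
        s0 <- start(gr)[j] - 1; e0 <- end(gr)[j]
        inside <- cuts[cuts > s0 & cuts < e0]
        if (length(inside)) {
          blind[j] <- FALSE; fc[j] <- min(inside); lc[j] <- max(inside)
        } else blind[j] <- TRUE
      }
    }
    mcols(gr)$blind <- blind
    mcols(gr)$firstCut <- fc
    mcols(gr)$lastCut <- lc
  }
  initialize(map, fragments = gr, secondary = secondary)
}

#' Catalog of fragment-end k-mers
#'
#' Reads the k-mer at each primary fragment boundary, inward: for
#' `side = "left"` the k-mer starts at the fragment start on the forward
#' strand; for `side = "right"` it is the reverse complement of the last
#' `k` bases of the fragment. The catalog backs the toy exact mapper used
#' to place trimmed 4C reads on fragment ends.
#'
#' @param map An annotated or unannotated [FragmentMap-class].
#' @param genome The genome the map was digested from.
#' @param k k-mer length in bp (> 0). Fragments shorter than `k` are
#'   skipped with a warning.
#' @param includeBlind Include blind fragments (default `TRUE`).
#' @return `data.frame` with columns `fragmentId`, `side`, `strand`, `kmer`.
#' @export
endCatalog <- function(map, genome, k, includeBlind = TRUE) {
  if (k <= 0) stop("k must be > 0")
  genome <- .as_toy_genome(genome)
  gr <- map@fragments
  if (!includeBlind && !all(is.na(mcols(gr)$blind)))
    gr <- gr[!mcols(gr)$blind]
  short <- width(gr) < k
  if (any(short)) {
    warning(sprintf("%d fragment(s) shorter than k = %d skipped from the end catalog",
                    sum(short), k))
    gr <- gr[!short]
  }
  if (length(gr) == 0L)
    return(data.frame(fragmentId = integer(0), side = character(0),
                      strand = character(0), kmer = character(0),
                      stringsAsFactors = FALSE))
  seqs <- sequences(genome)
  orig <- origins(genome)
  ct <- as.character(seqnames(gr))
  ls0 <- start(gr) - 1 - orig[ct]           # local 0-based fragment start
  le0 <- end(gr) - orig[ct]                 # local 0-based exclusive end
  left <- as.character(Biostrings::subseq(seqs[ct], start = ls0 + 1,
                                          end = ls0 + k))
  rightFwd <- Biostrings::subseq(seqs[ct], start = le0 - k + 1, end = le0)
  right <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rightFwd)))
  data.frame(
    fragmentId = rep(mcols(gr)$id, 2L),
    side = rep(c("left", "right"), each = length(gr)),
    strand = rep(c("+", "-"), each = length(gr)),
    kmer = c(left, right), stringsAsFactors = FALSE)
}

#' Locate the fragment covering a position
#'
#' @param map A [FragmentMap-class].
#' @param contig Contig name.
#' @param position 0-based origin-shifted position.
#' @return The fragment id, or `NA` if uncovered.
#' @export
fragmentAt <- function(map, contig, position) {
  gr <- map@fragments
  hit <- which(as.character(seqnames(gr)) == contig &
               start(gr) - 1 <= position & end(gr) > position)
  if (length(hit) == 0L) return(NA_integer_)
  mcols(gr)$id[hit[1]]
}

#' Export a fragment map as BED and TSV
#'
#' BED uses `name = fragment id` and `score = blind flag` (1 = blind);
#' the TSV carries the end-region columns.
#'
#' @param map A [FragmentMap-class].
#' @param prefix Output prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @return Files written, invisibly.
#' @export
exportFragmentMap <- function(map, prefix) {
  tab <- fragmentTable(map)
  bed <- paste0(prefix, ".bed")
  blind_score <- ifelse(is.na(tab$blind), 0L, as.integer(tab$blind))
  writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t.", tab$contig,
                     as.integer(tab$start), as.integer(tab$end),
                     tab$id, blind_score), bed)
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed, tsv = tsv))
}

#' Wrap a plain sequence (or FASTA file) as a ToyGenome
#'
#' Convenience constructor for worked examples and tests.
#'
#' @param x A character vector of sequences (named or not), or a FASTA path.
#' @param origin Numeric origins (recycled; default 0).
#' @return A [ToyGenome-class].
#' @export
toyGenomeFromSeq <- function(x, origin = 0) {
  if (length(x) == 1L && file.exists(x) && grepl("\\.(fa|fasta|fna)$", x))
    x <- as.character(Biostrings::readDNAStringSet(x))
  if (is.null(names(x))) names(x) <- sprintf("chrT%d", seq_along(x))
  x <- toupper(x)
  for (i in seq_along(x)) {
    ch <- strsplit(x[[i]], "")[[1]]
    bad <- which(!ch %in% c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop(sprintf("contig %s has a non-ACGTN character at position %d",
                   names(x)[i], bad[1] - 1L))
  }
  origin <- rep_len(origin, length(x))
  names(origin) <- names(x)
  new("ToyGenome", sequences = Biostrings::DNAStringSet(x), origin = origin,
      ctcfSites = GRanges(), modules = GRanges())
}

.as_toy_genome <- function(genome) {
  if (is(genome, "ToyGenome")) return(genome)
  if (is.character(genome)) return(toyGenomeFromSeq(genome))
  stop("genome must be a ToyGenome or a FASTA path")
}
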