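#' Construct a derivative chromosome from explicit segments
#'
#' @param name Derivative name.
#' @param segments `data.frame` with columns `contig`, `start`, `end`
#'   (0-based half-open, origin-shifted) and `strand` (`+`/`-`), in
#'   derivative order.
#' @return A [DerivativeChromosome-class].
#' @examples
#' derivativeChromosome("der", data.frame(
#'   contig = c("c1", "c2"), start = c(0, 50), end = c(100, 150),
#'   strand = "+"))
#' @export
derivativeChromosome <- function(name, segments) {
  seg <- data.frame(contig = as.character(segments$contig),
                    start = as.numeric(segments$start),
                    end = as.numeric(segments$end),
                    strand = as.character(segments$strand),
                    stringsAsFactors = FALSE, row.names = NULL)
  new("DerivativeChromosome", name = name, segments = seg)
}

#' Build the derivative chromosome implied by a breakpoint
#'
#' Emits the two-segment derivative joining the retained flank of each
#' partner: with sides `left-of`/`right-of` (the typical reciprocal
#' translocation product) the result is
#' `[contigA: startA..posA, +] + [contigB: posB..endB, +]`. Segment
#' orientation is a user input, never inferred. With `reciprocal = TRUE`
#' both reciprocal products are returned.
#'
#' @param bp A [Breakpoint-class] (0-based internal coordinates).
#' @param genome A [ToyGenome-class] supplying contig extents, or a named
#'   list/vector of `c(start, end)` extents per contig (0-based half-open,
#'   origin-shifted).
#' @param name Derivative name (default `der`).
#' @param orientation Length-2 strand vector for the two segments
#'   (default `c("+", "+")`).
#' @param reciprocal Also emit the reciprocal product.
#' @return A [DerivativeChromosome-class], or a list of two when
#'   `reciprocal = TRUE`.
#' @export
buildDerivative <- function(bp, genome, name = "der",
                            orientation = c("+", "+"), reciprocal = FALSE) {
  ext <- .contig_extents(genome)
  exA <- ext[[bp@contigA]]; exB <- ext[[bp@contigB]]
  if (is.null(exA) || is.null(exB))
    stop("breakpoint contigs not found in the genome")
  if (bp@posA <= exA[1] || bp@posA >= exA[2] ||
      bp@posB <= exB[1] || bp@posB >= exB[2])
    stop("breakpoint position out of contig bounds or produces a degenerate segment")
  segA <- if (bp@sideA == "left-of") c(exA[1], bp@posA) else c(bp@posA, exA[2])
  segB <- if (bp@sideB == "left-of") c(exB[1], bp@posB) else c(bp@posB, exB[2])
  der <- derivativeChromosome(name, data.frame(
    contig = c(bp@contigA, bp@contigB),
    start = c(segA[1], segB[1]), end = c(segA[2], segB[2]),
    strand = orientation, stringsAsFactors = FALSE))
  if (!reciprocal) return(der)
  segA2 <- if (bp@sideA == "left-of") c(bp@posA, exA[2]) else c(exA[1], bp@posA)
  segB2 <- if (bp@sideB == "left-of") c(bp@posB, exB[2]) else c(exB[1], bp@posB)
  der2 <- derivativeChromosome(paste0(name, "_reciprocal"), data.frame(
    contig = c(bp@contigB, bp@contigA),
    start = c(segB2[1], segA2[1]), end = c(segB2[2], segA2[2]),
    strand = orientation, stringsAsFactors = FALSE))
  list(der, der2)
}

.contig_extents <- function(genome) {
  if (is(genome, "ToyGenome")) {
    o <- origins(genome); w <- Biostrings::width(sequences(genome))
    out <- lapply(seq_along(o), function(i) c(o[i], o[i] + w[i]))
    names(out) <- names(o)
    return(out)
  }
  as.list(genome)
}

.der_offsets <- function(der) {
  w <- der@segments$end - der@segments$start
  cumsum(c(0, w[-length(w)]))
}

#' Derivative chromosome length in bp
#' @param der A [DerivativeChromosome-class].
#' @export
derivativeLength <- function(der) {
  sum(der@segments$end - der@segments$start)
}

#' Map native positions onto a derivative chromosome
#'
#' For `+` segments `derPos = offset + (pos - start)`; for `-` segments
#' `derPos = offset + (end - 1 - pos)`. A position covered by no segment
#' maps to `NA` (a typed not-covered result, not an error). The maps are
#' mutually inverse on covered positions.
#'
#' @param der A [DerivativeChromosome-class].
#' @param contig,pos Native contig(s) and 0-based position(s) (vectorised,
#'   recycled).
#' @return Numeric vector of 0-based derivative positions (`NA` where
#'   uncovered). Positions covered by several segments (possible for
#'   same-contig inversions) take the first covering segment.
#' @export
mapToDerivative <- function(der, contig, pos) {
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n); pos <- rep_len(pos, n)
  seg <- der@segments
  off <- .der_offsets(der)
  out <- rep(NA_real_, n)
  for (i in seq_len(nrow(seg))) {
    hit <- is.na(out) & contig == seg$contig[i] &
      pos >= seg$start[i] & pos < seg$end[i]
    out[hit] <- if (seg$strand[i] == "+") off[i] + (pos[hit] - seg$start[i])
                else off[i] + (seg$end[i] - 1 - pos[hit])
  }
  out
}

#' @rdname mapToDerivative
#' @param derPos 0-based derivative position(s).
#' @return `mapFromDerivative`: `data.frame` with `contig` and `pos`
#'   (`NA` rows where `derPos` is outside the derivative).
#' @export
mapFromDerivative <- function(der, derPos) {
  seg <- der@segments
  off <- .der_offsets(der)
  w <- seg$end - seg$start
  contig <- rep(NA_character_, length(derPos))
  pos <- rep(NA_real_, length(derPos))
  for (i in seq_len(nrow(seg))) {
    hit <- is.na(pos) & derPos >= off[i] & derPos < off[i] + w[i]
    contig[hit] <- seg$contig[i]
    pos[hit] <- if (seg$strand[i] == "+") seg$start[i] + (derPos[hit] - off[i])
                else seg$end[i] - 1 - (derPos[hit] - off[i])
  }
  data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
}

#' Extract the derivative chromosome sequence
#'
#' Concatenates the (reverse-complemented, for `-` strand) segment
#' sequences from the native genome.
#'
#' @param genome A [ToyGenome-class].
#' @param der A [DerivativeChromosome-class].
#' @return A [Biostrings::DNAString].
#' @export
derivativeSequence <- function(genome, der) {
  seqs <- sequences(genome); orig <- origins(genome)
  parts <- lapply(seq_len(nrow(der@segments)), function(i) {
    seg <- der@segments[i, ]
    local <- c(seg$start, seg$end) - orig[seg$contig]
    s <- Biostrings::subseq(seqs[[seg$contig]], local[1] + 1, local[2])
    if (seg$strand == "-") Biostrings::reverseComplement(s) else s
  })
  out <- parts[[1]]
  for (p in parts[-1]) out <- Biostrings::xscat(out, p)
  out
}

#' Read/write a derivative segment table
#'
#' Plain-text 4-column table (`contig start end strand`, 0-based
#' half-open), the interchange format for derivative structures.
#'
#' @param der A [DerivativeChromosome-class].
#' @param path File path.
#' @param name Name for the derivative read from `path`.
#' @return `writeDerivative`: `path` invisibly; `readDerivative`: a
#'   [DerivativeChromosome-class].
#' @export
writeDerivative <- function(der, path) {
  utils::write.table(der@segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDerivative
#' @export
readDerivative <- function(path, name = "der") {
  derivativeChromosome(name, utils::read.table(path, header = TRUE,
                                               sep = "\t",
                                               stringsAsFactors = FALSE))
}
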