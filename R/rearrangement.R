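#' Extract discordant read pairs from paired-end alignments
#'
#' A pair is discordant iff the mates map to different contigs, or to the
#' same contig with an insert larger than `maxConcordantInsert` or in an
#' unexpected relative orientation (anything but forward-reverse with the
#' leftmost mate forward). Pairs with either mate below `minMapq` are
#' dropped and counted.
#'
#' @param sam SAM path or internal record `data.frame` (paired records;
#'   unpaired input is an error).
#' @param maxConcordantInsert Maximum concordant insert size in bp
#'   (default 1000).
#' @param minMapq Minimum mapping quality (default 10).
#' @return List with `pairs` (`data.frame`, one row per discordant pair
#'   with canonically ordered partners A/B) and tallies `nPairs`,
#'   `nLowMapq`, `nConcordant`.
#' @export
findDiscordant <- function(sam, maxConcordantInsert = 1000L, minMapq = 10L) {
  rec <- if (is.character(sam)) .read_sam(sam) else sam
  if (nrow(rec) == 0L)
    return(list(pairs = .empty_pairs(), nPairs = 0L, nLowMapq = 0L,
                nConcordant = 0L))
  if (any(bitwAnd(rec$flag, 1L) == 0L))
    stop("unpaired records in input; the discordant-pair caller needs paired-end data")
  first <- rec[bitwAnd(rec$flag, 64L) > 0L, ]
  second <- rec[bitwAnd(rec$flag, 128L) > 0L, ]
  m <- match(first$qname, second$qname)
  ok <- !is.na(m)
  first <- first[ok, ]; second <- second[m[ok], ]
  lowq <- first$mapq < minMapq | second$mapq < minMapq
  nLow <- sum(lowq)
  first <- first[!lowq, ]; second <- second[!lowq, ]
  n <- nrow(first)
  if (n == 0L)
    return(list(pairs = .empty_pairs(), nPairs = 0L, nLowMapq = nLow,
                nConcordant = 0L))
  w1 <- vapply(first$cigar, .cigar_ref_width, numeric(1), USE.NAMES = FALSE)
  w2 <- vapply(second$cigar, .cigar_ref_width, numeric(1), USE.NAMES = FALSE)
  df <- data.frame(
    qname = first$qname,
    contig1 = first$rname, start1 = first$pos - 1, end1 = first$pos - 1 + w1,
    strand1 = ifelse(bitwAnd(first$flag, 16L) > 0L, "-", "+"),
    contig2 = second$rname, start2 = second$pos - 1,
    end2 = second$pos - 1 + w2,
    strand2 = ifelse(bitwAnd(second$flag, 16L) > 0L, "-", "+"),
    stringsAsFactors = FALSE)
  sameContig <- df$contig1 == df$contig2
  insert <- pmax(df$end1, df$end2) - pmin(df$start1, df$start2)
  leftIsFirst <- df$start1 <= df$start2
  leftStrand <- ifelse(leftIsFirst, df$strand1, df$strand2)
  rightStrand <- ifelse(leftIsFirst, df$strand2, df$strand1)
  properFR <- leftStrand == "+" & rightStrand == "-"
  discordant <- !sameContig | insert > maxConcordantInsert | !properFR
  out <- df[discordant, , drop = FALSE]
  # canonical partner order: lexicographic (contig, start)
  swap <- out$contig1 > out$contig2 |
    (out$contig1 == out$contig2 & out$start1 > out$start2)
  pairs <- data.frame(
    qname = out$qname,
    contigA = ifelse(swap, out$contig2, out$contig1),
    startA = ifelse(swap, out$start2, out$start1),
    endA = ifelse(swap, out$end2, out$end1),
    strandA = ifelse(swap, out$strand2, out$strand1),
    contigB = ifelse(swap, out$contig1, out$contig2),
    startB = ifelse(swap, out$start1, out$start2),
    endB = ifelse(swap, out$end1, out$end2),
    strandB = ifelse(swap, out$strand1, out$strand2),
    stringsAsFactors = FALSE)
  list(pairs = pairs, nPairs = n, nLowMapq = nLow,
       nConcordant = sum(!discordant))
}

.empty_pairs <- function() {
  data.frame(qname = character(0), contigA = character(0),
             startA = numeric(0), endA = numeric(0), strandA = character(0),
             contigB = character(0), startB = numeric(0), endB = numeric(0),
             strandB = character(0), stringsAsFactors = FALSE)
}

#' Cluster discordant pairs into candidate breakpoints
#'
#' Pairs are grouped by ordered contig pair and orientation class, then
#' single-linkage clustered with gap at most `clusterWindow` on both
#' partners. Each cluster with support at least `minSupport` yields a
#' candidate [Breakpoint-class] at interval resolution whose positions are
#' the innermost read edges (forward flank: maximum mate end; reverse
#' flank: minimum mate start). Candidates are sorted by `(contigA, posA)`,
#' ties by support descending; the output is invariant under input
#' shuffling.
#'
#' @param pairs Discordant-pair `data.frame` from [findDiscordant()].
#' @param clusterWindow Single-linkage gap in bp (default 1000).
#' @param minSupport Minimum pairs per emitted candidate (default 2).
#' @return List of [Breakpoint-class] candidates.
#' @export
clusterCandidates <- function(pairs, clusterWindow = 1000L, minSupport = 2L) {
  if (nrow(pairs) == 0L) return(list())
  key <- paste(pairs$contigA, pairs$contigB, pairs$strandA, pairs$strandB)
  out <- list()
  for (k in unique(key)) {
    g <- pairs[key == k, , drop = FALSE]
    n <- nrow(g)
    # union-find single linkage on both partner coordinates
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      if (abs(g$startA[i] - g$startA[j]) <= clusterWindow &&
          abs(g$startB[i] - g$startB[j]) <= clusterWindow) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (c0 in unique(comp)) {
      cl <- g[comp == c0, , drop = FALSE]
      if (nrow(cl) < minSupport) next
      sideA <- if (cl$strandA[1] == "+") "left-of" else "right-of"
      sideB <- if (cl$strandB[1] == "+") "left-of" else "right-of"
      posA <- if (sideA == "left-of") max(cl$endA) else min(cl$startA)
      posB <- if (sideB == "left-of") max(cl$endB) else min(cl$startB)
      wA <- if (sideA == "left-of") diff(range(cl$endA))
            else diff(range(cl$startA))
      wB <- if (sideB == "left-of") diff(range(cl$endB))
            else diff(range(cl$startB))
      out[[length(out) + 1L]] <- new("Breakpoint",
        contigA = cl$contigA[1], posA = posA, sideA = sideA,
        contigB = cl$contigB[1], posB = posB, sideB = sideB,
        supportPairs = nrow(cl), supportSplit = 0L,
        resolution = "interval", intervalWidth = max(wA, wB))
    }
  }
  ord <- order(vapply(out, function(b) b@contigA, character(1)),
               vapply(out, function(b) b@posA, numeric(1)),
               -vapply(out, function(b) b@supportPairs, integer(1)))
  out[ord]
}

#' Refine a candidate breakpoint with junction-spanning reads
#'
#' For each spanning read, the split point maximizing the exact prefix
#' match to the partner-A flank plus the exact suffix match to the
#' partner-B flank is located (each side anchored by a unique `k`-mer and
#' extended base-by-base). The modal `(posA, posB)` across reads is
#' reported with `resolution = "exact"`; ties break toward the smallest
#' `posA`. Split-read refinement goes beyond pair-based callers and is
#' what delivers base-pair-exact junction coordinates.
#'
#' @param candidate An interval-resolution [Breakpoint-class].
#' @param spanningReads [Biostrings::DNAStringSet] (or FASTQ path) of
#'   junction-spanning reads.
#' @param genome The native [ToyGenome-class].
#' @param k Minimum matched bases required on each side (default 15).
#' @param flank Flank width searched around the candidate (default 2000).
#' @return The refined [Breakpoint-class], or the unrefined candidate when
#'   no read achieves `k` matched bases on both sides.
#' @export
refineJunction <- function(candidate, spanningReads, genome, k = 15L,
                           flank = 2000L) {
  if (is.character(spanningReads)) spanningReads <- readFastq(spanningReads)
  if (length(spanningReads) == 0L) return(candidate)
  seqs <- sequences(genome)
  orig <- origins(genome)
  fl <- .junction_flank(candidate@contigA, candidate@posA, seqs, orig, flank)
  flB <- .junction_flank(candidate@contigB, candidate@posB, seqs, orig, flank)
  votes <- character(0)
  for (i in seq_along(spanningReads)) {
    rd <- as.character(spanningReads[[i]])
    L <- nchar(rd)
    if (L < 2L * k) next
    # anchor the read prefix in flank A, extend the exact match forward
    aHit <- Biostrings::matchPattern(substr(rd, 1L, k), fl$seq)
    bHit <- Biostrings::matchPattern(
      substr(rd, L - k + 1L, L), flB$seq)
    if (length(aHit) != 1L || length(bHit) != 1L) next
    fa <- as.character(fl$seq); fb <- as.character(flB$seq)
    a0 <- Biostrings::start(aHit)          # 1-based in flank A
    p <- k
    while (a0 + p <= nchar(fa) && p < L &&
           substr(fa, a0 + p, a0 + p) == substr(rd, p + 1L, p + 1L))
      p <- p + 1L
    b0 <- Biostrings::start(bHit)          # 1-based suffix anchor in flank B
    q <- k
    while (b0 - 1L >= 1L && q < L &&
           substr(fb, b0 - 1L, b0 - 1L) == substr(rd, L - q, L - q)) {
      b0 <- b0 - 1L; q <- q + 1L
    }
    if (p < k || q < k || p + q < L) next
    jA <- fl$offset0 + (a0 - 1L) + p       # 0-based exclusive end on A
    jB <- flB$offset0 + (b0 - 1L)          # 0-based first retained base on B
    # junction microhomology: p + q > L means several (jA, jB) are
    # consistent; report the leftmost (smallest posA) representative
    overlap <- p + q - L
    if (overlap > 0L) jA <- jA - overlap
    votes <- c(votes, sprintf("%.0f:%.0f", jA, jB))
  }
  if (length(votes) == 0L) return(candidate)
  t <- table(votes)
  best <- names(t)[t == max(t)]
  coords <- do.call(rbind, lapply(strsplit(best, ":"), as.numeric))
  pick <- which.min(coords[, 1])           # ties toward smallest posA
  initialize(candidate,
             posA = coords[pick, 1], posB = coords[pick, 2],
             supportSplit = as.integer(max(t)),
             resolution = "exact", intervalWidth = 0)
}

.junction_flank <- function(contig, pos, seqs, orig, flank) {
  local <- pos - orig[contig]
  L <- Biostrings::width(seqs)[match(contig, names(seqs))]
  s0 <- max(0, local - flank); e0 <- min(L, local + flank)
  list(seq = Biostrings::subseq(seqs[[contig]], s0 + 1, e0),
       offset0 = orig[contig] + s0)
}

#' Write breakpoints as TSV and BEDPE
#'
#' The TSV carries 1-based human-facing coordinates (see
#' [breakpointTable()]); the BEDPE uses 0-based half-open single-base
#' intervals at each partner position.
#'
#' @param breakpoints List of [Breakpoint-class] objects.
#' @param prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.bedpe`.
#' @return Files written, invisibly.
#' @export
writeBreakpoints <- function(breakpoints, prefix) {
  bt <- breakpointTable(breakpoints)
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(bt, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bedpe <- paste0(prefix, ".bedpe")
  a0 <- bt$pos_a - 1L; b0 <- bt$pos_b - 1L
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tbp%d\t%d\t.\t.",
                     bt$contig_a, as.integer(a0), as.integer(a0 + 1),
                     bt$contig_b, as.integer(b0), as.integer(b0 + 1),
                     seq_len(nrow(bt)), bt$support_pairs), bedpe)
  invisible(c(tsv = tsv, bedpe = bedpe))
}

#' Render breakpoints as a human-facing table
#'
#' Coordinates are 1-based: for a `left-of` flank the last retained base,
#' for a `right-of` flank the first retained base (the
#' `Chr.A:pos-Chr.B:pos` reporting style).
#'
#' @param breakpoints List of [Breakpoint-class] objects (or a single one).
#' @return `data.frame` with one row per breakpoint.
#' @export
breakpointTable <- function(breakpoints) {
  if (is(breakpoints, "Breakpoint")) breakpoints <- list(breakpoints)
  do.call(rbind, lapply(breakpoints, function(b) {
    data.frame(
      contig_a = b@contigA,
      pos_a = if (b@sideA == "left-of") b@posA else b@posA + 1,
      side_a = b@sideA,
      contig_b = b@contigB,
      pos_b = if (b@sideB == "left-of") b@posB else b@posB + 1,
      side_b = b@sideB,
      support_pairs = b@supportPairs, support_split = b@supportSplit,
      resolution = b@resolution, interval_bp = b@intervalWidth,
      stringsAsFactors = FALSE)
  }))
}
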