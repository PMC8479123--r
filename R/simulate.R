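#' Construct a contact model
#'
#' @param decayExponent Power-law exponent of the contact-frequency decay
#'   with genomic separation (default 1).
#' @param backgroundRate Per-fragment weight for trans contacts
#'   (default 1e-6).
#' @param loopAnchors `data.frame` with columns `fragmentA`, `fragmentB`,
#'   `enrichment` (applied when one member is the viewpoint fragment).
#' @param selfExclusionRadius Fragments around the viewpoint never sampled
#'   (default 5).
#' @return A [ContactModel-class].
#' @export
contactModel <- function(decayExponent = 1, backgroundRate = 1e-6,
                         loopAnchors = data.frame(fragmentA = integer(0),
                                                  fragmentB = integer(0),
                                                  enrichment = numeric(0)),
                         selfExclusionRadius = 5L) {
  new("ContactModel", decayExponent = decayExponent,
      backgroundRate = backgroundRate, loopAnchors = loopAnchors,
      selfExclusionRadius = as.integer(selfExclusionRadius))
}

#' Construct a simulation configuration
#'
#' @param seed Integer seed. Identical seed and configuration give
#'   byte-identical outputs.
#' @param nReads Number of 4C reads, or capture pairs, to emit.
#' @param readLength Read length in bp (default 50).
#' @param insertMean,insertSd Capture insert size in bp (defaults 500/50).
#' @param junctionSpanFraction Fraction of capture fragments straddling the
#'   junction (default 0.2).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nReads = 10000L, readLength = 50L,
                             insertMean = 500L, insertSd = 50L,
                             junctionSpanFraction = 0.2) {
  new("SimulationConfig", seed = as.integer(seed),
      nReads = as.integer(nReads), readLength = as.integer(readLength),
      insertMean = as.integer(insertMean), insertSd = as.integer(insertSd),
      junctionSpanFraction = junctionSpanFraction)
}

#' Per-fragment sampling weights of a contact model
#'
#' Cis fragments (same contig as the viewpoint) are weighted
#' `s^-decayExponent` with `s` the midpoint separation; trans fragments get
#' the constant `backgroundRate`; fragments looped to the viewpoint are
#' multiplied by their enrichment; fragments within the self-exclusion
#' radius get weight 0. Weights are normalised to probabilities.
#'
#' @param map A [FragmentMap-class].
#' @param vpFrag Viewpoint fragment id.
#' @param model A [ContactModel-class].
#' @return Numeric vector of sampling probabilities over `fragments(map)`.
#' @export
contactWeights <- function(map, vpFrag, model) {
  gr <- map@fragments
  ids <- mcols(gr)$id
  vi <- match(vpFrag, ids)
  if (is.na(vi)) stop("viewpoint fragment not in map")
  mid <- (start(gr) - 1 + end(gr)) / 2
  sameContig <- as.character(seqnames(gr)) == as.character(seqnames(gr))[vi]
  s <- abs(mid - mid[vi])
  w <- ifelse(sameContig, ifelse(s > 0, s^(-model@decayExponent), 0),
              model@backgroundRate)
  la <- model@loopAnchors
  if (nrow(la)) {
    partner <- c(la$fragmentB[la$fragmentA == vpFrag],
                 la$fragmentA[la$fragmentB == vpFrag])
    enr <- c(la$enrichment[la$fragmentA == vpFrag],
             la$enrichment[la$fragmentB == vpFrag])
    m <- match(partner, ids)
    w[m[!is.na(m)]] <- w[m[!is.na(m)]] * enr[!is.na(m)]
  }
  w[sameContig & abs(ids - vpFrag) <= model@selfExclusionRadius] <- 0
  if (sum(w) <= 0) stop("no eligible partner fragment has positive weight")
  w / sum(w)
}

#' Simulate a 4C library from a viewpoint
#'
#' Each read is the viewpoint reading primer (ending in the primary motif)
#' followed by the partner fragment-end sequence, total length
#' `readLength`. The partner fragment is drawn per the [ContactModel-class]
#' (power-law distance decay, loop enrichment, self-exclusion), and the
#' captured end (left/right) uniformly. The ligation junction carries a
#' single shared primary motif, so after primer clipping the trimmed read
#' reproduces the fragment-end sequence the catalog indexes.
#'
#' @param genome A [ToyGenome-class] (typically the derivative locus as one
#'   contig, so separations are cis on the derivative).
#' @param map [FragmentMap-class] of `genome`.
#' @param vp The [Viewpoint-class]; its position must fall in a fragment.
#' @param model A [ContactModel-class].
#' @param cfg A [SimulationConfig-class].
#' @return List with `reads` (named [Biostrings::DNAStringSet]) and `truth`
#'   (`data.frame` `read`, `fragmentId`, `side`: the emitter's ground
#'   truth).
#' @export
simulate4CReads <- function(genome, map, vp, model, cfg) {
  primer <- vp@readingPrimer
  motifLen <- nchar(map@primary@recognition)
  m <- cfg@readLength - nchar(primer)
  if (m <= 0)
    stop("readLength shorter than primer + motif; no partner sequence would be sequenced")
  vpFrag <- fragmentAt(map, vp@contig, vp@position)
  if (is.na(vpFrag)) stop("viewpoint fragment does not exist")
  prob <- contactWeights(map, vpFrag, model)
  gr <- map@fragments
  ids <- mcols(gr)$id
  eligible <- which(prob > 0 & width(gr) >= m + motifLen)
  if (length(eligible) == 0L) stop("no eligible partner fragments")
  prob <- prob[eligible] / sum(prob[eligible])
  seqs <- sequences(genome); orig <- origins(genome)
  ct <- as.character(seqnames(gr))[eligible]
  ls0 <- start(gr)[eligible] - 1 - orig[ct]
  le0 <- end(gr)[eligible] - orig[ct]
  # partner contribution after the shared ligation motif
  leftContrib <- as.character(Biostrings::subseq(
    seqs[ct], start = ls0 + motifLen + 1, end = ls0 + motifLen + m))
  rightContrib <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(Biostrings::subseq(
      seqs[ct], start = le0 - m + 1, end = le0))))
  # a fragment end is ligatable only where it is a restriction cut, not a
  # contig edge: contig-edge fragments emit only their cut-side end
  ctg_len <- Biostrings::width(seqs)[match(ct, names(seqs))]
  leftOk <- ls0 > 0; rightOk <- le0 < ctg_len
  if (cfg@nReads == 0L)
    return(list(reads = Biostrings::DNAStringSet(),
                truth = data.frame(read = character(0),
                                   fragmentId = integer(0),
                                   side = character(0),
                                   stringsAsFactors = FALSE)))
  .with_seed(cfg@seed, {
    n <- cfg@nReads
    pick <- sample.int(length(eligible), n, replace = TRUE, prob = prob)
    side <- ifelse(stats::runif(n) < 0.5 & leftOk[pick] | !rightOk[pick],
                   "left", "right")
    contrib <- ifelse(side == "left", leftContrib[pick], rightContrib[pick])
    reads <- Biostrings::DNAStringSet(paste0(primer, contrib))
    if (n > 0) names(reads) <- sprintf("sim4c_%06d", seq_len(n))
    list(reads = reads,
         truth = data.frame(read = names(reads) %||% character(0),
                            fragmentId = ids[eligible][pick], side = side,
                            stringsAsFactors = FALSE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate capture read pairs over a derivative junction
#'
#' Samples sequencing fragments from the derivative chromosome: a fraction
#' `junctionSpanFraction` straddle the junction (their mates map to the two
#' native partner contigs, i.e. discordant pairs) and each straddling
#' fragment additionally yields one single read crossing the junction base
#' (split evidence); remaining pairs are concordant background sampled away
#' from the junction. Mate positions are reported in native origin-shifted
#' coordinates, paired-end FR, constant MAPQ 60.
#'
#' @param genome The native [ToyGenome-class].
#' @param der A two-segment [DerivativeChromosome-class] whose junction is
#'   at least an insert length from the segment ends.
#' @param cfg A [SimulationConfig-class] (`nReads` = number of pairs).
#' @return List with `sam` (record `data.frame` for [writeSam()]),
#'   `seqLengths`, `spanningReads` ([Biostrings::DNAStringSet]), `truth`
#'   (per-pair `data.frame` with `straddles`), and `junction` (native
#'   junction record).
#' @export
simulateCapturePairs <- function(genome, der, cfg) {
  seg <- der@segments
  if (nrow(seg) < 1L) stop("derivative has zero segments")
  if (nrow(seg) != 2L)
    stop("capture simulation expects a two-segment derivative")
  if (any(seg$strand != "+"))
    stop("capture simulation supports forward-oriented segments")
  derSeq <- derivativeSequence(genome, der)
  J <- seg$end[1] - seg$start[1]            # junction, 0-based on derivative
  derLen <- derivativeLength(der)
  rl <- cfg@readLength
  ins0 <- cfg@insertMean
  if (J < ins0 || derLen - J < ins0)
    stop("junction closer than one insert length to a segment end")
  .with_seed(cfg@seed, {
    n <- cfg@nReads
    nJ <- round(cfg@junctionSpanFraction * n)
    straddles <- c(rep(TRUE, nJ), rep(FALSE, n - nJ))
    insert <- pmax(2L * rl + 2L,
                   as.integer(round(stats::rnorm(n, ins0, cfg@insertSd))))
    fragStart <- numeric(n)
    for (i in seq_len(n)) {
      if (straddles[i]) {
        # both mates clear of the junction: sampled start keeps
        # [start+rl, start+insert-rl] around J
        lo <- J - insert[i] + rl + 1L; hi <- J - rl - 1L
        fragStart[i] <- sample(seq(lo, hi), 1L)
      } else {
        repeat {
          s <- sample.int(derLen - insert[i], 1L) - 1L
          if (s + insert[i] <= J || s >= J) break
        }
        fragStart[i] <- s
      }
    }
    r1der <- fragStart
    r2der <- fragStart + insert - rl
    n1 <- mapFromDerivative(der, r1der)
    n2 <- mapFromDerivative(der, r2der)
    r1seq <- as.character(Biostrings::DNAStringSet(Biostrings::extractAt(
      derSeq, IRanges(r1der + 1, r1der + rl))))
    r2fwd <- Biostrings::DNAStringSet(Biostrings::extractAt(
      derSeq, IRanges(r2der + 1, r2der + rl)))
    r2seq <- as.character(Biostrings::reverseComplement(r2fwd))
    qn <- sprintf("pair%06d", seq_len(n))
    qual <- strrep("I", rl)
    flag1 <- ifelse(straddles, 97L, 99L)    # paired, mate reverse, first
    flag2 <- ifelse(straddles, 145L, 147L)  # paired, reverse, second
    tlen <- ifelse(straddles, 0L, insert)
    sam <- rbind(
      data.frame(qname = qn, flag = flag1, rname = n1$contig,
                 pos = n1$pos + 1, mapq = 60L, cigar = sprintf("%dM", rl),
                 rnext = ifelse(n1$contig == n2$contig, "=", n2$contig),
                 pnext = n2$pos + 1, tlen = tlen, seq = r1seq, qual = qual,
                 stringsAsFactors = FALSE),
      data.frame(qname = qn, flag = flag2, rname = n2$contig,
                 pos = n2$pos + 1, mapq = 60L, cigar = sprintf("%dM", rl),
                 rnext = ifelse(n1$contig == n2$contig, "=", n1$contig),
                 pnext = n1$pos + 1, tlen = -tlen, seq = r2seq, qual = qual,
                 stringsAsFactors = FALSE))
    sam <- sam[order(sam$qname, sam$flag), ]
    # one junction-spanning single read per straddling fragment
    spanStarts <- if (nJ > 0)
      J - rl + sample(15:(rl - 15), nJ, replace = TRUE) else integer(0)
    spanning <- Biostrings::DNAStringSet(if (nJ > 0) as.character(
      Biostrings::DNAStringSet(Biostrings::extractAt(
        derSeq, IRanges(spanStarts + 1, spanStarts + rl)))) else character(0))
    if (nJ > 0) names(spanning) <- sprintf("span%04d", seq_len(nJ))
    ext <- .contig_extents(genome)
    seqLengths <- vapply(ext, function(e) e[2], numeric(1))
    truth <- data.frame(qname = qn, straddles = straddles,
                        contig1 = n1$contig, pos1 = n1$pos,
                        contig2 = n2$contig, pos2 = n2$pos,
                        stringsAsFactors = FALSE)
    junction <- list(contigA = seg$contig[1], lastBaseA = seg$end[1],
                     contigB = seg$contig[2], firstBaseB = seg$start[2] + 1)
    list(sam = sam, seqLengths = seqLengths, spanningReads = spanning,
         truth = truth, junction = junction)
  })
}

#' Write the plain-text junction record of a capture simulation
#'
#' @param junction The `junction` element of [simulateCapturePairs()]
#'   output (1-based last base of A, first base of B).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeJunctionRecord <- function(junction, path) {
  writeLines(sprintf("%s\t%d\t%s\t%d", junction$contigA,
                     as.integer(junction$lastBaseA), junction$contigB,
                     as.integer(junction$firstBaseB)), path)
  invisible(path)
}
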