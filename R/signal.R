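#' Normalize a contact profile to reads per million
#'
#' `rpm[f] = count[f] * 1e6 / D`, with `D` the total of reads kept in the
#' profile after all filtering (the denominator choice is recorded in track
#' headers and makes profiles comparable across viewpoints). The normalized
#' values sum to 1e6 up to floating tolerance.
#'
#' @param profile A [ContactProfile-class] with positive depth.
#' @return The profile with its `normalized` slot filled.
#' @examples
#' \dontrun{rpmNormalize(profile)}
#' @export
rpmNormalize <- function(profile) {
  D <- sum(profile@counts)
  if (D <= 0)
    stop("zero-depth profile cannot be RPM-normalized; export raw counts instead")
  initialize(profile, normalized = profile@counts * 1e6 / D)
}

#' Running mean with shrinking edges
#'
#' Smooths a fragment-ordered (or bin-ordered) value vector with a centred
#' running mean of odd window `w`: `smoothed[i]` is the mean of the raw
#' values at indices `[i-h, i+h]` intersected with the vector, `h=(w-1)/2`.
#' Edges shrink (only existing positions are averaged), so no signal is
#' invented beyond the ends. Values on different contigs must be smoothed
#' separately ([smoothTrack()] does this).
#'
#' @param x Numeric vector.
#' @param window Odd positive integer (default 21).
#' @return Numeric vector, same length as `x`.
#' @examples
#' runningMean(c(0, 0, 3, 0, 0), 3)  # 0 1 1 1 0
#' @export
runningMean <- function(x, window = 21L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  if (length(x) == 0L) return(x)
  as.numeric(zoo::rollapply(x, width = window, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Build a per-fragment signal track from a contact profile
#'
#' @param profile A [ContactProfile-class].
#' @param map The matching [FragmentMap-class].
#' @param use `"normalized"` (RPM, requires [rpmNormalize()]) or `"raw"`.
#' @return A [SignalTrack-class] of kind `per-fragment`, unsmoothed.
#' @export
contactTrack <- function(profile, map, use = c("normalized", "raw")) {
  use <- match.arg(use)
  vals <- if (use == "normalized") normalizedCounts(profile)
          else contactCounts(profile)
  gr <- map@fragments
  gr <- gr[match(as.integer(names(vals)), mcols(gr)$id)]
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
  mcols(out)$score <- as.numeric(vals)
  mcols(out)$fragmentId <- as.integer(names(vals))
  out <- sort(out)
  new("SignalTrack", kind = "per-fragment", data = out, binSize = NA_real_,
      normalization = if (use == "normalized") "RPM" else "raw",
      smoothing = "none")
}

#' Smooth a signal track contig-by-contig
#'
#' Applies [runningMean()] over the interval-ordered value vector of each
#' contig separately; fragments on different contigs never share a window.
#'
#' @param track A [SignalTrack-class].
#' @param window Odd window size in intervals (default 21).
#' @return The smoothed track, tagged `running_mean(w)`.
#' @export
smoothTrack <- function(track, window = 21L) {
  gr <- track@data
  sc <- mcols(gr)$score
  for (ct in unique(as.character(seqnames(gr)))) {
    sel <- which(as.character(seqnames(gr)) == ct)
    sc[sel] <- runningMean(sc[sel], window)
  }
  mcols(gr)$score <- sc
  initialize(track, data = gr,
             smoothing = sprintf("running_mean(%d)", as.integer(window)))
}

.check_track_sorted <- function(gr) {
  for (ct in unique(as.character(seqnames(gr)))) {
    s <- start(gr)[as.character(seqnames(gr)) == ct]
    if (is.unsorted(s, strictly = TRUE))
      stop(sprintf("track positions on %s are not strictly increasing", ct))
  }
}

#' Export a signal track as WIG (variableStep)
#'
#' Per-fragment values are anchored at fragment midpoints
#' (`floor((start+end)/2)` of the 0-based half-open interval, emitted as a
#' 1-based variableStep position); WIG requires single positions per value.
#'
#' @param track A [SignalTrack-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeWig <- function(track, path) {
  gr <- track@data
  .check_track_sorted(gr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s %s\"",
                     track@normalization, track@smoothing), con)
  for (ct in unique(as.character(seqnames(gr)))) {
    sel <- as.character(seqnames(gr)) == ct
    mid <- floor(((start(gr)[sel] - 1) + end(gr)[sel]) / 2)
    if (is.unsorted(mid, strictly = TRUE))
      stop(sprintf("fragment midpoints on %s are not strictly increasing", ct))
    writeLines(sprintf("variableStep chrom=%s", ct), con)
    writeLines(sprintf("%d\t%s", as.integer(mid),
                       format(mcols(gr)$score[sel], trim = TRUE,
                              scientific = FALSE)), con)
  }
  invisible(path)
}

#' Export / import a signal track as bedGraph
#'
#' bedGraph preserves the full 0-based half-open intervals, so
#' `readBedgraph(writeBedgraph(track))` reproduces interval coordinates and
#' values exactly.
#'
#' @param track A [SignalTrack-class].
#' @param path File path.
#' @return `writeBedgraph`: `path`, invisibly. `readBedgraph`: a
#'   [SignalTrack-class] (normalization/smoothing tags are not stored in
#'   bedGraph and read back as `raw`/`none`).
#' @export
writeBedgraph <- function(track, path) {
  .check_track_sorted(track@data)
  rtracklayer::export.bedGraph(track@data, path)
  invisible(path)
}

#' @rdname writeBedgraph
#' @export
readBedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  new("SignalTrack", kind = "per-fragment", data = gr, binSize = NA_real_,
      normalization = "raw", smoothing = "none")
}

#' Binned, RPKM-normalized, smoothed coverage track
#'
#' Counts reads overlapping fixed-width bins, normalizes to RPKM
#' (`count * 1e9 / (librarySize * binSize)`), then applies a running mean
#' over `smoothLength / binSize` bins (made odd by adding one bin if even;
#' a `smoothLength` that is not a multiple of `binSize` is rounded down,
#' with a message). Mirrors the standard coverage-track recipe
#' (RPKM normalization, 100 bp smoothing, 20 bp bins).
#'
#' @param reads `GRanges` of read intervals, or a BED path.
#' @param genomeSizes Named numeric vector of contig lengths (bp; bins tile
#'   `[0, size)` per contig).
#' @param binSize Bin width in bp (default 20).
#' @param smoothLength Smoothing window in bp (default 100).
#' @param librarySize Normalisation denominator; defaults to the number of
#'   reads supplied.
#' @return A [SignalTrack-class] of kind `fixed-bin`.
#' @export
binnedCoverage <- function(reads, genomeSizes, binSize = 20L,
                           smoothLength = 100L, librarySize = NULL) {
  if (is.character(reads)) reads <- rtracklayer::import(reads, format = "BED")
  if (binSize <= 0) stop("binSize must be > 0")
  libSize <- if (is.null(librarySize)) length(reads) else librarySize
  if (libSize == 0L) stop("empty read library")
  bins <- GRanges()
  for (ct in names(genomeSizes)) {
    starts <- seq(1L, genomeSizes[[ct]], by = binSize)
    ends <- pmin(starts + binSize - 1L, genomeSizes[[ct]])
    bins <- c(bins, GRanges(ct, IRanges(starts, ends)))
  }
  counts <- GenomicRanges::countOverlaps(bins, reads, minoverlap = 1L)
  rpkm <- counts * 1e9 / (libSize * binSize)
  nb <- floor(smoothLength / binSize)
  if (nb * binSize != smoothLength)
    message(sprintf("smoothLength rounded down to %d bp (%d bins)",
                    nb * binSize, nb))
  if (nb %% 2L == 0L) {
    nb <- nb + 1L
    message(sprintf("smoothing window made odd: %d bins", nb))
  }
  mcols(bins)$score <- rpkm
  track <- new("SignalTrack", kind = "fixed-bin", data = bins,
               binSize = as.numeric(binSize), normalization = "RPKM",
               smoothing = "none")
  if (nb > 1L) track <- smoothTrack(track, nb)
  track
}

#' Extent of the contact domain around a viewpoint target region
#'
#' Finds the maximal run of consecutive fragments inside `region` whose
#' smoothed value is at least `thresholdFraction` of the regional maximum,
#' and reports its genomic span (end of last fragment minus start of
#' first): the "long stretch of chromatin" a viewpoint interacts with.
#'
#' @param track A smoothed per-fragment [SignalTrack-class].
#' @param thresholdFraction Fraction of the regional maximum in (0, 1].
#' @param region `GRanges` (length 1) to scan.
#' @return List with `extent` (bp), `nFragments`, and the `indices` of the
#'   run within the region; `extent` 0 for an all-zero region.
#' @export
contactDomainExtent <- function(track, thresholdFraction, region) {
  gr <- track@data
  ov <- IRanges::overlapsAny(gr, region)
  if (!any(ov)) stop("region overlaps no fragment in the track")
  sub <- gr[ov]
  vals <- mcols(sub)$score
  m <- max(vals)
  if (m <= 0) return(list(extent = 0, nFragments = 0L, indices = integer(0)))
  above <- vals >= thresholdFraction * m
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  list(extent = end(sub)[idx[length(idx)]] - (start(sub)[idx[1]] - 1),
       nFragments = length(idx), indices = idx)
}
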