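#' Load oriented CTCF sites from a stranded BED file
#'
#' Strand `+` becomes orientation `forward`, `-` becomes `reverse`;
#' records with strand `.` carry no orientation and are skipped with a
#' warning (convergence analysis needs every site oriented).
#'
#' @param path 6-column BED file.
#' @return `GRanges` with metadata columns `label` and `orientation`.
#' @export
loadSites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 6L)
      stop(sprintf("malformed BED line %d: expected 6 columns, got %d",
                   i, length(f)))
    if (is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3]))))
      stop(sprintf("malformed BED line %d: non-numeric coordinates", i))
  }
  gr <- rtracklayer::import(path, format = "BED")
  nostrand <- as.character(strand(gr)) == "*"
  if (any(nostrand)) {
    warning(sprintf("%d site(s) without strand skipped (orientation undefined)",
                    sum(nostrand)))
    gr <- gr[!nostrand]
  }
  mcols(gr)$label <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
                     else sprintf("site%d", seq_along(gr))
  mcols(gr)$orientation <- ifelse(as.character(strand(gr)) == "+",
                                  "forward", "reverse")
  gr
}

# Flatten sites to (pos, orientation, label, contig), optionally mapped
# onto a derivative. Orientation flips through '-' segments.
.site_positions <- function(sites, der = NULL) {
  if (is(sites, "GRanges")) {
    df <- data.frame(contig = as.character(seqnames(sites)),
                     start = start(sites) - 1, end = end(sites),
                     orientation = mcols(sites)$orientation,
                     label = mcols(sites)$label %||%
                       sprintf("site%d", seq_along(sites)),
                     stringsAsFactors = FALSE)
  } else df <- sites
  df$pos <- (df$start + df$end) / 2
  if (is.null(der)) return(df)
  derPos <- mapToDerivative(der, df$contig, floor(df$pos))
  seg <- der@segments
  flip <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(seg))) {
    inSeg <- df$contig == seg$contig[i] & floor(df$pos) >= seg$start[i] &
      floor(df$pos) < seg$end[i]
    if (seg$strand[i] == "-") flip[inSeg] <- TRUE
  }
  df$pos <- derPos
  df$orientation <- ifelse(flip,
                           ifelse(df$orientation == "forward",
                                  "reverse", "forward"),
                           df$orientation)
  df[!is.na(df$pos), , drop = FALSE]
}

#' Enumerate convergent CTCF site pairs
#'
#' All ordered pairs (forward site before reverse site in coordinate
#' order) - the loop-compatible configuration in which a forward-oriented
#' motif can anchor a loop with a downstream reverse-oriented one. When a
#' [DerivativeChromosome-class] is supplied, sites are first mapped onto
#' derivative coordinates (orientation flipping through inverted
#' segments), so convergence is assessed on the rearranged chromosome.
#'
#' @param sites `GRanges` with an `orientation` column (see [loadSites()]),
#'   or a `data.frame` with `contig`, `start`, `end`, `orientation`,
#'   `label`.
#' @param maxSpan Optional maximum pair span in bp.
#' @param der Optional [DerivativeChromosome-class] to map sites onto.
#' @return `data.frame` of pairs (`forward`, `reverse`, `posForward`,
#'   `posReverse`, `span`), sorted by span ascending.
#' @export
convergentPairs <- function(sites, maxSpan = NULL, der = NULL) {
  df <- .site_positions(sites, der)
  if (is.null(der) && length(unique(df$contig)) > 1L)
    stop("sites span several contigs; supply a derivative to map them onto")
  fwd <- df[df$orientation == "forward", , drop = FALSE]
  rev <- df[df$orientation == "reverse", , drop = FALSE]
  out <- data.frame(forward = character(0), reverse = character(0),
                    posForward = numeric(0), posReverse = numeric(0),
                    span = numeric(0), stringsAsFactors = FALSE)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(out)
  grid <- expand.grid(i = seq_len(nrow(fwd)), j = seq_len(nrow(rev)))
  keep <- fwd$pos[grid$i] < rev$pos[grid$j]
  grid <- grid[keep, , drop = FALSE]
  span <- rev$pos[grid$j] - fwd$pos[grid$i]
  if (!is.null(maxSpan)) {
    grid <- grid[span <= maxSpan, , drop = FALSE]
    span <- span[span <= maxSpan]
  }
  out <- data.frame(forward = fwd$label[grid$i], reverse = rev$label[grid$j],
                    posForward = fwd$pos[grid$i],
                    posReverse = rev$pos[grid$j],
                    span = span, stringsAsFactors = FALSE)
  out[order(out$span), , drop = FALSE]
}

#' Construct a promoter anchor
#'
#' @param contig Contig of the promoter and its docking site.
#' @param promoterPos 0-based promoter position.
#' @param siteStart,siteEnd Docking-site interval (0-based half-open).
#' @param siteOrientation Observed orientation of the docking-site motif.
#' @param promoterStrand Promoter strand (default `+`); "upstream" is
#'   defined relative to it.
#' @param requiredOrientation Orientation required for docking
#'   (default `forward`).
#' @return A [PromoterAnchor-class].
#' @export
promoterAnchor <- function(contig, promoterPos, siteStart, siteEnd,
                           siteOrientation = "forward",
                           promoterStrand = "+",
                           requiredOrientation = "forward") {
  new("PromoterAnchor", contig = contig, promoterPos = promoterPos,
      promoterStrand = promoterStrand, siteStart = siteStart,
      siteEnd = siteEnd, siteOrientation = siteOrientation,
      requiredOrientation = requiredOrientation)
}

#' Is the enhancer-docking site preserved on a derivative chromosome?
#'
#' The docking configuration is preserved iff (i) the docking-site
#' interval and the promoter position are covered by the same derivative
#' segment, (ii) the site is not truncated by a segment boundary, and
#' (iii) the site carries its required orientation. Additionally reports
#' whether a convergent partner is possible: whether at least one
#' reverse-oriented site contributed by a joined partner segment lies on
#' the enhancer side of the junction, forming a convergent pair with the
#' docking site in derivative coordinates.
#'
#' @param anchor A [PromoterAnchor-class].
#' @param der The [DerivativeChromosome-class].
#' @param partnerSites Optional `GRanges`/`data.frame` of oriented CTCF
#'   sites (native coordinates, any contig) to assess convergent-partner
#'   possibility.
#' @return List verdict: `covered`, `preserved`,
#'   `convergentPartnerPossible`, `pairs` (the convergent pair list, when
#'   computed) and `details` (human-readable).
#' @export
dockingPreserved <- function(anchor, der, partnerSites = NULL) {
  seg <- der@segments
  segOf <- function(contig, pos) {
    for (i in seq_len(nrow(seg)))
      if (contig == seg$contig[i] && pos >= seg$start[i] && pos < seg$end[i])
        return(i)
    NA_integer_
  }
  sProm <- segOf(anchor@contig, anchor@promoterPos)
  sSite1 <- segOf(anchor@contig, anchor@siteStart)
  sSite2 <- segOf(anchor@contig, anchor@siteEnd - 1)
  if (is.na(sProm))
    return(list(covered = FALSE, preserved = FALSE,
                convergentPartnerPossible = FALSE, pairs = NULL,
                details = "promoter not covered by the derivative"))
  truncated <- is.na(sSite1) || is.na(sSite2) || sSite1 != sSite2
  sameSegment <- !truncated && sSite1 == sProm
  orientationOk <- anchor@siteOrientation == anchor@requiredOrientation
  preserved <- sameSegment && orientationOk
  convergent <- FALSE; pairs <- NULL
  if (preserved && !is.null(partnerSites)) {
    dock <- data.frame(contig = anchor@contig, start = anchor@siteStart,
                       end = anchor@siteEnd,
                       orientation = anchor@siteOrientation,
                       label = "docking_site", stringsAsFactors = FALSE)
    ps <- .site_positions(partnerSites)
    all <- rbind(dock, ps[, c("contig", "start", "end", "orientation",
                              "label")])
    pairs <- convergentPairs(all, der = der)
    partnerContigs <- setdiff(seg$contig, anchor@contig)
    fromPartner <- ps$label[ps$contig %in% partnerContigs &
                            ps$orientation == "reverse"]
    pairs <- pairs[pairs$forward == "docking_site" &
                   pairs$reverse %in% fromPartner, , drop = FALSE]
    convergent <- nrow(pairs) > 0L
  }
  list(covered = TRUE, preserved = preserved,
       convergentPartnerPossible = convergent, pairs = pairs,
       details = if (preserved)
         "docking site and promoter intact on one derivative segment"
       else if (is.na(sSite1) && is.na(sSite2))
         "docking site lost from the derivative"
       else if (truncated) "docking site truncated by a segment boundary"
       else if (!sameSegment)
         "junction separates the docking site from the promoter"
       else "docking site lacks the required orientation")
}

#' Quantify reads in enhancer modules
#'
#' Counts each read toward a module iff their intervals overlap by at
#' least 1 bp (each read at most once per module), computes
#' `RPKM = count * 1e9 / (librarySize * moduleLength)`, and, for exactly
#' two samples, the per-module `log2((RPKM1 + pc) / (RPKM2 + pc))` fold
#' change with pseudocount `pc = 1`.
#'
#' @param reads A `GRanges` of read intervals, a BED path, or a named list
#'   of either (one element per sample).
#' @param modules Named `GRanges` of enhancer-module intervals (e.g. the
#'   constituent modules A-I and S of a super-enhancer).
#' @param librarySizes Numeric vector of total library sizes, one per
#'   sample (must be positive).
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return `data.frame` with one row per module: `module`, `length`, and
#'   per-sample `count`/`RPKM` columns, plus `log2FC` for two samples.
#' @export
moduleQuantify <- function(reads, modules, librarySizes,
                           pseudocount = 1) {
  if (!is.list(reads)) reads <- list(sample1 = reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("sample%d", seq_along(reads))
  if (length(librarySizes) != length(reads))
    stop("one library size per sample is required")
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  if (is.null(names(modules)))
    stop("modules must be named")
  len <- width(modules)
  out <- data.frame(module = names(modules), length = len,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    if (is.character(rd)) rd <- rtracklayer::import(rd, format = "BED")
    cnt <- GenomicRanges::countOverlaps(modules, rd, minoverlap = 1L)
    out[[paste0("count_", names(reads)[i])]] <- cnt
    out[[paste0("rpkm_", names(reads)[i])]] <-
      cnt * 1e9 / (librarySizes[i] * len)
  }
  if (length(reads) == 2L) {
    r1 <- out[[paste0("rpkm_", names(reads)[1])]]
    r2 <- out[[paste0("rpkm_", names(reads)[2])]]
    out$log2FC <- log2((r1 + pseudocount) / (r2 + pseudocount))
  }
  out
}
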