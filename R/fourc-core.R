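#' Construct a 4C viewpoint
#'
#' @param name Viewpoint name.
#' @param contig Contig carrying the viewpoint.
#' @param position 0-based origin-shifted position inside the viewpoint
#'   fragment.
#' @param readingPrimer Reading-primer sequence; must end in the primary
#'   recognition motif (checked).
#' @param exclusionRadius Fragments on either side of the viewpoint fragment
#'   excluded from counting (default 1).
#' @param primaryMotif Primary recognition sequence the primer must end in
#'   (default `GATC`).
#' @return A [Viewpoint-class] object.
#' @export
viewpoint <- function(name, contig, position, readingPrimer,
                      exclusionRadius = 1L, primaryMotif = "GATC") {
  readingPrimer <- toupper(readingPrimer)
  if (!endsWith(readingPrimer, primaryMotif))
    stop(sprintf("reading primer of viewpoint %s must end in the primary motif %s",
                 name, primaryMotif))
  new("Viewpoint", name = name, contig = contig, position = position,
      readingPrimer = readingPrimer,
      exclusionRadius = as.integer(exclusionRadius))
}

#' Demultiplex raw 4C reads and clip the reading primers
#'
#' A read is assigned to a viewpoint when its prefix matches that
#' viewpoint's reading primer within `maxMismatch` mismatches; clipping
#' then removes the primer bases *before* the primary motif, so trimmed
#' reads begin with the motif (e.g. `GATC`), which anchors the subsequent
#' fragment-end match. Reads matching no primer (or more than one) are
#' dropped and counted.
#'
#' @param reads A [Biostrings::DNAStringSet] or FASTQ path.
#' @param viewpoints List of [Viewpoint-class] objects with pairwise
#'   distinct primers at the chosen mismatch tolerance.
#' @param maxMismatch Maximum primer mismatches (default 0).
#' @param motifLength Length of the primary motif retained on trimmed
#'   reads (default 4).
#' @return List with `assigned` (named list of trimmed `DNAStringSet`, one
#'   per viewpoint) and `summary` (`data.frame` of per-viewpoint and
#'   dropped-read tallies).
#' @export
demultiplexAndClip <- function(reads, viewpoints, maxMismatch = 0L,
                               motifLength = 4L) {
  if (is.character(reads)) reads <- readFastq(reads)
  if (is(viewpoints, "Viewpoint")) viewpoints <- list(viewpoints)
  primers <- vapply(viewpoints, function(v) v@readingPrimer, character(1))
  vnames <- vapply(viewpoints, function(v) v@name, character(1))
  for (i in seq_along(primers)) for (j in seq_along(primers)) {
    if (i >= j) next
    if (nchar(primers[i]) == nchar(primers[j])) {
      d <- sum(strsplit(primers[i], "")[[1]] != strsplit(primers[j], "")[[1]])
      if (d <= maxMismatch)
        stop(sprintf("viewpoints %s and %s have indistinguishable primers at max mismatch %d",
                     vnames[i], vnames[j], maxMismatch))
    }
  }
  n <- length(reads)
  hit <- matrix(FALSE, nrow = n, ncol = length(primers))
  for (j in seq_along(primers)) {
    L <- nchar(primers[j])
    long <- Biostrings::width(reads) >= L
    if (!any(long)) next
    pref <- Biostrings::subseq(reads[long], 1L, L)
    hit[long, j] <- Biostrings::vcountPattern(primers[j], pref,
                                              max.mismatch = maxMismatch) > 0
  }
  nhit <- rowSums(hit)
  assigned <- vector("list", length(primers))
  names(assigned) <- vnames
  for (j in seq_along(primers)) {
    sel <- which(nhit == 1L & hit[, j])
    clipAt <- nchar(primers[j]) - motifLength + 1L  # keep the motif
    assigned[[j]] <- Biostrings::subseq(reads[sel], start = clipAt)
  }
  summary <- data.frame(
    viewpoint = c(vnames, "unassigned", "ambiguous"),
    n = c(vapply(assigned, length, integer(1)),
          sum(nhit == 0L), sum(nhit > 1L)),
    stringsAsFactors = FALSE)
  list(assigned = assigned, summary = summary,
       nTotal = n, nUnassigned = sum(nhit == 0L), nAmbiguous = sum(nhit > 1L))
}

#' Assign trimmed 4C reads to fragment ends via the k-mer catalog
#'
#' The toy exact mapper: a trimmed read (beginning with the primary motif
#' contributed by the viewpoint side of the ligation junction) is matched
#' against the fragment-end catalog. Left fragment ends begin with the
#' motif themselves, so they are queried with the first `k` read bases;
#' right fragment ends are queried with the `k` bases following the motif
#' (the partner sequence proper). A unique catalog hit assigns the read;
#' zero hits count as unmapped, several as ambiguous.
#'
#' @param trimmed Trimmed reads ([Biostrings::DNAStringSet]).
#' @param catalog [endCatalog()] output built with the same `k`.
#' @param k k-mer length used for the catalog.
#' @param motifLength Primary motif length (default 4).
#' @return `data.frame` with one row per read: `read`, `fragmentId`,
#'   `side`, `status` (`assigned`/`unmapped`/`ambiguous`/`short`).
#' @export
mapTrimmedReads <- function(trimmed, catalog, k, motifLength = 4L) {
  n <- length(trimmed)
  res <- data.frame(read = if (is.null(names(trimmed))) seq_len(n)
                           else names(trimmed),
                    fragmentId = NA_integer_, side = NA_character_,
                    status = "short", stringsAsFactors = FALSE)
  if (n == 0L) return(res)
  chars <- as.character(trimmed)
  wl <- nchar(chars)
  catL <- catalog[catalog$side == "left", ]
  catR <- catalog[catalog$side == "right", ]
  # catalog k-mers may collide between fragments; count multiplicity
  multL <- table(catL$kmer); multR <- table(catR$kmer)
  qL <- ifelse(wl >= k, substr(chars, 1L, k), NA)
  qR <- ifelse(wl >= motifLength + k,
               substr(chars, motifLength + 1L, motifLength + k), NA)
  nL <- ifelse(is.na(qL), 0L, as.integer(multL[qL])); nL[is.na(nL)] <- 0L
  nR <- ifelse(is.na(qR), 0L, as.integer(multR[qR])); nR[is.na(nR)] <- 0L
  tot <- nL + nR
  long <- wl >= k
  res$status[long] <- "unmapped"
  res$status[tot > 1L] <- "ambiguous"
  one <- tot == 1L
  iL <- one & nL == 1L
  res$fragmentId[iL] <- catL$fragmentId[match(qL[iL], catL$kmer)]
  res$side[iL] <- "left"
  iR <- one & nR == 1L
  res$fragmentId[iR] <- catR$fragmentId[match(qR[iR], catR$kmer)]
  res$side[iR] <- "right"
  res$status[one] <- "assigned"
  res
}

#' Assign aligned 4C reads to fragments by their 5' ends
#'
#' Implements the fragment filter of the 4C pipeline: reads not mapping to
#' fragment boundaries determined by the restriction site positions are
#' removed. A read is valid iff its strand-aware 5' alignment end lies
#' within `boundaryTolerance` bp of a primary fragment boundary: forward
#' reads are compared to fragment starts (side `left`), reverse reads to
#' fragment ends (side `right`).
#'
#' @param sam SAM path or internal record `data.frame` (single-end
#'   semantics; each record assessed independently).
#' @param map A [FragmentMap-class].
#' @param boundaryTolerance Tolerance in bp (default 2).
#' @return `data.frame` with `read`, `fragmentId`, `side`, `status`
#'   (`assigned` or `filtered`).
#' @export
assignFromAlignments <- function(sam, map, boundaryTolerance = 2L) {
  rec <- if (is.character(sam)) .read_sam(sam) else sam
  gr <- map@fragments
  ct <- as.character(seqnames(gr))
  known <- unique(ct)
  res <- data.frame(read = rec$qname, fragmentId = NA_integer_,
                    side = NA_character_, status = "filtered",
                    stringsAsFactors = FALSE)
  warned <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (is.na(rec$pos[i])) next
    if (!rec$rname[i] %in% known) {
      if (!rec$rname[i] %in% warned) {
        warning(sprintf("alignments on contig %s absent from the fragment map are filtered",
                        rec$rname[i]))
        warned <- c(warned, rec$rname[i])
      }
      next
    }
    rev <- bitwAnd(rec$flag[i], 16L) > 0L
    sel <- which(ct == rec$rname[i])
    if (!rev) {
      p0 <- rec$pos[i] - 1                    # 0-based alignment start
      d <- abs((start(gr)[sel] - 1) - p0)
      side <- "left"
    } else {
      w <- .cigar_ref_width(rec$cigar[i])
      p0 <- rec$pos[i] - 1 + w                # 0-based exclusive 3'... 5' end
      d <- abs(end(gr)[sel] - p0)
      side <- "right"
    }
    j <- which.min(d)
    if (length(j) && d[j] <= boundaryTolerance) {
      res$fragmentId[i] <- mcols(gr)$id[sel[j]]
      res$side[i] <- side
      res$status[i] <- "assigned"
    }
  }
  res
}

#' Aggregate read assignments into a contact profile
#'
#' Counts assigned reads per fragment and removes the viewpoint fragment
#' together with its `exclusionRadius` neighbours on each side (inclusive;
#' radius 0 still excludes the viewpoint fragment itself, which carries
#' self-ligation products). The bookkeeping identity
#' `nTotal = kept + excluded + unmapped + ambiguous + unassigned + short`
#' holds exactly.
#'
#' @param assignments Assignment `data.frame` from [mapTrimmedReads()] or
#'   [assignFromAlignments()].
#' @param vp The [Viewpoint-class].
#' @param map The [FragmentMap-class].
#' @param nUnassigned,nAmbiguousDemux Reads dropped upstream at
#'   demultiplexing, carried into the profile bookkeeping.
#' @return A [ContactProfile-class] with zero-filled counts over all
#'   countable fragments.
#' @export
countContacts <- function(assignments, vp, map, nUnassigned = 0L,
                          nAmbiguousDemux = 0L) {
  gr <- map@fragments
  vpFrag <- fragmentAt(map, vp@contig, vp@position)
  if (is.na(vpFrag))
    stop(sprintf("viewpoint %s at %s:%.0f is not covered by any fragment",
                 vp@name, vp@contig, vp@position))
  ids <- mcols(gr)$id
  sameContig <- as.character(seqnames(gr)) ==
    as.character(seqnames(gr))[match(vpFrag, ids)]
  excluded <- ids[sameContig & abs(ids - vpFrag) <= vp@exclusionRadius]
  keepIds <- setdiff(ids, excluded)
  ok <- assignments$status == "assigned"
  asg <- assignments$fragmentId[ok]
  nExcluded <- sum(asg %in% excluded)
  kept <- asg[!asg %in% excluded]
  counts <- structure(numeric(length(keepIds)),
                      names = as.character(keepIds))
  if (length(kept)) {
    t <- table(factor(as.character(kept), levels = names(counts)))
    counts[] <- as.numeric(t)
  }
  nUnmapped <- sum(assignments$status == "unmapped")
  nAmb <- sum(assignments$status == "ambiguous") + nAmbiguousDemux
  nShort <- sum(assignments$status == "short")
  nFiltered <- sum(assignments$status == "filtered")
  stats <- c(nTotal = nrow(assignments) + nUnassigned + nAmbiguousDemux,
             nAssigned = sum(ok), nExcluded = nExcluded,
             nUnmapped = nUnmapped, nAmbiguous = nAmb,
             nUnassigned = nUnassigned, nShort = nShort,
             nFilteredOut = nFiltered + nExcluded)
  new("ContactProfile", viewpoint = vp, counts = counts, stats = stats,
      normalized = numeric(0))
}

#' Write a contact profile as TSV
#'
#' Emits `fragment_id`, `contig`, `start`, `end` (0-based half-open),
#' `count` and, if present, `rpm`, under a commented header recording the
#' viewpoint and bookkeeping parameters.
#'
#' @param profile A [ContactProfile-class].
#' @param map The matching [FragmentMap-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeContactProfile <- function(profile, map, path) {
  tab <- fragmentTable(map)
  tab <- tab[match(as.integer(names(profile@counts)), tab$id), ]
  out <- data.frame(fragment_id = tab$id, contig = tab$contig,
                    start = tab$start, end = tab$end,
                    count = as.numeric(profile@counts))
  if (length(profile@normalized)) out$rpm <- as.numeric(profile@normalized)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# viewpoint=%s contig=%s position=%.0f exclusion_radius=%d",
                     profile@viewpoint@name, profile@viewpoint@contig,
                     profile@viewpoint@position,
                     profile@viewpoint@exclusionRadius), con)
  writeLines(paste0("# ", paste(sprintf("%s=%d", names(profile@stats),
                                        as.integer(profile@stats)),
                                collapse = " ")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
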