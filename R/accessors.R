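# Accessors and show() methods.

#' @rdname ToyGenome-class
#' @export
setMethod("sequences", "ToyGenome", function(x) x@sequences)

#' @rdname ToyGenome-class
#' @export
setMethod("origins", "ToyGenome", function(x) x@origin)

#' @rdname ToyGenome-class
#' @export
setMethod("ctcfSites", "ToyGenome", function(x) x@ctcfSites)

#' @rdname ToyGenome-class
#' @export
setMethod("enhancerModules", "ToyGenome", function(x) x@modules)

setMethod("show", "ToyGenome", function(object) {
  cat(sprintf("ToyGenome with %d contig(s)\n", length(object@sequences)))
  for (i in seq_along(object@sequences))
    cat(sprintf("  %s: %d bp, origin %.0f\n", names(object@sequences)[i],
                Biostrings::width(object@sequences)[i], object@origin[i]))
  if (length(object@ctcfSites))
    cat(sprintf("  %d CTCF site(s), %d module(s)\n",
                length(object@ctcfSites), length(object@modules)))
})

#' @rdname FragmentMap-class
#' @export
setMethod("fragments", "FragmentMap", function(x) x@fragments)

#' Fragment table in 0-based half-open coordinates
#'
#' @rdname FragmentMap-class
#' @export
setMethod("fragmentTable", "FragmentMap", function(x) {
  fr <- x@fragments
  data.frame(id = mcols(fr)$id,
             contig = as.character(seqnames(fr)),
             start = start(fr) - 1, end = end(fr),
             blind = mcols(fr)$blind,
             firstCut = mcols(fr)$firstCut, lastCut = mcols(fr)$lastCut,
             row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "FragmentMap", function(object) {
  ann <- !is.null(object@secondary)
  cat(sprintf("FragmentMap: %d fragments (%s%s)\n",
              length(object@fragments), object@primary@name,
              if (ann) paste0(" + ", object@secondary@name) else ""))
  if (ann)
    cat(sprintf("  blind fragments: %d\n", sum(mcols(object@fragments)$blind)))
})

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s, cut offset %d\n",
              object@name, object@recognition, object@cutOffset))
})

setMethod("show", "Viewpoint", function(object) {
  cat(sprintf("Viewpoint %s at %s:%.0f (primer %s, exclusion radius %d)\n",
              object@name, object@contig, object@position,
              object@readingPrimer, object@exclusionRadius))
})

#' @rdname ContactProfile-class
#' @export
setMethod("contactCounts", "ContactProfile", function(x) x@counts)

#' @rdname ContactProfile-class
#' @export
setMethod("normalizedCounts", "ContactProfile", function(x) {
  if (length(x@normalized) == 0L)
    stop("profile has not been normalized; run rpmNormalize() first")
  x@normalized
})

#' @rdname ContactProfile-class
#' @export
setMethod("readStats", "ContactProfile", function(x) x@stats)

setMethod("show", "ContactProfile", function(object) {
  s <- object@stats
  cat(sprintf("ContactProfile for %s: %d fragments, %d reads kept\n",
              object@viewpoint@name, length(object@counts),
              as.integer(sum(object@counts))))
  cat(sprintf("  total %d | assigned %d | excluded %d | filtered %d\n",
              as.integer(s["nTotal"]), as.integer(s["nAssigned"]),
              as.integer(s["nExcluded"]), as.integer(s["nFilteredOut"])))
  if (length(object@normalized)) cat("  RPM-normalized\n")
})

#' @rdname DerivativeChromosome-class
#' @export
setMethod("segments", "DerivativeChromosome", function(x) x@segments)

setMethod("show", "DerivativeChromosome", function(object) {
  seg <- object@segments
  cat(sprintf("DerivativeChromosome %s: %d segment(s), %.0f bp\n",
              object@name, nrow(seg), sum(seg$end - seg$start)))
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  [%d] %s:%.0f-%.0f (%s)\n", i, seg$contig[i],
                seg$start[i], seg$end[i], seg$strand[i]))
})

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(x) mcols(x@data)$score)

#' @rdname SignalTrack-class
#' @export
setMethod("trackData", "SignalTrack", function(x) x@data)

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack (%s): %d intervals, %s, smoothing %s\n",
              object@kind, length(object@data), object@normalization,
              object@smoothing))
})

setMethod("show", "Breakpoint", function(object) {
  cat(sprintf("Breakpoint %s:%.0f (%s) <-> %s:%.0f (%s)\n",
              object@contigA, object@posA, object@sideA,
              object@contigB, object@posB, object@sideB))
  cat(sprintf("  support: %d pairs, %d split reads; resolution %s%s\n",
              object@supportPairs, object@supportSplit, object@resolution,
              if (object@resolution == "interval")
                sprintf(" (+/- %.0f bp)", object@intervalWidth) else ""))
})
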