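#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand strand<-
#' @importFrom IRanges IRanges
NULL

#' Restriction enzyme description
#'
#' Holds the recognition sequence and cut offset of a restriction enzyme.
#' Only palindromic recognition sequences are supported, so scanning the
#' forward strand finds every cut site.
#'
#' @slot name Enzyme name.
#' @slot recognition Recognition sequence (DNA, palindromic).
#' @slot cutOffset Cut position in bp from the start of the recognition
#'   sequence (0 to its length).
#'
#' @seealso [restrictionEnzyme()], [DpnII()], [Csp6I()]
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  rec <- object@recognition
  if (length(rec) != 1L || nchar(rec) == 0L)
    return("recognition sequence must be a single non-empty string")
  if (grepl("[^ACGT]", rec))
    return("recognition sequence must contain only A, C, G, T")
  if (object@cutOffset < 0L || object@cutOffset > nchar(rec))
    return("cutOffset must lie within the recognition sequence")
  rc <- .revcomp_chr(rec)
  if (rc != rec)
    return(sprintf("non-palindromic recognition sequence '%s' is not supported", rec))
  TRUE
})

#' Toy genome with origin-shifted coordinates
#'
#' A small set of contigs, each carrying an `origin`: the genomic coordinate
#' of its first base. The origin lets a desk-scale sequence stand in for a
#' genome-scale locus (e.g. a few hundred kb around 3q26 or 8q24) while all
#' reported coordinates remain on the genome scale. Planted CTCF motif
#' occurrences and enhancer-module intervals are carried as `GRanges`
#' annotations.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of contig sequences.
#' @slot origin Named numeric vector, 0-based genomic coordinate of the first
#'   base of each contig.
#' @slot ctcfSites `GRanges` of planted CTCF motifs with an `orientation`
#'   metadata column (`forward`/`reverse`).
#' @slot modules `GRanges` of planted enhancer-module intervals (named).
#'
#' @exportClass ToyGenome
setClass("ToyGenome",
  representation(sequences = "DNAStringSet", origin = "numeric",
                 ctcfSites = "GRanges", modules = "GRanges"))

setValidity("ToyGenome", function(object) {
  nm <- names(object@sequences)
  if (length(nm) != length(object@sequences) || anyDuplicated(nm))
    return("contig names must be present and unique")
  if (!identical(names(object@origin), nm))
    return("origin must be named to match the contigs")
  if (any(object@origin < 0))
    return("origins must be >= 0")
  freq <- Biostrings::alphabetFrequency(object@sequences)
  if (length(object@sequences) &&
      any(rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                       drop = FALSE]) > 0))
    return("sequences may contain only A, C, G, T, N")
  TRUE
})

#' Restriction fragment map
#'
#' The genome partition into primary restriction fragments, optionally
#' annotated with the nearest internal secondary cut from each primary
#' boundary. Fragments are stored as a `GRanges` (1-based, origin-shifted)
#' with metadata columns `id` (consecutive in coordinate order), `blind`
#' (no secondary cut strictly inside) and `firstCut`/`lastCut` (0-based
#' secondary cut positions, `NA` for blind fragments or before
#' [annotateSecondary()] has run).
#'
#' @slot fragments `GRanges` of fragments.
#' @slot primary [RestrictionEnzyme-class]; `secondary` is `NULL` until
#'   [annotateSecondary()] has run.
#' @slot secondary `NULL` or a [RestrictionEnzyme-class].
#' @slot checksum Digest fingerprint of the genome the map was built from.
#'
#' @seealso [digest()], [annotateSecondary()], [fragmentTable()]
#' @exportClass FragmentMap
setClass("FragmentMap",
  representation(fragments = "GRanges", primary = "RestrictionEnzyme",
                 secondary = "ANY", checksum = "character"))

#' 4C viewpoint
#'
#' The anchor locus of a 4C library: a reading primer ending in the primary
#' restriction motif, the genomic position of the viewpoint, and the number
#' of neighbouring fragments excluded from counting (self-ligation and
#' undigested neighbours).
#'
#' @slot name Viewpoint name (e.g. `EVI1_PR`, `MYC_SE`).
#' @slot contig,position Location of the viewpoint (0-based, origin-shifted).
#' @slot readingPrimer Primer sequence; must end in the primary recognition
#'   motif.
#' @slot exclusionRadius Fragments on either side of the viewpoint fragment
#'   removed from contact counts (default 1).
#'
#' @exportClass Viewpoint
setClass("Viewpoint",
  representation(name = "character", contig = "character",
                 position = "numeric", readingPrimer = "character",
                 exclusionRadius = "integer"))

#' Contact model for simulated 4C libraries
#'
#' Partner fragments are sampled with probability proportional to
#' `s^-decayExponent` for cis fragments at midpoint separation `s`,
#' `backgroundRate` for trans fragments, multiplied by `enrichment` for
#' fragments paired with the viewpoint fragment in `loopAnchors`. Fragments
#' within `selfExclusionRadius` fragments of the viewpoint are never sampled.
#'
#' @slot decayExponent Positive power-law exponent of contact decay.
#' @slot backgroundRate Positive per-fragment weight for trans contacts.
#' @slot loopAnchors `data.frame` with columns `fragmentA`, `fragmentB`,
#'   `enrichment` (>= 1).
#' @slot selfExclusionRadius Integer, in fragments.
#'
#' @exportClass ContactModel
setClass("ContactModel",
  representation(decayExponent = "numeric", backgroundRate = "numeric",
                 loopAnchors = "data.frame", selfExclusionRadius = "integer"))

setValidity("ContactModel", function(object) {
  if (object@decayExponent <= 0) return("decayExponent must be > 0")
  if (object@backgroundRate <= 0) return("backgroundRate must be > 0")
  la <- object@loopAnchors
  need <- c("fragmentA", "fragmentB", "enrichment")
  if (nrow(la) && !all(need %in% names(la)))
    return("loopAnchors needs columns fragmentA, fragmentB, enrichment")
  if (nrow(la) && any(la$enrichment < 1))
    return("loop enrichment must be >= 1")
  if (object@selfExclusionRadius < 0) return("selfExclusionRadius must be >= 0")
  TRUE
})

#' Simulation configuration
#'
#' @slot seed Integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @slot nReads Number of reads (4C) or read pairs (capture) to emit.
#' @slot readLength Read length in bp.
#' @slot insertMean,insertSd Capture-pair insert size distribution in bp.
#' @slot junctionSpanFraction Fraction of capture fragments forced to
#'   straddle the derivative junction.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(seed = "integer", nReads = "integer", readLength = "integer",
                 insertMean = "integer", insertSd = "integer",
                 junctionSpanFraction = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@nReads < 0) return("nReads must be >= 0")
  if (object@readLength <= 0) return("readLength must be > 0")
  if (object@junctionSpanFraction < 0 || object@junctionSpanFraction > 1)
    return("junctionSpanFraction must be in [0, 1]")
  TRUE
})

#' Per-fragment contact profile of one viewpoint library
#'
#' Raw (and, after [rpmNormalize()], RPM-normalised) contact counts per
#' fragment, together with the read bookkeeping of the processing pipeline.
#' Counts are absent for the viewpoint fragment and its excluded neighbours.
#'
#' @slot viewpoint The [Viewpoint-class] the profile belongs to.
#' @slot counts Named numeric vector, fragment id -> read count (zero-filled
#'   over all countable fragments).
#' @slot stats Named numeric vector with elements `nTotal`, `nAssigned`,
#'   `nExcluded`, `nUnmapped`, `nAmbiguous`, `nUnassigned`, `nFilteredOut`.
#' @slot normalized Named numeric vector of RPM values (empty until
#'   normalisation).
#'
#' @exportClass ContactProfile
setClass("ContactProfile",
  representation(viewpoint = "Viewpoint", counts = "numeric",
                 stats = "numeric", normalized = "numeric"))

#' Position/value signal track
#'
#' Either a per-fragment track (one value per restriction fragment) or a
#' fixed-bin coverage track. Interval coordinates live in the `data`
#' `GRanges` (1-based internally; bedGraph export converts to 0-based
#' half-open, WIG export anchors per-fragment values at fragment midpoints).
#'
#' @slot kind `"per-fragment"` or `"fixed-bin"`.
#' @slot data `GRanges` with a numeric `score` column, ordered within contig.
#' @slot binSize Bin width in bp (fixed-bin tracks; `NA` otherwise).
#' @slot normalization `"raw"`, `"RPM"` or `"RPKM"`.
#' @slot smoothing `"none"` or `"running_mean(w)"`.
#'
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(kind = "character", data = "GRanges", binSize = "numeric",
                 normalization = "character", smoothing = "character"))

setValidity("SignalTrack", function(object) {
  if (!object@kind %in% c("per-fragment", "fixed-bin"))
    return("kind must be 'per-fragment' or 'fixed-bin'")
  if (!"score" %in% names(mcols(object@data)))
    return("data must carry a 'score' column")
  sc <- mcols(object@data)$score
  if (length(sc) && (any(!is.finite(sc)) || any(sc < 0)))
    return("scores must be finite and >= 0")
  if (!object@normalization %in% c("raw", "RPM", "RPKM"))
    return("normalization must be raw, RPM or RPKM")
  TRUE
})

#' Translocation breakpoint
#'
#' A candidate or refined junction between two partner loci. Positions are
#' 0-based internally: `posA` is the exclusive end of the retained flank of
#' partner A when `sideA == "left-of"`, and `posB` the inclusive start of
#' the retained flank of B when `sideB == "right-of"`.
#' [breakpointTable()] renders the 1-based human-facing coordinates
#' (last retained base of A, first retained base of B).
#'
#' @slot contigA,posA,sideA Partner A contig, position, joined flank
#'   (`left-of` or `right-of`).
#' @slot contigB,posB,sideB Partner B.
#' @slot supportPairs,supportSplit Discordant-pair and split-read support.
#' @slot resolution `"exact"` (split-read refined) or `"interval"`.
#' @slot intervalWidth Half-width of the uncertainty interval in bp
#'   (0 when exact).
#'
#' @exportClass Breakpoint
setClass("Breakpoint",
  representation(contigA = "character", posA = "numeric", sideA = "character",
                 contigB = "character", posB = "numeric", sideB = "character",
                 supportPairs = "integer", supportSplit = "integer",
                 resolution = "character", intervalWidth = "numeric"))

setValidity("Breakpoint", function(object) {
  if (!object@resolution %in% c("exact", "interval"))
    return("resolution must be 'exact' or 'interval'")
  if (object@resolution == "exact" && object@supportSplit < 1)
    return("exact resolution requires split-read support")
  if (!all(c(object@sideA, object@sideB) %in% c("left-of", "right-of")))
    return("sides must be 'left-of' or 'right-of'")
  TRUE
})

#' Derivative chromosome
#'
#' An ordered list of oriented native-genome segments forming a rearranged
#' chromosome. Segments use 0-based half-open native coordinates
#' (origin-shifted). [mapToDerivative()] and [mapFromDerivative()] are
#' mutually inverse on covered positions.
#'
#' @slot name Derivative name (e.g. `der3`).
#' @slot segments `data.frame` with columns `contig`, `start`, `end`
#'   (0-based half-open) and `strand` (`+`/`-`), in derivative order.
#'
#' @exportClass DerivativeChromosome
setClass("DerivativeChromosome",
  representation(name = "character", segments = "data.frame"))

setValidity("DerivativeChromosome", function(object) {
  seg <- object@segments
  need <- c("contig", "start", "end", "strand")
  if (!all(need %in% names(seg)))
    return("segments needs columns contig, start, end, strand")
  if (nrow(seg) == 0L) return("a derivative must have at least one segment")
  if (any(seg$end <= seg$start)) return("segments must be non-degenerate")
  if (!all(seg$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  TRUE
})

#' Promoter anchor with its enhancer-docking CTCF site
#'
#' Couples a promoter position with the promoter-proximal CTCF site that is
#' required, in the stated orientation, to dock distal enhancers (the
#' configuration observed 2.6 kb upstream of the EVI1 transcriptional start
#' site). Used by [dockingPreserved()].
#'
#' @slot contig,promoterPos Promoter location (0-based, origin-shifted).
#' @slot promoterStrand Strand of the promoter; "upstream" is defined
#'   relative to this, never inferred from gene names.
#' @slot siteStart,siteEnd Docking-site interval (0-based half-open).
#' @slot siteOrientation Observed motif orientation of the docking site.
#' @slot requiredOrientation Orientation required for a positive call
#'   (default `forward`).
#'
#' @exportClass PromoterAnchor
setClass("PromoterAnchor",
  representation(contig = "character", promoterPos = "numeric",
                 promoterStrand = "character",
                 siteStart = "numeric", siteEnd = "numeric",
                 siteOrientation = "character",
                 requiredOrientation = "character"))

setValidity("PromoterAnchor", function(object) {
  if (object@siteStart >= object@siteEnd)
    return("docking site interval must be non-empty")
  if (!all(c(object@siteOrientation, object@requiredOrientation) %in%
           c("forward", "reverse")))
    return("orientations must be 'forward' or 'reverse'")
  TRUE
})
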