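# Bundled study conditions: a toy derivative 4C locus and a toy t(3;8)
# translocation genome. Their defaults define the simulation conditions
# used throughout the package's tests and the acceptance script.

#' Toy derivative 4C locus with promoter, docking site and enhancer zones
#'
#' Builds a single-contig toy locus emulating a derivative chromosome on
#' which a promoter viewpoint interacts in cis with a distal
#' super-enhancer: restriction sites every 200 bp (DpnII primary, Csp6I
#' secondary at fragment centres), a forward-oriented CTCF docking site
#' 2.6 kb upstream of the viewpoint, and reverse-oriented CTCF sites at
#' 60, 80 and 100 kb forming three loop-anchor zones. Each zone spans 25
#' consecutive fragments (a few kb, as loop-anchor regions do) with
#' 10-fold contact enrichment; elsewhere contacts decay as a power law
#' with exponent 1. Ten enhancer-module intervals (A-I and S) tile the
#' enhancer region.
#'
#' @param seed Integer seed for the toy sequence.
#' @return List with `genome`, `map` (secondary-annotated
#'   [FragmentMap-class]), `vp` ([Viewpoint-class]), `model`
#'   ([ContactModel-class]), `vpFragment`, `anchorFragments` (all enriched
#'   ids), `zoneCenters` (central fragment id per zone), and
#'   `decayExponent`.
#' @export
exampleFourCLocus <- function(seed = 1L) {
  L <- 130000L
  spacing <- 200L
  primarySites <- seq(spacing, L - spacing, by = spacing)
  secondarySites <- seq(100L, L - 100L, by = spacing)
  vpPos <- 6150
  zoneSep <- c(60000, 80000, 100000)
  ctcf <- data.frame(
    pos = c(vpPos - 2600, vpPos + zoneSep - 40),
    orientation = c("forward", rep("reverse", length(zoneSep))),
    label = c("CTCF_PR", sprintf("CTCF%d", seq_along(zoneSep))),
    stringsAsFactors = FALSE)
  modules <- data.frame(
    name = c(LETTERS[1:9], "S"),
    start = seq(58000, by = 5000, length.out = 10),
    end = seq(59000, by = 5000, length.out = 10))
  genome <- makeToyGenome(list(list(
    name = "derT3", length = L, origin = 0,
    primarySites = primarySites, secondarySites = secondarySites,
    ctcf = ctcf, modules = modules)), seed = seed)
  map <- annotateSecondary(digest(genome), genome)
  vp <- viewpoint("EVI1_PR", "derT3", vpPos,
                  readingPrimer = "CCTTCCTTCCTTCCTTGATC",
                  exclusionRadius = 1L)
  vpFrag <- fragmentAt(map, "derT3", vpPos)
  zoneCenters <- vapply(vpPos + zoneSep,
                        function(p) fragmentAt(map, "derT3", p), integer(1))
  zoneHalf <- 12L
  anchorFragments <- unlist(lapply(zoneCenters,
                                   function(c0) (c0 - zoneHalf):(c0 + zoneHalf)))
  model <- contactModel(
    decayExponent = 1, backgroundRate = 1e-6,
    loopAnchors = data.frame(fragmentA = vpFrag,
                             fragmentB = anchorFragments,
                             enrichment = 10),
    selfExclusionRadius = 5L)
  list(genome = genome, map = map, vp = vp, model = model,
       vpFragment = vpFrag, anchorFragments = anchorFragments,
       zoneCenters = zoneCenters, decayExponent = 1)
}

#' Toy t(3;8)-style translocation genome
#'
#' Two 200 kb toy contigs standing in for the 3q26 and 8q24 loci (origins
#' 168,800,000 and 130,400,000), joined by a reciprocal translocation at
#' the patient-derived junction Chr.3:168,917,999-Chr.8:130,487,191
#' (1-based last retained base of chromosome 3, first retained base of
#' chromosome 8). The derivative places the enhancer-donor segment
#' downstream of the promoter-side segment, the configuration that
#' relocates a super-enhancer 5' of the target gene.
#'
#' @param seed Integer seed for the toy sequences.
#' @return List with `genome`, `truth` (the junction [Breakpoint-class]),
#'   and `der` (the [DerivativeChromosome-class]).
#' @export
exampleT38Genome <- function(seed = 1L) {
  originA <- 168800000; originB <- 130400000
  genome <- makeToyGenome(list(
    list(name = "chrT3", length = 200000L, origin = originA),
    list(name = "chrT8", length = 200000L, origin = originB)),
    seed = seed)
  # pin the four bases flanking the junction so it carries no
  # microhomology: base-pair-exact breakpoint coordinates are then
  # well-defined (a clean blunt junction, as CRISPR-engineered models aim
  # for)
  jA <- 168917999 - originA  # local 0-based exclusive end on chrT3
  jB <- 130487190 - originB  # local 0-based first retained base on chrT8
  seqs <- as.character(sequences(genome))
  substr(seqs["chrT3"], jA, jA + 1) <- "AC"       # last kept, first lost
  substr(seqs["chrT8"], jB, jB + 1) <- "GT"       # last lost, first kept
  genome@sequences <- Biostrings::DNAStringSet(seqs)
  truth <- new("Breakpoint",
               contigA = "chrT3", posA = 168917999, sideA = "left-of",
               contigB = "chrT8", posB = 130487190, sideB = "right-of",
               supportPairs = 0L, supportSplit = 1L,
               resolution = "exact", intervalWidth = 0)
  der <- buildDerivative(truth, genome, name = "der3")
  list(genome = genome, truth = truth, der = der)
}
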