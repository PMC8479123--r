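#' Default CTCF motif planted by the toy-genome generator
#'
#' A 16 bp stand-in motif chosen so that neither it nor its reverse
#' complement contains the DpnII (GATC) or Csp6I (GTAC) recognition
#' sequences; planted motif counts therefore stay exact after filler
#' screening.
#'
#' @return Character, the forward-orientation motif.
#' @export
defaultCtcfMotif <- function() "CCAGCAGGGGGCGCTC"

#' Generate a toy genome with planted restriction sites, motifs and modules
#'
#' Builds small contigs in which every primary/secondary restriction site,
#' CTCF motif occurrence and enhancer-module interval is planted explicitly.
#' Filler bases are screened by rejection sampling so that no accidental
#' occurrence of the primary or secondary recognition sequence, nor of the
#' CTCF motif (either orientation), arises: all site counts are exact and
#' testable. Coordinates in the returned annotations are origin-shifted, so
#' a few hundred kb of sequence can stand in for a genome-scale locus.
#'
#' @param contigs List of contig descriptions; each a list with elements
#'   `name`, `length`, and optionally `origin` (default 0), `primarySites`,
#'   `secondarySites` (0-based local positions of planted recognition
#'   sequences), `ctcf` (`data.frame` with `pos`, `orientation`
#'   (`forward`/`reverse`) and optional `label`), and `modules`
#'   (`data.frame` with `name`, `start`, `end`, 0-based half-open local).
#' @param primary,secondary [RestrictionEnzyme-class] objects whose
#'   recognition sequences are planted and screened.
#' @param ctcfMotif Forward-orientation motif sequence to plant.
#' @param seed Integer seed for the filler sequence.
#' @return A [ToyGenome-class] object.
#' @examples
#' g <- makeToyGenome(list(list(name = "chrT", length = 500,
#'                              primarySites = seq(50, 450, by = 50))),
#'                    seed = 1)
#' @export
makeToyGenome <- function(contigs, primary = DpnII(), secondary = Csp6I(),
                          ctcfMotif = defaultCtcfMotif(), seed = 1L) {
  motifF <- toupper(ctcfMotif)
  motifR <- .revcomp_chr(motifF)
  patterns <- unique(c(primary@recognition, secondary@recognition,
                       motifF, motifR))
  for (p in patterns) for (q in setdiff(patterns, p))
    if (grepl(q, p, fixed = TRUE))
      stop(sprintf("planted pattern '%s' contains '%s'; site counts would not be exact",
                   p, q))

  seqs <- character(0); orig <- numeric(0)
  ctcf_all <- GRanges(); mod_all <- GRanges()
  for (cs in contigs) {
    nm <- cs$name
    L <- as.integer(cs$length)
    origin <- if (is.null(cs$origin)) 0 else cs$origin
    plant <- data.frame(what = character(0), pos = numeric(0),
                        seq = character(0), stringsAsFactors = FALSE)
    add_plant <- function(what, pos, sq)
      rbind(plant, data.frame(what = what, pos = pos, seq = sq,
                              stringsAsFactors = FALSE))
    for (p in cs$primarySites)
      plant <- add_plant(sprintf("%s@%d", primary@name, p), p,
                         primary@recognition)
    for (p in cs$secondarySites)
      plant <- add_plant(sprintf("%s@%d", secondary@name, p), p,
                         secondary@recognition)
    if (!is.null(cs$ctcf) && nrow(cs$ctcf)) {
      lab <- if (!is.null(cs$ctcf$label)) cs$ctcf$label
             else sprintf("ctcf%d", seq_len(nrow(cs$ctcf)))
      for (i in seq_len(nrow(cs$ctcf)))
        plant <- add_plant(lab[i], cs$ctcf$pos[i],
                           if (cs$ctcf$orientation[i] == "forward") motifF
                           else motifR)
    }
    if (nrow(plant)) {
      if (any(plant$pos < 0) || any(plant$pos + nchar(plant$seq) > L))
        stop(sprintf("contig %s: planted element outside [0, %d)", nm, L))
      o <- order(plant$pos)
      plant <- plant[o, ]
      ends <- plant$pos + nchar(plant$seq)
      clash <- which(plant$pos[-1] < ends[-nrow(plant)])
      if (length(clash))
        stop(sprintf("contig %s: planted elements overlap: %s and %s",
                     nm, plant$what[clash[1]], plant$what[clash[1] + 1L]))
    }
    seqs[nm] <- .with_seed(seed + length(seqs),
                           .screened_sequence(L, plant, patterns))
    orig[nm] <- origin

    if (!is.null(cs$ctcf) && nrow(cs$ctcf)) {
      lab <- if (!is.null(cs$ctcf$label)) cs$ctcf$label
             else sprintf("ctcf%d", seq_len(nrow(cs$ctcf)))
      ctcf_all <- c(ctcf_all, GRanges(nm,
        IRanges(origin + cs$ctcf$pos + 1, width = nchar(motifF)),
        orientation = cs$ctcf$orientation, label = lab))
    }
    if (!is.null(cs$modules) && nrow(cs$modules)) {
      m <- GRanges(nm, IRanges(origin + cs$modules$start + 1,
                               origin + cs$modules$end))
      names(m) <- cs$modules$name
      mod_all <- c(mod_all, m)
    }
  }
  new("ToyGenome",
      sequences = Biostrings::DNAStringSet(seqs),
      origin = orig, ctcfSites = ctcf_all, modules = mod_all)
}

# Build one contig: random filler, planted elements, then iterative
# re-randomisation of any accidental pattern occurrence until clean.
.screened_sequence <- function(L, plant, patterns, maxIter = 50L) {
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  protected <- rep(FALSE, L)
  planted_at <- list()  # pattern -> planted 0-based positions
  for (i in seq_len(nrow(plant))) {
    p0 <- plant$pos[i]; sq <- strsplit(plant$seq[i], "")[[1]]
    idx <- (p0 + 1):(p0 + length(sq))
    chars[idx] <- sq
    protected[idx] <- TRUE
    planted_at[[plant$seq[i]]] <- c(planted_at[[plant$seq[i]]], p0)
  }
  for (iter in seq_len(maxIter)) {
    s <- Biostrings::DNAString(paste(chars, collapse = ""))
    bad <- integer(0)
    for (pat in patterns) {
      occ <- Biostrings::start(Biostrings::matchPattern(pat, s)) - 1L
      occ <- setdiff(occ, planted_at[[pat]])
      for (p0 in occ) {
        idx <- (p0 + 1):(p0 + nchar(pat))
        free <- idx[!protected[idx]]
        if (length(free) == 0L)
          stop(sprintf("accidental '%s' occurrence at %d lies entirely within planted elements; spec is infeasible",
                       pat, p0))
        bad <- c(bad, free)
      }
    }
    if (length(bad) == 0L)
      return(paste(chars, collapse = ""))
    bad <- unique(bad)
    chars[bad] <- sample(c("A", "C", "G", "T"), length(bad), replace = TRUE)
  }
  stop("filler screening did not converge; spec too dense with planted elements")
}

#' Export toy-genome sequence and annotations
#'
#' Writes the genome FASTA, planted CTCF sites as a stranded 6-column BED
#' (forward = `+`, reverse = `-`) and enhancer modules as BED. All BED
#' coordinates are 0-based half-open and origin-shifted.
#'
#' @param genome A [ToyGenome-class].
#' @param prefix Output path prefix; files `<prefix>.fa`,
#'   `<prefix>.ctcf.bed`, `<prefix>.modules.bed` are created.
#' @return Named character vector of the files written, invisibly.
#' @export
exportToyGenome <- function(genome, prefix) {
  fa <- paste0(prefix, ".fa")
  Biostrings::writeXStringSet(sequences(genome), fa)
  out <- c(fasta = fa)
  sites <- ctcfSites(genome)
  if (length(sites)) {
    bed <- paste0(prefix, ".ctcf.bed")
    gr <- sites
    strand(gr) <- ifelse(mcols(gr)$orientation == "forward", "+", "-")
    names(gr) <- mcols(gr)$label
    mcols(gr) <- S4Vectors::DataFrame(score = rep(0L, length(gr)))
    rtracklayer::export(gr, bed, format = "BED")
    out["ctcf"] <- bed
  }
  mods <- enhancerModules(genome)
  if (length(mods)) {
    bed <- paste0(prefix, ".modules.bed")
    rtracklayer::export(mods, bed, format = "BED")
    out["modules"] <- bed
  }
  invisible(out)
}
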