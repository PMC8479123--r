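pair_records <- function(qname, c1, p1, c2, p2, rl = 50L, mapq = 60L) {
  rbind(sam_row(qname, 97L, c1, p1, mapq = mapq,
                cigar = sprintf("%dM", rl), rnext = c2, pnext = p2),
        sam_row(qname, 145L, c2, p2, mapq = mapq,
                cigar = sprintf("%dM", rl), rnext = c1, pnext = p1))
}

test_that("trans and long-insert pairs are discordant, proper FR pairs are not", {
  rec <- rbind(
    pair_records("trans", "chrT3", 1000L, "chrT8", 5000L),
    pair_records("near", "chrT3", 1000L, "chrT3", 1250L))
  fd <- findDiscordant(rec, maxConcordantInsert = 1000)
  expect_equal(fd$pairs$qname, "trans")
  expect_equal(fd$nConcordant, 1L)
  # same orientation class on one contig is discordant even if close
  ff <- rbind(sam_row("rr", 65L, "c", 100L), sam_row("rr", 129L, "c", 300L))
  expect_equal(nrow(findDiscordant(ff)$pairs), 1L)
})

test_that("low-quality pairs are dropped and unpaired input is an error", {
  rec <- pair_records("lowq", "chrT3", 1000L, "chrT8", 5000L, mapq = 3L)
  fd <- findDiscordant(rec, minMapq = 10)
  expect_equal(nrow(fd$pairs), 0L)
  expect_equal(fd$nLowMapq, 1L)
  expect_error(findDiscordant(sam_row("se", 0L, "c", 1L)), "unpaired")
})

test_that("clustering reports innermost edges and respects min support", {
  mk <- function(starts1, starts2) data.frame(
    qname = sprintf("p%d", seq_along(starts1)),
    contigA = "chrA", startA = starts1, endA = starts1 + 50, strandA = "+",
    contigB = "chrB", startB = starts2, endB = starts2 + 50, strandB = "-",
    stringsAsFactors = FALSE)
  pairs <- mk(c(4930, 4940, 4945), c(8000, 8010, 8030))
  cand <- clusterCandidates(pairs, clusterWindow = 1000, minSupport = 2)
  expect_length(cand, 1L)
  expect_equal(cand[[1]]@posA, 4995)          # innermost = max end
  expect_equal(cand[[1]]@posB, 8000)          # innermost = min start
  expect_equal(cand[[1]]@supportPairs, 3L)
  expect_equal(cand[[1]]@resolution, "interval")
  # a single pair below min support yields nothing
  expect_length(clusterCandidates(mk(100, 200), minSupport = 2), 0L)
  # two clusters 10 kb apart stay separate
  two <- mk(c(1000, 1050, 11000, 11050), c(500, 520, 9000, 9020))
  expect_length(clusterCandidates(two, 1000, 2), 2L)
})

test_that("clustering output is invariant under input shuffling", {
  set.seed(13)
  base <- data.frame(
    qname = sprintf("p%d", 1:8),
    contigA = "chrA", startA = c(1000, 1100, 1040, 9000, 9100, 9050, 1020, 9020),
    endA = c(1000, 1100, 1040, 9000, 9100, 9050, 1020, 9020) + 50,
    strandA = "+",
    contigB = "chrB", startB = c(500, 560, 540, 7000, 7040, 7100, 520, 7020),
    endB = c(500, 560, 540, 7000, 7040, 7100, 520, 7020) + 50,
    strandB = "-", stringsAsFactors = FALSE)
  ref <- breakpointTable(clusterCandidates(base))
  for (i in 1:5) {
    sh <- base[sample(nrow(base)), ]
    expect_equal(breakpointTable(clusterCandidates(sh)), ref)
  }
})

test_that("split-read refinement recovers the exact simulated junction", {
  t38 <- t38_fixture()
  cfg <- simulationConfig(seed = 5, nReads = 300, readLength = 100,
                          insertMean = 500, insertSd = 50,
                          junctionSpanFraction = 0.2)
  cap <- simulateCapturePairs(t38$genome, t38$der, cfg)
  fd <- findDiscordant(cap$sam)
  expect_equal(sort(fd$pairs$qname),
               sort(cap$truth$qname[cap$truth$straddles]))
  cand <- clusterCandidates(fd$pairs)
  expect_length(cand, 1L)
  ref <- refineJunction(cand[[1]], cap$spanningReads, t38$genome)
  bt <- breakpointTable(ref)
  expect_equal(bt$pos_a, 168917999)
  expect_equal(bt$pos_b, 130487191)
  expect_equal(bt$resolution, "exact")
  expect_equal(bt$support_split, length(cap$spanningReads))
})

test_that("refinement without spanning reads leaves the candidate unchanged", {
  t38 <- t38_fixture()
  cand <- new("Breakpoint", contigA = "chrT3", posA = 168917900,
              sideA = "left-of", contigB = "chrT8", posB = 130487100,
              sideB = "right-of", supportPairs = 5L, supportSplit = 0L,
              resolution = "interval", intervalWidth = 200)
  out <- refineJunction(cand, Biostrings::DNAStringSet(), t38$genome)
  expect_equal(out@resolution, "interval")
  expect_equal(out@posA, 168917900)
})

test_that("the modal junction wins a split vote", {
  # two adjacent junctions 7 vs 3: build reads by hand from two derivatives
  t38 <- t38_fixture()
  derB <- buildDerivative(
    new("Breakpoint", contigA = "chrT3", posA = 168917999 + 40,
        sideA = "left-of", contigB = "chrT8", posB = 130487190 + 40,
        sideB = "right-of", supportPairs = 0L, supportSplit = 1L,
        resolution = "exact", intervalWidth = 0),
    t38$genome, name = "alt")
  s1 <- derivativeSequence(t38$genome, t38$der)
  s2 <- derivativeSequence(t38$genome, derB)
  J <- 168917999 - 168800000
  mk <- function(s, n) Biostrings::DNAStringSet(
    vapply(seq_len(n), function(i)
      as.character(Biostrings::subseq(s, J - 50 + i, J + 49 + i)),
      character(1)))
  reads <- c(mk(s1, 7), mk(s2, 3))
  cand <- new("Breakpoint", contigA = "chrT3", posA = 168917990,
              sideA = "left-of", contigB = "chrT8", posB = 130487180,
              sideB = "right-of", supportPairs = 10L, supportSplit = 0L,
              resolution = "interval", intervalWidth = 100)
  ref <- refineJunction(cand, reads, t38$genome)
  expect_equal(ref@posA, 168917999)
  expect_equal(ref@supportSplit, 7L)
})

test_that("derivative construction conserves segment arithmetic", {
  ext <- list(cA = c(0, 200), cB = c(0, 200))
  bp <- new("Breakpoint", contigA = "cA", posA = 100, sideA = "left-of",
            contigB = "cB", posB = 50, sideB = "right-of",
            supportPairs = 2L, supportSplit = 0L, resolution = "interval",
            intervalWidth = 10)
  der <- buildDerivative(bp, ext)
  expect_equal(derivativeLength(der), 100 + 150)
  both <- buildDerivative(bp, ext, reciprocal = TRUE)
  expect_length(both, 2L)
  expect_equal(derivativeLength(both[[2]]), 400 - 250)
  # inversion-style: minus-strand second segment conserves length
  inv <- derivativeChromosome("inv", data.frame(
    contig = c("cA", "cA"), start = c(0, 100), end = c(100, 200),
    strand = c("+", "-")))
  expect_equal(derivativeLength(inv), 200)
  # degenerate segments rejected
  bp0 <- initialize(bp, posA = 0)
  expect_error(buildDerivative(bp0, ext), "bounds|degenerate")
})

test_that("coordinate maps follow the worked examples and invert exactly", {
  der <- derivativeChromosome("d", data.frame(
    contig = c("c1", "c2"), start = c(0, 50), end = c(100, 150),
    strand = c("+", "+")))
  expect_equal(mapToDerivative(der, "c2", 60), 110)
  derM <- derivativeChromosome("d", data.frame(
    contig = c("c1", "c2"), start = c(0, 50), end = c(100, 150),
    strand = c("+", "-")))
  expect_equal(mapToDerivative(derM, "c2", 60), 189)
  # typed not-covered result
  expect_true(is.na(mapToDerivative(der, "c2", 10)))
  expect_true(is.na(mapFromDerivative(der, 500)$pos))
  # round trip on random covered positions, + and - segments
  set.seed(19)
  for (d in list(der, derM)) {
    pos <- sample(0:199, 400, replace = TRUE)
    back <- mapFromDerivative(d, pos)
    expect_equal(mapToDerivative(d, back$contig, back$pos), as.numeric(pos))
  }
})

test_that("breakpoints export as TSV and BEDPE", {
  bp <- new("Breakpoint", contigA = "chrT3", posA = 168917999,
            sideA = "left-of", contigB = "chrT8", posB = 130487190,
            sideB = "right-of", supportPairs = 80L, supportSplit = 80L,
            resolution = "exact", intervalWidth = 0)
  out <- writeBreakpoints(list(bp), tempfile())
  tsv <- read.table(out[["tsv"]], header = TRUE, sep = "\t")
  expect_equal(tsv$pos_a, 168917999)
  expect_equal(tsv$pos_b, 130487191)
  bedpe <- read.table(out[["bedpe"]], sep = "\t")
  expect_equal(bedpe$V2, 168917998)  # 0-based start of the last kept base
  expect_equal(bedpe$V5, 130487190)
})

test_that("derivative segment tables round-trip through disk", {
  t38 <- t38_fixture()
  f <- tempfile()
  writeDerivative(t38$der, f)
  rt <- readDerivative(f, name = "der3")
  expect_equal(segments(rt), segments(t38$der))
})
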