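write_bed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

test_that("stranded BED sites load with orientations", {
  f <- write_bed(c("chrT\t100\t119\tctcf1\t0\t+",
                   "chrT\t300\t319\tctcf2\t0\t-"))
  sites <- loadSites(f)
  expect_equal(S4Vectors::mcols(sites)$orientation, c("forward", "reverse"))
  expect_equal(GenomicRanges::start(sites), c(101, 301))
  expect_equal(S4Vectors::mcols(sites)$label, c("ctcf1", "ctcf2"))
})

test_that("unstranded records are skipped and malformed lines named", {
  f <- write_bed(c("chrT\t100\t119\tctcf1\t0\t+",
                   "chrT\t200\t219\tctcf2\t0\t."))
  expect_warning(sites <- loadSites(f), "without strand")
  expect_length(sites, 1L)
  bad <- write_bed(c("chrT\t100\t119\tctcf1\t0\t+", "chrT\t100"))
  expect_error(loadSites(bad), "line 2")
  bad2 <- write_bed("chrT\tabc\tdef\tx\t0\t+")
  expect_error(loadSites(bad2), "line 1")
})

site_df <- function(pos, ori) data.frame(
  contig = "c", start = pos, end = pos, orientation = ori,
  label = sprintf("s%d", seq_along(pos)), stringsAsFactors = FALSE)

test_that("convergent pairs match the worked examples", {
  sites <- site_df(c(100, 200, 300, 400),
                   c("forward", "forward", "reverse", "reverse"))
  expect_equal(nrow(convergentPairs(sites)), 4L)
  p250 <- convergentPairs(sites, maxSpan = 250)
  expect_equal(nrow(p250), 3L)
  expect_true(all(p250$span <= 250))
  expect_equal(nrow(convergentPairs(site_df(c(1, 2), c("reverse", "reverse")))),
               0L)
  # sorted by span ascending
  expect_false(is.unsorted(convergentPairs(sites)$span))
})

test_that("convergent pairs equal the exhaustive oracle on random sets", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    pos <- sort(sample(1:100000, n))
    ori <- sample(c("forward", "reverse"), n, replace = TRUE)
    maxSpan <- if (runif(1) < 0.5) NULL else sample(1000:50000, 1)
    got <- convergentPairs(site_df(pos, ori), maxSpan = maxSpan)
    want <- oracle_convergent(pos, ori, maxSpan)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$span, want$span)
  }
})

test_that("orientation flips when sites map through an inverted segment", {
  der <- derivativeChromosome("d", data.frame(
    contig = c("c1", "c2"), start = c(0, 0), end = c(1000, 1000),
    strand = c("+", "-")))
  sites <- data.frame(contig = c("c1", "c2"), start = c(100, 500),
                      end = c(120, 520),
                      orientation = c("forward", "forward"),
                      label = c("f1", "f2"), stringsAsFactors = FALSE)
  pairs <- convergentPairs(sites, der = der)
  # the c2 forward site becomes reverse on the derivative => one pair
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$forward, "f1")
  expect_equal(pairs$reverse, "f2")
})

# --- docking-preservation truth table on hand-built toys --------------------

toy_anchor <- function(ori = "forward")
  promoterAnchor("c3", promoterPos = 1000, siteStart = 890, siteEnd = 910,
                 siteOrientation = ori)

partner_rev <- data.frame(contig = "c8", start = 5500, end = 5520,
                          orientation = "reverse", label = "partnerR",
                          stringsAsFactors = FALSE)

test_that("docking site and promoter on one segment are preserved", {
  der <- derivativeChromosome("d", data.frame(
    contig = c("c8", "c3"), start = c(5000, 500), end = c(6000, 2000),
    strand = "+"))
  v <- dockingPreserved(toy_anchor(), der)
  expect_true(v$covered)
  expect_true(v$preserved)
})

test_that("a junction between site and promoter breaks preservation", {
  der <- derivativeChromosome("d", data.frame(
    contig = c("c8", "c3"), start = c(5000, 950), end = c(6000, 2000),
    strand = "+"))
  v <- dockingPreserved(toy_anchor(), der)
  expect_true(v$covered)
  expect_false(v$preserved)
})

test_that("a junction through the site truncates it", {
  der <- derivativeChromosome("d", data.frame(
    contig = c("c8", "c3"), start = c(5000, 900), end = c(6000, 2000),
    strand = "+"))
  v <- dockingPreserved(toy_anchor(), der)
  expect_false(v$preserved)
  expect_match(v$details, "truncated")
})

test_that("an uncovered promoter gives a typed not-covered verdict", {
  der <- derivativeChromosome("d", data.frame(
    contig = "c8", start = 0, end = 6000, strand = "+"))
  v <- dockingPreserved(toy_anchor(), der)
  expect_false(v$covered)
  expect_false(v$preserved)
})

test_that("a reverse-oriented docking site cannot dock", {
  der <- derivativeChromosome("d", data.frame(
    contig = c("c8", "c3"), start = c(5000, 500), end = c(6000, 2000),
    strand = "+"))
  v <- dockingPreserved(toy_anchor("reverse"), der)
  expect_true(v$covered)
  expect_false(v$preserved)
})

test_that("reverse partner sites enable a convergent loop across the junction", {
  der <- derivativeChromosome("d", data.frame(
    contig = c("c3", "c8"), start = c(500, 5000), end = c(2000, 6000),
    strand = "+"))
  v <- dockingPreserved(toy_anchor(), der, partnerSites = partner_rev)
  expect_true(v$preserved)
  expect_true(v$convergentPartnerPossible)
  expect_equal(v$pairs$reverse, "partnerR")
  # all-forward partner sites cannot pair
  fwd <- partner_rev; fwd$orientation <- "forward"
  v2 <- dockingPreserved(toy_anchor(), der, partnerSites = fwd)
  expect_false(v2$convergentPartnerPossible)
})

test_that("preservation is monotone as the junction moves away", {
  # holding sides fixed, moving the junction farther upstream of the
  # site/promoter block never flips preserved from TRUE to FALSE
  was_preserved <- FALSE
  for (cut in c(950, 905, 880, 700, 300)) {
    der <- derivativeChromosome("d", data.frame(
      contig = c("c8", "c3"), start = c(5000, cut), end = c(6000, 2000),
      strand = "+"))
    v <- dockingPreserved(toy_anchor(), der)
    if (was_preserved) expect_true(v$preserved)
    was_preserved <- was_preserved || v$preserved
  }
  expect_true(was_preserved)
})

# --- module quantification ---------------------------------------------------

toy_modules <- function() {
  m <- GenomicRanges::GRanges("c", IRanges::IRanges(c(101, 501), c(200, 600)))
  names(m) <- c("M1", "M2")
  m
}

test_that("module counting uses >= 1 bp overlap, once per read", {
  reads <- GenomicRanges::GRanges("c", IRanges::IRanges(
    c(90, 150, 200, 550), c(110, 160, 250, 560)))
  q <- moduleQuantify(reads, toy_modules(), librarySizes = 4)
  expect_equal(q$count_sample1, c(3L, 1L))
  expect_equal(q$rpkm_sample1, c(3, 1) * 1e9 / (4 * 100))
})

test_that("empty modules and identical samples behave as expected", {
  reads <- GenomicRanges::GRanges("c", IRanges::IRanges(150, 160))
  q <- moduleQuantify(list(a = reads, b = reads), toy_modules(),
                      librarySizes = c(1, 1))
  expect_equal(q$count_a[2], 0L)
  expect_equal(q$rpkm_a[2], 0)
  expect_equal(q$log2FC, c(0, 0))
  expect_error(moduleQuantify(reads, toy_modules(), librarySizes = 0),
               "positive")
})

test_that("module counts are read-order invariant and RPKM scales with depth", {
  set.seed(29)
  reads <- GenomicRanges::GRanges("c", IRanges::IRanges(
    sample(1:700, 100, replace = TRUE), width = 30))
  q1 <- moduleQuantify(reads, toy_modules(), librarySizes = 100)
  q2 <- moduleQuantify(reads[sample(length(reads))], toy_modules(),
                       librarySizes = 100)
  expect_equal(q1$count_sample1, q2$count_sample1)
  qHalf <- moduleQuantify(reads, toy_modules(), librarySizes = 200)
  expect_equal(qHalf$rpkm_sample1, q1$rpkm_sample1 / 2)
})
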