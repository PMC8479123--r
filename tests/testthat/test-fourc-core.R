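vp_toy <- function(primer = "ACGTGATC", radius = 1L)
  viewpoint("VP", "chrT", 5, primer, exclusionRadius = radius)

test_that("demultiplexing clips primers down to the primary motif", {
  reads <- Biostrings::DNAStringSet(c(r1 = "ACGTGATCTTTT", r2 = "TTTTTTTT"))
  dm <- demultiplexAndClip(reads, list(vp_toy()))
  expect_equal(as.character(dm$assigned$VP), c(r1 = "GATCTTTT"))
  expect_equal(dm$nUnassigned, 1L)
  expect_equal(dm$summary$n[dm$summary$viewpoint == "unassigned"], 1L)
})

test_that("empty input demultiplexes to empty outputs", {
  dm <- demultiplexAndClip(Biostrings::DNAStringSet(), list(vp_toy()))
  expect_length(dm$assigned$VP, 0L)
  expect_equal(dm$nTotal, 0L)
})

test_that("indistinguishable primers are rejected at load time", {
  vps <- list(vp_toy(), viewpoint("VP2", "chrT", 50, "ACGTGATC"))
  expect_error(demultiplexAndClip(Biostrings::DNAStringSet("AAAA"), vps),
               "indistinguishable")
  # one mismatch apart is fine at maxMismatch 0 but not at 1
  vps2 <- list(vp_toy(), viewpoint("VP2", "chrT", 50, "ACGGGATC"))
  expect_silent(demultiplexAndClip(Biostrings::DNAStringSet(), vps2))
  expect_error(demultiplexAndClip(Biostrings::DNAStringSet(), vps2,
                                  maxMismatch = 1L), "indistinguishable")
})

test_that("viewpoint primers must end in the primary motif", {
  expect_error(viewpoint("bad", "chrT", 1, "ACGTAAAA"), "primary motif")
})

test_that("trimmed reads map to unique fragment-end k-mers", {
  catalog <- data.frame(
    fragmentId = c(7L, 8L, 9L, 7L),
    side = c("left", "left", "left", "right"),
    strand = c("+", "+", "+", "-"),
    kmer = c("GATCAA", "GATCCC", "GATCGG", "TTACGA"),
    stringsAsFactors = FALSE)
  reads <- Biostrings::DNAStringSet(c(
    uniq = "GATCAATTTT",       # unique left hit
    right = "GATCTTACGATT",    # unique right hit after the motif
    none = "GATCTGTGTGTG",     # no hit
    tiny = "GAT"))             # shorter than k
  asg <- mapTrimmedReads(reads, catalog, 6)
  expect_equal(asg$status, c("assigned", "assigned", "unmapped", "short"))
  expect_equal(asg$fragmentId[1:2], c(7L, 7L))
  expect_equal(asg$side[1:2], c("left", "right"))
})

test_that("multi-hit reads are ambiguous and dropped", {
  catalog <- data.frame(fragmentId = c(1L, 2L), side = c("left", "left"),
                        strand = "+", kmer = c("GATCAA", "GATCAA"),
                        stringsAsFactors = FALSE)
  asg <- mapTrimmedReads(Biostrings::DNAStringSet("GATCAATT"), catalog, 6)
  expect_equal(asg$status, "ambiguous")
  expect_true(is.na(asg$fragmentId))
})

test_that("alignment-based assignment applies the strand-aware 5' rule", {
  # three fragments: [0,2), [2,16), [16,22)
  m <- example_map()
  rec <- rbind(
    sam_row("fwd_at_start", 0L, "chrT", 3L, cigar = "4M"),   # starts at 2
    sam_row("mid_fragment", 0L, "chrT", 8L, cigar = "4M"),
    sam_row("rev_at_end", 16L, "chrT", 13L, cigar = "4M"),   # ends at 16
    sam_row("off_contig", 0L, "chrX", 1L, cigar = "4M"))
  expect_warning(asg <- assignFromAlignments(rec, m, boundaryTolerance = 2),
                 "chrX")
  expect_equal(asg$status,
               c("assigned", "filtered", "assigned", "filtered"))
  expect_equal(asg$fragmentId[1], 2L)
  expect_equal(asg$side[1], "left")
  expect_equal(asg$fragmentId[3], 2L)
  expect_equal(asg$side[3], "right")
})

test_that("contact counting applies the viewpoint exclusion radius", {
  g <- toyGenomeFromSeq(c(chrT = paste0(
    strrep("A", 20), "GATC", strrep("C", 20), "GATC", strrep("T", 20),
    "GATC", strrep("G", 20), "GATC", strrep("A", 20))))
  m <- digest(g)   # 5 fragments
  asg <- data.frame(read = sprintf("r%d", 1:4),
                    fragmentId = c(2L, 2L, 2L, 4L), side = "left",
                    status = "assigned", stringsAsFactors = FALSE)
  vp <- viewpoint("VP", "chrT", 30, "AAGATC", exclusionRadius = 1L)
  prof <- countContacts(asg, vp, m)
  expect_equal(sum(contactCounts(prof)), 1)            # only fragment 4
  expect_equal(unname(contactCounts(prof)["4"]), 1)
  expect_equal(unname(readStats(prof)["nExcluded"]), 3)
  expect_false("2" %in% names(contactCounts(prof)))
  # radius 0: the viewpoint fragment itself is still excluded
  vp0 <- viewpoint("VP", "chrT", 30, "AAGATC", exclusionRadius = 0L)
  prof0 <- countContacts(asg, vp0, m)
  expect_false("2" %in% names(contactCounts(prof0)))
  expect_true(all(c("1", "3") %in% names(contactCounts(prof0))))
})

test_that("counting fails when the viewpoint is uncovered", {
  m <- example_map()
  vp <- viewpoint("VP", "chrMissing", 5, "ACGTGATC")
  asg <- data.frame(read = character(0), fragmentId = integer(0),
                    side = character(0), status = character(0))
  expect_error(countContacts(asg, vp, m), "not covered")
})

test_that("read bookkeeping conserves every input read", {
  study <- study_locus()
  cfg <- simulationConfig(seed = 21, nReads = 2000, readLength = 50)
  sim <- simulate4CReads(study$genome, study$map, study$vp, study$model, cfg)
  dm <- demultiplexAndClip(sim$reads, list(study$vp))
  catalog <- endCatalog(study$map, study$genome, 20)
  asg <- mapTrimmedReads(dm$assigned[[1]], catalog, 20)
  prof <- countContacts(asg, study$vp, study$map,
                        nUnassigned = dm$nUnassigned,
                        nAmbiguousDemux = dm$nAmbiguous)
  s <- readStats(prof)
  expect_equal(unname(s["nTotal"]), 2000)
  expect_equal(unname(sum(contactCounts(prof)) + s["nExcluded"] +
                 s["nUnmapped"] + s["nAmbiguous"] + s["nUnassigned"] +
                 s["nShort"]), 2000)
})

test_that("the full pipeline reproduces simulator ground truth exactly", {
  study <- study_locus()
  cfg <- simulationConfig(seed = 33, nReads = 3000, readLength = 50)
  sim <- simulate4CReads(study$genome, study$map, study$vp, study$model, cfg)
  dm <- demultiplexAndClip(sim$reads, list(study$vp))
  catalog <- endCatalog(study$map, study$genome, 20)
  asg <- mapTrimmedReads(dm$assigned[[1]], catalog, 20)
  expect_true(all(asg$status == "assigned"))
  expect_equal(asg$fragmentId, sim$truth$fragmentId)
  expect_equal(asg$side, sim$truth$side)
})
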