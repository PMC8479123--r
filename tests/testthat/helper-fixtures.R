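# Shared fixtures and independent oracles, built in code at test time.

# the worked-example sequence: GATC at 2 and 16, GTAC at 10
example_seq <- "AAGATCTTTTGTACTTGATCAA"

example_genome <- function() toyGenomeFromSeq(c(chrT = example_seq))

# brute-force digestion oracle: scan every position for the recognition
# sequence with plain string comparison, then build intervals
oracle_digest <- function(seq, recognition = "GATC", cutOffset = 0L) {
  L <- nchar(seq)
  k <- nchar(recognition)
  occ <- which(vapply(seq_len(L - k + 1),
                      function(i) substr(seq, i, i + k - 1) == recognition,
                      logical(1))) - 1L
  cuts <- sort(unique(c(0L, occ + cutOffset, L)))
  s <- cuts[-length(cuts)]; e <- cuts[-1]
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

# brute-force running-mean oracle: double loop, shrink edges
oracle_running_mean <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    mean(x[idx])
  }, numeric(1))
}

# exhaustive convergent-pair oracle over all ordered site pairs
oracle_convergent <- function(pos, ori, maxSpan = NULL) {
  out <- data.frame(i = integer(0), j = integer(0), span = numeric(0))
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (pos[i] < pos[j] && ori[i] == "forward" && ori[j] == "reverse") {
      sp <- pos[j] - pos[i]
      if (is.null(maxSpan) || sp <= maxSpan)
        out <- rbind(out, data.frame(i = i, j = j, span = sp))
    }
  }
  out[order(out$span), , drop = FALSE]
}

# a 3-fragment toy map over the worked-example sequence
example_map <- function() annotateSecondary(digest(example_genome()),
                                            example_genome())

# minimal SAM record row
sam_row <- function(qname, flag, rname, pos, mapq = 60L, cigar = "50M",
                    rnext = "=", pnext = 1L, tlen = 0L,
                    seq = strrep("A", 50), qual = strrep("I", 50)) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

# cached study fixtures (built once per test run)
.fixture_env <- new.env()

study_locus <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- exampleFourCLocus(seed = 1)
  .fixture_env$study
}

t38_fixture <- function() {
  if (is.null(.fixture_env$t38))
    .fixture_env$t38 <- exampleT38Genome(seed = 1)
  .fixture_env$t38
}
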