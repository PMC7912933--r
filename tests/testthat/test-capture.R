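# withr only used for temp files in io tests; capture tests are in-memory

test_that("an exact implant yields one full-length forward match", {
  set.seed(21)
  probe <- rand_seq(500)
  genome <- c(chr1 = paste0("AAAA", probe, "TTTT"))
  mm <- find_exact_matches(genome, probe, min_match_len = 20)
  mm <- mm[mm$length == 500, ]
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$ref_start, 5L)
  expect_equal(mm$ref_end, 504L)
  expect_equal(mm$qry_start, 1L)
  expect_equal(mm$qry_end, 500L)
  expect_equal(mm$strand, "forward")
})

test_that("a reverse-complement implant is found on the reverse strand", {
  set.seed(22)
  probe <- rand_seq(500)
  genome <- c(chr1 = paste0("AAAA", revcomp(probe), "TTTT"))
  mm <- find_exact_matches(genome, probe, min_match_len = 20)
  mm <- mm[mm$length == 500, ]
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$strand, "reverse")
  expect_equal(c(mm$ref_start, mm$ref_end), c(5L, 504L))
  expect_equal(c(mm$qry_start, mm$qry_end), c(1L, 500L))
})

test_that("match finding agrees with the per-diagonal run oracle", {
  set.seed(23)
  for (rep in 1:6) {
    glen <- sample(2000:10000, 1)
    g <- strsplit(rand_seq(glen), "")[[1]]
    probe <- rand_seq(300)
    pos <- sample(glen - 400, 1)
    pc <- strsplit(probe, "")[[1]]
    subs <- sample(300, 5)
    for (s in subs) pc[s] <- sample(setdiff(c("A", "C", "G", "T"),
                                            pc[s]), 1)
    g[pos:(pos + 299)] <- pc
    genome <- c(ctg = paste(g, collapse = ""))
    k <- sample(c(12, 20), 1)
    got <- find_exact_matches(genome, probe, min_match_len = k)
    fwd <- got[got$strand == "forward",
               c("ref_start", "ref_end", "qry_start", "qry_end", "length")]
    exp_fwd <- mem_oracle(genome[[1]], probe, k)
    expect_equal(unname(as.matrix(fwd)), unname(as.matrix(exp_fwd)))
    # reverse strand against independently mapped oracle coordinates
    rc <- revcomp(probe)
    exp_rc <- mem_oracle(genome[[1]], rc, k)
    if (nrow(exp_rc)) {
      m <- nchar(probe)
      tmp <- exp_rc
      tmp$qry_start <- m - exp_rc$qry_end + 1L
      tmp$qry_end <- m - exp_rc$qry_start + 1L
      tmp <- tmp[order(tmp$ref_start, tmp$qry_start), ]
    } else tmp <- exp_rc
    rev <- got[got$strand == "reverse",
               c("ref_start", "ref_end", "qry_start", "qry_end", "length")]
    expect_equal(unname(as.matrix(rev)), unname(as.matrix(tmp)))
  }
})

test_that("N runs break exact matches", {
  set.seed(24)
  probe <- rand_seq(60)
  genome <- c(chr = paste0("CCCC", substr(probe, 1, 30), "N",
                           substr(probe, 31, 60), "GGGG"))
  mm <- find_exact_matches(genome, probe, min_match_len = 20)
  expect_true(all(mm$length <= 30))
  expect_false(any(mm$length >= 31))
})

test_that("chaining matches the exhaustive subset oracle", {
  set.seed(25)
  for (rep in 1:8) {
    n <- sample(4:11, 1)
    reverse <- rep %% 2 == 0
    mm <- data.frame(
      contig = "c", strand = if (reverse) "reverse" else "forward",
      ref_start = sort(sample(1000, n)), stringsAsFactors = FALSE)
    mm$length <- sample(10:80, n, replace = TRUE)
    mm$ref_end <- mm$ref_start + mm$length - 1L
    mm$qry_start <- sample(500, n)
    mm$qry_end <- mm$qry_start + mm$length - 1L
    got <- chain_matches(mm, probe_len = 600, max_gap = Inf)
    expect_equal(max(got$matched_bases), chain_oracle(mm, reverse))
  }
})

test_that("chain coverage follows the covered-bases arithmetic", {
  mm <- data.frame(contig = "c", strand = "forward",
                   ref_start = c(101L, 301L), ref_end = c(200L, 450L),
                   qry_start = c(1L, 151L), qry_end = c(100L, 300L),
                   length = c(100L, 150L), stringsAsFactors = FALSE)
  ch <- chain_matches(mm, probe_len = 300)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$coverage, 250 / 300)
  expect_equal(c(ch$S1, ch$E1), c(101L, 450L))
  # single match
  ch1 <- chain_matches(mm[1, ], probe_len = 300)
  expect_equal(ch1$coverage, 100 / 300)
  # adding a colinear match never decreases coverage
  expect_gte(ch$coverage, ch1$coverage)
})

test_that("extract_region uses 1-based inclusive faidx semantics", {
  g <- c(chr = "ACGTACGT")
  expect_equal(extract_region(g, "chr", 2, 4), "CGT")
  expect_equal(extract_region(g, "chr", 2, 4, "reverse"), "ACG")
  expect_error(extract_region(g, "nope", 1, 2), "unknown contig")
  expect_error(extract_region(g, "chr", 0, 2), "out of range")
  expect_error(extract_region(g, "chr", 3, 9), "out of range")
  set.seed(26)
  for (rep in 1:20) {
    s <- rand_seq(200)
    i <- sample(200, 1); j <- sample(i:200, 1)
    expect_equal(extract_region(c(x = s), "x", i, j), substr(s, i, j))
    expect_equal(extract_region(c(x = s), "x", i, j, "reverse"),
                 revcomp(substr(s, i, j)))
  }
})

test_that("exact implants are captured verbatim with exact coordinates", {
  set.seed(27)
  probe <- rand_seq(400)
  imp <- implant_markers(8000, data.frame(
    marker = "m", sequence = probe, position = 3001, strand = "forward"),
    seed = 101)
  hit <- capture_marker(imp$genome, probe, genome_id = "g")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$hit_id, "g")
  expect_equal(c(hit$S1, hit$E1), c(3001L, 3400L))
  expect_equal(hit$sequence, probe)
  expect_equal(hit$coverage, 1)
})

test_that("capture is strand-symmetric under contig reverse-complement", {
  set.seed(28)
  probe <- rand_seq(300)
  imp <- implant_markers(5000, data.frame(
    marker = "m", sequence = probe, position = 2001, strand = "forward"),
    seed = 102)
  fwd <- capture_marker(imp$genome, probe, genome_id = "g")
  flipped <- setNames(revcomp(imp$genome[[1]]), names(imp$genome))
  rev <- capture_marker(flipped, probe, genome_id = "g")
  expect_equal(rev$sequence, fwd$sequence)
  expect_equal(rev$strand, "reverse")
  glen <- nchar(imp$genome[[1]])
  expect_equal(rev$S1, glen - fwd$E1 + 1L)
  expect_equal(rev$E1, glen - fwd$S1 + 1L)
})

test_that("two diverged copies are both captured (multi-copy/hybrid case)", {
  set.seed(29)
  probe <- rand_seq(400)
  # second copy diverged at interior sites
  pc <- strsplit(probe, "")[[1]]
  for (s in sample(30:370, 8)) pc[s] <- sample(setdiff(c("A", "C", "G", "T"),
                                                       pc[s]), 1)
  copy2 <- paste(pc, collapse = "")
  imp <- implant_markers(10000, data.frame(
    marker = c("m", "m"), sequence = c(probe, copy2),
    position = c(1001, 6001), strand = c("forward", "reverse")),
    seed = 103)
  hits <- capture_marker(imp$genome, probe, genome_id = "gh")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$hit_id, c("gh.1", "gh.2"))
  expect_equal(sort(hits$S1), c(1001L, 6001L))
  # the exact copy has the higher coverage and comes first
  expect_equal(hits$S1[1], 1001L)
  expect_equal(hits$sequence[1], probe)
  expect_equal(hits$sequence[2], copy2)
})

test_that("no hit below min_coverage: empty result with a named warning", {
  set.seed(30)
  genome <- c(chr = rand_seq(3000))
  probe <- rand_seq(300)
  expect_warning(hits <- capture_marker(genome, probe, genome_id = "gX",
                                        marker = "ITS"),
                 "gX.*|ITS.*")
  expect_equal(nrow(hits), 0L)
})

test_that("probe shorter than min_match_len and empty genomes error", {
  expect_error(find_exact_matches(c(a = "ACGTACGT"), "ACGT", 20),
               "shorter than min_match_len")
  expect_error(find_exact_matches(character(0), "ACGTACGTACGTACGTACGTT"),
               "empty genome")
})
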