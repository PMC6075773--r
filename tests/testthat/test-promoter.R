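test_that("degenerate scanning handles all-N, IUPAC sets and examples", {
  # all-degenerate pattern: every window matches
  h <- scan_iupac("ACGT", "NNN", strands = "+")
  expect_identical(h$start, c(1L, 2L))
  # M = {A, C}: CAMG hits TCAAGT at 2 (brute-force checkable by hand)
  h2 <- scan_iupac("TCAAGT", "CAMG", strands = "+")
  expect_identical(h2$start, 2L)
  expect_identical(h2$matched_text, "CAAG")
  # invalid letter is rejected
  expect_error(scan_iupac("ACGT", "AXG"), "invalid IUPAC")
  # subject ambiguity letters match only by set intersection
  expect_identical(nrow(scan_iupac("ARGT", "AAG", strands = "+")), 1L)
  expect_identical(nrow(scan_iupac("AYGT", "AAG", strands = "+")), 0L)
})

test_that("scanner agrees with the naive per-window oracle", {
  set.seed(77)
  iupac <- c("A","C","G","T","R","Y","S","W","K","M","N")
  for (rep in 1:100) {
    seqlen <- 500
    s <- random_dna_str(seqlen)
    pat <- paste(sample(iupac, sample(5:12, 1), replace = TRUE,
                        prob = c(rep(2, 4), rep(1, 6), 3)),
                 collapse = "")
    mm <- sample(0:1, 1)
    got <- scan_iupac(s, pat, max_mismatch = mm)
    want <- oracle_scan(s, pat, max_mismatch = mm)
    expect_identical(got$start, want$start)
    expect_identical(as.character(got$strand), as.character(want$strand))
    expect_identical(got$mismatches, want$mismatches)
  }
})

test_that("strand symmetry and mismatch monotonicity hold", {
  set.seed(5)
  for (rep in 1:10) {
    s <- random_dna_str(300)
    pat <- "YTTGNNNNNVAMV"
    plus_on_rc <- scan_iupac(oracle_revcomp(s), pat, strands = "+")
    minus <- scan_iupac(s, pat, strands = "-")
    # coordinates reflect: start' = L - end + 1
    expect_identical(sort(301L - plus_on_rc$start - nchar(pat) + 1L),
                     sort(minus$start))
    # hit count non-decreasing in max_mismatch
    n0 <- nrow(scan_iupac(s, pat, 0))
    n1 <- nrow(scan_iupac(s, pat, 1))
    n2 <- nrow(scan_iupac(s, pat, 2))
    expect_true(n0 <= n1 && n1 <= n2)
  }
})

test_that("deviation classification flags single-site relaxations", {
  strict <- "CTTGNNNNNCAMG"
  expect_identical(classify_deviation("CTTGAAAAACAAG", strict)$deviations, 0L)
  d1 <- classify_deviation("TTTGAAAAACAAG", strict)
  expect_identical(d1$deviations, 1L)
  expect_identical(d1$site, 1L)
  d2 <- classify_deviation("TTTGAAAAAAAAG", strict)
  expect_identical(d2$deviations, 2L)
  expect_true(is.na(d2$site))
  expect_error(classify_deviation("CTTG", strict), "length")
})

test_that("element tallies sum planted motif counts per category", {
  cat_ <- load_catalogs()
  # empty catalog
  expect_identical(nrow(tally_elements("ACGT", cat_$regulator_motifs[0, ])),
                   0L)
  # planted copies tally into their category (using the generator audit)
  fam <- make_family(list(clade_counts = c(AOX1a = 1L, AOX1c = 1L)),
                     seed = 13)
  g <- "g01"
  tl <- tally_elements(fam$promoters[[g]], cat_$regulator_motifs)
  expect_identical(tl$count[tl$category == "mitochondrial_retrograde"],
                   sum(fam$manifest$promoters[[g]]$expected_counts))
  # unknown category is rejected
  rm2 <- cat_$regulator_motifs
  rm2$category[1] <- "mystery"
  expect_error(tally_elements("ACGT", rm2, categories = "known"),
               "unknown category")
})

test_that("CpG islands: closed-form block case and degenerate inputs", {
  # 1000 bp poly-A: nothing
  expect_identical(nrow(find_cpg_islands(strrep("A", 1000))), 0L)
  # too-short sequence warns and returns empty
  expect_warning(res <- find_cpg_islands("ACGT"), "shorter")
  expect_identical(nrow(res), 0L)
  # 300 bp strict CG block flanked by 400 bp poly-A each side
  s <- paste0(strrep("A", 400), strrep("CG", 150), strrep("A", 400))
  isl <- find_cpg_islands(s)
  expect_identical(nrow(isl), 1L)
  # island contains (up to window attribution) the planted block
  expect_true(isl$start >= 401 - 100 && isl$end <= 700 + 100)
  expect_true(isl$start <= 451 && isl$end >= 650)
  # closed-form window statistics at the block center: GC = 100,
  # OE = (#CG * window) / (#C * #G) = (50 * 100) / (50 * 50) = 2.0
  center <- strrep("CG", 50)
  v <- strsplit(center, "")[[1]]
  nC <- sum(v == "C"); nG <- sum(v == "G")
  nCG <- sum(v[-100] == "C" & v[-1] == "G")
  expect_identical(c(nC, nG, nCG), c(50L, 50L, 50L))
  expect_equal(nCG * 100 / (nC * nG), 2.0)
  i2 <- find_cpg_islands(paste0(strrep("A", 100), center, strrep("A", 100)),
                         min_len = 10)
  # partially overlapping windows have OE = 200/k > 2, so the run mean is
  # bounded below by the fully-CG window's 2.0
  expect_gte(max(i2$mean_oe), 2.0)
})

test_that("CpG detection is deterministic and flank-invariant", {
  s <- paste0(strrep("T", 300), strrep("CG", 200), strrep("T", 300))
  a <- find_cpg_islands(s)
  b <- find_cpg_islands(s)
  expect_identical(a, b)
  # appending non-qualifying sequence beyond one window leaves coordinates
  s2 <- paste0(s, strrep("A", 500))
  expect_identical(find_cpg_islands(s2), a)
})
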