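test_that("identity transcript gives one exon and zero introns", {
  g <- random_dna_str(400)
  st <- delineate_structure(g, g)
  expect_identical(st$n_exons, 1L)
  expect_identical(st$n_introns, 0L)
  expect_identical(splice_seq(g, st$exons), g)
})

test_that("planted GT-AG introns are recovered exactly (with manifest)", {
  fam <- make_family(seed = 101)
  for (g in names(fam$genomic)) {
    st <- delineate_structure(fam$transcripts[[paste0(g, ".t1")]],
                              fam$genomic[[g]])
    man <- fam$manifest$genes[[g]]
    expect_identical(st$exons, man$exons)
    expect_identical(st$n_introns, man$n_introns)
    if (st$n_introns > 0) {
      expect_true(all(st$splice_dinucleotides$donor == "GT"))
      expect_true(all(st$splice_dinucleotides$acceptor == "AG"))
    }
    # reconstruction invariant
    expect_identical(splice_seq(fam$genomic[[g]], st$exons),
                     fam$transcripts[[paste0(g, ".t1")]])
  }
})

test_that("recovery holds across 100 generated genes at fixed seeds", {
  n_ok <- 0L; n_total <- 0L
  for (seed in c(201, 202, 203, 204, 205)) {
    fam <- make_family(list(clade_counts = c(AOX1a = 8L, AOX1c = 6L,
                                             AOX1d = 6L)), seed = seed)
    for (g in names(fam$genomic)) {
      n_total <- n_total + 1L
      st <- delineate_structure(fam$transcripts[[paste0(g, ".t1")]],
                                fam$genomic[[g]])
      if (identical(st$exons, fam$manifest$genes[[g]]$exons)) {
        n_ok <- n_ok + 1L
      }
    }
  }
  expect_identical(n_total, 100L)
  expect_identical(n_ok, n_total)
})

test_that("delineation matches the exhaustive placement oracle", {
  set.seed(42)
  for (rep in 1:6) {
    ex1 <- random_dna_str(sample(40:70, 1))
    ex2 <- random_dna_str(sample(40:70, 1))
    intron <- paste0("GT", random_dna_str(sample(25:40, 1)), "AG")
    gen <- paste0(ex1, intron, ex2)
    tx <- paste0(ex1, ex2)
    got <- delineate_structure(tx, gen)
    want <- oracle_delineate(tx, gen)
    expect_identical(got$exons, matrix(as.integer(want), ncol = 2))
  }
})

test_that("unplaceable transcripts raise an error naming the offset", {
  g <- random_dna_str(200)
  expect_error(delineate_structure("NNNNNNNNNNNNNNNN", g), "offset 1")
  # a transcript whose tail is foreign fails mid-way
  tx <- paste0(substr(g, 1, 80), "TTTTGGGGCCCCAAAATTTTGGGG")
  expect_error(delineate_structure(tx, g), "unplaceable")
})

test_that("one substitution is tolerated only when max_mismatch allows", {
  g <- random_dna_str(300)
  tx <- g
  substr(tx, 150, 150) <- if (substr(g, 150, 150) == "A") "C" else "A"
  expect_error(delineate_structure(tx, g, max_mismatch = 0))
  st <- delineate_structure(tx, g, max_mismatch = 1)
  expect_identical(st$n_exons, 1L)
})

test_that("splice events classify retention and alternative UTRs", {
  cfg <- list(clade_counts = c(AOX1a = 2L, AOX1d = 1L),
              sv_plan = list(g01 = c("intron_retention", "alt_3utr"),
                             g02 = "alt_5utr"))
  fam <- make_family(cfg, seed = 7)
  # identical structures -> empty event list
  st <- delineate_structure(fam$transcripts[["g01.t1"]],
                            fam$genomic[["g01"]])
  expect_identical(nrow(classify_splice_events(st, st)), 0L)
  # planted events recovered with planted intervals
  for (g in c("g01", "g02")) {
    wt <- delineate_structure(fam$transcripts[[paste0(g, ".t1")]],
                              fam$genomic[[g]])
    vt <- delineate_structure(fam$transcripts[[paste0(g, ".t2")]],
                              fam$genomic[[g]])
    ev <- classify_splice_events(wt, vt)
    man <- fam$manifest$splice_variants[[g]]$events
    expect_identical(nrow(ev), length(man))
    for (k in seq_along(man)) {
      row <- ev[ev$event_type == man[[k]]$type, ]
      expect_identical(c(row$start, row$end), as.integer(man[[k]]$interval))
    }
  }
  # different genes are rejected
  other <- delineate_structure(fam$transcripts[["g03.t1"]],
                               fam$genomic[["g03"]])
  expect_error(classify_splice_events(st, other), "different genes")
})

test_that("structure summary reports lengths and counts consistently", {
  expect_identical(nrow(structure_summary(list())), 0L)
  fam <- make_family(list(clade_counts = c(AOX1a = 1L, AOX1d = 1L)),
                     seed = 31)
  sts <- lapply(names(fam$genomic), function(g)
    delineate_structure(fam$transcripts[[paste0(g, ".t1")]],
                        fam$genomic[[g]]))
  names(sts) <- names(fam$genomic)
  cds_len <- setNames(nchar(fam$cds), names(fam$cds))
  sm <- structure_summary(sts, cds_len)
  for (i in seq_len(nrow(sm))) {
    man <- fam$manifest$genes[[sm$name[i]]]
    expect_identical(sm$gene_length[i], man$gene_length)
    expect_identical(sm$transcript_length[i], man$transcript_length)
    expect_identical(sm$n_exons[i], man$n_exons)
    expect_identical(sm$n_introns[i], man$n_introns)
    expect_identical(sm$transcript_length[i],
                     sum(man$exons[, 2] - man$exons[, 1] + 1L))
  }
})
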