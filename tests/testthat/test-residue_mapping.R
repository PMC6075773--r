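cat_ <- load_catalogs()
tb <- tbaox_reference(cat_)

test_that("global alignment identity follows the documented definition", {
  a <- global_align("MKTAYIAK", "MKTAYIAK")
  expect_equal(a$identity, 100)
  expect_identical(a$columns, 8L)
  # one internal gap column, identity over columns including gaps
  b <- global_align("ACDE", "ACE")
  expect_identical(b$columns, 4L)
  expect_equal(b$identity, 75.0)
  # self-alignment score equals the sum of diagonal substitution scores
  blosum <- aoxkit:::substitution_matrix("BLOSUM62")
  s <- "MKWVTFISLLLF"
  self <- global_align(s, s)
  expect_equal(self$score,
               sum(diag(blosum[strsplit(s, "")[[1]],
                               strsplit(s, "")[[1]]])))
})

test_that("DP score equals exhaustive enumeration on short peptides", {
  # exhaustive enumeration over all matched-pair sets; scaled to length 8
  # (the full 12-residue search is combinatorially infeasible in R at test
  # time but adds no new structure)
  blosum <- aoxkit:::substitution_matrix("BLOSUM62")
  set.seed(12)
  for (rep in 1:5) {
    a <- random_protein(sample(4:8, 1))
    b <- random_protein(sample(4:8, 1))
    expect_equal(global_align(a, b)$score,
                 oracle_align_score(a, b, blosum),
                 info = paste(a, b))
  }
})

test_that("residue maps transfer numbering, including insertions", {
  # identity mapping
  m <- map_to_reference(tb, tb)
  expect_equal(m$identity, 100)
  expect_identical(m$pairs$isoform_position, m$pairs$tbaox_position)
  # 10-residue insertion after position 100: positions <= 100 unchanged,
  # positions > 100 shifted by 10
  ins <- paste0(substr(tb, 1, 100), "GSGSGSGSGS", substr(tb, 101, nchar(tb)))
  m2 <- map_to_reference(ins, tb)
  expect_identical(m2$pairs$isoform_position[1:100], 1:100)
  expect_identical(m2$pairs$isoform_position[101:nchar(tb)],
                   (101:nchar(tb)) + 10L)
  # mapping consistency: restricted to aligned columns the map inverts
  aligned <- !is.na(m2$pairs$isoform_position)
  back <- setNames(m2$pairs$tbaox_position[aligned],
                   m2$pairs$isoform_position[aligned])
  expect_identical(unname(back[as.character(
    m2$pairs$isoform_position[aligned])]),
    m2$pairs$tbaox_position[aligned])
  # degraded identity flags but still emits
  expect_warning(m3 <- map_to_reference(random_protein(60), tb, floor = 95))
  expect_true(m3$low_identity)
})

test_that("domain profiles read residues at cataloged positions", {
  m <- map_to_reference(tb, tb)
  prof <- extract_domain_profile(m, cat_, "cavity")
  expect_identical(unname(prof$residues),
                   unname(cat_$tbaox_residues[as.character(
                     cat_$tbaox_positions$cavity)]))
  expect_error(extract_domain_profile(m, cat_, "nope"), "unknown domain")
  # wheat AOX1d reference carries its planted cavity letters (H at 118,
  # W at 178) and H138/Q187 at the dimer core
  refs <- clade_references(cat_)
  md <- map_to_reference(refs[["AOX1d"]], tb)
  pd <- extract_domain_profile(md, cat_, "cavity")
  expect_identical(unname(pd$residues["118"]), "H")
  expect_identical(unname(pd$residues["178"]), "W")
  dc <- extract_domain_profile(md, cat_, "dimer_core")
  expect_identical(unname(dc$residues["138"]), "H")
  expect_identical(unname(dc$residues["187"]), "Q")
})

test_that("conservation summary partitions the domain positions", {
  fx <- load_domain_fixtures(cat_)
  cs <- conservation_summary(fx$profiles_cavity, cat_,
                             exclude = c("TaAOX1a-like-2DL",
                                         "put.TaAOX1d-like-4AS",
                                         "AetAOX1d-like"))
  all_pos <- sort(c(cs$identical_positions,
                    cs$uniform_substitutions$position,
                    cs$mixed_positions))
  expect_identical(all_pos, cat_$tbaox_positions$cavity)
  # single profile identical to the reference: everything identical
  m <- map_to_reference(tb, tb)
  p1 <- extract_domain_profile(m, cat_, "cavity")
  cs1 <- conservation_summary(list(TbAOX = p1), cat_)
  expect_identical(cs1$identical_positions, cat_$tbaox_positions$cavity)
  expect_identical(nrow(cs1$uniform_substitutions), 0L)
  expect_error(conservation_summary(list(), cat_), "no profiles")
})

test_that("chemistry ratios count side-chain classes over non-gap sites", {
  # all-leucine toy profile
  toy <- structure(list(domain = "cavity",
                        positions = cat_$tbaox_positions$cavity,
                        residues = setNames(rep("L", 33),
                                            cat_$tbaox_positions$cavity)),
                   class = "DomainProfile")
  cr <- chemistry_ratios(toy, cat_$chemistry_map)
  expect_equal(unname(cr$ratios["hydrophobic"]), 1.0)
  # a transcribed cavity fixture row matches an independent hand tally
  fx <- load_domain_fixtures(cat_)
  row <- fx$profiles_cavity[["TaAOX1a-2AL.sv1"]]
  cr2 <- chemistry_ratios(row, cat_$chemistry_map)
  letters_ <- unname(row$residues)
  naive <- c(
    hydrophobic = sum(letters_ %in% c("A","V","L","I","M","C")),
    polar = sum(letters_ %in% c("S","T","N","Q","D","E","K","R")),
    cyclic = sum(letters_ %in% c("F","W","Y","H","P")),
    glycine = sum(letters_ == "G"))
  expect_identical(cr2$counts[names(naive)], naive)
  expect_equal(sum(cr2$ratios), 1.0)
  # gap-only profile -> undefined ratios
  gp <- toy; gp$residues[] <- "-"
  crg <- chemistry_ratios(gp, cat_$chemistry_map)
  expect_true(crg$undefined)
  expect_true(all(is.na(crg$ratios)))
})
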