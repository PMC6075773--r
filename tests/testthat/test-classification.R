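cat_ <- load_catalogs()
refs <- clade_references(cat_)

test_that("signature motif scan distinguishes present/variant/absent", {
  base <- refs[["AOX1a"]]
  res <- scan_signature_motifs(base, cat_)
  expect_identical(res$status, rep("present", 4))

  # one substitution at a non-catalytic position -> variant (LETVAA with
  # its glutamate intact, like the published LEMVAA case)
  mod <- base
  substr(mod, 63, 63) <- "M"   # LETVAA footprint starts at 61; T -> M
  res2 <- scan_signature_motifs(mod, cat_)
  expect_identical(res2$status[res2$motif_name == "LETVAA"], "variant")
  expect_identical(res2$matched_text[res2$motif_name == "LETVAA"], "LEMVAA")
  # strict mode refuses the variant
  res2s <- scan_signature_motifs(mod, cat_, strict = TRUE)
  expect_identical(res2s$status[res2s$motif_name == "LETVAA"], "absent")

  # the same substitution at the catalytic glutamate is not a variant
  mod2 <- base
  substr(mod2, 62, 62) <- "A"
  res3 <- scan_signature_motifs(mod2, cat_)
  expect_identical(res3$status[res3$motif_name == "LETVAA"], "absent")

  # degenerate input
  res4 <- scan_signature_motifs("AAAA", cat_)
  expect_identical(res4$status, rep("absent", 4))
})

test_that("motif scan positions shift exactly with prepended residues", {
  base <- refs[["AOX1c"]]
  res <- scan_signature_motifs(base, cat_)
  shifted <- scan_signature_motifs(paste0("GSGSGSG", base), cat_)
  expect_identical(shifted$position, res$position + 7L)
  expect_identical(shifted$status, res$status)
})

test_that("diagnostic typing reads residues off the alignment", {
  ref <- diagnostic_reference(cat_)
  # reference typed against itself
  self <- type_diagnostic_residues(ref, ref, cat_)
  expect_false(anyNA(self$residues))
  expect_identical(self$type_call, "Type1")
  expect_identical(self$subtype_call, "ace")
  # planted subtype-d residues at all six positions
  d <- type_diagnostic_residues(refs[["AOX1d"]], ref, cat_)
  expect_identical(d$subtype_call, "d")
  # truncated protein (first 100 aa only) -> unresolved subtype
  frag <- substr(ref, 1, 100)
  fr <- type_diagnostic_residues(frag, ref, cat_)
  expect_identical(fr$subtype_call, "unresolved")
})

test_that("clade assignment combines subtype and nearest-reference identity", {
  a <- assign_clade(refs[["AOX1a"]], refs)
  expect_identical(a$clade, "AOX1a")
  expect_equal(a$identity, 100)
  # a chimera mostly identical to AOX1c stays AOX1c, checked against an
  # independent identity computation
  set.seed(9)
  cv <- strsplit(refs[["AOX1c"]], "")[[1]]
  at <- sample(seq_along(cv), 40)
  for (p in at) cv[p] <- sample(setdiff(c("A","G","S","T","V","L"), cv[p]), 1)
  chim <- paste(cv, collapse = "")
  cl <- assign_clade(chim, refs)
  expect_identical(cl$clade, "AOX1c")
  naive_identity <- 100 * sum(cv == strsplit(refs[["AOX1c"]], "")[[1]]) /
    length(cv)
  expect_equal(cl$identities[["AOX1c"]], naive_identity, tolerance = 0.01)
  # identity floor yields unknown
  u <- assign_clade(paste(rep("G", 60), collapse = ""), refs, floor = 25)
  expect_identical(u$clade, "unknown")
})

test_that("name grammar reproduces the published exemplars from parts", {
  bullet <- "\u2022"
  cases <- list(
    list(p = list(species = "Ta", clade = "AOX1a", location = "2BL"),
         n = "TaAOX1a-2BL"),
    list(p = list(species = "Ta", clade = "AOX1a", location = "2AL",
                  sv = 1L), n = "TaAOX1a-2AL.sv1"),
    list(p = list(species = "Ta", clade = "AOX1a", like = TRUE,
                  location = "2DL"), n = "TaAOX1a-like-2DL"),
    list(p = list(species = "Ta", reg = TRUE, location = "4BL", sv = 1L),
         n = "regTaAOX-4BL.sv1"),
    list(p = list(species = "Ta", reg = TRUE, put = TRUE, location = "3B"),
         n = "put.regTaAOX-3B"),
    list(p = list(species = "Ta", reg = TRUE, put = TRUE,
                  location = "6BL"), n = "put.regTaAOX-6BL"),
    list(p = list(species = "Ta", clade = "AOX1e", put = TRUE,
                  location = "3DS"), n = "put.TaAOX1e-3DS"),
    list(p = list(species = "Ta", clade = "AOX1d", location = "2AL",
                  paralog = 1L), n = "TaAOX1d-2AL.1"),
    list(p = list(species = "Ta", clade = "AOX1d", location = "2AL",
                  paralog = 2L, sv = 2L), n = "TaAOX1d-2AL.2.sv2"),
    list(p = list(species = "Ta", clade = "AOX1d", put = TRUE, like = TRUE,
                  location = "4AS"), n = "put.TaAOX1d-like-4AS"),
    list(p = list(species = "Tu", clade = "AOX1d", paralog = 1L),
         n = "TuAOX1d.1"),
    list(p = list(species = "Aet", clade = "AOX1d", like = TRUE),
         n = "AetAOX1d-like"),
    list(p = list(species = "Ta", clade = "AOX1d", ne = TRUE,
                  location = "2BL", paralog = 1L), n = "ne.TaAOX1d-2BL.1"),
    list(p = list(species = "Ta", ne = TRUE, location = "2AL"),
         n = paste0("ne.TaAOX", bullet, "-2AL")))
  for (cs in cases) {
    expect_identical(assign_name(cs$p), cs$n)
    # round trip through the parser
    back <- parse_name(cs$n)
    expect_identical(assign_name(back), cs$n)
  }
  # inconsistent parts are rejected
  expect_error(assign_name(list(species = "Ta", reg = TRUE, like = TRUE)),
               "reg")
  expect_error(assign_name(list(species = "Ta", reg = TRUE,
                                clade = "AOX1a")), "clade")
})

test_that("family classification recovers planted clades, classes, names", {
  cfg <- list(
    clade_counts = c(AOX1a = 3L, AOX1c = 2L, AOX1e = 1L, AOX1d = 3L),
    knockout_plan = list(g02 = "LETVAA", g05 = "all"),
    variant_plan = list(g01 = "ERMHLMT"),
    confidence_plan = c(g07 = "low"))
  fam <- make_family(cfg, seed = 55)
  cls <- classify_family(fam$proteins, fam$meta)
  man <- fam$manifest$isoforms
  for (i in seq_len(nrow(cls))) {
    id <- cls$isoform_id[i]
    expect_identical(cls$name[i], man[[id]]$expected_name)
    expect_identical(cls$clade[i], man[[id]]$clade)
    expect_identical(cls$class[i], man[[id]]$class)
  }
  # empty input -> empty output
  expect_identical(nrow(classify_family(character(0), fam$meta)), 0L)
})

test_that("clade recovery stays at 100% over several seeds", {
  hits <- 0L; total <- 0L
  for (seed in c(71, 72, 73)) {
    fam <- make_family(list(clade_counts = c(AOX1a = 2L, AOX1c = 2L,
                                             AOX1e = 2L, AOX1d = 2L),
                            sub_rate = 0.06), seed = seed)
    cls <- classify_family(fam$proteins, fam$meta)
    man_clades <- vapply(fam$manifest$isoforms, function(x) x$clade, "x")
    hits <- hits + sum(cls$clade == man_clades[cls$isoform_id])
    total <- total + nrow(cls)
  }
  expect_gte(hits / total, 0.95)
})
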