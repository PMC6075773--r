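# Pipeline orchestration and fixture loading.

FIXTURE_MD5 <- c(
  dimer_interface_residues.tsv = "08a04672bfe128c657b60070c4d0e03d",
  hydrophobic_cavity_residues.tsv = "44d7c3747f1d288f685b94f2d923d85e")

fixture_path <- function(name) {
  system.file("extdata", "fixtures", name, package = "aoxkit",
              mustWork = TRUE)
}

# Internal: fixture TSV -> list of DomainProfile objects for `positions`.
fixture_profiles <- function(df, positions, domain) {
  pcols <- paste0("p", positions)
  stopifnot(all(pcols %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    res <- setNames(as.character(df[i, pcols]), positions)
    structure(list(domain = domain, positions = positions, residues = res,
                   chemistry = NULL), class = "DomainProfile")
  })
  setNames(out, df$isoform)
}

#' Load the transcribed domain-table fixtures
#'
#' Reads the dimer-interface and hydrophobic-cavity residue matrices
#' transcribed from published curation tables, verifies their checksums
#' and their consistency with the catalog (column counts; the reference
#' row letters equal the catalog's TbAOX letters), and returns them as
#' data.frames plus ready-made \code{DomainProfile} lists.
#'
#' @param catalogs a \code{CatalogBundle}.
#' @return list with \code{dimer_table}, \code{cavity_table} (data.frames),
#'   \code{profiles_dimer_core}, \code{profiles_dimer_high},
#'   \code{profiles_cavity} (named \code{DomainProfile} lists, reference
#'   row removed).
#' @export
load_domain_fixtures <- function(catalogs = load_catalogs()) {
  paths <- vapply(names(FIXTURE_MD5), fixture_path, "x")
  sums <- tools::md5sum(paths)
  bad <- which(unname(sums) != unname(FIXTURE_MD5))
  if (length(bad)) {
    stop("load_domain_fixtures: checksum mismatch for ",
         names(FIXTURE_MD5)[bad[1]], " (tampered or corrupted fixture)")
  }
  t10 <- read.delim(paths[1], check.names = FALSE,
                    stringsAsFactors = FALSE)
  t11 <- read.delim(paths[2], check.names = FALSE,
                    stringsAsFactors = FALSE)
  core_pos <- catalogs$tbaox_positions$dimer_core
  high_pos <- catalogs$tbaox_positions$dimer_high
  cav_pos <- catalogs$tbaox_positions$cavity
  if (ncol(t11) - 1L != length(cav_pos)) {
    stop("load_domain_fixtures: cavity fixture must have ",
         length(cav_pos), " position columns")
  }
  if (ncol(t10) - 1L != length(core_pos) + length(high_pos)) {
    stop("load_domain_fixtures: dimer fixture must have ",
         length(core_pos) + length(high_pos), " position columns")
  }
  # reference-row consistency with the catalog letters
  for (df in list(t10, t11)) {
    ref_row <- df[df$isoform == "TbAOX", -1, drop = FALSE]
    pos <- as.integer(sub("^p", "", names(ref_row)))
    expect <- catalogs$tbaox_residues[as.character(pos)]
    if (!all(as.character(ref_row) == expect)) {
      stop("load_domain_fixtures: fixture reference row disagrees with ",
           "catalog TbAOX letters")
    }
  }
  iso10 <- t10[t10$isoform != "TbAOX", ]
  iso11 <- t11[t11$isoform != "TbAOX", ]
  list(dimer_table = t10, cavity_table = t11,
       profiles_dimer_core = fixture_profiles(iso10, core_pos,
                                              "dimer_core"),
       profiles_dimer_high = fixture_profiles(iso10, high_pos,
                                              "dimer_high"),
       profiles_cavity = fixture_profiles(iso11, cav_pos, "cavity"))
}

#' Run the curation pipeline over a set of inputs
#'
#' Sequences the analysis stages (structure, classification, domains,
#' promoter, cpg, properties, expression) over in-memory inputs such as
#' the output of \code{\link{make_family}}, writing one TSV per stage when
#' \code{out_dir} is given.  Stage failures halt with a stage-scoped error;
#' earlier outputs are preserved.
#'
#' @param inputs list with (any of) \code{genomic}, \code{transcripts},
#'   \code{cds}, \code{promoters}, \code{proteins} (named character
#'   vectors), \code{meta} (data.frame), \code{abundance} + \code{pairs}
#'   for the expression stage.
#' @param stages character subset of
#'   \code{c("structure", "classification", "domains", "promoter", "cpg",
#'   "properties", "expression")}; empty = validation-only run.
#' @param catalogs a \code{CatalogBundle}.
#' @param out_dir optional output directory for TSV reports.
#' @param strand_convention strands used for promoter scanning.
#' @param pka pKa set for the properties stage.
#' @param cpg list of CpG parameters (window, min_len, oe_threshold,
#'   gc_threshold).
#' @return named list of stage results plus a \code{log} data.frame of
#'   parameters (strand convention, pKa set, catalog checksum).
#' @export
run_pipeline <- function(inputs,
                         stages = c("structure", "classification",
                                    "domains", "promoter", "cpg",
                                    "properties", "expression"),
                         catalogs = load_catalogs(), out_dir = NULL,
                         strand_convention = c("+", "-"), pka = "emboss",
                         cpg = list()) {
  known <- c("structure", "classification", "domains", "promoter", "cpg",
             "properties", "expression")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  cpg <- modifyList(list(window = 100L, min_len = 200L,
                         oe_threshold = 0.6, gc_threshold = 50), cpg)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      write_report(df, file.path(out_dir, paste0(name, ".tsv")), "tsv")
    }
    df
  }
  stage_try <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("run_pipeline: stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  results <- list()

  if ("structure" %in% stages && !is.null(inputs$transcripts)) {
    results$structure <- stage_try("structure", {
      tx_gene <- sub("\\.t[0-9]+$", "", names(inputs$transcripts))
      sts <- lapply(seq_along(inputs$transcripts), function(i) {
        delineate_structure(inputs$transcripts[[i]],
                            inputs$genomic[[tx_gene[i]]])
      })
      names(sts) <- names(inputs$transcripts)
      cds_len <- if (!is.null(inputs$cds)) {
        setNames(nchar(inputs$cds)[tx_gene], names(inputs$transcripts))
      } else NULL
      summary <- structure_summary(sts, cds_len)
      emit(summary, "structure_summary")
      list(structures = sts, summary = summary)
    })
  }
  if ("classification" %in% stages && !is.null(inputs$proteins)) {
    results$classification <- stage_try("classification", {
      emit(classify_family(inputs$proteins, inputs$meta, catalogs),
           "classification")
    })
  }
  if ("domains" %in% stages && !is.null(inputs$proteins)) {
    results$domains <- stage_try("domains", {
      ref <- tbaox_reference(catalogs)
      profs <- lapply(inputs$proteins, function(p) {
        m <- suppressWarnings(map_to_reference(p, ref))
        extract_domain_profile(m, catalogs, "cavity")
      })
      mat <- do.call(rbind, lapply(profs, function(p) p$residues))
      df <- data.frame(isoform = names(profs), mat, check.names = FALSE,
                       stringsAsFactors = FALSE)
      emit(df, "cavity_profile")
      profs
    })
  }
  if ("promoter" %in% stages && !is.null(inputs$promoters)) {
    results$promoter <- stage_try("promoter", {
      rows <- lapply(names(inputs$promoters), function(g) {
        hits <- do.call(rbind, lapply(
          seq_len(nrow(catalogs$regulator_motifs)), function(r) {
            h <- scan_iupac(inputs$promoters[[g]],
                            catalogs$regulator_motifs$pattern[r],
                            max_mismatch = 0L,
                            strands = strand_convention)
            if (nrow(h)) cbind(gene = g,
                               motif = catalogs$regulator_motifs$name[r],
                               h)
            else NULL
          }))
        hits
      })
      df <- do.call(rbind, rows)
      if (is.null(df)) df <- data.frame(gene = character(0),
                                        motif = character(0))
      emit(df, "promoter_hits")
      df
    })
  }
  if ("cpg" %in% stages && !is.null(inputs$genomic)) {
    results$cpg <- stage_try("cpg", {
      rows <- lapply(names(inputs$genomic), function(g) {
        isl <- suppressWarnings(find_cpg_islands(
          inputs$genomic[[g]], window = cpg$window, min_len = cpg$min_len,
          oe_threshold = cpg$oe_threshold,
          gc_threshold = cpg$gc_threshold))
        if (nrow(isl)) cbind(gene = g, isl) else NULL
      })
      df <- do.call(rbind, rows)
      if (is.null(df)) df <- data.frame(gene = character(0),
                                        start = integer(0),
                                        end = integer(0))
      emit(df, "cpg_islands")
      df
    })
  }
  if ("properties" %in% stages && !is.null(inputs$proteins)) {
    results$properties <- stage_try("properties", {
      emit(protein_properties(inputs$proteins, pka = pka), "properties")
    })
  }
  if ("expression" %in% stages && !is.null(inputs$abundance)) {
    results$expression <- stage_try("expression", {
      rm_ <- ratio_matrix(inputs$abundance, inputs$pairs)
      if (!is.null(out_dir)) {
        export_heatmap_matrix(rm_, file.path(out_dir, "expression_ratios.tsv"))
      }
      rm_
    })
  }

  results$log <- data.frame(
    stage = "run", strand_convention = paste(strand_convention,
                                             collapse = ""),
    pka_set = if (is.character(pka)) pka else "custom",
    catalog_md5 = unname(tools::md5sum(default_catalog_path())),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) emit(results$log, "run_log")
  results
}
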