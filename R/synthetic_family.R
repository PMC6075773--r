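# Synthetic AOX gene families with a full ground-truth manifest.
#
# The generator emulates the curated family's stated world: clade-dependent
# intron counts (AOX1d intronless or single-intron, AOX1a/1c multi-exonic),
# GT..AG introns, 1500 bp promoters with planted degenerate-motif
# occurrences over a 45% GC background, CpG-rich blocks planted inside long
# introns, proteins built from clade reference backbones with optional
# signature-motif knockouts, and splice variants with planted intron
# retention / alternative UTR events.  Every planted feature is recorded in
# the manifest so each analysis stage can be audited at 100% recovery.

STANDARD_CODON <- c(
  A = "GCT", R = "CGT", N = "AAC", D = "GAC", C = "TGC", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAC", I = "ATC", L = "CTT", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAC", V = "GTT")

LOCATION_POOL <- c("2AL", "2BL", "2DL", "4BL", "6AL", "6BL", "6DL", "3B",
                   "3DS", "4AS", "5AL", "5BL", "5DL", "7AL", "7BL", "7DL")

random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Concrete realization of an IUPAC pattern.
realize_iupac <- function(pattern) {
  paste(vapply(chars(pattern), function(ch) {
    set <- IUPAC_DNA[[ch]]
    set[sample.int(length(set), 1)]
  }, "x"), collapse = "")
}

back_translate <- function(protein_seq) {
  paste0(paste(STANDARD_CODON[chars(protein_seq)], collapse = ""), "TAA")
}

# Substitute `n` free backbone positions with different letters.
mutate_free <- function(sv, free, n) {
  if (n == 0) return(sv)
  at <- sort(sample(free, min(n, length(free))))
  for (p in at) {
    sv[p] <- sample(setdiff(AA20, sv[p]), 1)
  }
  sv
}

# Break a motif beyond the 1-substitution variant tolerance.
knockout_motif <- function(sv, motif_name) {
  fp <- MOTIF_FOOTPRINTS[[motif_name]]
  idx <- fp + c(0L, 2L, 4L)
  for (p in idx) sv[p] <- sample(setdiff(AA20, sv[p]), 1)
  sv
}

# One substitution at a non-catalytic motif position (stays a "variant").
soften_motif <- function(sv, motif_name, catalogs) {
  sm <- catalogs$signature_motifs
  i <- match(motif_name, sm$name)
  L <- nchar(sm$pattern[i])
  ok <- setdiff(seq_len(L), sm$catalytic[[i]])
  p <- MOTIF_FOOTPRINTS[[motif_name]] + sample(ok, 1) - 1L
  sv[p] <- sample(setdiff(AA20, sv[p]), 1)
  sv
}

# Pick intron breakpoints inside a transcript such that junction bases do
# not allow silent boundary slides (no G adjacent to the junction).
pick_breakpoints <- function(tv, n_introns, min_exon = 30L) {
  if (n_introns == 0) return(integer(0))
  Tn <- length(tv)
  for (try in seq_len(200)) {
    bp <- sort(sample(seq(min_exon + 1L, Tn - min_exon + 1L), n_introns))
    if (n_introns > 1 && any(diff(bp) < min_exon)) next
    ok <- all(tv[bp] != "G") && all(tv[bp - 1L] != "G")
    if (ok) return(bp)
  }
  stop("make_family: cannot place introns (transcript too short?)")
}

#' Generate a synthetic AOX gene family with ground truth
#'
#' @param config list; recognized entries (all optional):
#'   \describe{
#'     \item{clade_counts}{named integer vector of genes per clade
#'       (default \code{c(AOX1a = 4, AOX1c = 3, AOX1e = 1, AOX1d = 4)}).}
#'     \item{sub_rate}{within-clade substitution rate at unconstrained
#'       backbone positions (default 0.03).}
#'     \item{intron_plan}{named list clade -> candidate intron counts
#'       (default AOX1a 3, AOX1c 3:5, AOX1e 3, AOX1d 0:1).}
#'     \item{knockout_plan}{named list gene index name ("g03") -> motif
#'       names to knock out ("all" for a motif-free regulator).}
#'     \item{variant_plan}{named list gene -> motif names to soften into
#'       single-substitution variants.}
#'     \item{confidence_plan}{named character vector gene -> confidence
#'       (default "high").}
#'     \item{promoter_plan}{named list gene -> data.frame(name, count)
#'       of catalog motifs to plant (default: 2 stringent MDM copies in
#'       every AOX1a and AOX1d gene).}
#'     \item{cpg_plan}{named list gene -> block length (default: a 300 bp
#'       CG block in the first AOX1a gene).}
#'     \item{sv_plan}{named list gene -> events among
#'       c("intron_retention", "alt_5utr", "alt_3utr").}
#'     \item{promoter_len, promoter_gc}{promoter background (1500, 0.45).}
#'   }
#' @param seed integer seed; identical config + seed reproduces bytes.
#' @param catalogs a \code{CatalogBundle}.
#' @return list with \code{genomic}, \code{transcripts}, \code{cds},
#'   \code{promoters}, \code{proteins} (named character vectors),
#'   \code{meta} (data.frame) and \code{manifest} (ground truth).
#' @export
make_family <- function(config = list(), seed = 1L,
                        catalogs = load_catalogs()) {
  cfg <- modifyList(list(
    clade_counts = c(AOX1a = 4L, AOX1c = 3L, AOX1e = 1L, AOX1d = 4L),
    sub_rate = 0.03,
    intron_plan = list(AOX1a = 3L, AOX1c = 3:5, AOX1e = 3L, AOX1d = 0:1),
    knockout_plan = list(), variant_plan = list(),
    confidence_plan = character(0),
    promoter_plan = NULL, cpg_plan = NULL, sv_plan = list(),
    promoter_len = 1500L, promoter_gc = 0.45), config)
  set.seed(as.integer(seed))
  refs <- clade_references(catalogs)
  free <- setdiff(seq_len(REF_LEN), ref_constrained_positions(catalogs))

  clades <- rep(names(cfg$clade_counts), cfg$clade_counts)
  n_genes <- length(clades)
  if (n_genes == 0) stop("make_family: empty clade_counts")
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  locations <- rep_len(LOCATION_POOL, n_genes)

  # default plans mirroring the stated world
  if (is.null(cfg$promoter_plan)) {
    cfg$promoter_plan <- setNames(lapply(seq_len(n_genes), function(i) {
      if (clades[i] %in% c("AOX1a", "AOX1d")) {
        data.frame(name = "MDM_stringent", count = 2L,
                   stringsAsFactors = FALSE)
      } else NULL
    }), gene_ids)
  }
  if (is.null(cfg$cpg_plan)) {
    first_1a <- gene_ids[clades == "AOX1a"][1]
    cfg$cpg_plan <- if (is.na(first_1a)) list() else
      setNames(list(300L), first_1a)
  }

  genomic <- transcripts <- cds <- promoters <- proteins <- character(0)
  meta <- NULL
  man_genes <- man_iso <- man_prom <- man_cpg <- man_sv <- list()

  for (i in seq_len(n_genes)) {
    gid <- gene_ids[i]
    clade <- clades[i]
    conf <- if (gid %in% names(cfg$confidence_plan)) {
      cfg$confidence_plan[[gid]]
    } else "high"

    ## protein
    sv_aa <- chars(refs[[clade]])
    n_sub <- stats::rbinom(1, length(free), cfg$sub_rate)
    sv_aa <- mutate_free(sv_aa, free, n_sub)
    kos <- cfg$knockout_plan[[gid]]
    if (!is.null(kos) && identical(kos, "all")) {
      kos <- catalogs$signature_motifs$name
    }
    for (ko in kos) sv_aa <- knockout_motif(sv_aa, ko)
    for (vm in cfg$variant_plan[[gid]]) {
      sv_aa <- soften_motif(sv_aa, vm, catalogs)
    }
    prot <- paste(sv_aa, collapse = "")
    n_ko <- length(kos)
    klass <- if (n_ko == 0) "aox"
             else if (n_ko < nrow(catalogs$signature_motifs)) "like"
             else "reg"

    ## transcript and gene
    cds_i <- back_translate(prot)
    utr5 <- random_dna(sample(60:150, 1), cfg$promoter_gc)
    utr3 <- random_dna(sample(80:200, 1), cfg$promoter_gc)
    tx <- paste0(utr5, cds_i, utr3)
    tv <- chars(tx)
    n_introns <- sample(rep(cfg$intron_plan[[clade]], 2), 1)
    bp <- pick_breakpoints(tv, n_introns)
    cpg_len <- cfg$cpg_plan[[gid]]
    if (!is.null(cpg_len) && n_introns == 0) {
      stop("make_family: CpG block planned for intronless gene ", gid)
    }
    intron_seqs <- lapply(seq_len(n_introns), function(j) {
      core <- random_dna(sample(60:120, 1), 0.40)
      if (!is.null(cpg_len) && j == 1L) {
        pad <- random_dna(80, 0.30)
        core <- paste0(pad, paste(rep("CG", ceiling(cpg_len / 2)),
                                  collapse = ""), pad)
      }
      paste0("GT", core, "AG")
    })
    # assemble genomic, tracking exon coordinates
    segs <- character(0)
    exons <- NULL
    cur <- 1L   # genomic cursor
    prev_bp <- 1L
    for (j in seq_len(n_introns)) {
      ex <- paste(tv[prev_bp:(bp[j] - 1L)], collapse = "")
      segs <- c(segs, ex, intron_seqs[[j]])
      exons <- rbind(exons, c(cur, cur + nchar(ex) - 1L))
      cur <- cur + nchar(ex) + nchar(intron_seqs[[j]])
      prev_bp <- bp[j]
    }
    ex <- paste(tv[prev_bp:length(tv)], collapse = "")
    segs <- c(segs, ex)
    exons <- rbind(exons, c(cur, cur + nchar(ex) - 1L))
    tail_len <- 100L
    gseq <- paste0(paste(segs, collapse = ""), random_dna(tail_len, 0.40))
    stopifnot(identical(splice_seq(gseq, exons), tx))
    introns <- if (n_introns > 0) {
      cbind(exons[-nrow(exons), 2] + 1L, exons[-1, 1] - 1L)
    } else matrix(integer(0), ncol = 2)
    cds_span <- c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds_i))

    ## promoter
    prom_bg <- random_dna(cfg$promoter_len, cfg$promoter_gc)
    plan <- cfg$promoter_plan[[gid]]
    planted <- data.frame(name = character(0), start = integer(0),
                          strand = character(0), site = character(0),
                          stringsAsFactors = FALSE)
    pseq <- prom_bg
    if (!is.null(plan)) {
      occupied <- matrix(integer(0), ncol = 2)
      for (r in seq_len(nrow(plan))) {
        pat <- catalogs$regulator_motifs$pattern[
          match(plan$name[r], catalogs$regulator_motifs$name)]
        if (is.na(pat)) pat <- plan$name[r]   # literal pattern allowed
        L <- nchar(pat)
        if (L > cfg$promoter_len) {
          stop("make_family: motif longer than promoter: ", plan$name[r])
        }
        for (cnt in seq_len(plan$count[r])) {
          placed <- FALSE
          for (try in seq_len(500)) {
            s <- sample.int(cfg$promoter_len - L + 1L, 1)
            clash <- nrow(occupied) > 0 &&
              any(s <= occupied[, 2] & (s + L - 1L) >= occupied[, 1])
            if (clash) next
            site <- realize_iupac(pat)
            pseq <- paste0(substr(pseq, 1, s - 1L), site,
                           substr(pseq, s + L, cfg$promoter_len))
            occupied <- rbind(occupied, c(s, s + L - 1L))
            planted <- rbind(planted, data.frame(
              name = plan$name[r], start = s, strand = "+", site = site,
              stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
          if (!placed) stop("make_family: cannot place motif ",
                            plan$name[r], " without overlap")
        }
      }
    }
    # post-plant audit: total counts a 0-mismatch scan should report
    audit <- vapply(seq_len(nrow(catalogs$regulator_motifs)), function(r) {
      nrow(scan_iupac(pseq, catalogs$regulator_motifs$pattern[r],
                      max_mismatch = 0L, strands = c("+", "-")))
    }, 1L)
    names(audit) <- catalogs$regulator_motifs$name

    ## splice variants
    iso_rows <- list()
    tx_out <- c(setNames(tx, paste0(gid, ".t1")))
    sv_events <- list()
    events <- cfg$sv_plan[[gid]]
    if (length(events) > 0) {
      v_ex <- exons
      ev_list <- list()
      for (ev in events) {
        if (ev == "intron_retention") {
          if (nrow(introns) == 0) {
            stop("make_family: intron_retention planned for intronless ", gid)
          }
          iv <- introns[1, ]
          v_ex <- rbind(c(v_ex[1, 1], v_ex[2, 2]),
                        v_ex[-(1:2), , drop = FALSE])
          ev_list[[length(ev_list) + 1]] <-
            list(type = "intron_retention", interval = iv)
        } else if (ev == "alt_3utr") {
          d <- 60L
          last <- nrow(v_ex)
          old_end <- v_ex[last, 2]
          v_ex[last, 2] <- old_end + d
          ev_list[[length(ev_list) + 1]] <-
            list(type = "alt_3utr", interval = c(old_end + 1L, old_end + d))
        } else if (ev == "alt_5utr") {
          d <- 40L
          old_start <- v_ex[1, 1]
          v_ex[1, 1] <- old_start + d
          ev_list[[length(ev_list) + 1]] <-
            list(type = "alt_5utr", interval = c(old_start, old_start + d - 1L))
        } else stop("make_family: unknown splice event: ", ev)
      }
      v_tx <- splice_seq(gseq, v_ex)
      tx_out <- c(tx_out, setNames(v_tx, paste0(gid, ".t2")))
      sv_events <- list(variant_id = paste0(gid, ".t2"), events = ev_list,
                        exons = v_ex)
    }

    ## assemble outputs
    genomic[gid] <- gseq
    transcripts <- c(transcripts, tx_out)
    cds[gid] <- cds_i
    promoters[gid] <- pseq
    iso_id <- gid
    proteins[iso_id] <- prot
    meta <- rbind(meta, data.frame(
      isoform_id = iso_id, gene_id = gid, species = "Ta",
      location = locations[i], paralog = NA_integer_,
      sv = if (length(events) > 0) 1L else NA_integer_,
      confidence = conf, stringsAsFactors = FALSE))

    expected_parts <- list(
      species = "Ta",
      clade = if (klass == "reg") NA_character_ else clade,
      put = conf == "low", reg = klass == "reg",
      ne = conf == "non_expressed", like = klass == "like",
      location = locations[i], paralog = NA_integer_,
      sv = if (length(events) > 0) 1L else NA_integer_)

    man_genes[[gid]] <- list(
      clade = clade, exons = exons, introns = introns,
      donor = if (nrow(introns)) rep("GT", nrow(introns)) else character(0),
      acceptor = if (nrow(introns)) rep("AG", nrow(introns))
                 else character(0),
      cds_span = cds_span, n_exons = nrow(exons),
      n_introns = nrow(introns),
      transcript_length = nchar(tx), gene_length = nchar(gseq))
    man_iso[[iso_id]] <- list(
      clade = clade, knockouts = if (is.null(kos)) character(0) else kos,
      variants = cfg$variant_plan[[gid]], class = klass,
      confidence = conf,
      expected_name = assign_name(expected_parts))
    man_prom[[gid]] <- list(planted = planted, expected_counts = audit)
    if (!is.null(cpg_len)) {
      # block genomic coordinates: inside intron 1, after GT + pad
      off <- introns[1, 1] + 2L + 80L
      man_cpg[[gid]] <- c(off, off + 2L * ceiling(cpg_len / 2) - 1L)
    }
    if (length(events) > 0) man_sv[[gid]] <- sv_events
  }

  list(genomic = genomic, transcripts = transcripts, cds = cds,
       promoters = promoters, proteins = proteins, meta = meta,
       manifest = list(seed = as.integer(seed), genes = man_genes,
                       isoforms = man_iso, promoters = man_prom,
                       cpg_blocks = man_cpg, splice_variants = man_sv))
}
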