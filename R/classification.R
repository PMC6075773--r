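# Isoform classification: signature-motif scanning, diagnostic-residue
# typing against a reference scheme, clade assignment, and orchestration.

#' Scan a protein for the signature motifs of the AOX diiron center
#'
#' A motif is \code{present} on an exact hit, \code{variant} when the best
#' window differs at no more than one position and every catalytic-flagged
#' position (the diiron glutamates/histidines) is preserved, else
#' \code{absent}.  The leftmost qualifying hit is reported per motif.
#'
#' @param protein_seq amino-acid string.
#' @param catalogs a \code{CatalogBundle}.
#' @param strict when \code{TRUE}, only exact hits count (no variant class).
#' @return data.frame with one row per catalog motif, in catalog order:
#'   \code{motif_name}, \code{status}, \code{position}, \code{matched_text}.
#' @export
scan_signature_motifs <- function(protein_seq, catalogs = load_catalogs(),
                                  strict = FALSE) {
  if (!nzchar(protein_seq)) stop("scan_signature_motifs: empty protein")
  pv <- chars(toupper(protein_seq))
  sm <- catalogs$signature_motifs
  out <- data.frame(motif_name = sm$name,
                    status = "absent",
                    position = NA_integer_,
                    matched_text = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sm))) {
    mv <- chars(sm$pattern[i])
    L <- length(mv)
    if (length(pv) < L) next
    n_win <- length(pv) - L + 1L
    # mismatch count per window, vectorized over offsets within the motif
    mm <- integer(n_win)
    mm_cat <- integer(n_win)
    flags <- seq_len(L) %in% sm$catalytic[[i]]
    for (k in seq_len(L)) {
      diff_k <- pv[k:(k + n_win - 1L)] != mv[k]
      mm <- mm + diff_k
      if (flags[k]) mm_cat <- mm_cat + diff_k
    }
    exact <- which(mm == 0L)
    if (length(exact)) {
      out$status[i] <- "present"
      out$position[i] <- exact[1]
      out$matched_text[i] <- paste(pv[exact[1]:(exact[1] + L - 1L)],
                                   collapse = "")
      next
    }
    if (!strict) {
      var <- which(mm == 1L & mm_cat == 0L)
      if (length(var)) {
        out$status[i] <- "variant"
        out$position[i] <- var[1]
        out$matched_text[i] <- paste(pv[var[1]:(var[1] + L - 1L)],
                                     collapse = "")
      }
    }
  }
  out
}

# Internal: decide a call given observed residues and per-class allowed sets.
diag_call <- function(observed, sets_by_pos, classes) {
  obs <- observed[!is.na(observed)]
  if (length(obs) < length(observed) / 2) return("unresolved")
  qualifies <- vapply(classes, function(cls) {
    all(vapply(names(obs), function(p) {
      obs[[p]] %in% unlist(sets_by_pos[[p]][[cls]])
    }, TRUE))
  }, TRUE)
  if (sum(qualifies) == 1) classes[qualifies]
  else if (sum(qualifies) == 0) "mixed"
  else "unresolved"
}

#' Type diagnostic residues against a reference scheme
#'
#' Globally aligns the query to the scheme's reference protein, reads the
#' query residues at the columns aligned to the scheme positions, and calls
#' the Type (1 vs 2) and subtype (a-c/e vs d) classes from the allowed
#' residue sets.
#'
#' @param protein_seq query protein.
#' @param reference_seq the scheme's reference protein (default: the
#'   synthetic diagnostic reference shipped with the package).
#' @param catalogs a \code{CatalogBundle} carrying the scheme.
#' @return list with \code{residues} (named character, NA = absent),
#'   \code{type_call}, \code{subtype_call}, \code{identity}.
#' @export
type_diagnostic_residues <- function(protein_seq,
                                     reference_seq = diagnostic_reference(catalogs),
                                     catalogs = load_catalogs()) {
  scheme <- catalogs$diagnostic_scheme
  all_pos <- as.integer(c(names(scheme$type_positions),
                          names(scheme$subtype_positions)))
  if (nchar(reference_seq) < max(all_pos)) {
    stop("type_diagnostic_residues: reference shorter than scheme position ",
         max(all_pos))
  }
  al <- global_align(protein_seq, reference_seq)
  map <- map_columns(al$aligned_b, al$aligned_a)   # ref position -> query letter
  read_at <- function(pos) {
    vapply(pos, function(p) {
      ch <- map[p]
      if (is.na(ch) || ch == "-") NA_character_ else ch
    }, "x")
  }
  type_obs <- setNames(read_at(as.integer(names(scheme$type_positions))),
                       names(scheme$type_positions))
  sub_obs <- setNames(read_at(as.integer(names(scheme$subtype_positions))),
                      names(scheme$subtype_positions))
  list(
    residues = c(type_obs, sub_obs),
    type_call = diag_call(type_obs, scheme$type_positions,
                          c("Type1", "Type2")),
    subtype_call = diag_call(sub_obs, scheme$subtype_positions,
                             c("ace", "d")),
    identity = al$identity)
}

#' Assign a clade by diagnostic typing plus nearest-reference identity
#'
#' When the diagnostic subtype call is decisive it restricts the candidate
#' clades (d vs a/c/e); the final clade is the candidate reference with the
#' highest global-alignment percent identity.  Identities below \code{floor}
#' yield \code{"unknown"}.
#'
#' @param protein_seq query protein.
#' @param references named character vector of clade representative
#'   sequences (default: the synthetic clade references).
#' @param typing optional result of \code{\link{type_diagnostic_residues}}.
#' @param floor minimum acceptable percent identity (default 25).
#' @return list with \code{clade}, \code{identity}, \code{rule},
#'   \code{identities} (per reference).
#' @export
assign_clade <- function(protein_seq, references = clade_references(),
                         typing = NULL, floor = 25) {
  ids <- vapply(references, function(ref)
    global_align(protein_seq, ref)$identity, 1.0)
  candidates <- names(references)
  rule <- "identity"
  if (!is.null(typing) && typing$subtype_call %in% c("ace", "d")) {
    keep <- if (typing$subtype_call == "d") {
      grepl("d$", candidates)
    } else !grepl("d$", candidates)
    if (any(keep)) {
      candidates <- candidates[keep]
      rule <- paste0("subtype(", typing$subtype_call, ")+identity")
    }
  }
  best <- candidates[which.max(ids[candidates])]
  if (ids[best] < floor) {
    return(list(clade = "unknown", identity = unname(ids[best]),
                rule = "below identity floor", identities = ids))
  }
  list(clade = best, identity = unname(ids[best]), rule = rule,
       identities = ids)
}

#' Classify a set of isoforms: motifs, clades and systematic names
#'
#' Applies the family curation protocol: signature-motif scan; proteins with
#' all motifs present (allowing the documented one-substitution variant)
#' keep the plain clade name, one or more absent motifs adds \code{-like},
#' all motifs absent marks a putative regulator (\code{reg}); low-confidence
#' gene models add \code{put.}; non-expressed models add \code{ne.} and the
#' placeholder core when the clade is unresolved.  Clades come from
#' \code{\link{assign_clade}}.
#'
#' @param proteins named character vector of protein sequences.
#' @param meta data.frame with columns \code{isoform_id}, \code{species}
#'   (Ta/Tu/Aet/Aes), \code{confidence} (high/low/non_expressed) and
#'   optionally \code{location}, \code{paralog}, \code{sv}.
#' @param catalogs a \code{CatalogBundle}.
#' @param references clade reference sequences.
#' @param strict_motifs passed to \code{\link{scan_signature_motifs}}.
#' @return data.frame with one row per isoform: motif statuses, clade,
#'   rule, class and generated \code{name}.
#' @export
classify_family <- function(proteins, meta, catalogs = load_catalogs(),
                            references = clade_references(catalogs),
                            strict_motifs = FALSE) {
  if (length(proteins) == 0) {
    return(data.frame(isoform_id = character(0), clade = character(0),
                      class = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(names(proteins) %in% meta$isoform_id))
  meta <- meta[match(names(proteins), meta$isoform_id), ]
  ref_seq <- diagnostic_reference(catalogs)
  rows <- lapply(seq_along(proteins), function(i) {
    seq_i <- proteins[[i]]
    mm <- scan_signature_motifs(seq_i, catalogs, strict = strict_motifs)
    n_absent <- sum(mm$status == "absent")
    klass <- if (n_absent == 0) "aox"
             else if (n_absent < nrow(mm)) "like"
             else "reg"
    typing <- tryCatch(
      type_diagnostic_residues(seq_i, ref_seq, catalogs),
      error = function(e) NULL)
    cl <- assign_clade(seq_i, references, typing = typing)
    conf <- meta$confidence[i]
    clade_known <- cl$clade != "unknown"
    parts <- list(
      species = meta$species[i],
      clade = if (klass == "reg" || !clade_known) NA_character_ else cl$clade,
      put = conf == "low",
      reg = klass == "reg",
      ne = conf == "non_expressed",
      like = klass == "like",
      location = if ("location" %in% names(meta)) meta$location[i]
                 else NA_character_,
      paralog = if ("paralog" %in% names(meta)) meta$paralog[i]
                else NA_integer_,
      sv = if ("sv" %in% names(meta)) meta$sv[i] else NA_integer_)
    data.frame(
      isoform_id = meta$isoform_id[i],
      motif_status = paste(mm$status, collapse = ","),
      n_motifs_ok = nrow(mm) - n_absent,
      type_call = if (is.null(typing)) NA_character_ else typing$type_call,
      subtype_call = if (is.null(typing)) NA_character_
                     else typing$subtype_call,
      clade = cl$clade,
      clade_identity = cl$identity,
      rule = cl$rule,
      class = klass,
      name = assign_name(parts),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
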