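#' Path to the default catalog configuration shipped with the package
#'
#' The catalog bundles the four signature motifs of the AOX diiron center,
#' the diagnostic-residue scheme used for Type/subtype classification, the
#' TbAOX position lists for the diiron, dimer-interface and
#' hydrophobic-cavity domains, the degenerate regulator motifs (including
#' the mitochondrial dysfunction motif, MDM), and the side-chain chemistry
#' map.  Values that cannot be transcribed from published tables (the
#' diagnostic allowed-residue sets, the diiron position list) are synthetic
#' defaults, flagged \code{synthetic_default} in the file, and are meant to
#' be overridden by user catalogs for real data.
#'
#' @return path to \code{default_catalog.json}.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "catalogs", "default_catalog.json",
              package = "aoxkit", mustWork = TRUE)
}

valid_iupac_pattern <- function(pattern) {
  all(chars(pattern) %in% names(IUPAC_DNA))
}

check_positions <- function(x, what) {
  x <- as.integer(x)
  if (anyDuplicated(x)) {
    stop("load_catalogs: duplicated position in ", what, ": ",
         paste(x[duplicated(x)], collapse = ", "))
  }
  if (is.unsorted(x, strictly = TRUE)) {
    stop("load_catalogs: positions not strictly increasing in ", what)
  }
  x
}

#' Load and validate a catalog configuration
#'
#' @param config_path path to a catalog JSON file; defaults to the catalog
#'   shipped with the package.
#' @return a validated \code{CatalogBundle} (list with class
#'   \code{"CatalogBundle"}) with components \code{signature_motifs},
#'   \code{diagnostic_scheme}, \code{tbaox_positions},
#'   \code{tbaox_residues}, \code{regulator_motifs}, \code{chemistry_map}.
#' @export
load_catalogs <- function(config_path = default_catalog_path()) {
  if (!file.exists(config_path)) {
    stop("load_catalogs: config not found: ", config_path)
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  required <- c("signature_motifs", "diagnostic_scheme", "tbaox_positions",
                "tbaox_residues", "regulator_motifs", "chemistry_map")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("load_catalogs: missing section(s): ", paste(missing, collapse = ", "))
  }

  sm <- cfg$signature_motifs
  if (anyDuplicated(sm$name)) stop("load_catalogs: duplicate motif name")
  for (i in seq_len(nrow(sm))) {
    if (!all(chars(sm$pattern[i]) %in% AA20)) {
      stop("load_catalogs: invalid amino-acid letter in signature motif '",
           sm$pattern[i], "'")
    }
    cat_pos <- sm$catalytic[[i]]
    if (any(cat_pos < 1 | cat_pos > nchar(sm$pattern[i]))) {
      stop("load_catalogs: catalytic position outside motif '",
           sm$name[i], "'")
    }
  }

  rm_ <- cfg$regulator_motifs
  if (anyDuplicated(rm_$name)) stop("load_catalogs: duplicate regulator name")
  for (i in seq_len(nrow(rm_))) {
    if (!valid_iupac_pattern(rm_$pattern[i])) {
      stop("load_catalogs: invalid IUPAC letter in pattern '",
           rm_$pattern[i], "' (motif ", rm_$name[i], ")")
    }
  }

  tp <- cfg$tbaox_positions
  tp <- lapply(setNames(names(tp), names(tp)),
               function(nm) check_positions(tp[[nm]], nm))
  res <- unlist(cfg$tbaox_residues)
  pos_all <- sort(unique(unlist(tp)))
  missing_res <- setdiff(as.character(pos_all), names(res))
  if (length(missing_res)) {
    stop("load_catalogs: tbaox_residues missing letters for positions: ",
         paste(missing_res, collapse = ", "))
  }
  if (!all(res %in% AA20)) {
    stop("load_catalogs: invalid residue letter in tbaox_residues")
  }

  ds <- cfg$diagnostic_scheme
  for (sec in c("type_positions", "subtype_positions")) {
    check_positions(as.integer(names(ds[[sec]])), sec)
    for (p in names(ds[[sec]])) {
      sets <- ds[[sec]][[p]]
      for (cls in names(sets)) {
        if (!all(unlist(sets[[cls]]) %in% AA20)) {
          stop("load_catalogs: invalid residue in diagnostic set at ", p)
        }
      }
    }
  }

  cm <- lapply(cfg$chemistry_map, unlist)
  covered <- unlist(cm)
  if (anyDuplicated(covered)) {
    stop("load_catalogs: residue assigned to several chemistry classes: ",
         paste(covered[duplicated(covered)], collapse = ", "))
  }

  out <- list(signature_motifs = sm, diagnostic_scheme = ds,
              tbaox_positions = tp,
              tbaox_residues = setNames(as.character(res), names(res)),
              regulator_motifs = rm_, chemistry_map = cm)
  class(out) <- "CatalogBundle"
  out
}

#' @export
print.CatalogBundle <- function(x, ...) {
  cat("CatalogBundle\n")
  cat("  signature motifs :", paste(x$signature_motifs$name, collapse = ", "),
      "\n")
  cat("  regulator motifs :", nrow(x$regulator_motifs), "\n")
  cat("  tbaox domains    :",
      paste(sprintf("%s(%d)", names(x$tbaox_positions),
                    lengths(x$tbaox_positions)), collapse = ", "), "\n")
  invisible(x)
}

# Internal: residue -> chemistry class lookup built from a chemistry map.
chemistry_lookup <- function(chemistry_map) {
  classes <- rep(names(chemistry_map), lengths(chemistry_map))
  setNames(classes, unlist(chemistry_map))
}
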