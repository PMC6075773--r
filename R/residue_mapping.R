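# Global alignment and transfer of residue numbering onto the TbAOX
# reference, with domain profile extraction and conservation summaries.

.submat_cache <- new.env(parent = emptyenv())

# Internal: fetch (and cache) a named substitution matrix from Biostrings.
substitution_matrix <- function(name) {
  if (!exists(name, envir = .submat_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .submat_cache)
  }
  get(name, envir = .submat_cache)
}

#' Needleman-Wunsch global alignment with percent identity
#'
#' Optimal global alignment under BLOSUM62 with affine gaps (open 10,
#' extend 0.5 by default), via \code{Biostrings::pairwiseAlignment}.
#' Percent identity uses alignment columns (gaps included) as the
#' denominator and is reported to 0.1%.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix name (default "BLOSUM62").
#' @return list with \code{aligned_a}, \code{aligned_b} (gapped strings),
#'   \code{score}, \code{identity} (percent), \code{columns}.
#' @export
global_align <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                         matrix = "BLOSUM62") {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("global_align: empty sequence")
  submat <- substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  av <- chars(a); bv <- chars(b)
  ncol_ <- length(av)
  ident <- round(100 * sum(av == bv & av != "-") / ncol_, 1)
  list(aligned_a = a, aligned_b = b, score = Biostrings::score(pa),
       identity = ident, columns = ncol_)
}

# Internal: from two gapped strings, return for each ungapped position of
# `gapped_ref` the character of `gapped_other` in the same column
# ("-" for a gap).
map_columns <- function(gapped_ref, gapped_other) {
  rv <- chars(gapped_ref); ov <- chars(gapped_other)
  ov[rv != "-"]
}

#' Transfer residue numbering from an isoform onto the TbAOX reference
#'
#' @param isoform_seq query protein.
#' @param tbaox_seq reference protein (default: the synthetic TbAOX
#'   scaffold).
#' @param floor percent-identity floor below which the map is flagged
#'   \code{low_identity} (default 20); the map is still emitted.
#' @param ... passed to \code{\link{global_align}}.
#' @return a \code{ResidueMap}: list with \code{pairs} (data.frame
#'   \code{tbaox_position}, \code{isoform_position} (NA = gap),
#'   \code{isoform_residue}), \code{identity}, \code{low_identity} flag.
#' @export
map_to_reference <- function(isoform_seq, tbaox_seq = tbaox_reference(),
                             floor = 20, ...) {
  al <- global_align(tbaox_seq, isoform_seq, ...)
  rv <- chars(al$aligned_a)   # reference with gaps
  qv <- chars(al$aligned_b)
  ref_pos <- cumsum(rv != "-")
  qry_pos <- cumsum(qv != "-")
  keep <- rv != "-"
  pairs <- data.frame(
    tbaox_position = ref_pos[keep],
    isoform_position = ifelse(qv[keep] == "-", NA_integer_, qry_pos[keep]),
    isoform_residue = ifelse(qv[keep] == "-", "-", qv[keep]),
    stringsAsFactors = FALSE)
  low <- al$identity < floor
  if (low) {
    warning("map_to_reference: identity ", al$identity,
            "% below floor (", floor, "%)")
  }
  out <- list(pairs = pairs, identity = al$identity, low_identity = low)
  class(out) <- "ResidueMap"
  out
}

#' Extract a functional-domain residue profile in TbAOX numbering
#'
#' @param map a \code{ResidueMap} from \code{\link{map_to_reference}}.
#' @param catalogs a \code{CatalogBundle}.
#' @param domain one of the catalog's domain names (\code{"diiron"},
#'   \code{"dimer_core"}, \code{"dimer_high"}, \code{"cavity"}, or
#'   \code{"dimer"} for core plus high).
#' @return a \code{DomainProfile}: list with \code{domain},
#'   \code{positions}, \code{residues} (named character, \code{"-"} for
#'   absent/unaligned) and \code{chemistry} (named character of classes,
#'   NA at gaps).
#' @export
extract_domain_profile <- function(map, catalogs = load_catalogs(),
                                   domain = "cavity") {
  pos <- if (domain == "dimer") {
    sort(c(catalogs$tbaox_positions$dimer_core,
           catalogs$tbaox_positions$dimer_high))
  } else catalogs$tbaox_positions[[domain]]
  if (is.null(pos)) stop("extract_domain_profile: unknown domain: ", domain)
  idx <- match(pos, map$pairs$tbaox_position)
  if (anyNA(idx)) {
    stop("extract_domain_profile: map does not cover position ",
         pos[which(is.na(idx))[1]])
  }
  residues <- setNames(map$pairs$isoform_residue[idx], pos)
  lut <- chemistry_lookup(catalogs$chemistry_map)
  chem <- setNames(ifelse(residues == "-", NA_character_,
                          unname(lut[residues])), pos)
  out <- list(domain = domain, positions = pos, residues = residues,
              chemistry = chem)
  class(out) <- "DomainProfile"
  out
}

#' Summarize conservation of a domain across isoform profiles
#'
#' Partitions the domain's positions into: identical to the reference in
#' every included isoform; uniform substitutions (all included isoforms
#' share one letter different from the reference); and mixed (everything
#' else, including any position where an included isoform is unaligned).
#'
#' @param profiles named list of \code{DomainProfile}s sharing a domain.
#' @param catalogs a \code{CatalogBundle} (supplies the reference letters).
#' @param exclude character vector of profile names dropped from the tally.
#' @return a \code{ConservationSummary}: list with
#'   \code{identical_positions}, \code{uniform_substitutions} (data.frame
#'   position/residue), \code{mixed_positions}, \code{excluded}.
#' @export
conservation_summary <- function(profiles, catalogs = load_catalogs(),
                                 exclude = character(0)) {
  if (length(profiles) == 0) stop("conservation_summary: no profiles")
  doms <- unique(vapply(profiles, function(p) p$domain, "x"))
  if (length(doms) != 1) stop("conservation_summary: mixed domains")
  keep <- setdiff(names(profiles), exclude)
  if (length(keep) == 0) stop("conservation_summary: all profiles excluded")
  pos <- profiles[[keep[1]]]$positions
  ref <- catalogs$tbaox_residues[as.character(pos)]
  mat <- do.call(rbind, lapply(profiles[keep], function(p)
    p$residues[as.character(pos)]))
  identical_pos <- integer(0)
  uniform <- data.frame(position = integer(0), residue = character(0),
                        stringsAsFactors = FALSE)
  mixed <- integer(0)
  for (j in seq_along(pos)) {
    col <- mat[, j]
    if (any(col == "-")) { mixed <- c(mixed, pos[j]); next }
    u <- unique(col)
    if (length(u) == 1 && u == ref[j]) {
      identical_pos <- c(identical_pos, pos[j])
    } else if (length(u) == 1) {
      uniform <- rbind(uniform, data.frame(position = pos[j], residue = u,
                                           stringsAsFactors = FALSE))
    } else mixed <- c(mixed, pos[j])
  }
  out <- list(domain = doms, identical_positions = identical_pos,
              uniform_substitutions = uniform, mixed_positions = mixed,
              excluded = exclude)
  class(out) <- "ConservationSummary"
  out
}

#' @export
print.ConservationSummary <- function(x, ...) {
  cat("ConservationSummary [", x$domain, "]\n", sep = "")
  cat("  identical to reference :", length(x$identical_positions), "\n")
  cat("  uniform substitutions  :", nrow(x$uniform_substitutions), "\n")
  cat("  mixed                  :", length(x$mixed_positions), "\n")
  if (length(x$excluded)) cat("  excluded:", paste(x$excluded,
                                                  collapse = ", "), "\n")
  invisible(x)
}

#' Side-chain chemistry counts and ratios for a domain profile
#'
#' @param profile a \code{DomainProfile}.
#' @param chemistry_map chemistry class map (residue sets per class).
#' @return list with \code{counts} (per class, plus \code{gaps}),
#'   \code{ratios} (over classified residues; all NA when only gaps) and
#'   \code{undefined} flag.
#' @export
chemistry_ratios <- function(profile,
                             chemistry_map = load_catalogs()$chemistry_map) {
  lut <- chemistry_lookup(chemistry_map)
  res <- profile$residues
  gaps <- sum(res == "-")
  res <- res[res != "-"]
  unknown <- setdiff(unique(res), names(lut))
  if (length(unknown)) {
    stop("chemistry_ratios: residue not in chemistry map: ",
         paste(unknown, collapse = ", "))
  }
  classes <- names(chemistry_map)
  counts <- setNames(vapply(classes, function(cl)
    sum(lut[res] == cl), 1L), classes)
  total <- sum(counts)
  ratios <- if (total == 0) setNames(rep(NA_real_, length(classes)), classes)
            else counts / total
  list(counts = c(counts, gaps = gaps), ratios = ratios,
       undefined = total == 0)
}
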