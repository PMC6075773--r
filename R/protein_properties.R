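# Protein physical properties: molecular weight (average masses),
# Henderson-Hasselbalch net charge and isoelectric point by bisection.

# Average residue masses (Da); one water is added per chain.
AVERAGE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Named pKa sets for isoelectric-point computation
#'
#' Published pKa sets; the tool behind typical curation tables does not
#' document its set, so results should always be reported together with the
#' set used.
#'
#' @return named list of pKa vectors with entries \code{Nterm},
#'   \code{Cterm}, \code{K}, \code{R}, \code{H}, \code{D}, \code{E},
#'   \code{C}, \code{Y}.
#' @export
pka_sets <- function() {
  list(
    emboss = c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
               D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    lehninger = c(Nterm = 9.69, Cterm = 2.34, K = 10.53, R = 12.48,
                  H = 6.0, D = 3.65, E = 4.25, C = 8.18, Y = 10.07),
    sillero = c(Nterm = 8.2, Cterm = 3.2, K = 10.4, R = 12.0, H = 6.4,
                D = 4.0, E = 4.5, C = 9.0, Y = 10.0))
}

resolve_pka <- function(pka) {
  if (is.character(pka)) {
    sets <- pka_sets()
    if (!pka %in% names(sets)) stop("unknown pKa set: ", pka)
    return(sets[[pka]])
  }
  needed <- c("Nterm", "Cterm", "K", "R", "H", "D", "E", "C", "Y")
  missing <- setdiff(needed, names(pka))
  if (length(missing)) stop("pKa set missing entries: ",
                            paste(missing, collapse = ", "))
  pka
}

#' Molecular weight of a protein (kDa)
#'
#' Sum of average residue masses plus one water; X is disallowed here.
#'
#' @param protein_seq amino-acid string (20 standard letters).
#' @param mass_table named residue mass vector (Da).
#' @return list with \code{da} (Daltons) and \code{kda} (kilodaltons,
#'   rounded half-even to 1 decimal, the convention of curation tables).
#' @export
compute_mw <- function(protein_seq, mass_table = AVERAGE_MASS) {
  v <- chars(toupper(protein_seq))
  unknown <- setdiff(unique(v), names(mass_table))
  if (length(unknown)) {
    stop("compute_mw: unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  da <- sum(mass_table[v]) + WATER_MASS
  list(da = da, kda = round(da / 1000, 1))
}

#' Net charge of a protein at a given pH
#'
#' Positive groups (N-terminus, K, R, H) contribute
#' \code{1/(1+10^(pH-pKa))}; negative groups (C-terminus, D, E, C, Y)
#' contribute \code{-1/(1+10^(pKa-pH))}.
#'
#' @param protein_seq amino-acid string.
#' @param pH pH value(s).
#' @param pka pKa set name (\code{"emboss"}, \code{"lehninger"},
#'   \code{"sillero"}) or a named vector.
#' @return numeric net charge (vectorized over \code{pH}).
#' @export
net_charge <- function(protein_seq, pH, pka = "emboss") {
  pk <- resolve_pka(pka)
  v <- chars(toupper(protein_seq))
  counts <- table(factor(v, levels = c("K", "R", "H", "D", "E", "C", "Y")))
  pos_groups <- c(Nterm = 1, K = as.numeric(counts["K"]),
                  R = as.numeric(counts["R"]), H = as.numeric(counts["H"]))
  neg_groups <- c(Cterm = 1, D = as.numeric(counts["D"]),
                  E = as.numeric(counts["E"]), C = as.numeric(counts["C"]),
                  Y = as.numeric(counts["Y"]))
  vapply(pH, function(p) {
    pos <- sum(pos_groups / (1 + 10^(p - pk[names(pos_groups)])))
    neg <- sum(neg_groups / (1 + 10^(pk[names(neg_groups)] - p)))
    pos - neg
  }, 1.0)
}

#' Theoretical isoelectric point by bisection
#'
#' Bisects the net-charge function on [0, 14] to tolerance \code{tol};
#' reported to 2 decimals.
#'
#' @inheritParams net_charge
#' @param tol pH tolerance of the bisection (default 0.001).
#' @return list with \code{pi} (2 decimals), \code{pi_raw}, \code{pka_set}.
#' @export
compute_pi <- function(protein_seq, pka = "emboss", tol = 0.001) {
  pk <- resolve_pka(pka)
  lo <- 0; hi <- 14
  c_lo <- net_charge(protein_seq, lo, pk)
  c_hi <- net_charge(protein_seq, hi, pk)
  if (!(c_lo > 0 && c_hi < 0)) {
    stop("compute_pi: no isoelectric point in [0, 14] ",
         "(no ionizable groups bracketing zero)")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(protein_seq, mid, pk) > 0) lo <- mid else hi <- mid
  }
  root <- (lo + hi) / 2
  list(pi = round(root, 2), pi_raw = root,
       pka_set = if (is.character(pka)) pka else "custom")
}

#' Per-isoform protein property table
#'
#' @param proteins named character vector of protein sequences.
#' @param pka pKa set (see \code{\link{net_charge}}).
#' @return data.frame with \code{isoform_id}, \code{length},
#'   \code{mw_kda}, \code{pi}, \code{pka_set}.
#' @export
protein_properties <- function(proteins, pka = "emboss") {
  rows <- lapply(names(proteins), function(id) {
    s <- proteins[[id]]
    data.frame(isoform_id = id, length = nchar(s),
               mw_kda = compute_mw(s)$kda,
               pi = compute_pi(s, pka = pka)$pi,
               pka_set = if (is.character(pka)) pka else "custom",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
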