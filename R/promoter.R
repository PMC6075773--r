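# Degenerate (IUPAC) motif scanning over promoters and gene bodies, and
# catalog-driven cis-element tallies.

# Internal: mismatch count of one window against an IUPAC pattern
# (character vectors).  N pattern positions never mismatch; ambiguity
# letters in the subject match by set intersection.
iupac_mismatches <- function(window, pattern) {
  n <- 0L
  for (k in seq_along(pattern)) {
    if (pattern[k] == "N") next
    pset <- IUPAC_DNA[[pattern[k]]]
    sset <- IUPAC_DNA[[window[k]]]
    if (is.null(sset) || !any(sset %in% pset)) n <- n + 1L
  }
  n
}

#' Scan a sequence for a degenerate IUPAC motif
#'
#' A window matches when every non-N pattern position's IUPAC set contains
#' the base (ambiguity letters in the sequence match by set intersection),
#' allowing up to \code{max_mismatch} violations.  Minus-strand hits are
#' matches of the reverse complement of the pattern, reported in plus
#' coordinates of the scanned sequence.  All overlapping hits are reported,
#' sorted by start then strand.
#'
#' @param seq DNA string (softmasked lowercase is uppercased first).
#' @param pattern IUPAC pattern.
#' @param max_mismatch maximum tolerated violations (default 0).
#' @param strands subset of \code{c("+", "-")}.
#' @return data.frame with \code{start}, \code{end}, \code{strand},
#'   \code{matched_text}, \code{mismatches}.
#' @export
scan_iupac <- function(seq, pattern, max_mismatch = 0L,
                       strands = c("+", "-")) {
  pattern <- toupper(pattern)
  if (!valid_iupac_pattern(pattern)) {
    stop("scan_iupac: invalid IUPAC letter in pattern '", pattern, "'")
  }
  stopifnot(all(strands %in% c("+", "-")))
  seq <- toupper(seq)
  subject <- Biostrings::DNAString(seq)
  L <- nchar(pattern)
  hits <- NULL
  for (strand in strands) {
    pat <- if (strand == "+") pattern else revcomp(pattern)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatch,
                                  fixed = FALSE)
    if (length(m) == 0) next
    starts <- Biostrings::start(m)
    # drop out-of-limit alignments (allowed by matchPattern when
    # max.mismatch > 0): only fully contained windows count
    starts <- starts[starts >= 1L & starts + L - 1L <= nchar(seq)]
    if (length(starts) == 0) next
    texts <- substring(seq, starts, starts + L - 1L)
    pv <- chars(pat)
    mm <- vapply(texts, function(tx) iupac_mismatches(chars(tx), pv), 1L,
                 USE.NAMES = FALSE)
    hits <- rbind(hits, data.frame(
      start = starts, end = starts + L - 1L, strand = strand,
      matched_text = texts, mismatches = mm, stringsAsFactors = FALSE))
  }
  if (is.null(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), matched_text = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count deviations of a matched site from a stringent pattern
#'
#' For a hit found with a relaxed pattern, counts the non-N positions of
#' the stringent pattern whose IUPAC set excludes the matched base; a
#' single-deviation hit is flagged with its 1-based site index.
#'
#' @param matched_text the matched window (plain bases).
#' @param stringent_pattern IUPAC pattern of the same length.
#' @return list with \code{deviations} and \code{site} (NA unless exactly
#'   one deviation).
#' @export
classify_deviation <- function(matched_text, stringent_pattern) {
  matched_text <- toupper(matched_text)
  stringent_pattern <- toupper(stringent_pattern)
  if (nchar(matched_text) != nchar(stringent_pattern)) {
    stop("classify_deviation: length mismatch")
  }
  if (!valid_iupac_pattern(stringent_pattern)) {
    stop("classify_deviation: invalid IUPAC letter in pattern")
  }
  pv <- chars(stringent_pattern); wv <- chars(matched_text)
  dev <- integer(0)
  for (k in seq_along(pv)) {
    if (pv[k] == "N") next
    if (!wv[k] %in% IUPAC_DNA[[pv[k]]]) dev <- c(dev, k)
  }
  list(deviations = length(dev),
       site = if (length(dev) == 1) dev else NA_integer_)
}

#' Tally cis-element categories in a promoter
#'
#' Scans each catalog motif at 0 mismatches and sums hits per category.
#'
#' @param promoter_seq DNA string.
#' @param regulator_motifs data.frame with \code{name}, \code{pattern},
#'   \code{category} (as in a \code{CatalogBundle}).
#' @param categories character vector of known categories; a motif
#'   referencing an unknown category is an error.
#' @param strands strand convention passed to \code{\link{scan_iupac}}.
#' @return data.frame with \code{category}, \code{motif_names},
#'   \code{count}.
#' @export
tally_elements <- function(promoter_seq, regulator_motifs,
                           categories = unique(regulator_motifs$category),
                           strands = c("+", "-")) {
  if (is.null(regulator_motifs) || nrow(regulator_motifs) == 0) {
    return(data.frame(category = character(0), motif_names = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  unknown <- setdiff(regulator_motifs$category, categories)
  if (length(unknown)) {
    stop("tally_elements: motif references unknown category: ",
         paste(unknown, collapse = ", "))
  }
  per_motif <- vapply(seq_len(nrow(regulator_motifs)), function(i) {
    nrow(scan_iupac(promoter_seq, regulator_motifs$pattern[i],
                    max_mismatch = 0L, strands = strands))
  }, 1L)
  out <- lapply(categories, function(cat) {
    idx <- which(regulator_motifs$category == cat)
    data.frame(category = cat,
               motif_names = paste(regulator_motifs$name[idx],
                                   collapse = ","),
               count = sum(per_motif[idx]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect CpG islands by windowed observed/expected statistics
#'
#' Slides a window of size \code{window} in steps of 1; each window's GC%
#' and observed/expected CpG ratio (\code{#CG * window / (#C * #G)}) are
#' attributed to the window midpoint (\code{start + floor(window/2)}).
#' Islands are maximal runs of midpoints exceeding both thresholds
#' (strictly) spanning at least \code{min_len} bases; reported coordinates
#' are the first and last midpoint of the run.
#'
#' @param seq DNA string.
#' @param window window size (default 100).
#' @param min_len minimum island span (default 200).
#' @param oe_threshold observed/expected threshold (default 0.6).
#' @param gc_threshold GC percentage threshold (default 50).
#' @return data.frame with \code{start}, \code{end}, \code{length},
#'   \code{mean_gc}, \code{mean_oe}; empty (with a warning) when the
#'   sequence is shorter than the window.
#' @export
find_cpg_islands <- function(seq, window = 100L, min_len = 200L,
                             oe_threshold = 0.6, gc_threshold = 50) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), mean_gc = numeric(0),
                      mean_oe = numeric(0), stringsAsFactors = FALSE)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < window) {
    warning("find_cpg_islands: sequence shorter than window")
    return(empty)
  }
  v <- chars(seq)
  isC <- as.integer(v == "C")
  isG <- as.integer(v == "G")
  isCG <- as.integer(v[-L] == "C" & v[-1] == "G")
  csC <- c(0L, cumsum(isC))
  csG <- c(0L, cumsum(isG))
  csCG <- c(0L, cumsum(isCG))
  starts <- seq_len(L - window + 1L)
  nC <- csC[starts + window] - csC[starts]
  nG <- csG[starts + window] - csG[starts]
  # CG dinucleotides fully inside the window: starts at s .. s+window-2
  nCG <- csCG[pmin(starts + window - 1L, L)] - csCG[starts]
  gc <- 100 * (nC + nG) / window
  oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
  qual <- gc > gc_threshold & oe > oe_threshold
  if (!any(qual)) return(empty)
  r <- rle(qual)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  mid <- as.integer(floor(window / 2))
  out <- NULL
  for (k in which(r$values)) {
    s_run <- starts_idx[k]; e_run <- ends_idx[k]
    island_start <- starts[s_run] + mid
    island_end <- starts[e_run] + mid
    len <- island_end - island_start + 1L
    if (len < min_len) next
    idx <- s_run:e_run
    out <- rbind(out, data.frame(
      start = island_start, end = island_end, length = len,
      mean_gc = round(mean(gc[idx]), 2), mean_oe = round(mean(oe[idx]), 3),
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) empty else out
}
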