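# Exon/intron delineation by spliced exact matching of a transcript (or CDS)
# against its genomic sequence.  Transcript and gene come from the same
# assembly, so an anchor-and-extend exact matcher is sufficient; boundary
# ambiguity (identical bases on both sides of a junction) is resolved by
# preferring canonical GT..AG introns, then the leftmost donor.

# Internal: all start positions of `pat` in `subj` (exact, 1-based).
find_exact <- function(pat, subj) {
  m <- gregexpr(pat, subj, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Internal: length of the maximal exact extension of transcript[t..] against
# genomic[g..].
max_extension <- function(tv, gv, t, g) {
  n <- min(length(tv) - t, length(gv) - g) + 1L
  if (n <= 0) return(0L)
  cmp <- tv[t:(t + n - 1L)] != gv[g:(g + n - 1L)]
  w <- which(cmp)
  if (length(w) == 0) n else w[1] - 1L
}

#' Delineate exon/intron structure from a transcript and its gene
#'
#' Aligns \code{transcript_seq} to \code{genomic_seq} as a spliced exact
#' subsequence and returns the implied exons, introns and splice
#' dinucleotides.  Among equally valid junction placements, GT..AG introns
#' are preferred, then the leftmost donor; remaining ties set
#' \code{ambiguous = TRUE}.
#'
#' @param transcript_seq spliced transcript (or CDS) sequence.
#' @param genomic_seq genomic sequence of the gene.
#' @param min_intron minimum intron length (default 20).
#' @param max_mismatch total substitution mismatches tolerated inside exons
#'   (default 0, i.e. exact; reconstruction is exact only at 0).
#' @param anchor exact seed length used to locate the next exon (default 12).
#' @return a \code{GeneStructure}: list with \code{exons} and \code{introns}
#'   (2-column matrices of 1-based inclusive genomic intervals),
#'   \code{n_exons}, \code{n_introns}, \code{splice_dinucleotides}
#'   (data.frame of donor/acceptor pairs), \code{transcript_length},
#'   \code{ambiguous} flag and the input sequences.
#' @export
delineate_structure <- function(transcript_seq, genomic_seq, min_intron = 20L,
                                max_mismatch = 0L, anchor = 12L) {
  transcript_seq <- toupper(transcript_seq)
  genomic_seq <- toupper(genomic_seq)
  tv <- chars(transcript_seq)
  gv <- chars(genomic_seq)
  Tn <- length(tv)
  if (Tn == 0) stop("delineate_structure: empty transcript")
  budget <- as.integer(max_mismatch)
  ambiguous <- FALSE

  seed1 <- substr(transcript_seq, 1L, min(anchor, Tn))
  starts <- find_exact(seed1, genomic_seq)
  if (length(starts) == 0) {
    stop("delineate_structure: transcript not derivable from genomic; ",
         "first unplaceable offset 1")
  }
  if (length(starts) > 1) ambiguous <- TRUE
  g <- starts[1]
  t <- 1L
  exons <- NULL

  repeat {
    m <- max_extension(tv, gv, t, g)
    # absorb isolated substitutions while mismatch budget remains
    while (budget > 0L && t + m <= Tn && g + m <= length(gv)) {
      m2 <- max_extension(tv, gv, t + m + 1L, g + m + 1L)
      if (m2 >= anchor || t + m + m2 >= Tn) {
        budget <- budget - 1L
        m <- m + 1L + m2
      } else break
    }
    if (t + m - 1L == Tn) {
      exons <- rbind(exons, c(g, g + m - 1L))
      break
    }
    if (m == 0L) {
      stop("delineate_structure: transcript not derivable from genomic; ",
           "first unplaceable offset ", t)
    }
    t_next <- t + m
    seed <- paste(tv[t_next:min(t_next + anchor - 1L, Tn)], collapse = "")
    cand <- find_exact(seed, genomic_seq)
    cand <- cand[cand > g + m]   # next exon must start past current match
    placed <- FALSE
    for (g2 in cand) {
      # boundary slide: bases equal on both sides of the junction
      b <- 0L
      while (b < m - 1L && t_next - b - 1L >= t + 1L &&
             g2 - b - 1L >= 1L &&
             gv[g2 - b - 1L] == tv[t_next - b - 1L]) {
        b <- b + 1L
      }
      svals <- 0:b
      istart <- g + m - svals          # intron first base
      iend <- g2 - svals - 1L          # intron last base
      ok <- (iend - istart + 1L) >= min_intron
      if (!any(ok)) next
      svals <- svals[ok]; istart <- istart[ok]; iend <- iend[ok]
      donor <- paste0(gv[istart], gv[istart + 1L])
      accpt <- paste0(gv[iend - 1L], gv[iend])
      canonical <- donor == "GT" & accpt == "AG"
      pick <- if (any(canonical)) which(canonical) else seq_along(svals)
      if (length(pick) > 1) {
        # leftmost donor among the preferred class
        best <- pick[which.min(istart[pick])]
        if (!any(canonical)) ambiguous <- TRUE
        if (any(canonical) && sum(canonical) > 1) ambiguous <- TRUE
      } else best <- pick
      s <- svals[best]
      exons <- rbind(exons, c(g, g + m - s - 1L))
      t <- t_next - s
      g <- g2 - s
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("delineate_structure: transcript not derivable from genomic; ",
           "first unplaceable offset ", t_next)
    }
  }

  build_structure(exons, genomic_seq, transcript_seq, ambiguous)
}

# Internal: assemble a GeneStructure from an exon matrix.
build_structure <- function(exons, genomic_seq, transcript_seq = NULL,
                            ambiguous = FALSE) {
  exons <- matrix(as.integer(exons), ncol = 2)
  n <- nrow(exons)
  introns <- if (n > 1) {
    cbind(exons[-n, 2] + 1L, exons[-1, 1] - 1L)
  } else matrix(integer(0), ncol = 2)
  gv <- chars(genomic_seq)
  dinuc <- if (nrow(introns)) {
    data.frame(
      donor = paste0(gv[introns[, 1]], gv[introns[, 1] + 1L]),
      acceptor = paste0(gv[introns[, 2] - 1L], gv[introns[, 2]]),
      stringsAsFactors = FALSE)
  } else data.frame(donor = character(0), acceptor = character(0))
  st <- list(exons = exons, introns = introns, n_exons = n,
             n_introns = nrow(introns), splice_dinucleotides = dinuc,
             transcript_length = sum(exons[, 2] - exons[, 1] + 1L),
             genomic_seq = genomic_seq, transcript_seq = transcript_seq,
             ambiguous = ambiguous)
  class(st) <- "GeneStructure"
  st
}

#' @export
print.GeneStructure <- function(x, ...) {
  cat("GeneStructure:", x$n_exons, "exon(s),", x$n_introns, "intron(s)\n")
  cat("  exons  :", paste(format_span(x$exons[, 1], x$exons[, 2]),
                          collapse = " "), "\n")
  if (x$n_introns > 0) {
    cat("  introns:", paste(format_span(x$introns[, 1], x$introns[, 2]),
                            collapse = " "), "\n")
    cat("  splice :", paste(paste0(x$splice_dinucleotides$donor, "..",
                                   x$splice_dinucleotides$acceptor),
                            collapse = " "), "\n")
  }
  if (isTRUE(x$ambiguous)) cat("  warning: junction placement ambiguous\n")
  invisible(x)
}

#' Splice a genomic sequence by an exon matrix
#'
#' @param genomic_seq genomic sequence.
#' @param exons 2-column matrix of 1-based inclusive intervals.
#' @return the concatenated exon sequence.
#' @export
splice_seq <- function(genomic_seq, exons) {
  paste(substring(genomic_seq, exons[, 1], exons[, 2]), collapse = "")
}

# Internal: interval-set helpers on integer ranges (closed, 1-based).
ranges_setdiff <- function(a, b) {
  # a, b: 2-col matrices; returns maximal sub-intervals of a not covered by b
  out <- NULL
  for (i in seq_len(nrow(a))) {
    pieces <- matrix(a[i, ], ncol = 2)
    for (j in seq_len(nrow(b))) {
      nxt <- NULL
      for (k in seq_len(nrow(pieces))) {
        s <- pieces[k, 1]; e <- pieces[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be < s || bs > e) { nxt <- rbind(nxt, c(s, e)); next }
        if (bs > s) nxt <- rbind(nxt, c(s, bs - 1L))
        if (be < e) nxt <- rbind(nxt, c(be + 1L, e))
      }
      pieces <- if (is.null(nxt)) matrix(integer(0), ncol = 2) else nxt
      if (nrow(pieces) == 0) break
    }
    out <- rbind(out, pieces)
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

ranges_contain <- function(iv, ranges) {
  any(apply(matrix(ranges, ncol = 2), 1,
            function(r) iv[1] >= r[1] && iv[2] <= r[2]))
}

#' Classify structural differences between two splice variants
#'
#' Each maximal interval exonic in exactly one structure is emitted once and
#' labeled: inside the other structure's intron, \code{intron_retention};
#' upstream of the other's first exon, \code{alt_5utr}; downstream of its
#' last exon, \code{alt_3utr}; otherwise \code{other}.
#'
#' @param structure_a,structure_b \code{GeneStructure} objects delineated on
#'   the same genomic sequence.
#' @return data.frame with columns \code{event_type}, \code{start},
#'   \code{end}, \code{exonic_in}, \code{description}.
#' @export
classify_splice_events <- function(structure_a, structure_b) {
  if (!identical(structure_a$genomic_seq, structure_b$genomic_seq)) {
    stop("classify_splice_events: structures are from different genes")
  }
  out <- data.frame(event_type = character(0), start = integer(0),
                    end = integer(0), exonic_in = character(0),
                    description = character(0), stringsAsFactors = FALSE)
  pair <- list(a = structure_a, b = structure_b)
  for (who in c("a", "b")) {
    this <- pair[[who]]; other <- pair[[setdiff(c("a", "b"), who)]]
    only <- ranges_setdiff(this$exons, other$exons)
    if (nrow(only) == 0) next
    only <- only[order(only[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(only))) {
      iv <- only[i, ]
      first_exon <- min(other$exons[, 1]); last_exon <- max(other$exons[, 2])
      type <- if (nrow(other$introns) > 0 && ranges_contain(iv, other$introns)) {
        "intron_retention"
      } else if (iv[2] < first_exon) {
        "alt_5utr"
      } else if (iv[1] > last_exon) {
        "alt_3utr"
      } else "other"
      desc <- sprintf("interval %s exonic only in structure %s (%s)",
                      format_span(iv[1], iv[2]), who, type)
      out <- rbind(out, data.frame(event_type = type, start = iv[1],
                                   end = iv[2], exonic_in = who,
                                   description = desc,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Summarize gene structures
#'
#' @param structures named list of \code{GeneStructure} objects.
#' @param cds_lengths optional named integer vector of coding-sequence
#'   lengths per structure.
#' @return data.frame with gene length, transcript length, CDS length,
#'   exon and intron counts, in input order.
#' @export
structure_summary <- function(structures, cds_lengths = NULL) {
  if (length(structures) == 0) {
    return(data.frame(name = character(0), gene_length = integer(0),
                      transcript_length = integer(0), cds_length = integer(0),
                      n_exons = integer(0), n_introns = integer(0),
                      stringsAsFactors = FALSE))
  }
  nm <- names(structures)
  data.frame(
    name = nm,
    gene_length = vapply(structures, function(s) nchar(s$genomic_seq), 1L),
    transcript_length = vapply(structures, function(s)
      as.integer(s$transcript_length), 1L),
    cds_length = if (is.null(cds_lengths)) NA_integer_
                 else as.integer(cds_lengths[nm]),
    n_exons = vapply(structures, function(s) as.integer(s$n_exons), 1L),
    n_introns = vapply(structures, function(s) as.integer(s$n_introns), 1L),
    stringsAsFactors = FALSE, row.names = NULL)
}
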