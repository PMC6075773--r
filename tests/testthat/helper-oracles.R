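# Independent brute-force oracles used by the property tests.  These stay
# deliberately naive and share no code with the implementation paths they
# check.

# IUPAC base sets, restated independently of the package internals.
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# Naive per-window degenerate scanner (plus strand of the given pattern).
oracle_scan_one_strand <- function(seq, pattern, max_mismatch) {
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  L <- length(pv)
  hits <- integer(0)
  mism <- integer(0)
  for (s in seq_len(length(sv) - L + 1L)) {
    mm <- 0L
    for (k in seq_len(L)) {
      if (pv[k] == "N") next
      base <- sv[s + k - 1L]
      bset <- ORACLE_IUPAC[[base]]
      if (is.null(bset) || !any(bset %in% ORACLE_IUPAC[[pv[k]]])) mm <- mm + 1L
    }
    if (mm <= max_mismatch) { hits <- c(hits, s); mism <- c(mism, mm) }
  }
  data.frame(start = hits, mismatches = mism)
}

oracle_scan <- function(seq, pattern, max_mismatch = 0L,
                        strands = c("+", "-")) {
  out <- NULL
  if ("+" %in% strands) {
    h <- oracle_scan_one_strand(seq, pattern, max_mismatch)
    if (nrow(h)) out <- rbind(out, cbind(h, strand = "+"))
  }
  if ("-" %in% strands) {
    h <- oracle_scan_one_strand(seq, oracle_revcomp(pattern), max_mismatch)
    if (nrow(h)) out <- rbind(out, cbind(h, strand = "-"))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), mismatches = integer(0),
                      strand = character(0)))
  }
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Exhaustive global-alignment score by enumerating all sets of matched
# pairs; each unmatched stretch between consecutive matches is charged as
# (at most) one gap run per sequence: open + extend * len.
oracle_align_score <- function(a, b, submat, gap_open = 10,
                               gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na_ <- length(av); nb <- length(bv)
  gap_cost <- function(len) if (len > 0) gap_open + gap_extend * len else 0
  score_pairs <- function(ia, ib) {
    s <- 0
    prev_a <- 0L; prev_b <- 0L
    for (k in seq_along(ia)) {
      s <- s + submat[av[ia[k]], bv[ib[k]]] -
        gap_cost(ia[k] - prev_a - 1L) - gap_cost(ib[k] - prev_b - 1L)
      prev_a <- ia[k]; prev_b <- ib[k]
    }
    s - gap_cost(na_ - prev_a) - gap_cost(nb - prev_b)
  }
  best <- -Inf
  for (k in 0:min(na_, nb)) {
    ia_set <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(na_, k), 2)
    ib_set <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(nb, k), 2)
    for (ia in ia_set) for (ib in ib_set) {
      best <- max(best, score_pairs(as.integer(ia), as.integer(ib)))
    }
  }
  best
}

# Exhaustive spliced-placement search: all ways to place `transcript` on
# `genomic` as exact exons separated by introns >= min_intron, ranked by
# the documented preference (per junction: GT..AG first, then leftmost
# donor).  Returns the exon matrix of the best structure.
oracle_delineate <- function(transcript, genomic, min_intron = 20L) {
  tv <- strsplit(transcript, "")[[1]]
  gv <- strsplit(genomic, "")[[1]]
  Tn <- length(tv); Gn <- length(gv)
  results <- list()
  recurse <- function(t, g, exons) {
    # maximal extension
    m <- 0L
    while (t + m - 1L < Tn && g + m - 1L < Gn &&
           tv[t + m] == gv[g + m]) m <- m + 1L
    if (t + m - 1L == Tn) {
      results[[length(results) + 1L]] <<- rbind(exons, c(g, g + m - 1L))
    }
    if (m == 0L) return(invisible())
    for (e_len in seq_len(m)) {
      t2 <- t + e_len
      if (t2 > Tn) next
      g_lo <- g + e_len + min_intron
      if (g_lo > Gn) next
      for (g2 in g_lo:Gn) {
        if (gv[g2] != tv[t2]) next
        recurse(t2, g2, rbind(exons, c(g, g + e_len - 1L)))
      }
    }
  }
  for (g0 in which(gv == tv[1])) recurse(1L, g0, NULL)
  if (length(results) == 0) return(NULL)
  # rank: per junction, GT-AG beats non-canonical; then smaller donor pos;
  # fewer introns preferred only via earlier full-extension (compare keys).
  key <- function(ex) {
    n <- nrow(ex)
    if (n == 1) return(list(first_exon = ex[1, 1], junctions = NULL))
    don <- ex[-n, 2] + 1L
    acc <- ex[-1, 1] - 1L
    canon <- ifelse(gv[don] == "G" & gv[don + 1L] == "T" &
                    gv[acc - 1L] == "A" & gv[acc] == "G", 0L, 1L)
    list(first_exon = ex[1, 1],
         junctions = as.vector(rbind(canon, don)))
  }
  better <- function(k1, k2) {
    if (k1$first_exon != k2$first_exon) return(k1$first_exon < k2$first_exon)
    j1 <- k1$junctions; j2 <- k2$junctions
    L <- min(length(j1), length(j2))
    if (L > 0) for (i in seq_len(L)) {
      if (j1[i] != j2[i]) return(j1[i] < j2[i])
    }
    length(j1) <= length(j2)
  }
  best <- results[[1]]; kb <- key(best)
  for (r in results[-1]) {
    kr <- key(r)
    if (better(kr, kb)) { best <- r; kb <- kr }
  }
  best
}

# pI oracle: dense grid argmin of |net charge|.
oracle_pi_grid <- function(protein, pka = "emboss", step = 1e-4) {
  grid <- seq(0, 14, by = step)
  ch <- abs(net_charge(protein, grid, pka))
  grid[which.min(ch)]
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
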