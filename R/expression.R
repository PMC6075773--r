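# Expression matrices for heat-map display: treatment-vs-control log2
# ratios of transcript abundance (TPM).

#' Build a log2 treatment/control ratio matrix
#'
#' @param abundance numeric matrix (isoforms x conditions) of non-negative
#'   abundances, with dimnames.
#' @param pairs data.frame with columns \code{name}, \code{treatment},
#'   \code{control} naming abundance columns.
#' @param pseudocount added to numerator and denominator (default 0.01);
#'   set 0 only when abundances are strictly positive.
#' @param log2_scale when FALSE, plain ratios are returned instead.
#' @return an \code{ExpressionMatrix}: list with \code{values} (matrix),
#'   \code{kind}, \code{pairs}, \code{pseudocount}.
#' @export
ratio_matrix <- function(abundance, pairs, pseudocount = 0.01,
                         log2_scale = TRUE) {
  stopifnot(is.matrix(abundance))
  if (any(abundance < 0)) stop("ratio_matrix: negative abundance")
  missing_cols <- setdiff(c(pairs$treatment, pairs$control),
                          colnames(abundance))
  if (length(missing_cols)) {
    stop("ratio_matrix: unmatched column name(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (pseudocount < 0) stop("ratio_matrix: pseudocount must be >= 0")
  vals <- sapply(seq_len(nrow(pairs)), function(i) {
    tr <- abundance[, pairs$treatment[i]] + pseudocount
    ct <- abundance[, pairs$control[i]] + pseudocount
    r <- tr / ct
    if (log2_scale) log2(r) else r
  })
  vals <- matrix(vals, nrow = nrow(abundance),
                 dimnames = list(rownames(abundance), pairs$name))
  out <- list(values = vals,
              kind = if (log2_scale) "log2_ratio" else "ratio",
              pairs = pairs, pseudocount = pseudocount)
  class(out) <- "ExpressionMatrix"
  out
}

#' Export a heat-map matrix as TSV (optionally with an image)
#'
#' The TSV is bit-stable across runs; the image is cosmetic.
#'
#' @param matrix an \code{ExpressionMatrix} or plain numeric matrix.
#' @param path output TSV path.
#' @param image optional PNG path; drawn with \code{stats::heatmap} when
#'   the matrix is at least 2x2.
#' @return invisibly, \code{path}.
#' @export
export_heatmap_matrix <- function(matrix, path, image = NULL) {
  vals <- if (inherits(matrix, "ExpressionMatrix")) matrix$values else matrix
  df <- data.frame(isoform = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("export_heatmap_matrix: cannot write ", path, ": ",
                        conditionMessage(ok))
  if (!is.null(image) && nrow(vals) >= 2 && ncol(vals) >= 2) {
    grDevices::png(image, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    stats::heatmap(vals, Rowv = NA, Colv = NA, scale = "none")
  }
  invisible(path)
}

#' Read a heat-map matrix back from TSV
#'
#' @param path TSV written by \code{\link{export_heatmap_matrix}}.
#' @return numeric matrix with isoform rownames.
#' @export
read_heatmap_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Simulate a TPM table with planted fold changes
#'
#' Abundance = baseline x planted fold x lognormal noise.  The returned
#' manifest records the true folds so recovery can be audited.
#'
#' @param config list with \code{conditions} (character, must include the
#'   control conditions referenced by \code{pairs}), \code{n_isoforms},
#'   optional \code{pairs} (data.frame name/treatment/control; default
#'   pairs every non-control condition with the first condition),
#'   \code{baseline_range} (default c(5, 200)), \code{fold_changes}
#'   (matrix isoforms x treatments of true folds; default lognormal draws),
#'   \code{sigma} (lognormal noise sd on log2 scale, default 0.1).
#' @param seed integer seed.
#' @return list with \code{abundance}, \code{pairs}, \code{manifest}.
#' @export
make_expression <- function(config = list(), seed = 1L) {
  cfg <- modifyList(list(conditions = c("control", "heat", "drought"),
                         n_isoforms = 20L, pairs = NULL,
                         baseline_range = c(5, 200), fold_changes = NULL,
                         sigma = 0.1), config)
  if (length(cfg$conditions) == 0) stop("make_expression: no conditions")
  set.seed(as.integer(seed))
  iso <- sprintf("iso%02d", seq_len(cfg$n_isoforms))
  ctrl <- cfg$conditions[1]
  treatments <- setdiff(cfg$conditions, ctrl)
  pairs <- if (is.null(cfg$pairs)) {
    data.frame(name = paste0(treatments, "_vs_", ctrl),
               treatment = treatments, control = ctrl,
               stringsAsFactors = FALSE)
  } else cfg$pairs
  baseline <- runif(cfg$n_isoforms, cfg$baseline_range[1],
                    cfg$baseline_range[2])
  folds <- cfg$fold_changes
  if (is.null(folds)) {
    folds <- matrix(2^rnorm(cfg$n_isoforms * length(treatments), 0, 1),
                    nrow = cfg$n_isoforms,
                    dimnames = list(iso, treatments))
  }
  if (any(folds < 0)) stop("make_expression: negative fold change")
  noise <- function() 2^rnorm(cfg$n_isoforms, 0, cfg$sigma)
  ab <- matrix(0, nrow = cfg$n_isoforms, ncol = length(cfg$conditions),
               dimnames = list(iso, cfg$conditions))
  ab[, ctrl] <- baseline * noise()
  for (tr in treatments) ab[, tr] <- baseline * folds[, tr] * noise()
  list(abundance = ab, pairs = pairs,
       manifest = list(fold_changes = folds, baseline = baseline,
                       sigma = cfg$sigma, seed = as.integer(seed)))
}
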