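#' Read a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readBStringSet} that enforces the
#' package contracts: unique record ids, non-empty sequences, uppercased
#' letters, and U mapped to T only when the file is declared DNA.
#'
#' @param path path to a FASTA file.
#' @param type one of \code{"auto"}, \code{"dna"}, \code{"protein"}.  With
#'   \code{"auto"} the alphabet is guessed from the letters present (ACGTUN
#'   plus IUPAC ambiguity codes imply DNA).
#' @return named character vector of sequences, with attribute
#'   \code{"type"} set to \code{"dna"} or \code{"protein"}.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("read_fasta: empty record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (type == "auto") {
    letters_used <- unique(chars(paste(seqs, collapse = "")))
    dna_letters <- c(names(IUPAC_DNA), "U")
    type <- if (all(letters_used %in% dna_letters)) "dna" else "protein"
  }
  if (type == "dna") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  attr(seqs, "type") <- type
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width (default 70).
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("write_fasta: all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a tabular result as TSV or JSON
#'
#' Column order is preserved deterministically.  Any columns named
#' \code{start}/\code{end} (1-based inclusive) gain a companion display
#' column \code{span} in the "(start..end)" style of published curation
#' tables.
#'
#' @param results a data.frame.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return invisibly, \code{path}.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (all(c("start", "end") %in% names(results)) &&
      !"span" %in% names(results) && nrow(results) > 0) {
    results$span <- format_span(results$start, results$end)
  }
  if (format == "tsv") {
    ok <- tryCatch({
      write.table(results, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("write_report: cannot write ", path, ": ",
                          conditionMessage(ok))
  } else {
    ok <- tryCatch({
      jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                           na = "null", pretty = TRUE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("write_report: cannot write ", path, ": ",
                          conditionMessage(ok))
  }
  invisible(path)
}

#' Read back a report written by \code{write_report}
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return data.frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Write delineated gene structures as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with 1-based inclusive coordinates on
#' the supplied sequence ids (one sequence per gene).
#'
#' @param structures named list of \code{GeneStructure} objects (see
#'   \code{\link{delineate_structure}}); names are transcript ids.
#' @param gene_ids character vector mapping each structure to its gene id
#'   (recycled if length 1).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gff3 <- function(structures, gene_ids, path) {
  gene_ids <- rep_len(gene_ids, length(structures))
  lines <- "##gff-version 3"
  for (i in seq_along(structures)) {
    st <- structures[[i]]
    tid <- names(structures)[i]
    gid <- gene_ids[i]
    gspan <- c(min(st$exons[, 1]), max(st$exons[, 2]))
    lines <- c(
      lines,
      sprintf("%s\taoxkit\tgene\t%d\t%d\t.\t+\t.\tID=%s", gid,
              gspan[1], gspan[2], gid),
      sprintf("%s\taoxkit\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s", gid,
              gspan[1], gspan[2], tid, gid),
      sprintf("%s\taoxkit\texon\t%d\t%d\t.\t+\t.\tParent=%s", gid,
              st$exons[, 1], st$exons[, 2], tid)
    )
    if (!is.null(st$cds_genomic)) {
      lines <- c(lines, sprintf(
        "%s\taoxkit\tCDS\t%d\t%d\t.\t+\t0\tParent=%s", gid,
        st$cds_genomic[, 1], st$cds_genomic[, 2], tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
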