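# Systematic isoform names.
#
# Grammar (reproducing the published family's naming exemplars):
#   [put.][reg|ne.]<species>AOX<cladeSuffix|bullet>[-like][-<location>]
#   [.<paralog>][.sv<n>]
# where cladeSuffix is "1a"/"1c"/"1e"/"1d", the bullet (U+2022) stands in
# for an unresolved clade of a non-expressed model, "reg" marks motif-free
# putative regulators (never combined with a clade or -like), "put." marks
# low-confidence models and "ne." non-expressed ones.

NAME_SPECIES <- c("Ta", "Tu", "Aet", "Aes")

#' Build a systematic isoform name from its parts
#'
#' @param parts list with elements \code{species} (one of Ta/Tu/Aet/Aes),
#'   \code{clade} ("AOX1a"/"AOX1c"/"AOX1e"/"AOX1d" or NA), logicals
#'   \code{put}, \code{reg}, \code{ne}, \code{like}, and optional
#'   \code{location} (chromosome arm, e.g. "2AL"), \code{paralog},
#'   \code{sv} (integers or NA).
#' @return the name string.
#' @export
assign_name <- function(parts) {
  p <- modifyList(list(species = NA, clade = NA_character_, put = FALSE,
                       reg = FALSE, ne = FALSE, like = FALSE,
                       location = NA_character_, paralog = NA_integer_,
                       sv = NA_integer_), parts)
  if (!p$species %in% NAME_SPECIES) {
    stop("assign_name: unknown species code: ", p$species)
  }
  if (p$reg && p$like) stop("assign_name: 'reg' excludes '-like'")
  if (p$reg && !is.na(p$clade)) stop("assign_name: 'reg' excludes a clade core")
  if (p$reg && p$ne) stop("assign_name: 'reg' excludes 'ne.'")
  clade_suffix <- if (!is.na(p$clade)) {
    if (!p$clade %in% c("AOX1a", "AOX1c", "AOX1e", "AOX1d")) {
      stop("assign_name: unknown clade: ", p$clade)
    }
    sub("^AOX", "", p$clade)
  } else if (p$ne && !p$reg) {
    "\u2022"     # placeholder core for unresolved non-expressed models
  } else if (p$reg) "" else {
    stop("assign_name: clade required unless 'reg' or unresolved 'ne'")
  }
  paste0(
    if (p$put) "put." else "",
    if (p$reg) "reg" else if (p$ne) "ne." else "",
    p$species, "AOX", clade_suffix,
    if (p$like) "-like" else "",
    if (!is.na(p$location) && nzchar(p$location)) paste0("-", p$location)
      else "",
    if (!is.na(p$paralog)) paste0(".", p$paralog) else "",
    if (!is.na(p$sv)) paste0(".sv", p$sv) else "")
}

#' Parse a systematic isoform name back into its parts
#'
#' Inverse of \code{\link{assign_name}}: \code{parse_name(assign_name(p))}
#' recovers \code{p}.
#'
#' @param name name string.
#' @return list of parts as taken by \code{\link{assign_name}}.
#' @export
parse_name <- function(name) {
  rx <- paste0(
    "^(put\\.)?",                      # 1 put
    "(reg|ne\\.)?",                    # 2 reg / ne
    "(Ta|Tu|Aet|Aes)",                 # 3 species
    "AOX(1[acde]|\u2022)?",            # 4 clade suffix or bullet
    "(-like)?",                        # 5 like
    "(-[0-9][ABD][SL]?)?",             # 6 location
    "(\\.[0-9]+)?",                    # 7 paralog
    "(\\.sv[0-9]+)?$")                 # 8 sv
  m <- regmatches(name, regexec(rx, name))[[1]]
  if (length(m) == 0) stop("parse_name: cannot parse '", name, "'")
  grab <- function(i) if (is.na(m[i + 1]) || !nzchar(m[i + 1])) NA_character_
                      else m[i + 1]
  clade_tok <- grab(4)
  list(
    species = m[4],
    clade = if (is.na(clade_tok) || clade_tok == "\u2022") NA_character_
            else paste0("AOX", clade_tok),
    put = !is.na(grab(1)),
    reg = identical(grab(2), "reg"),
    ne = identical(grab(2), "ne."),
    like = !is.na(grab(5)),
    location = if (is.na(grab(6))) NA_character_ else sub("^-", "", grab(6)),
    paralog = if (is.na(grab(7))) NA_integer_
              else as.integer(sub("^\\.", "", grab(7))),
    sv = if (is.na(grab(8))) NA_integer_
         else as.integer(sub("^\\.sv", "", grab(8))))
}
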