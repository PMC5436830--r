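#' Composite atom-name aliases
#'
#' The shorthand labels used in binding-site analyses mapped to concrete PDB
#' atom names. `NHx` covers the two terminal arginine guanidinium nitrogens;
#' `OEx` the glutamate carboxylate oxygens; `N3/7/9` the adenine ring
#' nitrogens; `Oalpha`/`Obeta`/`Ogamma` the non-bridging oxygens of the ATP
#' alpha-, beta- and gamma-phosphates (bridging O3A/O3B are deliberately
#' excluded: Mg2+ chelation and arginine contacts involve the non-bridging
#' oxygens, and distances over an alias are taken as minima over the set).
#'
#' The naming convention for ATP follows the PDB chemical-component
#' dictionary; it is exposed here so an alternative convention can be
#' supplied to [resolve_group()].
#'
#' @return Named list mapping alias to a character vector of atom names.
#' @export
atom_aliases <- function() {
  list(
    NHx = c("NH1", "NH2"),
    OEx = c("OE1", "OE2"),
    ODx = c("OD1", "OD2"),
    `N3/7/9` = c("N3", "N7", "N9"),
    Oalpha = c("O1A", "O2A"),
    Obeta = c("O1B", "O2B"),
    Ogamma = c("O1G", "O2G", "O3G")
  )
}

.normalise_alias <- function(name) {
  synonyms <- c(
    "NHX" = "NHx", "OEX" = "OEx", "ODX" = "ODx",
    "N3/7/9" = "N3/7/9", "N379" = "N3/7/9",
    "OALPHA" = "Oalpha", "OBETA" = "Obeta", "OGAMMA" = "Ogamma",
    "OA" = "Oalpha", "OB" = "Obeta", "OG*" = "Ogamma"
  )
  unname(synonyms[toupper(name)])
}

#' Resolve a selector to the matching atoms of one frame
#'
#' A selector is a string of whitespace- or colon-separated tokens: an
#' optional residue name (e.g. `ARG`, `ATP`), an optional residue number,
#' and a final atom name or alias (see [atom_aliases()]). Examples:
#' `"ARG 92 NHx"`, `"R92:NHx"` (one-letter residue code + number),
#' `"ATP Oalpha"`, `"MG"`.
#'
#' @param frame A single-frame atom tibble (one `frame` value).
#' @param selector Selector string, or a list with any of `resname`,
#'   `resid`, `chain`, `name` (where `name` may be an alias).
#' @param aliases Alias table, by default [atom_aliases()].
#' @return The matching rows of `frame`; zero matches raise a selection
#'   error naming the selector.
#' @export
resolve_group <- function(frame, selector, aliases = atom_aliases()) {
  spec <- if (is.list(selector)) selector else .parse_selector(selector)
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(spec$resname)) keep <- keep & frame$resname == spec$resname
  if (!is.null(spec$resid)) keep <- keep & frame$resid %in% spec$resid
  if (!is.null(spec$chain)) keep <- keep & frame$chain == spec$chain
  if (!is.null(spec$name)) {
    nm <- spec$name
    alias <- .normalise_alias(nm)
    members <- if (!is.na(alias)) aliases[[alias]] else nm
    keep <- keep & frame$name %in% members
  }
  out <- frame[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    lab <- if (is.character(selector)) selector else {
      paste(unlist(selector), collapse = " ")
    }
    abort(sprintf("selector '%s' matched no atoms", lab))
  }
  out
}

ONE_LETTER <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

.parse_selector <- function(selector) {
  stopifnot(is.character(selector), length(selector) == 1)
  tokens <- strsplit(trimws(selector), "[[:space:]:]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) abort("empty selector")
  spec <- list()
  # compact residue token like R92 or E83
  tokens <- unlist(lapply(tokens, function(tk) {
    m <- regmatches(tk, regexec("^([A-Za-z])([0-9]+)$", tk))[[1]]
    if (length(m) == 3 && toupper(m[2]) %in% names(ONE_LETTER)) {
      c(ONE_LETTER[[toupper(m[2])]], m[3])
    } else {
      tk
    }
  }))
  atom_tok <- tokens[[length(tokens)]]
  rest <- tokens[-length(tokens)]
  for (tk in rest) {
    if (grepl("^[0-9]+$", tk)) {
      spec$resid <- as.integer(tk)
    } else {
      spec$resname <- toupper(tk)
    }
  }
  if (length(rest) == 0 && grepl("^[0-9]+$", atom_tok)) {
    abort(sprintf("selector '%s' has no atom name", selector))
  }
  # a lone residue-name token such as "MG" selects the whole residue
  if (length(rest) == 0 && atom_tok %in% c("MG", "ATP", "HOH", AMINO_ACIDS)) {
    spec$resname <- atom_tok
  } else {
    spec$name <- atom_tok
  }
  spec
}

#' Extract one frame of a trajectory
#'
#' @param trajectory Trajectory tibble.
#' @param frame Frame index (1-based).
#' @return The single-frame atom tibble.
#' @export
get_frame <- function(trajectory, frame) {
  out <- trajectory[trajectory$frame == frame, , drop = FALSE]
  if (nrow(out) == 0) abort(sprintf("no frame %s in trajectory", frame))
  out
}

# Frame-count and retained-frame helpers -------------------------------------

#' Drop equilibration frames from a trajectory
#'
#' @param trajectory Trajectory tibble.
#' @param skip_ps Frames with `time_ps < skip_ps` are discarded.
#' @return The retained frames; an error if nothing remains.
#' @export
skip_equilibration <- function(trajectory, skip_ps) {
  stopifnot(skip_ps >= 0)
  out <- trajectory[trajectory$time_ps >= skip_ps, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(sprintf("all frames fall before skip_ps = %g", skip_ps))
  }
  out
}

# internal: resolve a "set spec" (selector string, list spec, logical-filter
# function, or an already-subset atom tibble) against one frame
.atoms_matching <- function(frame, spec) {
  if (is.null(spec)) return(frame)
  if (is.function(spec)) {
    return(frame[spec(frame), , drop = FALSE])
  }
  if (is.data.frame(spec)) {
    return(spec)
  }
  resolve_group(frame, spec)
}

#' Selection helpers for set specifications
#'
#' Convenience predicates for the `donors`/`acceptors` arguments of the
#' hydrogen-bond functions: select by residue name, residue-number range, or
#' all standard amino-acid residues.
#'
#' @param resname Residue name(s).
#' @param range Two-element inclusive residue-number range (order-free).
#' @return A function mapping an atom tibble to a logical vector.
#' @export
sel_resname <- function(resname) {
  force(resname)
  function(df) df$resname %in% resname
}

#' @rdname sel_resname
#' @export
sel_resid_range <- function(range) {
  lo <- min(range)
  hi <- max(range)
  function(df) df$resid >= lo & df$resid <= hi
}

#' @rdname sel_resname
#' @export
sel_protein <- function() {
  function(df) df$resname %in% AMINO_ACIDS
}
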