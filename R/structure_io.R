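#' Read a (multi-model) PDB file into a trajectory tibble
#'
#' Parses fixed-column `ATOM`/`HETATM` records, keeping hetero groups (ATP,
#' MG, waters). `MODEL`/`ENDMDL` records delimit frames; a single-model file
#' yields a one-frame trajectory. Heavy lifting is delegated to
#' [bio3d::read.pdb()]; a light pre-validation pass supplies line-numbered
#' parse errors and recovers per-frame times from `REMARK 6 TIME_PS` lines
#' (written by [write_pdb()]). Files without time remarks get times from
#' `default_spacing_ps`.
#'
#' @param x Path to a PDB file, or PDB text (a string containing newlines, or
#'   a character vector of lines).
#' @param label Run label stored as the `"label"` attribute (defaults to the
#'   file name).
#' @param default_spacing_ps Frame spacing, in ps, used when the file carries
#'   no time remarks. Frame `i` then gets time `(i - 1) * default_spacing_ps`.
#'
#' @return A tibble with one row per atom per frame and columns `frame`,
#'   `time_ps`, `serial`, `name`, `element`, `resname`, `resid`, `chain`,
#'   `x`, `y`, `z` (coordinates in Angstrom).
#' @seealso [write_pdb()], [resolve_group()]
#' @export
read_pdb <- function(x, label = NULL, default_spacing_ps = 1) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    path <- x
    label <- label %||% basename(x)
  } else {
    lines <- unlist(strsplit(as.character(x), "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
    label <- label %||% "trajectory"
  }

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    abort("no ATOM/HETATM records found; not a PDB structure")
  }
  # line-numbered validation of the fixed coordinate columns
  for (i in which(is_atom)) {
    ln <- lines[[i]]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed ATOM/HETATM record at line %d: too short", i))
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(coords) || any(!is.finite(coords))) {
      abort(sprintf(
        "malformed ATOM/HETATM record at line %d: non-numeric coordinates", i
      ))
    }
  }

  # frame boundaries and per-model atom-name consistency
  model_starts <- grep("^MODEL", lines)
  n_models <- max(1L, length(model_starts))
  model_of_line <- cumsum(grepl("^MODEL", lines))
  if (length(model_starts) == 0) model_of_line <- rep(1L, length(lines))
  model_of_line[model_of_line == 0L] <- 1L
  names_by_model <- split(
    trimws(substr(lines[is_atom], 13, 16)),
    model_of_line[is_atom]
  )
  counts <- lengths(names_by_model)
  if (length(unique(counts)) > 1) {
    abort(sprintf(
      "inconsistent atom count across models: %s",
      paste(counts, collapse = ", ")
    ))
  }
  ref <- names_by_model[[1]]
  for (m in seq_along(names_by_model)) {
    if (!identical(names_by_model[[m]], ref)) {
      abort(sprintf("atom ordering/naming differs in model %d", m))
    }
  }

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3

  times <- .extract_time_remarks(lines)
  if (length(times) != n_frames) {
    times <- (seq_len(n_frames) - 1) * default_spacing_ps
  }

  at <- pdb$atom
  element <- trimws(at$elesy %||% "")
  element[is.na(element) | element == ""] <-
    .element_from_name(at$elety[is.na(element) | element == ""])

  base <- tibble(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    element = as.character(element),
    resname = as.character(at$resid),
    resid = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "", as.character(at$chain))
  )
  traj <- purrr::map_dfr(seq_len(n_frames), function(f) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    dplyr::mutate(base,
      frame = f, time_ps = times[[f]],
      x = co[, 1], y = co[, 2], z = co[, 3],
      .before = 1
    )
  })
  new_trajectory(traj, label = label)
}

.extract_time_remarks <- function(lines) {
  hits <- grep("^REMARK +6 +TIME_PS", lines, value = TRUE)
  as.numeric(sub("^REMARK +6 +TIME_PS +", "", hits))
}

.element_from_name <- function(name) {
  if (length(name) == 0) return(character(0))
  stripped <- sub("^[0-9']*", "", toupper(name))
  two <- substr(stripped, 1, 2)
  el <- substr(stripped, 1, 1)
  el[two %in% c("MG", "NA", "CL", "ZN", "FE", "MN", "CA ")] <- two[
    two %in% c("MG", "NA", "CL", "ZN", "FE", "MN", "CA ")
  ]
  el
}

#' Construct/validate a trajectory tibble
#'
#' Checks the column contract, finite coordinates, constant atom count and
#' identical atom ordering across frames, and strictly increasing times.
#'
#' @param atoms Data frame of per-atom, per-frame records (see [read_pdb()]
#'   for the column set).
#' @param label Run label.
#' @return The validated trajectory tibble with a `"label"` attribute.
#' @export
new_trajectory <- function(atoms, label = "trajectory") {
  atoms <- as_tibble(atoms)
  needed <- c(
    "frame", "time_ps", "serial", "name", "element", "resname",
    "resid", "chain", "x", "y", "z"
  )
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("trajectory is missing columns: ", toString(missing)))
  }
  if (nrow(atoms) == 0) abort("trajectory has no atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("trajectory contains non-finite coordinates")
  }
  if (any(!nzchar(atoms$name))) abort("trajectory contains empty atom names")
  by_frame <- split(atoms$name, atoms$frame)
  if (length(unique(lengths(by_frame))) > 1) {
    abort("atom count differs across frames")
  }
  ref <- by_frame[[1]]
  if (!all(vapply(by_frame, identical, logical(1), y = ref))) {
    abort("atom ordering/naming differs across frames")
  }
  ft <- unique(atoms[, c("frame", "time_ps")])
  ft <- ft[order(ft$frame), ]
  if (nrow(ft) > 1 && any(diff(ft$time_ps) <= 0)) {
    abort("frame times must strictly increase with frame index")
  }
  attr(atoms, "label") <- label
  atoms
}

#' Write a trajectory as fixed-column PDB text
#'
#' Emits standard `ATOM`/`HETATM` records (hetero residues such as ATP, MG
#' and waters become `HETATM`). Multi-frame trajectories are wrapped in
#' `MODEL`/`ENDMDL` blocks; per-frame times are stored as `REMARK 6 TIME_PS`
#' lines so that [read_pdb()] round-trips them. Coordinates are written at
#' the PDB column precision of 0.001 Angstrom.
#'
#' @param trajectory Trajectory tibble (see [read_pdb()]).
#' @param path Optional output path; when `NULL` the text is only returned.
#' @param multi_model Force (`TRUE`) or suppress (`FALSE`) `MODEL` records
#'   for single-frame trajectories; default wraps only multi-frame input.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(trajectory, path = NULL, multi_model = NULL) {
  traj <- new_trajectory(trajectory, label = attr(trajectory, "label") %||% "trajectory")
  if (any(nchar(traj$name) > 4)) {
    abort("atom names longer than 4 characters cannot be written to PDB")
  }
  frames <- sort(unique(traj$frame))
  use_models <- multi_model %||% (length(frames) > 1)

  fmt_atom <- function(df) {
    record <- ifelse(df$resname %in% AMINO_ACIDS, "ATOM  ", "HETATM")
    # names of 1-3 characters start in column 14; 4-character names fill 13-16
    nm <- ifelse(nchar(df$name) < 4, paste0(" ", df$name), df$name)
    ch <- substr(paste0(df$chain, " "), 1, 1)
    sprintf(
      "%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, df$serial, nm, df$resname, ch,
      df$resid, df$x, df$y, df$z, 1, 0, substr(df$element, 1, 2)
    )
  }

  out <- character(0)
  for (f in frames) {
    df <- traj[traj$frame == f, ]
    t_line <- sprintf("REMARK   6 TIME_PS %.6f", df$time_ps[[1]])
    if (use_models) {
      out <- c(out, sprintf("MODEL %8d", match(f, frames)), t_line,
               fmt_atom(df), "ENDMDL")
    } else {
      out <- c(out, t_line, fmt_atom(df))
    }
  }
  out <- c(out, "END")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

#' Time series of scalar samples
#'
#' The container for free-energy inputs: per-window dH/dlambda samples or any
#' (time, value) series read from XVG-dialect files.
#'
#' @param time_ps Sample times in ps, non-decreasing.
#' @param value Sample values.
#' @param unit Energy unit tag, e.g. `"kJ/mol"` or `"kcal/mol"`.
#' @return A tibble with columns `time_ps` and `value` and a `"unit"`
#'   attribute.
#' @export
sample_series <- function(time_ps, value, unit = "kJ/mol") {
  if (length(time_ps) != length(value)) {
    abort("time and value must have equal length")
  }
  if (length(time_ps) == 0) abort("empty sample series")
  if (is.unsorted(time_ps)) abort("sample times must be non-decreasing")
  out <- tibble(time_ps = as.numeric(time_ps), value = as.numeric(value))
  attr(out, "unit") <- unit
  out
}

#' Read an XVG-dialect two-column series
#'
#' Whitespace-delimited numeric rows; lines starting with `#` or `@` are
#' comments/metadata and are skipped (the dialect of GROMACS analysis
#' output such as `g_bar` input files).
#'
#' @inheritParams read_pdb
#' @param unit Unit tag attached to the returned series.
#' @return A [sample_series()] tibble.
#' @export
read_xvg <- function(x, unit = "kJ/mol") {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(x), "\n", fixed = TRUE))
  }
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) abort("no numeric data rows found (empty series)")
  rows <- which(keep)
  tv <- matrix(NA_real_, nrow = length(rows), ncol = 2)
  for (k in seq_along(rows)) {
    tok <- strsplit(trimws(lines[[rows[k]]]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok[1:2]))
    if (length(tok) < 2 || anyNA(val)) {
      abort(sprintf("non-numeric token in data row at line %d", rows[k]))
    }
    tv[k, ] <- val
  }
  sample_series(tv[, 1], tv[, 2], unit = unit)
}

#' Write a sample series in XVG dialect
#'
#' Values are formatted with `%.17g` so that [read_xvg()] reparses them
#' bit-identically.
#'
#' @param series A [sample_series()] tibble.
#' @param path Optional output path.
#' @return The text, invisibly when `path` is given.
#' @export
write_xvg <- function(series, path = NULL) {
  unit <- attr(series, "unit") %||% "kJ/mol"
  lines <- c(
    sprintf("@    yaxis label \"%s\"", unit),
    sprintf("%.17g %.17g", series$time_ps, series$value)
  )
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}
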