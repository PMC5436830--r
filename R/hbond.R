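#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond D-H...A is accepted when the hydrogen-acceptor distance
#' d(H,A) is at most `max_h_acceptor_distance` and the deviation of the
#' D-H...A angle from linearity is at most `max_angle_deviation` (i.e. the
#' angle at the hydrogen is at least 180 - `max_angle_deviation` degrees).
#'
#' @param max_h_acceptor_distance Cut-off distance from the donor hydrogen
#'   to the acceptor atom, Angstrom.
#' @param max_angle_deviation Cut-off angular deviation from linearity,
#'   degrees.
#' @return A validated criteria list.
#' @export
hbond_criteria <- function(max_h_acceptor_distance = 2.7,
                           max_angle_deviation = 30) {
  stopifnot(
    max_h_acceptor_distance > 0, max_h_acceptor_distance < 10,
    max_angle_deviation > 0, max_angle_deviation <= 90
  )
  structure(
    list(
      max_h_acceptor_distance = max_h_acceptor_distance,
      max_angle_deviation = max_angle_deviation
    ),
    class = "hbond_criteria"
  )
}

#' Default donor/acceptor chemistry
#'
#' Atom-name tables deciding which heavy atoms may act as hydrogen-bond
#' donors (N-H and O-H groups: backbone N, Arg NE/NH1/NH2, Lys NZ, His/Trp
#' ring NH, Asn/Gln amide NH, Ser/Thr/Tyr hydroxyls, and the adenine N6 and
#' ribose O2'/O3' of ATP) and acceptors (carbonyl/carboxylate oxygens, the
#' ATP phosphate and ribose oxygens, and ring nitrogens with lone pairs).
#' The tables are plain character vectors and may be edited or replaced.
#'
#' @return List with components `donors` and `acceptors`.
#' @export
default_hbond_chemistry <- function() {
  list(
    donors = c(
      "N", "NE", "NH1", "NH2", "NZ", "ND1", "ND2", "NE1", "NE2",
      "OG", "OG1", "OH",
      "N6", "O2'", "O3'"
    ),
    acceptors = c(
      "O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
      "O1A", "O2A", "O3A", "O1B", "O2B", "O3B", "O1G", "O2G", "O3G",
      "O5'", "O4'", "O3'", "O2'", "N1", "N3", "N7", "N9"
    )
  )
}

.is_hydrogen <- function(name, element) {
  element == "H" | grepl("^[0-9]*H", name)
}

#' Detect hydrogen bonds in one frame
#'
#' Enumerates every donor-hydrogen-acceptor triple satisfying the geometric
#' criteria. Hydrogens are identified in the full frame and paired to a
#' donor heavy atom of the same residue within a 1.2 Angstrom covalent
#' cut-off. Donors with no bonded hydrogen are skipped (their count is
#' attached as the `"skipped_donors"` attribute and reported via a
#' warning). One hydrogen may form bonds with several acceptors; all
#' qualifying triples are recorded.
#'
#' @param frame Single-frame atom tibble.
#' @param donors,acceptors Set specifications (selector string, list spec,
#'   predicate function, or atom tibble) for the candidate donor heavy atoms
#'   and acceptor atoms. Chemistry filtering is *not* applied here; see
#'   [hbond_count_series()] for the chemistry-aware wrappers.
#' @param criteria [hbond_criteria()].
#' @param quiet Suppress the skipped-donor warning.
#' @return Tibble of records: donor/hydrogen/acceptor identity columns,
#'   `d_ha` (Angstrom), `angle_deviation` (degrees), `frame`.
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criteria = hbond_criteria(), quiet = FALSE) {
  don <- .atoms_matching(frame, donors)
  acc <- .atoms_matching(frame, acceptors)
  empty <- tibble(
    frame = integer(0),
    donor_serial = integer(0), donor_name = character(0),
    donor_resname = character(0), donor_resid = integer(0),
    donor_chain = character(0),
    hydrogen_serial = integer(0), hydrogen_name = character(0),
    acceptor_serial = integer(0), acceptor_name = character(0),
    acceptor_resname = character(0), acceptor_resid = integer(0),
    acceptor_chain = character(0),
    d_ha = numeric(0), angle_deviation = numeric(0)
  )
  if (nrow(don) == 0 || nrow(acc) == 0) {
    return(structure(empty, skipped_donors = 0L))
  }

  hyd <- frame[.is_hydrogen(frame$name, frame$element), , drop = FALSE]
  # covalent pairing: hydrogen of the same residue within 1.2 A
  pairs <- dplyr::inner_join(
    dplyr::rename(don,
      donor_serial = "serial", donor_name = "name",
      dx = "x", dy = "y", dz = "z"
    )[, c("donor_serial", "donor_name", "resname", "resid", "chain",
          "dx", "dy", "dz")],
    dplyr::rename(hyd,
      hydrogen_serial = "serial", hydrogen_name = "name",
      hx = "x", hy = "y", hz = "z"
    )[, c("hydrogen_serial", "hydrogen_name", "resname", "resid", "chain",
          "hx", "hy", "hz")],
    by = c("resname", "resid", "chain"),
    relationship = "many-to-many"
  )
  pairs <- pairs[
    (pairs$dx - pairs$hx)^2 + (pairs$dy - pairs$hy)^2 +
      (pairs$dz - pairs$hz)^2 <= 1.2^2, ,
    drop = FALSE
  ]
  n_skipped <- sum(!don$serial %in% pairs$donor_serial)
  if (n_skipped > 0 && !quiet) {
    warn(sprintf("%d donor atom(s) without a bonded hydrogen skipped",
                 n_skipped))
  }
  if (nrow(pairs) == 0) {
    return(structure(empty, skipped_donors = n_skipped))
  }

  acc2 <- dplyr::rename(acc,
    acceptor_serial = "serial", acceptor_name = "name",
    acceptor_resname = "resname", acceptor_resid = "resid",
    acceptor_chain = "chain", ax = "x", ay = "y", az = "z"
  )[, c("acceptor_serial", "acceptor_name", "acceptor_resname",
        "acceptor_resid", "acceptor_chain", "ax", "ay", "az")]
  grid <- tidyr::expand_grid(
    dplyr::rename(pairs,
      donor_resname = "resname", donor_resid = "resid", donor_chain = "chain"
    ),
    acc2
  )
  grid <- grid[grid$acceptor_serial != grid$donor_serial &
                 grid$acceptor_serial != grid$hydrogen_serial, , drop = FALSE]
  if (nrow(grid) == 0) return(structure(empty, skipped_donors = n_skipped))

  hax <- grid$ax - grid$hx
  hay <- grid$ay - grid$hy
  haz <- grid$az - grid$hz
  hdx <- grid$dx - grid$hx
  hdy <- grid$dy - grid$hy
  hdz <- grid$dz - grid$hz
  d_ha <- sqrt(hax^2 + hay^2 + haz^2)
  nd <- sqrt(hdx^2 + hdy^2 + hdz^2)
  cosang <- (hax * hdx + hay * hdy + haz * hdz) / (d_ha * nd)
  cosang <- pmin(1, pmax(-1, cosang))
  deviation <- 180 - acos(cosang) * 180 / pi

  keep <- d_ha <= criteria$max_h_acceptor_distance &
    deviation <= criteria$max_angle_deviation
  grid <- grid[keep, , drop = FALSE]
  out <- tibble(
    frame = rep(frame$frame[[1]], nrow(grid)),
    donor_serial = grid$donor_serial, donor_name = grid$donor_name,
    donor_resname = grid$donor_resname, donor_resid = grid$donor_resid,
    donor_chain = grid$donor_chain,
    hydrogen_serial = grid$hydrogen_serial,
    hydrogen_name = grid$hydrogen_name,
    acceptor_serial = grid$acceptor_serial,
    acceptor_name = grid$acceptor_name,
    acceptor_resname = grid$acceptor_resname,
    acceptor_resid = grid$acceptor_resid,
    acceptor_chain = grid$acceptor_chain,
    d_ha = d_ha[keep], angle_deviation = deviation[keep]
  )
  structure(out, skipped_donors = n_skipped)
}

# chemistry-filtered bond records between two atom sets, both donor/acceptor
# role assignments
.hbonds_between <- function(frame, set_a, set_b, criteria, chemistry,
                            bidirectional = TRUE) {
  a <- .atoms_matching(frame, set_a)
  b <- .atoms_matching(frame, set_b)
  don_a <- a[a$name %in% chemistry$donors, , drop = FALSE]
  acc_b <- b[b$name %in% chemistry$acceptors, , drop = FALSE]
  recs <- detect_hbonds(frame, don_a, acc_b, criteria, quiet = TRUE)
  if (bidirectional) {
    don_b <- b[b$name %in% chemistry$donors, , drop = FALSE]
    acc_a <- a[a$name %in% chemistry$acceptors, , drop = FALSE]
    recs <- dplyr::bind_rows(
      recs, detect_hbonds(frame, don_b, acc_a, criteria, quiet = TRUE)
    )
  }
  recs
}

#' Per-frame hydrogen-bond counts between two atom sets
#'
#' Counts donor-hydrogen-acceptor triples between `donors`-side and
#' `acceptors`-side atoms in every retained frame, after filtering each side
#' by the donor/acceptor chemistry table. With `bidirectional = TRUE` (the
#' default, appropriate for protein-ligand counting) both role assignments
#' are counted.
#'
#' @param trajectory Trajectory tibble.
#' @param donors,acceptors Set specifications for the two sides (see
#'   [detect_hbonds()]).
#' @param criteria [hbond_criteria()].
#' @param skip_ps Equilibration time discarded before counting, ps.
#' @param bidirectional Also count bonds donated by the `acceptors` side.
#' @param chemistry Donor/acceptor chemistry table,
#'   [default_hbond_chemistry()].
#' @return Tibble with `frame`, `time_ps`, `n_hbonds`.
#' @export
hbond_count_series <- function(trajectory, donors, acceptors,
                               criteria = hbond_criteria(), skip_ps = 0,
                               bidirectional = TRUE,
                               chemistry = default_hbond_chemistry()) {
  traj <- skip_equilibration(trajectory, skip_ps)
  frames <- split(traj, traj$frame)
  purrr::map_dfr(frames, function(fr) {
    recs <- .hbonds_between(fr, donors, acceptors, criteria, chemistry,
                            bidirectional = bidirectional)
    tibble(frame = fr$frame[[1]], time_ps = fr$time_ps[[1]],
           n_hbonds = nrow(recs))
  })
}

#' Helix-to-rest hydrogen-bond counts
#'
#' Counts hydrogen bonds in which exactly one heavy partner (donor or
#' acceptor) lies in the given residue range of the protein and the other
#' lies outside it; intra-helix bonds are excluded. This isolates the
#' network anchoring a helical segment (here the second C-terminal alpha
#' helix, residues 112-133 by default) to the remaining protein.
#'
#' @inheritParams hbond_count_series
#' @param helix_range Two-element inclusive residue-number range
#'   (order-free).
#' @return Tibble with `frame`, `time_ps`, `n_hbonds`.
#' @export
helix_network_hbonds <- function(trajectory, helix_range = c(112, 133),
                                 criteria = hbond_criteria(), skip_ps = 0,
                                 chemistry = default_hbond_chemistry()) {
  lo <- min(helix_range)
  hi <- max(helix_range)
  traj <- skip_equilibration(trajectory, skip_ps)
  prot <- traj[traj$resname %in% AMINO_ACIDS, , drop = FALSE]
  if (!any(prot$resid >= lo & prot$resid <= hi)) {
    abort(sprintf("helix range %d-%d selects no atoms", lo, hi))
  }
  frames <- split(prot, prot$frame)
  purrr::map_dfr(frames, function(fr) {
    don <- fr[fr$name %in% chemistry$donors, , drop = FALSE]
    acc <- fr[fr$name %in% chemistry$acceptors, , drop = FALSE]
    recs <- detect_hbonds(fr, don, acc, criteria, quiet = TRUE)
    in_helix_d <- recs$donor_resid >= lo & recs$donor_resid <= hi
    in_helix_a <- recs$acceptor_resid >= lo & recs$acceptor_resid <= hi
    tibble(
      frame = fr$frame[[1]], time_ps = fr$time_ps[[1]],
      n_hbonds = sum(xor(in_helix_d, in_helix_a))
    )
  })
}

#' Per-frame minimal distance between two atom groups
#'
#' For every frame, the minimum pairwise Euclidean distance between the
#' atoms resolved by the two selectors — the quantity underlying
#' minimal-distance distributions such as Mg2+ versus the ATP phosphate
#' oxygen groups.
#'
#' @param trajectory Trajectory tibble.
#' @param selector_a,selector_b Selectors (see [resolve_group()]).
#' @param skip_ps Equilibration time discarded, ps.
#' @return Tibble with `frame`, `time_ps`, `min_dist` (Angstrom) and a
#'   `"label"` attribute naming the pair.
#' @export
min_distance_series <- function(trajectory, selector_a, selector_b,
                                skip_ps = 0) {
  traj <- skip_equilibration(trajectory, skip_ps)
  frames <- split(traj, traj$frame)
  out <- purrr::map_dfr(frames, function(fr) {
    a <- .atoms_matching(fr, selector_a)
    b <- .atoms_matching(fr, selector_b)
    tibble(
      frame = fr$frame[[1]], time_ps = fr$time_ps[[1]],
      min_dist = .min_pair_distance(a, b)
    )
  })
  lab_a <- if (is.character(selector_a)) selector_a else "groupA"
  lab_b <- if (is.character(selector_b)) selector_b else "groupB"
  attr(out, "label") <- paste0(lab_a, "—", lab_b)
  out
}

.min_pair_distance <- function(a, b) {
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
    outer(a$z, b$z, "-")^2
  sqrt(min(d2))
}

#' Normalised histogram of a distance (or any numeric) series
#'
#' Bins are half-open `[lo, hi)`; values equal to the upper range limit are
#' placed in the last bin. Frequencies sum to one.
#'
#' @param x Numeric vector, or a tibble with a `min_dist` or `value` column.
#' @param bin_width Bin width (same unit as `x`).
#' @param range Optional two-element range; defaults to the data range
#'   expanded to whole bins.
#' @return Tibble with `bin_lo`, `bin_hi`, `freq`.
#' @export
distance_histogram <- function(x, bin_width, range = NULL) {
  if (is.data.frame(x)) {
    x <- x[["min_dist"]] %||% x[["value"]]
  }
  x <- as.numeric(x)
  if (length(x) == 0) abort("cannot histogram an empty series")
  stopifnot(bin_width > 0)
  if (is.null(range)) {
    lo <- floor(min(x) / bin_width) * bin_width
    hi <- ceiling(max(x) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
  } else {
    lo <- range[[1]]
    hi <- range[[2]]
    x <- x[x >= lo & x <= hi]
    if (length(x) == 0) abort("no values fall inside the histogram range")
  }
  n_bins <- ceiling((hi - lo) / bin_width - 1e-9)
  idx <- pmin(floor((x - lo) / bin_width) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    bin_lo = lo + (seq_len(n_bins) - 1) * bin_width,
    bin_hi = lo + seq_len(n_bins) * bin_width,
    freq = counts / sum(counts)
  )
}
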