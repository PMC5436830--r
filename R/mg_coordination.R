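MG_STATES <- c(
  "first_sphere_alpha_beta", "first_sphere_beta_gamma",
  "second_sphere", "unbound"
)

#' Repulsive-contact criteria
#'
#' A repulsive contact is a positively charged binding-site residue with a
#' cationic side-chain atom within `max_distance` of the Mg2+ cation.
#'
#' @param max_distance Cut-off distance, Angstrom (default 4.5).
#' @param cation_atoms Map from residue type to its cationic atom names.
#' @param mode `"per_residue"` counts residues having at least one
#'   qualifying atom (default); `"per_atom"` counts the qualifying atoms.
#' @return Criteria list.
#' @export
contact_criteria <- function(max_distance = 4.5,
                             cation_atoms = list(
                               ARG = c("NE", "NH1", "NH2"),
                               LYS = "NZ"
                             ),
                             mode = c("per_residue", "per_atom")) {
  stopifnot(max_distance > 0, length(cation_atoms) > 0)
  structure(
    list(
      max_distance = max_distance,
      cation_atoms = cation_atoms,
      mode = match.arg(mode)
    ),
    class = "contact_criteria"
  )
}

.find_mg <- function(frame, mg = NULL) {
  if (!is.null(mg)) {
    m <- .atoms_matching(frame, mg)
  } else {
    m <- frame[frame$resname == "MG" | frame$name == "MG", , drop = FALSE]
  }
  if (nrow(m) == 0) abort("no Mg2+ ion present in the frame")
  m[1, , drop = FALSE]
}

#' Count repulsive cation contacts with Mg2+ in one frame
#'
#' @param frame Single-frame atom tibble.
#' @param criteria [contact_criteria()].
#' @param mg Optional selector for the Mg2+ ion (default: the first atom
#'   with residue or atom name `MG`).
#' @param binding_site Optional residue numbers restricting the candidate
#'   residues; by default every residue of a type listed in the criteria's
#'   cation-atom table is considered.
#' @return Integer contact count (per residue or per atom according to the
#'   criteria's counting mode).
#' @export
repulsive_contacts <- function(frame, criteria = contact_criteria(),
                               mg = NULL, binding_site = NULL) {
  mg_atom <- .find_mg(frame, mg)
  cand <- frame[frame$resname %in% names(criteria$cation_atoms), ,
                drop = FALSE]
  if (!is.null(binding_site)) {
    cand <- cand[cand$resid %in% binding_site, , drop = FALSE]
  }
  keep <- mapply(function(rn, nm) nm %in% criteria$cation_atoms[[rn]],
                 cand$resname, cand$name)
  cand <- cand[as.logical(keep), , drop = FALSE]
  if (nrow(cand) == 0) return(0L)
  d <- sqrt((cand$x - mg_atom$x)^2 + (cand$y - mg_atom$y)^2 +
              (cand$z - mg_atom$z)^2)
  hit <- d <= criteria$max_distance
  if (criteria$mode == "per_atom") {
    sum(hit)
  } else {
    length(unique(paste(cand$resname, cand$resid, cand$chain)[hit]))
  }
}

#' Per-frame repulsive-contact series
#'
#' @inheritParams repulsive_contacts
#' @param trajectory Trajectory tibble.
#' @param skip_ps Equilibration time discarded, ps.
#' @return Tibble with `frame`, `time_ps`, `n_contacts`.
#' @export
repulsive_contact_series <- function(trajectory,
                                     criteria = contact_criteria(),
                                     mg = NULL, binding_site = NULL,
                                     skip_ps = 0) {
  traj <- skip_equilibration(trajectory, skip_ps)
  purrr::map_dfr(split(traj, traj$frame), function(fr) {
    tibble(
      frame = fr$frame[[1]], time_ps = fr$time_ps[[1]],
      n_contacts = repulsive_contacts(fr, criteria, mg, binding_site)
    )
  })
}

#' Mg2+ coordination-sphere thresholds
#'
#' Distance cut-offs separating direct (first-sphere) Mg-O coordination
#' from water-bridged (second-sphere) binding. The defaults (2.6 and 5.0
#' Angstrom) reflect the bimodal separation typical of Mg-O radial
#' distributions: direct Mg-O contacts sit near 2.1 A, water-bridged ones
#' near 4 A.
#'
#' @param first_sphere_max Maximum Mg-O distance for direct coordination.
#' @param second_sphere_max Maximum minimal Mg-O distance for water-bridged
#'   coordination; beyond it the ion counts as unbound.
#' @return Threshold list.
#' @export
mg_thresholds <- function(first_sphere_max = 2.6, second_sphere_max = 5.0) {
  stopifnot(first_sphere_max > 0, second_sphere_max > first_sphere_max)
  structure(
    list(
      first_sphere_max = first_sphere_max,
      second_sphere_max = second_sphere_max
    ),
    class = "mg_thresholds"
  )
}

#' Classify the Mg2+ coordination state of one frame
#'
#' Computes the minimal distances from the Mg2+ ion to the non-bridging
#' alpha-, beta- and gamma-phosphate oxygens of ATP and assigns exactly one
#' of four states: bidentate first-sphere coordination to Oalpha/Obeta or
#' to Obeta/Ogamma (both partner distances within the first-sphere
#' cut-off), water-bridged second-sphere binding (minimal distance within
#' the second-sphere cut-off), or unbound. If both bidentate patterns hold
#' simultaneously the pair whose two distances have the smaller maximum
#' wins (a deterministic tie-break).
#'
#' @param frame Single-frame atom tibble.
#' @param thresholds [mg_thresholds()].
#' @param mg Optional Mg2+ selector (see [repulsive_contacts()]).
#' @param atp_resname Residue name of the ATP ligand.
#' @param aliases Alias table providing the `Oalpha`/`Obeta`/`Ogamma` sets.
#' @return One-row tibble with `d_alpha`, `d_beta`, `d_gamma` (Angstrom)
#'   and `state`.
#' @export
classify_mg_state <- function(frame, thresholds = mg_thresholds(),
                              mg = NULL, atp_resname = "ATP",
                              aliases = atom_aliases()) {
  mg_atom <- .find_mg(frame, mg)
  atp <- frame[frame$resname == atp_resname, , drop = FALSE]
  if (nrow(atp) == 0) abort(sprintf("no residue '%s' in frame", atp_resname))
  dist_to <- function(alias) {
    grp <- atp[atp$name %in% aliases[[alias]], , drop = FALSE]
    if (nrow(grp) == 0) {
      abort(sprintf("alias '%s' resolves to no atoms on '%s'",
                    alias, atp_resname))
    }
    .min_pair_distance(mg_atom, grp)
  }
  da <- dist_to("Oalpha")
  db <- dist_to("Obeta")
  dg <- dist_to("Ogamma")
  f <- thresholds$first_sphere_max
  s <- thresholds$second_sphere_max
  ab <- da <= f && db <= f
  bg <- db <= f && dg <= f
  state <- if (ab && bg) {
    if (max(da, db) <= max(db, dg)) MG_STATES[[1]] else MG_STATES[[2]]
  } else if (ab) {
    MG_STATES[[1]]
  } else if (bg) {
    MG_STATES[[2]]
  } else if (min(da, db, dg) <= s) {
    MG_STATES[[3]]
  } else {
    MG_STATES[[4]]
  }
  tibble(d_alpha = da, d_beta = db, d_gamma = dg,
         state = factor(state, levels = MG_STATES))
}

#' Per-frame Mg2+ coordination states
#'
#' @inheritParams classify_mg_state
#' @param trajectory Trajectory tibble.
#' @param skip_ps Equilibration time discarded, ps.
#' @return Tibble with `frame`, `time_ps`, `d_alpha`, `d_beta`, `d_gamma`,
#'   `state`.
#' @export
mg_state_series <- function(trajectory, thresholds = mg_thresholds(),
                            mg = NULL, atp_resname = "ATP",
                            aliases = atom_aliases(), skip_ps = 0) {
  traj <- skip_equilibration(trajectory, skip_ps)
  purrr::map_dfr(split(traj, traj$frame), function(fr) {
    cls <- classify_mg_state(fr, thresholds, mg, atp_resname, aliases)
    dplyr::mutate(cls, frame = fr$frame[[1]], time_ps = fr$time_ps[[1]],
                  .before = 1)
  })
}

#' Coordination-state occupancy of a trajectory
#'
#' Aggregates per-frame classifications into state fractions; fractions sum
#' to one over the four states.
#'
#' @inheritParams mg_state_series
#' @return Object of class `mg_occupancy`: a tibble with `state`,
#'   `n_frames`, `fraction` (all four states listed) and an `"n_frames"`
#'   attribute for the total.
#' @export
mg_occupancy <- function(trajectory, thresholds = mg_thresholds(),
                         mg = NULL, atp_resname = "ATP",
                         aliases = atom_aliases(), skip_ps = 0) {
  states <- mg_state_series(trajectory, thresholds, mg, atp_resname,
                            aliases, skip_ps)
  counts <- table(states$state)
  out <- tibble(
    state = factor(MG_STATES, levels = MG_STATES),
    n_frames = as.integer(counts[MG_STATES]),
    fraction = as.numeric(counts[MG_STATES]) / nrow(states)
  )
  attr(out, "n_frames") <- nrow(states)
  class(out) <- c("mg_occupancy", class(out))
  out
}
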