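#' Parameters of the exponential hydrogen-bond energy relation
#'
#' The empirical Espinosa-type relation maps the hydrogen-acceptor distance
#' d (Angstrom) to a bond energy \eqn{E = -A \exp(-b d)} in kJ/mol. The
#' defaults are a prefactor A of 502e3 kJ/mol and a decay b of 3.6 per
#' Angstrom. The prefactor is configurable because published fits of this
#' relation differ; the default is the value used throughout this package's
#' energy tables.
#'
#' @param prefactor_kj Prefactor A, kJ/mol (> 0).
#' @param decay_per_ang Exponential decay b, 1/Angstrom (> 0).
#' @return Parameter list.
#' @export
espinosa_params <- function(prefactor_kj = 502e3, decay_per_ang = 3.6) {
  stopifnot(prefactor_kj > 0, decay_per_ang > 0)
  structure(
    list(prefactor_kj = prefactor_kj, decay_per_ang = decay_per_ang),
    class = "espinosa_params"
  )
}

#' Hydrogen-bond energy from the hydrogen-acceptor distance
#'
#' @param d_ha Hydrogen-acceptor distance(s), Angstrom, strictly positive.
#' @param params [espinosa_params()].
#' @return Energy in kJ/mol (negative; strictly increasing towards zero as
#'   the distance grows).
#' @export
espinosa_energy <- function(d_ha, params = espinosa_params()) {
  if (any(!is.finite(d_ha)) || any(d_ha <= 0)) {
    abort("d_ha must be finite and strictly positive")
  }
  -params$prefactor_kj * exp(-params$decay_per_ang * d_ha)
}

#' Total hydrogen-bond energy of a record set
#'
#' Sums the per-bond energies of a set of hydrogen-bond records (typically
#' one frame's detections) and reports the magnitude in kcal/mol, matching
#' the sign convention of the energy tables (internally the energies are
#' negative; tables print magnitudes).
#'
#' @param records Hydrogen-bond record tibble from [detect_hbonds()] (only
#'   the `d_ha` column is used), or a numeric vector of distances.
#' @param params [espinosa_params()].
#' @return Magnitude of the summed energy, kcal/mol (0 for no records).
#' @export
frame_ehb <- function(records, params = espinosa_params()) {
  d <- if (is.data.frame(records)) records$d_ha else as.numeric(records)
  if (length(d) == 0) return(0)
  abs(sum(espinosa_energy(d, params))) / KJ_PER_KCAL
}

#' Replicate statistics over independent runs
#'
#' Summarises a quantity over independent simulation replicas with the
#' mean-of-means convention: each run is first averaged over its frames,
#' then the mean and the sample (n-1) standard deviation are taken across
#' the run means. Pooling frames of unequal-length runs would weight runs
#' unequally; this function never pools.
#'
#' @param runs A list of per-frame numeric vectors (one per run), or a
#'   numeric vector already holding one mean per run.
#' @return An object of class `replica_summary` with `run_means`, `mean`
#'   and `sd` (`NA` for a single run, for which a spread is undefined).
#' @export
replica_summary <- function(runs) {
  if (is.numeric(runs)) runs <- as.list(runs)
  if (length(runs) == 0) abort("at least one run is required")
  if (any(lengths(runs) == 0)) abort("runs must be non-empty")
  run_means <- vapply(runs, function(r) mean(as.numeric(r)), numeric(1))
  structure(
    list(
      run_means = unname(run_means),
      mean = mean(run_means),
      sd = if (length(run_means) > 1) sd(run_means) else NA_real_,
      n_runs = length(run_means)
    ),
    class = "replica_summary"
  )
}

#' @export
print.replica_summary <- function(x, ...) {
  cat(sprintf("replica summary over %d run(s): mean %.4g +/- %.4g\n",
              x$n_runs, x$mean, x$sd))
  invisible(x)
}

#' @export
tidy.replica_summary <- function(x, ...) {
  tibble(run = seq_along(x$run_means), run_mean = x$run_means)
}

#' @export
glance.replica_summary <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, n_runs = x$n_runs)
}

#' Hydrogen-bond energy components over replicate trajectories
#'
#' For each run: per retained frame, the protein-ligand hydrogen-bond
#' energy and the helix-to-rest network energy are computed via
#' [detect_hbonds()] and [frame_ehb()]; each component is averaged over
#' frames, and the per-run total is the sum of the two components. Each of
#' the three quantities is then summarised across runs with
#' [replica_summary()], so the component/total identity holds run by run.
#'
#' @param runs List of trajectory tibbles (one per replica).
#' @param ligand Set specification for the ligand (default residue name
#'   `"ATP"`).
#' @param helix_range Inclusive residue range of the helical segment.
#' @param criteria [hbond_criteria()].
#' @param params [espinosa_params()].
#' @param skip_ps Equilibration time discarded per run, ps.
#' @param chemistry Donor/acceptor chemistry table.
#' @return Object of class `energy_components`: a list with
#'   `replica_summary` elements `protein_ligand`, `helix_network`, `total`
#'   (all magnitudes, kcal/mol).
#' @export
energy_components <- function(runs, ligand = sel_resname("ATP"),
                              helix_range = c(112, 133),
                              criteria = hbond_criteria(),
                              params = espinosa_params(), skip_ps = 0,
                              chemistry = default_hbond_chemistry()) {
  if (is.data.frame(runs)) runs <- list(runs)
  per_run <- purrr::map(runs, function(traj) {
    traj <- skip_equilibration(traj, skip_ps)
    frames <- split(traj, traj$frame)
    pl <- vapply(frames, function(fr) {
      recs <- .hbonds_between(fr, sel_protein(), ligand, criteria, chemistry)
      frame_ehb(recs, params)
    }, numeric(1))
    hx <- helix_network_ehb(traj, helix_range, criteria, params,
                            chemistry = chemistry)
    list(protein_ligand = pl, helix_network = hx)
  })
  pl_sum <- replica_summary(purrr::map(per_run, "protein_ligand"))
  hx_sum <- replica_summary(purrr::map(per_run, "helix_network"))
  tot_sum <- replica_summary(purrr::map2(
    purrr::map(per_run, "protein_ligand"),
    purrr::map(per_run, "helix_network"),
    function(a, b) mean(a) + mean(b)
  ))
  structure(
    list(protein_ligand = pl_sum, helix_network = hx_sum, total = tot_sum),
    class = "energy_components"
  )
}

# per-frame helix-to-rest network energies, kcal/mol magnitudes
helix_network_ehb <- function(trajectory, helix_range = c(112, 133),
                              criteria = hbond_criteria(),
                              params = espinosa_params(), skip_ps = 0,
                              chemistry = default_hbond_chemistry()) {
  lo <- min(helix_range)
  hi <- max(helix_range)
  traj <- skip_equilibration(trajectory, skip_ps)
  prot <- traj[traj$resname %in% AMINO_ACIDS, , drop = FALSE]
  if (!any(prot$resid >= lo & prot$resid <= hi)) {
    # no helix residues in this system: its network energy is zero
    return(rep(0, length(unique(traj$frame))))
  }
  frames <- split(prot, prot$frame)
  vapply(frames, function(fr) {
    don <- fr[fr$name %in% chemistry$donors, , drop = FALSE]
    acc <- fr[fr$name %in% chemistry$acceptors, , drop = FALSE]
    recs <- detect_hbonds(fr, don, acc, criteria, quiet = TRUE)
    in_d <- recs$donor_resid >= lo & recs$donor_resid <= hi
    in_a <- recs$acceptor_resid >= lo & recs$acceptor_resid <= hi
    frame_ehb(recs[xor(in_d, in_a), , drop = FALSE], params)
  }, numeric(1))
}

#' Assemble energy components into totals
#'
#' Takes per-cell component energies (protein-ligand and helix-network, as
#' printed magnitudes in kcal/mol) and returns them with their totals —
#' the arithmetic backbone of the hydrogen-bond energy table.
#'
#' @param protein_ligand,helix_network Numeric vectors of component
#'   energies (kcal/mol magnitudes), recycled to a common length.
#' @param label Optional character vector of cell labels (e.g. variant x
#'   coordination state).
#' @return Tibble with `label`, `protein_ligand`, `helix_network`, `total`.
#' @export
tabulate_energy_components <- function(protein_ligand, helix_network,
                                       label = NULL) {
  n <- max(length(protein_ligand), length(helix_network))
  protein_ligand <- rep_len(as.numeric(protein_ligand), n)
  helix_network <- rep_len(as.numeric(helix_network), n)
  tibble(
    label = label %||% paste0("cell_", seq_len(n)),
    protein_ligand = protein_ligand,
    helix_network = helix_network,
    total = protein_ligand + helix_network
  )
}

#' Hydrogen-bond energy penalty between two variants
#'
#' The difference in total hydrogen-bond energy, mutant minus wild type, at
#' the same Mg2+ coordination state. Positive values mean the mutant's
#' network is stronger, i.e. the wild type pays the penalty.
#'
#' @param mutant,wild_type Either numeric totals (kcal/mol magnitudes),
#'   `energy_components` objects, or per-variant rows of an energy table
#'   produced by [run_compare()] (with `coordination` and `total` entries).
#' @return Penalty in kcal/mol.
#' @export
energy_penalty <- function(mutant, wild_type) {
  tot <- function(x) {
    if (inherits(x, "energy_components")) return(x$total$mean)
    if (is.list(x) && !is.null(x$total)) return(x$total)
    as.numeric(x)
  }
  coord <- function(x) if (is.list(x)) x$coordination else NULL
  cm <- coord(mutant)
  cw <- coord(wild_type)
  if (!is.null(cm) && !is.null(cw) && !identical(cm, cw)) {
    abort(sprintf(
      "coordination states differ ('%s' vs '%s'); tables are not comparable",
      cm, cw
    ))
  }
  tot(mutant) - tot(wild_type)
}
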