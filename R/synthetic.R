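#' Specify a planted hydrogen bond
#'
#' Describes one donor-hydrogen-acceptor contact the synthetic binding-site
#' generator must realise exactly: the hydrogen-acceptor distance `d_ha`
#' and the deviation of the D-H...A angle from linearity. The donor heavy
#' atom is placed 1.0 Angstrom from its hydrogen (the covalent constraint
#' assumed by the detection pairing rule).
#'
#' @param donor,acceptor Atom specifications as `"RESNAME RESID ATOM"`
#'   strings (e.g. `"ARG 92 NE"`, `"GLU 83 OE1"`) or `"ATP ATOM"` for the
#'   ligand (its scaffold position is then used).
#' @param d_ha Planted hydrogen-acceptor distance, Angstrom; must exceed
#'   the 1.2 Angstrom covalent cut-off and stay below 10.
#' @param deviation_deg Planted angular deviation from linearity, degrees
#'   in `[0, 90)`.
#' @param hydrogen Hydrogen atom name; default derived from the donor atom
#'   (e.g. `NE -> HE`, backbone `N -> H`).
#' @return One-row tibble understood by [site_config()].
#' @export
planted_hbond <- function(donor, acceptor, d_ha, deviation_deg = 0,
                          hydrogen = NULL) {
  if (d_ha <= 1.2) {
    abort("planted d_ha must exceed the 1.2 A covalent cut-off")
  }
  if (d_ha >= 10) abort("planted d_ha must be below 10 A")
  if (deviation_deg < 0 || deviation_deg >= 90) {
    abort("planted deviation must lie in [0, 90) degrees")
  }
  d <- .parse_atom_spec(donor)
  a <- .parse_atom_spec(acceptor)
  chem <- default_hbond_chemistry()
  if (!d$atom %in% chem$donors) {
    abort(sprintf(
      "'%s' is not a donor-capable atom under the default chemistry", d$atom
    ))
  }
  if (!a$atom %in% chem$acceptors) {
    abort(sprintf(
      "'%s' is not an acceptor-capable atom under the default chemistry",
      a$atom
    ))
  }
  tibble(
    donor_resname = d$resname, donor_resid = d$resid, donor_atom = d$atom,
    hydrogen_atom = hydrogen %||% .default_hydrogen_name(d$atom),
    acceptor_resname = a$resname, acceptor_resid = a$resid,
    acceptor_atom = a$atom,
    d_ha = d_ha, deviation_deg = deviation_deg
  )
}

.parse_atom_spec <- function(spec) {
  tok <- strsplit(trimws(spec), "[[:space:]:]+")[[1]]
  if (length(tok) == 2 && toupper(tok[[1]]) == "ATP") {
    list(resname = "ATP", resid = 500L, atom = tok[[2]])
  } else if (length(tok) == 3) {
    list(resname = toupper(tok[[1]]), resid = as.integer(tok[[2]]),
         atom = tok[[3]])
  } else {
    abort(sprintf("cannot parse atom spec '%s'", spec))
  }
}

.default_hydrogen_name <- function(atom) {
  map <- c(
    N = "H", NE = "HE", NH1 = "HH11", NH2 = "HH21", NZ = "HZ1",
    OG = "HG", OG1 = "HG1", OH = "HH", ND1 = "HD1", ND2 = "HD21",
    NE1 = "HE1", NE2 = "HE21", N6 = "H61", `O2'` = "HO2'", `O3'` = "HO3'"
  )
  out <- unname(map[atom])
  if (is.na(out)) out <- paste0("H", substr(atom, 2, 4))
  out
}

#' Specify a planted cation contact
#'
#' @param resname `"ARG"` or `"LYS"`.
#' @param resid Residue number.
#' @param distance Distance from the residue's primary cationic atom (Arg
#'   NH1, Lys NZ) to the Mg2+ ion, Angstrom. Remaining cationic atoms of
#'   the residue are placed strictly farther from the ion.
#' @return One-row tibble understood by [site_config()].
#' @export
cation_contact <- function(resname, resid, distance) {
  stopifnot(resname %in% c("ARG", "LYS"), distance > 0)
  tibble(resname = resname, resid = as.integer(resid), distance = distance)
}

#' Configuration of a synthetic binding-site trajectory
#'
#' The generator emulates a minimal nucleotide binding site: an ATP-like
#' ligand with canonically named phosphate/nucleoside atoms, an optional
#' Mg2+ ion planted in a chosen coordination state, cationic residues at
#' chosen distances from the ion, and explicit donor/hydrogen/acceptor
#' triples realising requested hydrogen-bond geometries. Frames add
#' isotropic, i.i.d. Gaussian positional jitter to every atom.
#'
#' @param n_frames Number of frames.
#' @param frame_spacing_ps Time between frames, ps (times start at 0).
#' @param planted_hbonds Tibble of [planted_hbond()] rows (possibly empty).
#' @param mg_state One of `"first_sphere_alpha_beta"`,
#'   `"first_sphere_beta_gamma"`, `"second_sphere"`, `"unbound"`, or `NULL`
#'   for no Mg2+ ion.
#' @param mg_distance Target Mg-O distance, Angstrom: the bidentate Mg-O
#'   distance for first-sphere states (default 2.0), the minimal Mg-O
#'   distance for `"second_sphere"` (default 4.0); ignored for
#'   `"unbound"` (placed at 10 A).
#' @param cation_contacts Tibble of [cation_contact()] rows.
#' @param jitter_sigma Per-coordinate Gaussian jitter, Angstrom.
#' @param seed Integer seed making the trajectory reproducible.
#' @return Validated configuration list.
#' @export
site_config <- function(n_frames = 1, frame_spacing_ps = 100,
                        planted_hbonds = NULL, mg_state = NULL,
                        mg_distance = NULL, cation_contacts = NULL,
                        jitter_sigma = 0, seed = 1) {
  stopifnot(n_frames >= 1, frame_spacing_ps > 0, jitter_sigma >= 0)
  if (!is.null(mg_state)) {
    mg_state <- match.arg(mg_state, MG_STATES)
    if (is.null(mg_distance)) {
      mg_distance <- if (grepl("^first_sphere", mg_state)) 2.0 else 4.0
    }
  }
  structure(
    list(
      n_frames = as.integer(n_frames),
      frame_spacing_ps = frame_spacing_ps,
      planted_hbonds = planted_hbonds %||% planted_hbond("ARG 1 N", "GLY 2 O", 2)[0, ],
      mg_state = mg_state,
      mg_distance = mg_distance,
      cation_contacts = cation_contacts %||% cation_contact("ARG", 1, 4)[0, ],
      jitter_sigma = jitter_sigma,
      seed = as.integer(seed)
    ),
    class = "site_config"
  )
}

# noiseless scaffold positions of the ATP-like ligand (Angstrom).
# phosphate oxygens cluster near the origin; nucleoside atoms are spaced
# >= 6 A apart so planted hydrogens cannot graze a neighbouring acceptor.
.atp_scaffold <- function() {
  pos <- list(
    O1A = c(0, 0, 0), O2A = c(-1.0, -2.2, 0), O3A = c(1.3, -1.5, 0.8),
    O1B = c(3.0, 0, 0), O2B = c(4.0, -2.2, 0), O3B = c(4.5, -1.0, 1.2),
    O1G = c(6.0, 2.0, 0), O2G = c(7.0, 0.5, 1.5), O3G = c(7.0, 0.5, -1.5),
    `O5'` = c(-6, 0, 0), `O4'` = c(-6, 6, 0), `O2'` = c(-6, 12, 0),
    `O3'` = c(-6, 18, 0),
    N1 = c(-12, 0, 0), N3 = c(-12, 6, 0), N6 = c(-12, 12, 0),
    N7 = c(-12, 18, 0), N9 = c(-12, 24, 0)
  )
  tibble(
    name = names(pos),
    resname = "ATP", resid = 500L, chain = "L",
    x = unname(vapply(pos, `[[`, numeric(1), 1)),
    y = unname(vapply(pos, `[[`, numeric(1), 2)),
    z = unname(vapply(pos, `[[`, numeric(1), 3))
  )
}

.mg_position <- function(state, r) {
  o1a <- c(0, 0, 0)
  o1b <- c(3, 0, 0)
  o1g <- c(6, 2, 0)
  switch(state,
    first_sphere_alpha_beta = {
      if (r <= 1.5) abort("mg_distance too small for Oalpha/Obeta chelation")
      c(1.5, sqrt(r^2 - 1.5^2), 0)
    },
    first_sphere_beta_gamma = {
      sep <- sqrt(sum((o1g - o1b)^2))
      if (r <= sep / 2) abort("mg_distance too small for Obeta/Ogamma chelation")
      mid <- (o1b + o1g) / 2
      n <- c(-(o1g - o1b)[[2]], (o1g - o1b)[[1]], 0)
      n <- n / sqrt(sum(n^2))
      mid + sqrt(r^2 - (sep / 2)^2) * n
    },
    second_sphere = {
      if (r <= 2.6 || r > 5.0) {
        abort("second-sphere mg_distance must lie in (2.6, 5.0]")
      }
      c(1.5, sqrt(r^2 - 1.5^2), 0)
    },
    unbound = c(1.5, 10, 0)
  )
}

.unit <- function(v) v / sqrt(sum(v^2))

.perp_of <- function(a) {
  p <- c(a[[2]], -a[[1]], 0)
  if (sum(p^2) < 1e-12) p <- c(1, 0, 0)
  .unit(p)
}

#' Generate a synthetic binding-site trajectory with ground truth
#'
#' Builds the noiseless structure from the configuration — ligand scaffold,
#' Mg2+ ion, cation residues, and planted hydrogen-bond triples, each in
#' its own spatial cell so no accidental contacts arise — validates the
#' construction (covalent constraint; no stray acceptor within 3 Angstrom
#' of a planted hydrogen), then emits `n_frames` frames of i.i.d. Gaussian
#' jitter around it.
#'
#' @param config [site_config()].
#' @return List with `trajectory` (tibble, see [read_pdb()]) and
#'   `ground_truth`: planted totals (`n_hbonds`, `n_protein_atp`,
#'   `n_helix`, with helix taken as residues 112-133), noiseless energies
#'   in kcal/mol (`ehb_total`, `ehb_protein_atp`, `ehb_helix`), the planted
#'   `state`, and the planted contact counts (`contacts_per_residue`,
#'   `contacts_per_atom` at the 4.5 Angstrom cut-off).
#' @export
build_site_trajectory <- function(config) {
  stopifnot(inherits(config, "site_config"))
  atoms <- .atp_scaffold()

  mg_pos <- NULL
  if (!is.null(config$mg_state)) {
    mg_pos <- .mg_position(config$mg_state, config$mg_distance)
    atoms <- dplyr::bind_rows(atoms, tibble(
      name = "MG", resname = "MG", resid = 600L, chain = "L",
      x = mg_pos[[1]], y = mg_pos[[2]], z = mg_pos[[3]]
    ))
  }

  cc <- config$cation_contacts
  contacts_atom <- 0L
  if (nrow(cc) > 0) {
    if (is.null(mg_pos)) abort("cation contacts require an Mg2+ ion")
    for (k in seq_len(nrow(cc))) {
      th <- 2 * pi * (k - 1) / nrow(cc)
      u <- .unit(c(0.4 * cos(th), 0.4 * sin(th), 1))
      d <- cc$distance[[k]]
      prim <- mg_pos + d * u
      extra <- if (cc$resname[[k]] == "ARG") {
        p <- .perp_of(u)
        list(NE = mg_pos + (d + 1.35) * u, NH2 = mg_pos + (d + 1.0) * u + p)
      } else {
        list()
      }
      nm <- c(if (cc$resname[[k]] == "ARG") "NH1" else "NZ", names(extra))
      po <- c(list(prim), unname(extra))
      atoms <- dplyr::bind_rows(atoms, tibble(
        name = nm, resname = cc$resname[[k]], resid = cc$resid[[k]],
        chain = "A",
        x = vapply(po, `[[`, numeric(1), 1),
        y = vapply(po, `[[`, numeric(1), 2),
        z = vapply(po, `[[`, numeric(1), 3)
      ))
      contacts_atom <- contacts_atom + sum(vapply(
        po, function(q) sqrt(sum((q - mg_pos)^2)) <= 4.5, logical(1)
      ))
    }
  }

  hb <- config$planted_hbonds
  planted_h <- list()
  if (nrow(hb) > 0) {
    for (k in seq_len(nrow(hb))) {
      if (hb$acceptor_resname[[k]] == "ATP") {
        row <- atoms[atoms$resname == "ATP" &
                       atoms$name == hb$acceptor_atom[[k]], ]
        if (nrow(row) == 0) {
          abort(sprintf("unknown ATP scaffold atom '%s'",
                        hb$acceptor_atom[[k]]))
        }
        a_pos <- c(row$x, row$y, row$z)
        centroid <- c(-1, 6, 0)
        v <- .unit(a_pos - centroid + c(0, 0, 0.8 * (-1)^k))
      } else {
        a_pos <- c(20 + 15 * k, -30, 0)
        v <- c(0, 0, 1)
        atoms <- dplyr::bind_rows(atoms, tibble(
          name = hb$acceptor_atom[[k]],
          resname = hb$acceptor_resname[[k]],
          resid = hb$acceptor_resid[[k]], chain = "A",
          x = a_pos[[1]], y = a_pos[[2]], z = a_pos[[3]]
        ))
      }
      h_pos <- a_pos + hb$d_ha[[k]] * v
      a_hat <- -v
      dev <- hb$deviation_deg[[k]] * pi / 180
      w <- -cos(dev) * a_hat + sin(dev) * .perp_of(a_hat)
      d_pos <- h_pos + 1.0 * w
      if (hb$donor_resname[[k]] == "ATP") {
        # the donor is a ligand atom: move the scaffold atom into place
        # rather than duplicating it, and bond its hydrogen on the ligand
        i <- which(atoms$resname == "ATP" & atoms$name == hb$donor_atom[[k]])
        if (length(i) != 1) {
          abort(sprintf("unknown ATP scaffold atom '%s'", hb$donor_atom[[k]]))
        }
        atoms$x[[i]] <- d_pos[[1]]
        atoms$y[[i]] <- d_pos[[2]]
        atoms$z[[i]] <- d_pos[[3]]
        atoms <- dplyr::bind_rows(atoms, tibble(
          name = hb$hydrogen_atom[[k]], resname = "ATP", resid = 500L,
          chain = "L", x = h_pos[[1]], y = h_pos[[2]], z = h_pos[[3]]
        ))
      } else {
        atoms <- dplyr::bind_rows(atoms, tibble(
          name = c(hb$donor_atom[[k]], hb$hydrogen_atom[[k]]),
          resname = hb$donor_resname[[k]],
          resid = hb$donor_resid[[k]], chain = "A",
          x = c(d_pos[[1]], h_pos[[1]]),
          y = c(d_pos[[2]], h_pos[[2]]),
          z = c(d_pos[[3]], h_pos[[3]])
        ))
      }
      planted_h[[k]] <- list(h = h_pos, acceptor = a_pos, donor = d_pos)
    }
  }

  if (anyDuplicated(atoms[, c("name", "resname", "resid", "chain")]) > 0) {
    abort("conflicting construction: duplicate atom placement requested")
  }
  .check_construction(atoms, planted_h)

  chem <- default_hbond_chemistry()
  params <- espinosa_params()
  is_pa <- xor(hb$donor_resname == "ATP", hb$acceptor_resname == "ATP")
  in_hx <- function(rn, ri) rn %in% AMINO_ACIDS & ri >= 112 & ri <= 133
  both_prot <- hb$donor_resname != "ATP" & hb$acceptor_resname != "ATP"
  is_hx <- both_prot & xor(in_hx(hb$donor_resname, hb$donor_resid),
                           in_hx(hb$acceptor_resname, hb$acceptor_resid))
  ehb_of <- function(sel) {
    if (!any(sel)) 0 else frame_ehb(hb$d_ha[sel], params)
  }
  ground_truth <- list(
    n_hbonds = nrow(hb),
    n_protein_atp = sum(is_pa),
    n_helix = sum(is_hx),
    ehb_total = ehb_of(rep(TRUE, nrow(hb))),
    ehb_protein_atp = ehb_of(is_pa),
    ehb_helix = ehb_of(is_hx),
    state = config$mg_state,
    contacts_per_residue = if (nrow(cc)) sum(cc$distance <= 4.5) else 0L,
    contacts_per_atom = contacts_atom
  )

  atoms$element <- ifelse(
    .is_hydrogen(atoms$name, ""), "H", .element_from_name(atoms$name)
  )
  atoms$serial <- seq_len(nrow(atoms))
  n_at <- nrow(atoms)

  # planted hydrogens share their donor's jitter: the covalent X-H unit
  # moves rigidly (as bond constraints enforce in simulation), so noise
  # perturbs bond geometry, never the donor-hydrogen pairing itself
  h_idx <- d_idx <- integer(0)
  if (nrow(hb) > 0) {
    for (k in seq_len(nrow(hb))) {
      hi <- which(atoms$resname == hb$donor_resname[[k]] &
                    atoms$resid == hb$donor_resid[[k]] &
                    atoms$name == hb$hydrogen_atom[[k]])
      di <- which(atoms$resname == hb$donor_resname[[k]] &
                    atoms$resid == hb$donor_resid[[k]] &
                    atoms$name == hb$donor_atom[[k]])
      h_idx <- c(h_idx, hi)
      d_idx <- c(d_idx, di)
    }
  }

  set.seed(config$seed)
  traj <- purrr::map_dfr(seq_len(config$n_frames), function(f) {
    jit <- if (config$jitter_sigma > 0) {
      matrix(rnorm(3 * n_at, 0, config$jitter_sigma), ncol = 3)
    } else {
      matrix(0, nrow = n_at, ncol = 3)
    }
    jit[h_idx, ] <- jit[d_idx, ]
    dplyr::mutate(atoms,
      frame = f, time_ps = (f - 1) * config$frame_spacing_ps,
      x = .data$x + jit[, 1], y = .data$y + jit[, 2], z = .data$z + jit[, 3],
      .before = 1
    )
  })
  traj <- new_trajectory(
    traj[, c("frame", "time_ps", "serial", "name", "element", "resname",
             "resid", "chain", "x", "y", "z")],
    label = sprintf("synthetic_site_seed%d", config$seed)
  )
  list(trajectory = traj, ground_truth = ground_truth, config = config)
}

# construction feasibility: every planted hydrogen must see only its own
# acceptor within a 3.0 A guard and only its own donor within the 1.2 A
# covalent cut-off, so noiseless detection equals the planted set exactly.
.check_construction <- function(atoms, planted_h) {
  if (length(planted_h) == 0) return(invisible(TRUE))
  chem <- default_hbond_chemistry()
  acc <- atoms[atoms$name %in% chem$acceptors, , drop = FALSE]
  heavy <- atoms[!.is_hydrogen(atoms$name, ""), , drop = FALSE]
  for (k in seq_along(planted_h)) {
    h <- planted_h[[k]]$h
    a <- planted_h[[k]]$acceptor
    d <- planted_h[[k]]$donor
    d_acc <- sqrt((acc$x - h[[1]])^2 + (acc$y - h[[2]])^2 +
                    (acc$z - h[[3]])^2)
    # the bond's own acceptor, and its own donor heavy atom (which may be
    # acceptor-capable, e.g. a carboxylate or hydroxyl oxygen), are exempt
    own <- (sqrt((acc$x - a[[1]])^2 + (acc$y - a[[2]])^2 +
                   (acc$z - a[[3]])^2) < 1e-9) |
      (sqrt((acc$x - d[[1]])^2 + (acc$y - d[[2]])^2 +
              (acc$z - d[[3]])^2) < 1e-9)
    if (any(d_acc < 3.0 & !own)) {
      abort(sprintf(
        "infeasible geometry: planted hydrogen %d grazes another acceptor", k
      ))
    }
    d_hv <- sqrt((heavy$x - h[[1]])^2 + (heavy$y - h[[2]])^2 +
                   (heavy$z - h[[3]])^2)
    if (sum(d_hv <= 1.2) != 1) {
      abort(sprintf(
        "infeasible geometry: planted hydrogen %d violates the covalent constraint", k
      ))
    }
  }
  invisible(TRUE)
}

#' Crooks-consistent Gaussian work samples
#'
#' Draws forward work from Normal(delta_f + beta sigma^2 / 2, sigma^2) and
#' backward work from Normal(-delta_f + beta sigma^2 / 2, sigma^2) — the
#' Gaussian pair satisfying the Crooks fluctuation theorem — so the exact
#' free-energy difference underlying the samples is known.
#'
#' @param delta_f True free-energy difference.
#' @param sigma Work standard deviation (> 0).
#' @param n_samples Samples per direction (>= 2).
#' @param beta Inverse temperature (reduced units by default).
#' @param seed Integer seed.
#' @return [work_set()] with a `"delta_f"` attribute holding the truth.
#' @export
gaussian_work_samples <- function(delta_f, sigma, n_samples, beta = 1,
                                  seed = 1) {
  stopifnot(sigma > 0, n_samples >= 2)
  set.seed(seed)
  ws <- work_set(
    forward = rnorm(n_samples, delta_f + beta * sigma^2 / 2, sigma),
    backward = rnorm(n_samples, -delta_f + beta * sigma^2 / 2, sigma),
    beta = beta, unit = "reduced"
  )
  attr(ws, "delta_f") <- delta_f
  ws
}

#' Synthetic per-window dH/dlambda samples
#'
#' Emits one sample series per lambda window whose noiseless mean follows a
#' closed-form profile, for validating thermodynamic integration against
#' the analytic integral.
#'
#' @param profile `"constant"`, `"linear"`, `"cubic"`, or a function of
#'   lambda.
#' @param coefficients Numeric polynomial coefficients in increasing order
#'   (1 value for constant, 2 for linear, 4 for cubic); ignored for a
#'   function profile.
#' @param lambda_grid Strictly increasing grid in `[0, 1]`; the default
#'   mirrors an 85-window alchemical protocol.
#' @param n_samples Samples per window.
#' @param spacing_ps Time between samples, ps (times start at 0).
#' @param noise_sigma Gaussian noise sd added to every sample.
#' @param seed Integer seed.
#' @return [lambda_series()] with an `"analytic_integral"` attribute (for
#'   polynomial profiles) holding the exact integral over the grid span.
#' @export
synthetic_dhdl <- function(profile = c("constant", "linear", "cubic"),
                           coefficients = 1, lambda_grid = seq(0, 1, length.out = 85),
                           n_samples = 50, spacing_ps = 10,
                           noise_sigma = 0, seed = 1) {
  if (length(lambda_grid) == 0) abort("empty lambda grid")
  if (is.function(profile)) {
    fun <- profile
    analytic <- NA_real_
  } else {
    profile <- match.arg(profile)
    need <- c(constant = 1, linear = 2, cubic = 4)[[profile]]
    if (length(coefficients) != need) {
      abort(sprintf("profile '%s' needs %d coefficient(s)", profile, need))
    }
    co <- coefficients
    fun <- function(l) {
      vapply(seq_along(co), function(p) co[[p]] * l^(p - 1), numeric(length(l))) |>
        matrix(nrow = length(l)) |>
        rowSums()
    }
    anti <- function(l) sum(co * l^(seq_along(co)) / seq_along(co))
    analytic <- anti(max(lambda_grid)) - anti(min(lambda_grid))
  }
  set.seed(seed)
  times <- spacing_ps * (seq_len(n_samples) - 1)
  series <- purrr::map(lambda_grid, function(l) {
    vals <- rep(fun(l), n_samples)
    if (noise_sigma > 0) vals <- vals + rnorm(n_samples, 0, noise_sigma)
    sample_series(times, vals)
  })
  ls <- lambda_series(lambda_grid, series)
  attr(ls, "analytic_integral") <- analytic
  ls
}
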