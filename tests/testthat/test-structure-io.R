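test_that("a single-model PDB yields a one-frame trajectory", {
  txt <- paste(
    "ATOM      1  N   ARG A  92      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ARG A  92      12.000   7.000  -6.000  1.00  0.00           C",
    "HETATM    3 MG   MG  L 600       1.500   1.323   0.000  1.00  0.00          MG",
    "END",
    sep = "\n"
  )
  traj <- read_pdb(txt)
  expect_equal(length(unique(traj$frame)), 1)
  expect_equal(nrow(traj), 3)
  expect_equal(traj$name, c("N", "CA", "MG"))
  expect_equal(traj$resid, c(92L, 92L, 600L))
  expect_equal(traj$x, c(11.104, 12.000, 1.500))
})

test_that("MODEL/ENDMDL records delimit frames with consistent ordering", {
  sim <- build_site_trajectory(site_config(
    n_frames = 5, jitter_sigma = 0.1, seed = 11,
    mg_state = "second_sphere"
  ))
  txt <- write_pdb(sim$trajectory)
  expect_true(grepl("MODEL", txt))
  back <- read_pdb(txt)
  expect_equal(length(unique(back$frame)), 5)
  nm <- split(back$name, back$frame)
  for (m in nm) expect_identical(m, nm[[1]])
})

test_that("PDB round trip preserves identity exactly and coordinates to 1e-3", {
  sim <- build_site_trajectory(site_config(
    n_frames = 3, jitter_sigma = 0.2, seed = 4,
    planted_hbonds = planted_hbond("ARG 126 NH1", "ATP O5'", 1.9),
    mg_state = "first_sphere_alpha_beta"
  ))
  traj <- sim$trajectory
  back <- read_pdb(write_pdb(traj))
  expect_identical(back$name, traj$name)
  expect_identical(back$resname, traj$resname)
  expect_identical(back$resid, traj$resid)
  expect_identical(back$serial, traj$serial)
  expect_lt(max(abs(back$x - traj$x), abs(back$y - traj$y),
                abs(back$z - traj$z)), 1e-3 + 1e-12)
  expect_equal(unique(back$time_ps), unique(traj$time_ps))
})

test_that("the PDB writer enforces its format contract", {
  fr <- make_frame("N", "ARG", 92, 0, 0, 0)
  expect_no_error(write_pdb(fr))
  expect_false(grepl("MODEL", write_pdb(fr)))
  expect_true(grepl("MODEL", write_pdb(fr, multi_model = TRUE)))

  bad <- fr
  bad$name <- "HH123"
  expect_error(write_pdb(bad), "4 characters")
  expect_error(write_pdb(fr[0, ]), "no atoms")
})

test_that("malformed and inconsistent PDB input fails with diagnostics", {
  bad <- paste(
    "ATOM      1  N   ARG A  92      11.104   6.134  -6.504",
    "ATOM      2  CA  ARG A  92      twelve   7.000  -6.000",
    sep = "\n"
  )
  expect_error(read_pdb(bad), "line 2")

  inconsistent <- paste(
    "MODEL        1",
    "ATOM      1  N   ARG A  92       1.000   0.000   0.000",
    "ATOM      2  O   ARG A  92       2.000   0.000   0.000",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ARG A  92       1.000   0.000   0.000",
    "ENDMDL",
    sep = "\n"
  )
  expect_error(read_pdb(inconsistent), "atom count")
})

test_that("XVG reading skips metadata, errors on junk, and round-trips", {
  txt <- "@ title \"dhdl\"\n# created by test\n0.0 1.5\n1.0 -2.25\n2.0 0.125\n"
  s <- read_xvg(txt)
  expect_equal(nrow(s), 3)
  expect_equal(s$value, c(1.5, -2.25, 0.125))

  expect_error(read_xvg("@ only\n# comments\n"), "empty")
  expect_error(read_xvg("0.0 1.5\n1.0 oops\n"), "line 2")

  set.seed(9)
  orig <- sample_series(0:49, rnorm(50, 0, 3), unit = "kcal/mol")
  back <- read_xvg(write_xvg(orig), unit = "kcal/mol")
  expect_identical(back$value, orig$value) # bit-exact via %.17g
  expect_identical(back$time_ps, orig$time_ps)
})

test_that("sample_series validates its contract", {
  expect_error(sample_series(1:3, 1:2), "equal length")
  expect_error(sample_series(numeric(0), numeric(0)), "empty")
  expect_error(sample_series(c(2, 1), c(0, 0)), "non-decreasing")
})

test_that("selectors resolve aliases and match a linear-scan filter", {
  sim <- build_site_trajectory(site_config(
    planted_hbonds = dplyr::bind_rows(
      planted_hbond("ARG 92 NH1", "ATP O3G", 2.0),
      planted_hbond("ARG 92 NH2", "ATP O4'", 2.1, hydrogen = "HH21")
    ),
    mg_state = "first_sphere_alpha_beta"
  ))
  fr <- get_frame(sim$trajectory, 1)

  expect_setequal(resolve_group(fr, "ARG 92 NHx")$name, c("NH1", "NH2"))
  expect_setequal(resolve_group(fr, "ATP Oalpha")$name, c("O1A", "O2A"))
  expect_setequal(resolve_group(fr, "ATP Ogamma")$name,
                  c("O1G", "O2G", "O3G"))
  expect_setequal(resolve_group(fr, "ATP N3/7/9")$name, c("N3", "N7", "N9"))
  expect_equal(resolve_group(fr, "R92:NH1")$serial,
               fr$serial[fr$resname == "ARG" & fr$name == "NH1"])

  # alias resolution equals a naive full scan
  scan <- fr[fr$resname == "ATP" & fr$name %in% c("O1B", "O2B"), ]
  expect_identical(resolve_group(fr, "ATP Obeta"), scan)

  expect_error(resolve_group(fr, "LYS 7 NZ"), "LYS 7 NZ")
})

test_that("trajectory validation rejects broken input", {
  fr <- make_frame(c("N", "O"), "GLY", c(1, 2), c(0, 1), c(0, 0), c(0, 0))
  expect_no_error(new_trajectory(fr))
  f2 <- dplyr::mutate(fr, frame = 2L, time_ps = 0) # time not increasing
  expect_error(new_trajectory(dplyr::bind_rows(fr, f2)), "strictly increase")
  f3 <- dplyr::mutate(fr[1, ], frame = 2L, time_ps = 10)
  expect_error(new_trajectory(dplyr::bind_rows(fr, f3)), "atom count")
})
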