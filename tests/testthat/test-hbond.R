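# constructed D-H...A geometry: donor at origin, hydrogen 1 A along +z,
# acceptor placed at a chosen H-A distance and deviation from linearity
dha_frame <- function(d_ha, deviation_deg) {
  dev <- deviation_deg * pi / 180
  a <- c(0, 0, 1) + d_ha * c(sin(dev), 0, cos(dev))
  make_frame(
    name = c("N", "H", "O"),
    resname = c("GLY", "GLY", "ALA"),
    resid = c(1, 1, 2),
    x = c(0, 0, a[1]), y = c(0, 0, a[2]), z = c(0, 1, a[3])
  )
}

test_that("detection applies the distance and angle cut-offs exactly", {
  crit <- hbond_criteria(2.7, 30)
  don <- function(df) df$name == "N"
  acc <- function(df) df$name == "O"

  hit <- detect_hbonds(dha_frame(2.0, 0), don, acc, crit)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$d_ha, 2.0, tolerance = 1e-12)
  expect_equal(hit$angle_deviation, 0, tolerance = 1e-9)

  expect_equal(nrow(detect_hbonds(dha_frame(2.8, 0), don, acc, crit)), 0)
  expect_equal(nrow(detect_hbonds(dha_frame(2.0, 35), don, acc, crit)), 0)
  # boundary geometries are accepted (<=)
  expect_equal(nrow(detect_hbonds(dha_frame(2.7, 0), don, acc, crit)), 1)
  expect_equal(nrow(detect_hbonds(dha_frame(2.0, 29.99), don, acc, crit)), 1)
})

test_that("donors without a bonded hydrogen are skipped with a warning", {
  fr <- make_frame(
    name = c("N", "O"), resname = c("GLY", "ALA"), resid = c(1, 2),
    x = c(0, 2), y = c(0, 0), z = c(0, 0)
  )
  expect_warning(
    out <- detect_hbonds(fr, function(df) df$name == "N",
                         function(df) df$name == "O"),
    "without a bonded hydrogen"
  )
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "skipped_donors"), 1L)
})

test_that("detection equals the brute-force double loop on random frames", {
  for (seed in 1:25) {
    fr <- random_frame(seed)
    got <- detect_hbonds(fr, function(df) df$name == "N",
                         function(df) df$name == "O", quiet = TRUE)
    expect_identical(hbond_keys(got), oracle_hbond_keys(fr),
                     label = sprintf("seed %d", seed))
  }
})

test_that("detection is invariant under rigid rotation and translation", {
  fr <- random_frame(101)
  moved <- rigid_transform(fr)
  a <- detect_hbonds(fr, function(df) df$name == "N",
                     function(df) df$name == "O", quiet = TRUE)
  b <- detect_hbonds(moved, function(df) df$name == "N",
                     function(df) df$name == "O", quiet = TRUE)
  expect_identical(hbond_keys(a), hbond_keys(b))
  ord_a <- order(a$donor_serial, a$hydrogen_serial, a$acceptor_serial)
  ord_b <- order(b$donor_serial, b$hydrogen_serial, b$acceptor_serial)
  expect_equal(a$d_ha[ord_a], b$d_ha[ord_b], tolerance = 1e-6)
  expect_equal(a$angle_deviation[ord_a], b$angle_deviation[ord_b],
               tolerance = 1e-6)
})

test_that("tightening either criterion never increases the bond count", {
  don <- function(df) df$name == "N"
  acc <- function(df) df$name == "O"
  for (seed in c(3, 17, 44)) {
    fr <- random_frame(seed)
    n_loose <- nrow(detect_hbonds(fr, don, acc, hbond_criteria(2.7, 30),
                                  quiet = TRUE))
    for (crit in list(hbond_criteria(2.2, 30), hbond_criteria(2.7, 15),
                      hbond_criteria(2.2, 15))) {
      expect_lte(nrow(detect_hbonds(fr, don, acc, crit, quiet = TRUE)),
                 n_loose)
    }
  }
})

test_that("per-frame count series honours planting and equilibration skip", {
  hb <- dplyr::bind_rows(
    planted_hbond("ARG 126 NH1", "ATP O5'", 1.9),
    planted_hbond("ATP O2'", "GLU 83 OE1", 2.0)
  )
  sim <- build_site_trajectory(site_config(
    n_frames = 5, frame_spacing_ps = 100, planted_hbonds = hb
  ))
  cs <- hbond_count_series(sim$trajectory, sel_protein(), sel_resname("ATP"))
  expect_equal(cs$n_hbonds, rep(2L, 5))

  cs2 <- hbond_count_series(sim$trajectory, sel_protein(),
                            sel_resname("ATP"), skip_ps = 200)
  expect_equal(nrow(cs2), 3)
  expect_true(all(cs2$time_ps >= 200))

  expect_error(
    hbond_count_series(sim$trajectory, sel_protein(), sel_resname("ATP"),
                       skip_ps = 1e6),
    "skip_ps"
  )
})

test_that("jittered planted bonds are recovered in almost every frame", {
  hb <- dplyr::bind_rows(
    planted_hbond("ARG 126 NH1", "ATP O5'", 1.9),
    planted_hbond("ATP O2'", "GLU 83 OE1", 2.0)
  )
  sim <- build_site_trajectory(site_config(
    n_frames = 200, planted_hbonds = hb, jitter_sigma = 0.05, seed = 21
  ))
  cs <- hbond_count_series(sim$trajectory, sel_protein(), sel_resname("ATP"))
  expect_gte(mean(cs$n_hbonds == 2), 0.99)
})

test_that("helix network counts bonds crossing the boundary only", {
  hb <- dplyr::bind_rows(
    planted_hbond("ARG 120 NE", "ASP 50 OD1", 2.0),   # helix -> rest
    planted_hbond("SER 115 OG", "THR 130 OG1", 2.1),  # intra-helix
    planted_hbond("ARG 40 NH1", "GLU 125 OE2", 1.9)   # rest -> helix
  )
  sim <- build_site_trajectory(site_config(n_frames = 2, planted_hbonds = hb))
  hx <- helix_network_hbonds(sim$trajectory)
  expect_equal(hx$n_hbonds, rep(2L, 2))
  # inverted range is normalised
  hx_inv <- helix_network_hbonds(sim$trajectory, helix_range = c(133, 112))
  expect_identical(hx, hx_inv)
  expect_error(
    helix_network_hbonds(sim$trajectory, helix_range = c(300, 310)),
    "selects no atoms"
  )
})

test_that("minimal distances follow min semantics and the pairwise scan", {
  fr <- make_frame(
    name = c("NH1", "NH2", "O1G"),
    resname = c("ARG", "ARG", "ATP"),
    resid = c(92, 92, 500),
    x = c(0, 0, 3), y = c(0, -8, 4), z = c(0, 0, 0)
  )
  traj <- new_trajectory(fr)
  s <- min_distance_series(traj, "ARG 92 NH1", "ATP O1G")
  expect_equal(s$min_dist, 5) # 3-4-5 triangle
  s2 <- min_distance_series(traj, "ARG 92 NHx", "ATP O1G")
  expect_equal(s2$min_dist, 5) # NH2 is farther; min picks NH1

  for (seed in c(5, 6)) {
    rf <- random_frame(seed)
    s3 <- min_distance_series(new_trajectory(rf),
                              function(df) df$name == "N",
                              function(df) df$name == "O")
    expect_equal(
      s3$min_dist,
      oracle_min_dist(rf[rf$name == "N", ], rf[rf$name == "O", ]),
      tolerance = 1e-12
    )
  }
})

test_that("histograms are normalised with half-open bins", {
  h <- distance_histogram(rep(2.35, 40), bin_width = 0.1)
  expect_equal(sum(h$freq), 1, tolerance = 1e-9)
  expect_equal(sum(h$freq > 0), 1)

  set.seed(33)
  vals <- runif(20000, 1, 2)
  h2 <- distance_histogram(vals, 0.1, range = c(1, 2))
  expect_equal(sum(h2$freq), 1, tolerance = 1e-9)
  expect_lt(max(abs(h2$freq - 0.1)), 0.01) # approximately flat

  expect_error(distance_histogram(numeric(0), 0.1), "empty")
})
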