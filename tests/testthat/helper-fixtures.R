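# fixture builders and independent brute-force oracles shared across tests.
# the oracles use plain loops and explicit vector arithmetic on purpose:
# they must stay independent of the package's vectorised code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_frame <- function(name, resname, resid, x, y, z,
                       chain = "A", element = NULL, frame = 1L,
                       time_ps = 0) {
  n <- length(name)
  element <- element %||% ifelse(grepl("^[0-9]*H", name), "H",
                                 substr(sub("^[0-9']*", "", name), 1, 1))
  tibble::tibble(
    frame = as.integer(frame), time_ps = time_ps,
    serial = seq_len(n), name = name, element = element,
    resname = resname, resid = as.integer(resid),
    chain = rep_len(chain, n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
}

# random frame of ~50 atoms: donor N-H groups and acceptor O atoms thrown
# uniformly into a box small enough that some contacts fall inside 2.7 A
random_frame <- function(seed, n_donors = 12, n_acceptors = 26, box = 9) {
  set.seed(seed)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_donors)) {
    p <- runif(3, 0, box)
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    h <- p + u # 1.0 A covalent offset
    rows[[length(rows) + 1]] <- tibble::tibble(
      serial = serial + 1:2, name = c("N", "H"), element = c("N", "H"),
      resname = "GLY", resid = i, chain = "A",
      x = c(p[1], h[1]), y = c(p[2], h[2]), z = c(p[3], h[3])
    )
    serial <- serial + 2L
  }
  for (j in seq_len(n_acceptors)) {
    p <- runif(3, 0, box)
    rows[[length(rows) + 1]] <- tibble::tibble(
      serial = serial + 1L, name = "O", element = "O",
      resname = "GLY", resid = 100L + j, chain = "A",
      x = p[1], y = p[2], z = p[3]
    )
    serial <- serial + 1L
  }
  df <- dplyr::bind_rows(rows)
  dplyr::mutate(df, frame = 1L, time_ps = 0, .before = 1)
}

# exhaustive O(donors x hydrogens x acceptors) hydrogen-bond scan
oracle_hbond_keys <- function(frame, donor_names = "N",
                              acceptor_names = "O",
                              max_d = 2.7, max_dev = 30) {
  keys <- character(0)
  don_rows <- which(frame$name %in% donor_names)
  acc_rows <- which(frame$name %in% acceptor_names)
  hyd_rows <- which(frame$element == "H" | grepl("^[0-9]*H", frame$name))
  for (di in don_rows) {
    for (hi in hyd_rows) {
      same_res <- frame$resid[hi] == frame$resid[di] &&
        frame$resname[hi] == frame$resname[di] &&
        frame$chain[hi] == frame$chain[di]
      if (!same_res) next
      dh <- c(frame$x[di] - frame$x[hi], frame$y[di] - frame$y[hi],
              frame$z[di] - frame$z[hi])
      if (sqrt(sum(dh^2)) > 1.2) next
      for (ai in acc_rows) {
        if (ai == di || ai == hi) next
        ha <- c(frame$x[ai] - frame$x[hi], frame$y[ai] - frame$y[hi],
                frame$z[ai] - frame$z[hi])
        d_ha <- sqrt(sum(ha^2))
        if (d_ha > max_d) next
        cosang <- sum(ha * dh) / (d_ha * sqrt(sum(dh^2)))
        dev <- 180 - acos(max(-1, min(1, cosang))) * 180 / pi
        if (dev <= max_dev) {
          keys <- c(keys, paste(frame$serial[di], frame$serial[hi],
                                frame$serial[ai], sep = "-"))
        }
      }
    }
  }
  sort(keys)
}

hbond_keys <- function(records) {
  sort(paste(records$donor_serial, records$hydrogen_serial,
             records$acceptor_serial, sep = "-"))
}

oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

oracle_contacts <- function(frame, max_d = 4.5, per_atom = FALSE) {
  table <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  mg <- frame[frame$resname == "MG", ][1, ]
  hits_res <- character(0)
  hits_atom <- 0L
  for (i in seq_len(nrow(frame))) {
    rn <- frame$resname[i]
    if (!rn %in% names(table) || !frame$name[i] %in% table[[rn]]) next
    d <- sqrt((frame$x[i] - mg$x)^2 + (frame$y[i] - mg$y)^2 +
                (frame$z[i] - mg$z)^2)
    if (d <= max_d) {
      hits_atom <- hits_atom + 1L
      hits_res <- c(hits_res, paste(rn, frame$resid[i], frame$chain[i]))
    }
  }
  if (per_atom) hits_atom else length(unique(hits_res))
}

# rigid-body transform: rotation about an arbitrary axis plus translation
rigid_transform <- function(frame, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle)
  s_ <- sin(angle)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  rot <- matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), nrow = 3, byrow = TRUE)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(rot)
  frame$x <- xyz[, 1] + shift[1]
  frame$y <- xyz[, 2] + shift[2]
  frame$z <- xyz[, 3] + shift[3]
  frame
}

# independent BAR route: fixed-point iteration of the self-consistency
# log-ratio update (different algorithm from the package's bisection)
bar_fixed_point <- function(wf, wr, beta = 1, iters = 300) {
  m <- log(length(wf) / length(wr)) / beta
  d <- (mean(wf) - mean(wr)) / 2
  for (i in seq_len(iters)) {
    num <- sum(stats::plogis(-beta * (-m + wr + d)))
    den <- sum(stats::plogis(-beta * (m + wf - d)))
    d <- d + log(num / den) / beta
  }
  d
}

# analytic standard error of BAR on Crooks-consistent Gaussian work
# (Bennett variance for Gaussian overlap, evaluated by quadrature)
gaussian_bar_se <- function(delta_f, sigma, n, beta = 1) {
  mu <- delta_f + beta * sigma^2 / 2
  integrand <- function(w) {
    pf <- stats::dnorm(w, mu, sigma)
    f <- stats::plogis(-beta * (w - delta_f))
    pf * f^2
  }
  e_f2 <- stats::integrate(integrand, mu - 10 * sigma, mu + 10 * sigma)$value
  integrand1 <- function(w) {
    stats::dnorm(w, mu, sigma) * stats::plogis(-beta * (w - delta_f))
  }
  e_f <- stats::integrate(integrand1, mu - 10 * sigma, mu + 10 * sigma)$value
  sqrt(2 * (e_f2 / e_f^2 - 1) / n) / beta
}
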