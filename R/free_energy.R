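#' Discard equilibration samples from a series
#'
#' @param series [sample_series()] tibble.
#' @param t_eq_ps Samples with `time_ps < t_eq_ps` are removed.
#' @return The retained series; an error if nothing remains.
#' @export
discard_equilibration <- function(series, t_eq_ps) {
  stopifnot(t_eq_ps >= 0)
  keep <- series$time_ps >= t_eq_ps
  if (!any(keep)) {
    abort(sprintf("no samples remain after discarding t < %g ps", t_eq_ps))
  }
  out <- series[keep, , drop = FALSE]
  attr(out, "unit") <- attr(series, "unit")
  out
}

#' Forward/backward work samples
#'
#' Container for Bennett-acceptance-ratio input: work values of the forward
#' perturbation and of the reverse perturbation (each in the direction of
#' its own switching), plus the inverse temperature beta. With the default
#' unit and temperature (300 K, kJ/mol), beta is 1/(kB T); pass `beta`
#' directly for reduced-unit work.
#'
#' @param forward,backward Numeric work samples, one per switching
#'   realisation.
#' @param beta Inverse temperature in the work unit; overrides
#'   `temperature_K`.
#' @param temperature_K Temperature used to derive beta from the unit.
#' @param unit `"kJ/mol"`, `"kcal/mol"` or `"reduced"` (beta = 1).
#' @return Object of class `work_set`.
#' @export
work_set <- function(forward, backward, beta = NULL, temperature_K = 300,
                     unit = c("kJ/mol", "kcal/mol", "reduced")) {
  unit <- match.arg(unit)
  forward <- as.numeric(forward)
  backward <- as.numeric(backward)
  if (length(forward) == 0 || length(backward) == 0) {
    abort("both forward and backward work samples are required")
  }
  if (any(!is.finite(forward)) || any(!is.finite(backward))) {
    abort("work samples must be finite")
  }
  if (is.null(beta)) {
    beta <- switch(unit,
      "kJ/mol" = 1 / (KB_KJ * temperature_K),
      "kcal/mol" = 1 / (KB_KCAL * temperature_K),
      "reduced" = 1
    )
  }
  structure(
    list(forward = forward, backward = backward, beta = beta, unit = unit),
    class = "work_set"
  )
}

#' Free-energy estimate container
#'
#' @param delta_g Estimated free-energy difference.
#' @param uncertainty Non-negative uncertainty (`NA` when not computed).
#' @param method `"BAR"` or `"TI"`.
#' @param unit Energy unit tag.
#' @param details Optional list of method-specific diagnostics.
#' @return Object of class `fe_estimate`.
#' @export
fe_estimate <- function(delta_g, uncertainty = NA_real_,
                        method = c("BAR", "TI"), unit = "kJ/mol",
                        details = list()) {
  method <- match.arg(method)
  if (!is.na(uncertainty) && uncertainty < 0) {
    abort("uncertainty must be non-negative")
  }
  structure(
    list(delta_g = delta_g, uncertainty = uncertainty, method = method,
         unit = unit, details = details),
    class = "fe_estimate"
  )
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: dG = %.6g +/- %.3g %s\n",
              x$method, x$delta_g, x$uncertainty, x$unit))
  invisible(x)
}

#' @export
tidy.fe_estimate <- function(x, ...) {
  tibble(method = x$method, delta_g = x$delta_g,
         uncertainty = x$uncertainty, unit = x$unit)
}

#' @export
glance.fe_estimate <- function(x, ...) tidy(x)

# Bennett self-consistency residual at a trial dF:
#   sum_F fermi(beta*(M + W_F - dF)) - sum_R fermi(beta*(-M + W_R + dF))
# with M = log(n_F/n_R)/beta and fermi(x) = 1/(1+exp(x)).
.bar_residual <- function(d_f, wf, wr, beta, m) {
  sum(stats::plogis(-beta * (m + wf - d_f))) -
    sum(stats::plogis(-beta * (-m + wr + d_f)))
}

#' Bennett-acceptance-ratio free-energy estimate
#'
#' Solves the Bennett self-consistency equation for the free-energy
#' difference by bisection on a bracket expanded geometrically from the
#' work-based initial guess, to a residual below `tol`. The reported
#' uncertainty is the asymptotic standard error from Bennett's variance
#' expression evaluated at the solution.
#'
#' @param ws [work_set()].
#' @param tol Absolute tolerance on the (sample-averaged) residual.
#' @return [fe_estimate()] with method `"BAR"`; the details carry the
#'   sample sizes and the residual at the solution.
#' @export
bar_estimate <- function(ws, tol = 1e-10) {
  stopifnot(inherits(ws, "work_set"))
  wf <- ws$forward
  wr <- ws$backward
  beta <- ws$beta
  nf <- length(wf)
  nr <- length(wr)
  m <- log(nf / nr) / beta

  # the self-consistency residual is monotone and always has a root, but
  # with disjoint forward / negated-backward work supports that root is
  # statistically meaningless: refuse with an overlap diagnostic
  overlap <- min(max(wf), max(-wr)) - max(min(wf), min(-wr))
  if (overlap < 0) {
    abort(sprintf(
      paste0("forward and backward work distributions do not overlap ",
             "(gap of %.3g between supports); BAR cannot converge"),
      -overlap
    ))
  }

  mid <- (mean(wf) - mean(wr)) / 2
  span <- max(1, stats::sd(c(wf, -wr)))
  lo <- mid - span
  hi <- mid + span
  r_lo <- .bar_residual(lo, wf, wr, beta, m)
  r_hi <- .bar_residual(hi, wf, wr, beta, m)
  tries <- 0
  # residual is increasing in d_f: expand until it brackets zero
  while (r_lo * r_hi > 0 && tries < 200) {
    span <- span * 2
    lo <- mid - span
    hi <- mid + span
    r_lo <- .bar_residual(lo, wf, wr, beta, m)
    r_hi <- .bar_residual(hi, wf, wr, beta, m)
    tries <- tries + 1
  }
  if (r_lo * r_hi > 0) {
    overlap <- min(max(wf), max(-wr)) - max(min(wf), min(-wr))
    abort(sprintf(
      paste0("BAR failed to bracket a root: forward and backward work ",
             "distributions do not overlap (overlap span %.3g)"), overlap
    ))
  }
  for (i in 1:500) {
    mid <- (lo + hi) / 2
    r_mid <- .bar_residual(mid, wf, wr, beta, m)
    if (abs(r_mid) < tol * (nf + nr) || (hi - lo) < 1e-14 * max(1, abs(mid))) {
      break
    }
    if (r_mid > 0) hi <- mid else lo <- mid
  }
  d_f <- mid

  # Bennett (1976) asymptotic variance from the Fermi weights at the root
  ff <- stats::plogis(-beta * (m + wf - d_f))
  fr <- stats::plogis(-beta * (-m + wr + d_f))
  var_beta_df <- (mean(ff^2) / mean(ff)^2 - 1) / nf +
    (mean(fr^2) / mean(fr)^2 - 1) / nr
  fe_estimate(
    delta_g = d_f,
    uncertainty = sqrt(max(var_beta_df, 0)) / beta,
    method = "BAR", unit = ws$unit,
    details = list(n_forward = nf, n_backward = nr,
                   residual = .bar_residual(d_f, wf, wr, beta, m))
  )
}

#' Per-window dH/dlambda samples for thermodynamic integration
#'
#' @param lambda_values Coupling-parameter grid in `[0, 1]`, strictly
#'   increasing (the alchemical protocols this mirrors use 85 windows).
#' @param dhdl_samples List of [sample_series()] (or bare numeric vectors),
#'   one per window.
#' @param unit Energy unit tag.
#' @return Object of class `lambda_series`.
#' @export
lambda_series <- function(lambda_values, dhdl_samples, unit = "kJ/mol") {
  lambda_values <- as.numeric(lambda_values)
  if (length(lambda_values) == 0) abort("empty lambda grid")
  if (any(lambda_values < 0 | lambda_values > 1)) {
    abort("lambda values must lie in [0, 1]")
  }
  if (any(diff(lambda_values) <= 0)) {
    abort("lambda grid must be strictly increasing")
  }
  if (length(dhdl_samples) != length(lambda_values)) {
    abort("one sample series per lambda window is required")
  }
  dhdl_samples <- purrr::map(dhdl_samples, function(s) {
    if (is.data.frame(s)) s else sample_series(seq_along(s) - 1, s, unit)
  })
  structure(
    list(lambda = lambda_values, dhdl = dhdl_samples, unit = unit),
    class = "lambda_series"
  )
}

#' Thermodynamic-integration estimate
#'
#' Discards the per-window equilibration time, averages dH/dlambda within
#' each window, and integrates the mean profile over lambda with the
#' trapezoidal rule (exact for affine profiles on any grid).
#'
#' @param ls [lambda_series()].
#' @param t_eq_ps Equilibration time discarded per window, ps.
#' @return [fe_estimate()] with method `"TI"`; the details carry the
#'   per-window means.
#' @export
ti_integrate <- function(ls, t_eq_ps = 0) {
  stopifnot(inherits(ls, "lambda_series"))
  if (length(ls$lambda) < 2) abort("TI requires at least 2 windows")
  means <- vapply(ls$dhdl, function(s) {
    mean(discard_equilibration(s, t_eq_ps)$value)
  }, numeric(1))
  fe_estimate(
    delta_g = pracma::trapz(ls$lambda, means),
    method = "TI", unit = ls$unit,
    details = list(window_means = means, lambda = ls$lambda)
  )
}

#' Two-point forward/backward standard deviation
#'
#' The spread of two estimates of the same free-energy difference obtained
#' from the forward and the backward switching direction: the sample
#' standard deviation of the pair, equal to |difference| / sqrt(2).
#'
#' @param estimate_fwd,estimate_bwd Numeric values or [fe_estimate()]s.
#' @return Non-negative standard deviation, symmetric in its arguments.
#' @export
forward_backward_sd <- function(estimate_fwd, estimate_bwd) {
  val <- function(x) if (inherits(x, "fe_estimate")) x$delta_g else as.numeric(x)
  sd(c(val(estimate_fwd), val(estimate_bwd)))
}

#' Time-slice convergence check
#'
#' Re-runs an estimator on sub-intervals of the per-window sampling time
#' and reports the per-slice estimates — agreeing slices indicate a
#' converged, stationary calculation. The default slices are the full
#' production interval and its two halves (100-500, 100-300 and 300-500 ps
#' of a 500 ps window).
#'
#' @param ls [lambda_series()] (sliced per window on `time_ps`), or a
#'   function `(t_lo, t_hi) -> fe_estimate` for custom estimators.
#' @param slice_windows List of `(t_lo, t_hi)` ps pairs; samples with
#'   `t_lo <= time_ps <= t_hi` enter a slice.
#' @return Tibble with `t_lo`, `t_hi`, `delta_g`, `uncertainty`, `error`
#'   (`NA` for successful slices; failed slices report the message and
#'   leave the others intact).
#' @export
slice_convergence <- function(ls,
                              slice_windows = list(
                                c(100, 500), c(100, 300), c(300, 500)
                              )) {
  run_slice <- function(t_lo, t_hi) {
    if (is.function(ls)) return(ls(t_lo, t_hi))
    sliced <- purrr::map(ls$dhdl, function(s) {
      keep <- s$time_ps >= t_lo & s$time_ps <= t_hi
      if (!any(keep)) abort(sprintf("empty slice %g-%g ps", t_lo, t_hi))
      sample_series(s$time_ps[keep], s$value[keep], unit = ls$unit)
    })
    ti_integrate(lambda_series(ls$lambda, sliced, unit = ls$unit))
  }
  purrr::map_dfr(slice_windows, function(w) {
    est <- tryCatch(run_slice(w[[1]], w[[2]]), error = identity)
    if (inherits(est, "error")) {
      tibble(t_lo = w[[1]], t_hi = w[[2]], delta_g = NA_real_,
             uncertainty = NA_real_, error = conditionMessage(est))
    } else {
      tibble(t_lo = w[[1]], t_hi = w[[2]], delta_g = est$delta_g,
             uncertainty = est$uncertainty, error = NA_character_)
    }
  })
}

#' Snapshot subsampling on a stride grid
#'
#' Selects frame indices starting at the first frame with time at or after
#' `start_ps` and then greedily every `stride_ps` — the schedule used to
#' thin a production trajectory for snapshot-based post-processing (e.g.
#' 900 snapshots of 90 ns at a 100 ps stride after a 10 ns equilibration).
#'
#' @param trajectory Trajectory tibble, or a numeric vector of frame times
#'   (ps).
#' @param start_ps First eligible time, ps.
#' @param stride_ps Stride between retained snapshots, ps (> 0).
#' @return Strictly increasing integer frame indices (possibly empty).
#' @export
subsample_snapshots <- function(trajectory, start_ps, stride_ps) {
  stopifnot(stride_ps > 0)
  times <- if (is.data.frame(trajectory)) {
    ft <- unique(trajectory[, c("frame", "time_ps")])
    ft$time_ps[order(ft$frame)]
  } else {
    as.numeric(trajectory)
  }
  idx <- integer(0)
  next_t <- start_ps
  for (i in seq_along(times)) {
    if (times[[i]] >= next_t - 1e-9) {
      idx <- c(idx, i)
      next_t <- times[[i]] + stride_ps
    }
  }
  idx
}
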