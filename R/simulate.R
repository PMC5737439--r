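#' Run the kinetic Monte-Carlo simulation
#'
#' Exact continuous-time (Gillespie) simulation of the motor-roadblock
#' lattice gas. Open mode starts from an empty lattice (or `init`);
#' periodic mode starts from `n_motors` evenly spaced motors. Snapshots of
#' the full lattice are recorded every `dt_sample` seconds after `burn_in`,
#' and per-site occupancy/stepping accumulators are collected over the same
#' window (these feed [estimate_profiles()]).
#'
#' @param params a [model_params()] object.
#' @param t_max total simulated time, s.
#' @param dt_sample snapshot interval, s.
#' @param burn_in time discarded before sampling, s. Defaults to
#'   `5 * L / k_tp` (several transit times) in open mode and `10 * L / k_ip`
#'   site-updates-per-motor worth of relaxation in periodic mode.
#' @param seed RNG seed (integer); falls back to `params$seed`. Identical
#'   seeds give identical event logs.
#' @param record_events keep the full time-ordered event log (can be large
#'   for long runs; snapshots and accumulators are always kept).
#' @param init optional [lattice_state()] to start from.
#' @param max_events safety cap on KMC iterations.
#' @return an object of class `peloton_traj`: a list with `params`,
#'   `events` (tibble or `NULL`), `snapshots` (tibble: time, kind,
#'   position), `snapshot_times`, `site_stats` (tibble: x, motor_time,
#'   rb_time, front_time, steps), `initiation_times`, `termination_times`,
#'   `final_state`, and the run controls.
#' @examples
#' p <- model_params(k_ip = 2, k_tp = 0.5, k_b = 0.5, L = 20,
#'                   boundary = "periodic", n_motors = 2)
#' tr <- simulate_traffic(p, t_max = 50, dt_sample = 1, burn_in = 5, seed = 1)
#' tr
#' @export
simulate_traffic <- function(params, t_max, dt_sample = 1, burn_in = NULL,
                             seed = NULL, record_events = TRUE, init = NULL,
                             max_events = 5e8) {
  validate_params(params)
  p <- params
  if (is.null(burn_in)) {
    burn_in <- if (p$boundary == "open") 5 * p$L / p$k_tp else 10 * p$L / p$k_ip
  }
  if (t_max <= burn_in) abort("t_max must exceed burn_in")
  if (dt_sample <= 0) abort("dt_sample must be > 0")
  seed <- if (!is.null(seed)) seed else p$seed
  if (!is.null(seed)) set.seed(as.integer(seed))

  open <- p$boundary == "open"
  if (is.null(init)) {
    motors0 <- if (open) integer() else {
      n <- p$n_motors
      if (n > 0) as.integer(floor(seq(0, p$L - 1, length.out = n + 1)[seq_len(n)])) else integer()
    }
    rbs0 <- integer()
  } else {
    validate_lattice_state(init, p)
    motors0 <- init$motors
    rbs0 <- init$roadblocks
  }
  if (!open && length(motors0) != (p$n_motors %||% length(motors0)))
    abort("initial state must carry n_motors motors in periodic mode")

  raw <- run_kmc(
    p$delta_m, p$delta_rb, p$k_ip, p$k_tp,
    if (p$interaction == "dyad") dyad_rate(p) else p$k_tp,
    if (open) p$k_in else 0, p$k_b, p$L, open,
    switch(p$eviction, contact = 0L, traversal = 1L, dyad = 2L),
    motors0, rbs0, t_max, dt_sample, burn_in,
    record_events, TRUE, max_events
  )

  kind_levels <- c("step", "initiate", "terminate", "bind")
  events <- if (record_events) {
    tibble(time = raw$ev_time,
           kind = factor(kind_levels[raw$ev_kind], levels = kind_levels),
           position = raw$ev_pos)
  } else NULL
  snapshots <- tibble(time = raw$sn_time,
                      kind = factor(c("motor", "roadblock")[raw$sn_kind],
                                    levels = c("motor", "roadblock")),
                      position = raw$sn_pos)
  site_stats <- tibble(x = 0:(p$L - 1L),
                       motor_time = raw$motor_time, rb_time = raw$rb_time,
                       front_time = raw$front_time, steps = raw$steps_from)
  out <- list(
    params = p, events = events, snapshots = snapshots,
    snapshot_times = raw$snap_times, site_stats = site_stats,
    initiation_times = raw$initiation_times,
    termination_times = raw$termination_times,
    final_state = lattice_state(raw$final_motors, raw$final_roadblocks, raw$t_end),
    t_max = t_max, burn_in = burn_in, dt_sample = dt_sample,
    seed = seed, n_events = raw$n_events
  )
  class(out) <- "peloton_traj"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.peloton_traj <- function(x, ...) {
  cat(sprintf("<peloton_traj> %s lattice, L = %d, t_max = %g s (%0.0f events)\n",
              x$params$boundary, x$params$L, x$t_max, x$n_events))
  cat(sprintf("  %d snapshots every %g s after burn-in %g s\n",
              length(x$snapshot_times), x$dt_sample, x$burn_in))
  cat(sprintf("  %d initiations, %d terminations\n",
              length(x$initiation_times), length(x$termination_times)))
  invisible(x)
}

#' Extract one snapshot as a `lattice_state`
#'
#' @param traj a `peloton_traj`.
#' @param which snapshot index (1-based) into `traj$snapshot_times`.
#' @return a [lattice_state()].
#' @export
snapshot_state <- function(traj, which = 1L) {
  ts <- traj$snapshot_times
  if (which < 1L || which > length(ts)) abort("snapshot index out of range")
  sn <- dplyr::filter(traj$snapshots, .data$time == ts[which])
  lattice_state(motors = sort(sn$position[sn$kind == "motor"]),
                roadblocks = sn$position[sn$kind == "roadblock"],
                time = ts[which])
}

#' Rasterize a trajectory into a kymograph
#'
#' Deterministic rasterization of snapshots onto a (time bin, lattice site)
#' matrix with occupancy codes 0 = empty, 1 = roadblock, 2 = motor; the
#' motor symbol takes precedence on shared bins.
#'
#' @param traj a `peloton_traj`.
#' @param t0,t1 time range, s; defaults to the sampled range.
#' @param dt_bin time bin width, s; defaults to `traj$dt_sample`.
#' @return an object of class `peloton_kymo`: list with the integer
#'   `matrix` (n_bins x L) and bin metadata.
#' @export
as_kymograph <- function(traj, t0 = NULL, t1 = NULL, dt_bin = NULL) {
  ts <- traj$snapshot_times
  if (!length(ts)) abort("trajectory has no snapshots")
  t0 <- t0 %||% min(ts)
  t1 <- t1 %||% max(ts)
  dt_bin <- dt_bin %||% traj$dt_sample
  if (t0 >= t1) abort("need t0 < t1")
  if (t0 < min(ts) - 1e-9 || t1 > max(ts) + 1e-9)
    abort("requested range lies outside the sampled trajectory")
  p <- traj$params
  n_bins <- max(1L, as.integer(ceiling((t1 - t0) / dt_bin)))
  mat <- matrix(0L, nrow = n_bins, ncol = p$L)
  sn <- dplyr::filter(traj$snapshots, .data$time >= t0, .data$time <= t1)
  periodic <- p$boundary == "periodic"
  fill <- function(df, w, code) {
    if (!nrow(df)) return()
    bins <- pmin(n_bins, floor((df$time - t0) / dt_bin) + 1L)
    rows <- rep(bins, each = w)
    sites <- as.vector(vapply(df$position,
                              function(q) covered_sites(q, w, p$L, periodic),
                              integer(w)))
    mat[cbind(rows, sites + 1L)] <<- code
  }
  fill(sn[sn$kind == "roadblock", ], p$delta_rb, 1L)
  fill(sn[sn$kind == "motor", ], p$delta_m, 2L)
  structure(list(matrix = mat, t0 = t0, t1 = t1, dt_bin = dt_bin, L = p$L),
            class = "peloton_kymo")
}

#' @export
print.peloton_kymo <- function(x, ...) {
  cat(sprintf("<peloton_kymo> %d time bins x %d sites, t in [%g, %g] s, dt = %g s\n",
              nrow(x$matrix), x$L, x$t0, x$t1, x$dt_bin))
  invisible(x)
}

#' Plot a kymograph
#'
#' Motors are drawn in black and roadblocks in pink over a white background,
#' with position running horizontally and time downwards.
#'
#' @param object a `peloton_kymo`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.peloton_kymo <- function(object, ...) {
  df <- tibble(
    time = object$t0 + (rep(seq_len(nrow(object$matrix)), times = ncol(object$matrix)) - 0.5) * object$dt_bin,
    x = rep(seq_len(ncol(object$matrix)) - 1L, each = nrow(object$matrix)),
    code = factor(as.vector(object$matrix), levels = c(0, 1, 2),
                  labels = c("empty", "roadblock", "motor"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$time, fill = .data$code)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(empty = "white", roadblock = "#f4a6b8",
                                          motor = "black"), name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (bp)", y = "time (s)") +
    ggplot2::theme_minimal()
}
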