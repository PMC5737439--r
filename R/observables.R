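#' Motor-motor gaps in a snapshot
#'
#' The gap between consecutive motors is the number of sites strictly
#' between the front of the trailing motor and the left edge of the
#' leading motor. Gaps are classified `intra`-peloton when no roadblock
#' interaction site lies in the gap (uniform interaction: no roadblock
#' footprint overlaps the gap; dyad interaction: no intact dyad in the
#' gap) and `trans` otherwise. Periodic lattices contribute the cyclic
#' wrap gap as well.
#'
#' @param state a [lattice_state()].
#' @param params a [model_params()].
#' @return a tibble with columns `gap` (sites), `n_rb`, `type`
#'   (`"intra"`/`"trans"`), ordered by the trailing motor.
#' @export
gap_sizes <- function(state, params) {
  p <- params
  periodic <- p$boundary == "periodic"
  m <- sort(state$motors)
  n <- length(m)
  empty <- tibble(gap = integer(), n_rb = integer(),
                  type = factor(character(), levels = c("intra", "trans")))
  if (n == 0L || (!periodic && n < 2L)) return(empty)
  q <- sort(state$roadblocks)
  count_rb <- function(lo, hi) {
    # roadblock interaction sites within [lo, hi] (unwrapped coordinates)
    if (lo > hi || !length(q)) return(0L)
    if (p$interaction == "uniform") {
      qq <- c(q, if (periodic) q + p$L)
      sum(qq <= hi & qq + p$delta_rb - 1L >= lo)
    } else {
      d <- (q + dyad_offset(p)) %% if (periodic) p$L else .Machine$integer.max
      dd <- c(d, if (periodic) d + p$L)
      sum(dd >= lo & dd <= hi)
    }
  }
  trail <- m
  lead <- if (periodic) c(m[-1], m[1] + p$L) else m[-1]
  if (!periodic) trail <- m[-n]
  if (periodic && n == 1L) { trail <- m; lead <- m + p$L }
  gaps <- lead - trail - p$delta_m
  nrb <- mapply(function(a, b) count_rb(a + p$delta_m, b - 1L), trail, lead)
  tibble(gap = as.integer(gaps), n_rb = as.integer(nrb),
         type = factor(ifelse(nrb > 0, "trans", "intra"),
                       levels = c("intra", "trans")))
}

#' Pool gaps over all snapshots of a trajectory
#'
#' @param traj a `peloton_traj`.
#' @param params parameters; defaults to `traj$params`.
#' @return a tibble with columns `time`, `gap`, `n_rb`, `type`.
#' @export
gap_table <- function(traj, params = traj$params) {
  purrr::map_dfr(seq_along(traj$snapshot_times), function(i) {
    st <- snapshot_state(traj, i)
    g <- gap_sizes(st, params)
    if (nrow(g)) g$time <- st$time
    g
  })
}

#' Partition the motors of a snapshot into pelotons
#'
#' A peloton is a maximal group of motors with no interspersing roadblock
#' interaction site: consecutive motors whose gap is `intra` per
#' [gap_sizes()] belong to the same peloton. On a periodic lattice the
#' partition is cyclic (all motors form one peloton if every gap is intra).
#'
#' @inheritParams gap_sizes
#' @return a tibble with one row per peloton: `peloton`, `size`,
#'   `trail_position`, `lead_position`.
#' @export
identify_pelotons <- function(state, params) {
  p <- params
  periodic <- p$boundary == "periodic"
  m <- sort(state$motors)
  n <- length(m)
  if (n == 0L) {
    return(tibble(peloton = integer(), size = integer(),
                  trail_position = integer(), lead_position = integer()))
  }
  if (n == 1L) {
    return(tibble(peloton = 1L, size = 1L, trail_position = m, lead_position = m))
  }
  g <- gap_sizes(state, params)
  inner <- g$type[seq_len(n - 1L)] == "trans"   # break after motor i?
  id <- cumsum(c(1L, as.integer(inner)))
  out <- tibble(position = m, id = id) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(size = dplyr::n(),
                     trail_position = min(.data$position),
                     lead_position = max(.data$position), .groups = "drop")
  if (periodic && nrow(out) > 1L && g$type[n] == "intra") {
    # wrap gap joins the last run to the first
    first <- out[1, ]; last <- out[nrow(out), ]
    merged <- tibble(id = first$id,
                     size = first$size + last$size,
                     trail_position = last$trail_position,
                     lead_position = first$lead_position)
    out <- dplyr::bind_rows(merged, out[-c(1, nrow(out)), ])
  }
  out$peloton <- seq_len(nrow(out))
  dplyr::select(out, "peloton", "size", "trail_position", "lead_position")
}

#' Peloton statistics over a trajectory
#'
#' Identifies pelotons in every snapshot and summarises their sizes.
#' `x_min`/`x_max` restrict to pelotons lying entirely within a positional
#' window (e.g. beyond the formation region but clear of the termination
#' site, where exiting pelotons are counted only partially).
#'
#' @param traj a `peloton_traj`.
#' @param params parameters; defaults to `traj$params`.
#' @param x_min,x_max positional window applied to
#'   `trail_position`/`lead_position`.
#' @return an object of class `peloton_stats`: list with `pelotons`
#'   (tibble: time, peloton, size, trail_position, lead_position),
#'   `mean_size`, `n_snapshots`.
#' @export
peloton_stats <- function(traj, params = traj$params, x_min = 0, x_max = Inf) {
  pel <- purrr::map_dfr(seq_along(traj$snapshot_times), function(i) {
    st <- snapshot_state(traj, i)
    out <- identify_pelotons(st, params)
    if (nrow(out)) out$time <- st$time
    out
  })
  if (nrow(pel)) {
    pel <- dplyr::filter(pel, .data$trail_position >= x_min,
                         .data$lead_position <= x_max)
  }
  structure(list(pelotons = pel,
                 mean_size = if (nrow(pel)) mean(pel$size) else NA_real_,
                 n_snapshots = length(traj$snapshot_times)),
            class = "peloton_stats")
}

#' @export
print.peloton_stats <- function(x, ...) {
  cat(sprintf("<peloton_stats> %d pelotons over %d snapshots, mean size %.3g\n",
              nrow(x$pelotons), x$n_snapshots, x$mean_size))
  invisible(x)
}

#' Fit geometric models to a sample of gap sizes
#'
#' Maximum-likelihood single geometric (support 0, 1, 2, ...) and
#' two-component geometric mixture, the latter by EM over a deterministic
#' grid of starting points built from the sample quantiles. Model choice
#' is reported via BIC but not enforced: in the TASEP limits a single
#' geometric describes the gaps; in the peloton regime the intra-/
#' trans-peloton mixture is preferred. Component 1 is the intra-peloton
#' (small-gap, large `p`) component.
#'
#' @param gaps integer vector of gaps (>= 0).
#' @param max_iter,tol EM controls.
#' @return an object of class `gap_fit`; see [tidy()] and [glance()]
#'   methods.
#' @export
fit_gap_distribution <- function(gaps, max_iter = 500L, tol = 1e-9) {
  g <- as.numeric(gaps)
  if (!length(g)) abort("no gaps to fit")
  if (any(g < 0)) abort("gaps must be >= 0")
  n <- length(g)
  geom_ll <- function(p) sum(log(p) + g * log1p(-p))
  p_single <- 1 / (1 + mean(g))
  ll_s <- if (p_single < 1) geom_ll(p_single) else 0  # all gaps 0: point mass
  single <- list(p = p_single, loglik = ll_s, bic = -2 * ll_s + log(n))

  degenerate <- var(g) == 0
  mixture <- NULL
  if (!degenerate) {
    med <- stats::median(g)
    lo <- g[g <= med]; hi <- g[g > med]
    if (!length(hi)) hi <- max(g)
    means <- list(c(mean(lo), mean(hi)),
                  c(quantile(g, 0.25), quantile(g, 0.9)))
    starts <- list()
    for (mm in means) for (w in c(0.3, 0.5, 0.7)) {
      starts[[length(starts) + 1]] <- list(
        w = w,
        p1 = min(1 - 1e-9, 1 / (1 + max(mm[1], 1e-9))),
        p2 = min(1 - 1e-9, 1 / (1 + max(mm[2], 1e-9))))
    }
    run_em <- function(s) {
      w <- s$w; p1 <- s$p1; p2 <- s$p2
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        l1 <- log(w) + log(p1) + g * log1p(-p1)
        l2 <- log1p(-w) + log(p2) + g * log1p(-p2)
        mx <- pmax(l1, l2)
        den <- mx + log(exp(l1 - mx) + exp(l2 - mx))
        r <- exp(l1 - den)
        w <- mean(r)
        if (w < 1e-12 || w > 1 - 1e-12) break
        p1 <- sum(r) / sum(r * (1 + g))
        p2 <- sum(1 - r) / sum((1 - r) * (1 + g))
        p1 <- min(max(p1, 1e-12), 1 - 1e-12)
        p2 <- min(max(p2, 1e-12), 1 - 1e-12)
        ll <- sum(den)
        if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
        ll_old <- ll
      }
      l1 <- log(w) + log(p1) + g * log1p(-p1)
      l2 <- log1p(-w) + log(p2) + g * log1p(-p2)
      mx <- pmax(l1, l2)
      list(w = w, p1 = p1, p2 = p2, loglik = sum(mx + log(exp(l1 - mx) + exp(l2 - mx))))
    }
    fits <- lapply(starts, run_em)
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    if (best$p1 < best$p2) {  # component 1 = intra (larger p, smaller gaps)
      best <- list(w = 1 - best$w, p1 = best$p2, p2 = best$p1, loglik = best$loglik)
    }
    if (abs(best$p1 - best$p2) < 1e-6) degenerate <- TRUE
    mixture <- list(w = best$w, p1 = best$p1, p2 = best$p2,
                    loglik = best$loglik, bic = -2 * best$loglik + 3 * log(n))
  }
  preferred <- if (is.null(mixture) || degenerate) "single" else {
    if (mixture$bic < single$bic) "mixture" else "single"
  }
  hist <- dplyr::count(tibble(gap = as.integer(g)), .data$gap, name = "count")
  structure(list(n = n, histogram = hist, single = single, mixture = mixture,
                 preferred = preferred, degenerate = degenerate),
            class = "gap_fit")
}

#' @export
print.gap_fit <- function(x, ...) {
  cat(sprintf("<gap_fit> n = %d gaps, preferred: %s%s\n", x$n, x$preferred,
              if (x$degenerate) " (degenerate)" else ""))
  cat(sprintf("  single:  p = %.4g (BIC %.1f)\n", x$single$p, x$single$bic))
  if (!is.null(x$mixture)) {
    cat(sprintf("  mixture: w = %.3g, p_intra = %.4g, p_trans = %.4g (BIC %.1f)\n",
                x$mixture$w, x$mixture$p1, x$mixture$p2, x$mixture$bic))
  }
  invisible(x)
}

#' @export
tidy.gap_fit <- function(x, ...) {
  out <- tibble(model = "single", component = "all", weight = 1,
                p = x$single$p, mean_gap = 1 / x$single$p - 1)
  if (!is.null(x$mixture)) {
    out <- dplyr::bind_rows(out, tibble(
      model = "mixture", component = c("intra", "trans"),
      weight = c(x$mixture$w, 1 - x$mixture$w),
      p = c(x$mixture$p1, x$mixture$p2),
      mean_gap = 1 / c(x$mixture$p1, x$mixture$p2) - 1))
  }
  out
}

#' @export
glance.gap_fit <- function(x, ...) {
  tibble(n = x$n,
         loglik_single = x$single$loglik, bic_single = x$single$bic,
         loglik_mixture = if (is.null(x$mixture)) NA_real_ else x$mixture$loglik,
         bic_mixture = if (is.null(x$mixture)) NA_real_ else x$mixture$bic,
         preferred = x$preferred, degenerate = x$degenerate)
}

#' Plot a gap-size distribution fit
#'
#' @param object a `gap_fit`.
#' @param ... unused.
#' @return a ggplot object (log-scaled counts with fitted geometric pmfs).
#' @export
autoplot.gap_fit <- function(object, ...) {
  h <- object$histogram
  h$freq <- h$count / object$n
  xs <- 0:max(h$gap)
  fit <- tibble(gap = xs, model = "single",
                pmf = object$single$p * (1 - object$single$p)^xs)
  if (!is.null(object$mixture)) {
    m <- object$mixture
    fit <- dplyr::bind_rows(fit, tibble(
      gap = xs, model = "mixture",
      pmf = m$w * m$p1 * (1 - m$p1)^xs + (1 - m$w) * m$p2 * (1 - m$p2)^xs))
  }
  ggplot2::ggplot(h, ggplot2::aes(x = .data$gap, y = .data$freq)) +
    ggplot2::geom_point(colour = "darkgreen") +
    ggplot2::geom_line(data = fit,
                       ggplot2::aes(y = .data$pmf, colour = .data$model)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gap size (sites)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Position-resolved density and velocity profiles
#'
#' Time-averaged, footprint-aware per-site occupancies of motors and
#' roadblocks (a site counts as occupied when covered by any part of a
#' footprint), and the local motor velocity estimated as realized steps
#' per unit motor-front occupancy time -- robust at low density, unlike
#' displacement differencing. Densities can alternatively be recounted
#' from the stored snapshots (`source = "snapshots"`), which must agree
#' with the event-based accumulators.
#'
#' @param traj a `peloton_traj`.
#' @param bin aggregation width in sites.
#' @param smooth optional centred moving-average window (sites, applied
#'   after binning); the paper-scale convention is one roadblock footprint.
#' @param source `"events"` (per-site accumulators, default) or
#'   `"snapshots"` (recount of coverage from snapshots; velocity still
#'   comes from the accumulators).
#' @return a tibble with columns `x` (bin left edge), `rho_m`, `rho_rb`
#'   (occupancy probability per site), `v_m` (sites/s).
#' @export
estimate_profiles <- function(traj, bin = 1L, smooth = NULL,
                              source = c("events", "snapshots")) {
  source <- match.arg(source)
  p <- traj$params
  T_obs <- traj$t_max - traj$burn_in
  ss <- traj$site_stats
  if (source == "events") {
    rho_m <- ss$motor_time / T_obs
    rho_rb <- ss$rb_time / T_obs
  } else {
    d <- density_from_snapshots(traj)
    rho_m <- d$rho_m
    rho_rb <- d$rho_rb
  }
  df <- tibble(x = ss$x, rho_m = rho_m, rho_rb = rho_rb,
               steps = ss$steps, front_time = ss$front_time)
  if (bin > 1L) {
    df <- df |>
      dplyr::mutate(x = (.data$x %/% bin) * bin) |>
      dplyr::group_by(.data$x) |>
      dplyr::summarise(rho_m = mean(.data$rho_m), rho_rb = mean(.data$rho_rb),
                       steps = sum(.data$steps),
                       front_time = sum(.data$front_time), .groups = "drop")
  }
  if (!is.null(smooth) && smooth > 1) {
    w <- as.integer(smooth)
    roll <- function(z) as.numeric(stats::filter(z, rep(1 / w, w), sides = 2))
    df$rho_m <- roll(df$rho_m)
    df$rho_rb <- roll(df$rho_rb)
    df$steps <- roll(df$steps)
    df$front_time <- roll(df$front_time)
  }
  df$v_m <- ifelse(df$front_time > 0, df$steps / df$front_time, NA_real_)
  dplyr::select(df, "x", "rho_m", "rho_rb", "v_m")
}

#' Recount per-site coverage from snapshots
#'
#' @param traj a `peloton_traj`.
#' @return a tibble with `x`, `rho_m`, `rho_rb` (fraction of snapshots in
#'   which the site is covered).
#' @export
density_from_snapshots <- function(traj) {
  p <- traj$params
  periodic <- p$boundary == "periodic"
  ns <- length(traj$snapshot_times)
  if (ns == 0L) abort("trajectory has no snapshots")
  cover_counts <- function(pos, w) {
    if (!length(pos)) return(numeric(p$L))
    sites <- rep(pos, each = w) + rep(0:(w - 1L), times = length(pos))
    if (periodic) sites <- sites %% p$L
    tabulate(sites + 1L, nbins = p$L)
  }
  sn <- traj$snapshots
  tibble(x = 0:(p$L - 1L),
         rho_m = cover_counts(sn$position[sn$kind == "motor"], p$delta_m) / ns,
         rho_rb = cover_counts(sn$position[sn$kind == "roadblock"], p$delta_rb) / ns)
}

#' Fit the exponential relaxation of a profile
#'
#' Least-squares fit of `A - B * exp(-x / x_p)` to a profile column over
#' the peloton-forming region, estimated as the first `4 * x_p_guess`
#' lattice points. Recovers the formation distance `x_p` from simulated
#' density (or velocity) profiles.
#'
#' @param profile a tibble from [estimate_profiles()] (columns `x` and the
#'   response).
#' @param x_p_guess prior guess for the decay length, sites; sets the
#'   fitting window.
#' @param response which column to fit (default `"rho_m"`).
#' @return a one-row tibble: `x_p_hat`, `amplitude` (B), `offset` (A),
#'   `response`.
#' @export
fit_relaxation <- function(profile, x_p_guess, response = "rho_m") {
  stopifnot(response %in% names(profile))
  d <- profile[is.finite(profile[[response]]) & profile$x <= 4 * x_p_guess, ]
  if (nrow(d) < 5L) abort("too few points in the fitting window")
  y <- d[[response]]
  a0 <- mean(tail(y, max(3L, nrow(d) %/% 10L)))
  b0 <- a0 - y[1L]
  if (abs(b0) < 1e-12) b0 <- 1e-6
  fit <- minpack.lm::nlsLM(
    y ~ A - B * exp(-x / xp),
    data = tibble(x = d$x, y = y),
    start = list(A = a0, B = b0, xp = x_p_guess),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  tibble(x_p_hat = unname(cf["xp"]), amplitude = unname(cf["B"]),
         offset = unname(cf["A"]), response = response)
}

#' Windowed burst statistics of an event stream
#'
#' Counts events (typically termination times, i.e. mRNA production
#' events) in fixed windows and reports the Fano factor, the variance to
#' mean ratio of the window counts: 1 for a Poisson stream, > 1 for
#' bursty production.
#'
#' @param times event times, s.
#' @param window window length, s (1 min matches the usual mRNA-counting
#'   convention).
#' @param t_range observation interval `c(t0, t1)`; defaults to the span
#'   of `times`. Only complete windows are used.
#' @return an object of class `burst_series`: list with `counts` (tibble:
#'   t_mid, count), `fano`, `window`, `interarrivals`.
#' @export
burst_statistics <- function(times, window = 60, t_range = NULL) {
  times <- sort(as.numeric(times))
  t_range <- t_range %||% range(times)
  n_win <- floor((t_range[2] - t_range[1]) / window)
  if (n_win < 2) abort("observation range shorter than two windows")
  breaks <- t_range[1] + window * (0:n_win)
  inw <- times[times >= breaks[1] & times < breaks[n_win + 1]]
  counts <- tabulate(findInterval(inw, breaks), nbins = n_win)
  fano <- if (mean(counts) > 0) var(counts) / mean(counts) else NA_real_
  structure(list(
    counts = tibble(t_mid = breaks[-(n_win + 1)] + window / 2, count = counts),
    fano = fano, window = window, interarrivals = diff(times)),
    class = "burst_series")
}

#' @export
print.burst_series <- function(x, ...) {
  cat(sprintf("<burst_series> %d windows of %g s, mean count %.3g, Fano %.3g\n",
              nrow(x$counts), x$window, mean(x$counts$count), x$fano))
  invisible(x)
}

#' Fano factor as a function of window size
#'
#' @param times event times, s.
#' @param windows vector of window lengths, s.
#' @param t_range observation interval; defaults to the span of `times`.
#' @return a tibble with columns `window`, `fano`, `mean_count`.
#' @export
fano_curve <- function(times, windows = c(10, 30, 60, 120, 300), t_range = NULL) {
  purrr::map_dfr(windows, function(w) {
    b <- burst_statistics(times, window = w, t_range = t_range)
    tibble(window = w, fano = b$fano, mean_count = mean(b$counts$count))
  })
}
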