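#' Simulate a two-state (telegraph) promoter
#'
#' Exact simulation of the standard bursty-promoter reference model: the
#' promoter switches off -> on at `k_on` and on -> off at `k_off`;
#' production events fire as a Poisson process at `k_tr` while on.
#' `k_off = 0` gives a pure Poisson stream at `k_tr`.
#'
#' @param k_on,k_off,k_tr switching and production rates, 1/s.
#' @param t_max simulated time, s.
#' @param seed RNG seed.
#' @param state0 initial promoter state, `"off"` or `"on"`.
#' @return sorted numeric vector of production event times, s.
#' @export
simulate_telegraph <- function(k_on, k_off, k_tr, t_max, seed = NULL,
                               state0 = c("off", "on")) {
  state0 <- match.arg(state0)
  if (any(c(k_on, k_off, k_tr) < 0)) abort("rates must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- 0
  on <- state0 == "on"
  events <- list()
  if (k_off == 0) {
    if (!on) {
      if (k_on == 0) return(numeric())
      t <- rexp(1, k_on)
    }
    n <- rpois(1, k_tr * max(0, t_max - t))
    return(sort(t + runif(n) * (t_max - t)))
  }
  while (t < t_max) {
    if (on) {
      len <- rexp(1, k_off)
      hi <- min(t + len, t_max)
      n <- rpois(1, k_tr * (hi - t))
      if (n > 0) events[[length(events) + 1]] <- t + runif(n) * (hi - t)
      t <- t + len
    } else {
      t <- t + if (k_on > 0) rexp(1, k_on) else Inf
    }
    on <- !on
  }
  sort(unlist(events))
}

#' Compare lattice termination bursts with the mapped telegraph model
#'
#' Simulates the two-state model at the burst parameters implied by the
#' peloton theory ([burst_parameters()]) over the same observation span as
#' the lattice termination stream, then compares the two streams through
#' their Fano-vs-window curves and a Kolmogorov-Smirnov test on
#' interarrival times. The mapping is approximate, so distances are
#' reported, not thresholded.
#'
#' @param terminations termination event times from the lattice model, s.
#' @param mapped one-row tibble/list with `k_on`, `k_off`, `k_tr` (1/s).
#' @param t_range observation interval; defaults to the span of
#'   `terminations`.
#' @param seed RNG seed for the telegraph simulation.
#' @param windows Fano windows, s.
#' @return an object of class `burst_comparison`: list with `fano`
#'   (tibble: window, fano_lattice, fano_telegraph), `ks` (statistic and
#'   p-value), `fano_distance` (mean absolute log-ratio), `n_lattice`,
#'   `n_telegraph`.
#' @export
compare_burstiness <- function(terminations, mapped, t_range = NULL,
                               seed = NULL, windows = c(10, 30, 60, 120, 300)) {
  terminations <- sort(as.numeric(terminations))
  t_range <- t_range %||% range(terminations)
  span <- diff(t_range)
  tel <- t_range[1] + simulate_telegraph(mapped$k_on, mapped$k_off, mapped$k_tr,
                                         t_max = span, seed = seed)
  windows <- windows[windows * 2 <= span]
  f1 <- fano_curve(terminations, windows, t_range = t_range)
  f2 <- fano_curve(tel, windows, t_range = t_range)
  fano <- tibble(window = f1$window, fano_lattice = f1$fano,
                 fano_telegraph = f2$fano)
  ks <- suppressWarnings(ks.test(diff(terminations), diff(tel)))
  structure(list(
    fano = fano,
    fano_distance = mean(abs(log(fano$fano_lattice / fano$fano_telegraph)),
                         na.rm = TRUE),
    ks = list(statistic = unname(ks$statistic), p_value = ks$p.value),
    n_lattice = length(terminations), n_telegraph = length(tel)),
    class = "burst_comparison")
}

#' @export
print.burst_comparison <- function(x, ...) {
  cat(sprintf("<burst_comparison> %d lattice vs %d telegraph events\n",
              x$n_lattice, x$n_telegraph))
  print(as.data.frame(x$fano), row.names = FALSE)
  cat(sprintf("  mean |log Fano ratio| = %.3g; KS D = %.3g (p = %.3g)\n",
              x$fano_distance, x$ks$statistic, x$ks$p_value))
  invisible(x)
}
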