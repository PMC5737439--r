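#' Effective roadblock-rebinding time
#'
#' The time a motor needs to clear the roadblock shadow so a roadblock can
#' rebind behind it:
#' \deqn{\tau_\Delta = \tau + \delta_{rb} / k_{tp} = \Delta / k_{tp}}
#' with the shadow \eqn{\Delta = v^{bulk}\tau + \delta_{rb}} and the bulk
#' velocity pinned to `k_tp` once pelotons have formed.
#'
#' @param tau roadblock equilibration time, s.
#' @param delta_rb roadblock footprint, sites.
#' @param k_tp hindered hopping rate, 1/s.
#' @return tau_Delta in seconds.
#' @export
effective_rebinding_time <- function(tau, delta_rb, k_tp) {
  if (k_tp <= 0) abort("k_tp must be > 0")
  if (tau < 0 || delta_rb < 0) abort("tau and delta_rb must be >= 0")
  tau + delta_rb / k_tp
}

#' Roadblock shadow length
#'
#' The roadblock-depleted region trailing every moving motor:
#' \eqn{\Delta = v^{bulk}\tau + \delta_{rb}}. The `v_bulk * tau` term is the
#' distance travelled during the equilibration time; `delta_rb` accounts
#' for the footprint that must be cleared before rebinding.
#'
#' @param v_bulk bulk motor velocity, sites/s.
#' @param tau equilibration time, s.
#' @param delta_rb roadblock footprint, sites.
#' @return shadow length in sites.
#' @export
roadblock_shadow <- function(v_bulk, tau, delta_rb) {
  v_bulk * tau + delta_rb
}

#' Average peloton size on a finite track
#'
#' In the initiation-limited regime, `n_p = 1 + k_in * tau_Delta`: beyond
#' the leading motor, the peloton collects the motors initiated during one
#' effective roadblock-rebinding time.
#'
#' @param k_in initiation rate, 1/s.
#' @param tau_delta effective rebinding time, s ([effective_rebinding_time()]).
#' @return mean peloton size (motors).
#' @export
peloton_size <- function(k_in, tau_delta) {
  if (k_in < 0) abort("k_in must be >= 0")
  1 + k_in * tau_delta
}

#' Peloton formation distance
#'
#' The distance over which initial pelotons form,
#' \deqn{x_p = \frac{1/k_{in}}{1/k_{tp} - 1/k_{ip}}
#'       \frac{1}{\ln(1 + 1/(k_{in}\tau_\Delta))},}
#' i.e. the number of steps a trailing fast motor needs to catch up with
#' the forming peloton ahead.
#'
#' @param k_in initiation rate, 1/s (> 0).
#' @param k_tp,k_ip hindered and unhindered hopping rates, 1/s, `k_ip > k_tp`.
#' @param tau_delta effective rebinding time, s.
#' @return x_p in sites.
#' @export
peloton_formation_distance <- function(k_in, k_tp, k_ip, tau_delta) {
  if (k_in <= 0) abort("k_in must be > 0")
  if (k_ip <= k_tp) abort("need k_ip > k_tp (otherwise motors never catch up)")
  (1 / k_in) / (1 / k_tp - 1 / k_ip) / log(1 + 1 / (k_in * tau_delta))
}

#' Relative density and velocity profiles along the track
#'
#' The motor density, motor velocity and roadblock density relax
#' exponentially towards their post-formation values with the shared decay
#' length `x_p`:
#' \deqn{\rho_m(x)/\rho_m = 1 - \frac{k_{in}\tau_\Delta}{1+k_{in}\tau_\Delta}
#'       (1 - k_{tp}/k_{ip}) e^{-x/x_p}}
#' \deqn{v_m(x)/v_m = 1 + \frac{k_{in}\tau_\Delta}{1+k_{in}\tau_\Delta}
#'       (k_{ip}/k_{tp} - 1) e^{-x/x_p}}
#' \deqn{\rho_{rb}(x)/\rho_{rb} = 1 - \frac{k_{in}\tau_\Delta}
#'       {e^{\delta_{rb}/x_p} + k_{in}\tau_\Delta} e^{-x/x_p}}
#' The absolute velocity is `v_m(x) = v_bulk * (v_m(x)/v_m)` with
#' `v_bulk = k_tp` once pelotons have formed.
#'
#' @param x positions along the track, sites (>= 0).
#' @param params a [model_params()] (uses `k_in`, `k_ip`, `k_tp`,
#'   `delta_rb`, `tau`).
#' @param v_bulk bulk velocity; defaults to `k_tp`.
#' @return a tibble with columns `x`, `rho_m_rel`, `v_m_rel`, `rho_rb_rel`,
#'   `v_m` (absolute, sites/s).
#' @export
relative_profiles <- function(x, params, v_bulk = NULL) {
  p <- params
  if (any(x < 0)) abort("x must be >= 0")
  v_bulk <- v_bulk %||% p$k_tp
  td <- effective_rebinding_time(p$tau, p$delta_rb, p$k_tp)
  xp <- peloton_formation_distance(p$k_in, p$k_tp, p$k_ip, td)
  a <- p$k_in * td / (1 + p$k_in * td)
  e <- exp(-x / xp)
  tibble(
    x = x,
    rho_m_rel = 1 - a * (1 - p$k_tp / p$k_ip) * e,
    v_m_rel = 1 + a * (p$k_ip / p$k_tp - 1) * e,
    rho_rb_rel = 1 - p$k_in * td / (exp(p$delta_rb / xp) + p$k_in * td) * e,
    v_m = v_bulk * (1 + a * (p$k_ip / p$k_tp - 1) * e)
  )
}

#' Two-state (telegraph) burst parameters implied by peloton traffic
#'
#' Pelotons arriving at termination make the production look like a bursty
#' two-state promoter with
#' \deqn{k_{tr} = \frac{k_{in}\tau_\Delta}{1+k_{in}\tau_\Delta}
#'       \frac{k_{tp}}{\delta_m},\quad
#'       k_{off} = \frac{1}{1+k_{in}\tau_\Delta}\frac{k_{tp}}{\delta_m},\quad
#'       k_{on} = 1/\tau_\Delta.}
#' The identity `k_tr + k_off = k_tp / delta_m` holds exactly.
#'
#' @param k_in initiation rate, 1/s.
#' @param tau_delta effective rebinding time, s.
#' @param k_tp hindered hopping rate, 1/s.
#' @param delta_m motor footprint, sites.
#' @return a one-row tibble with columns `k_tr`, `k_off`, `k_on` (1/s).
#' @export
burst_parameters <- function(k_in, tau_delta, k_tp, delta_m) {
  if (tau_delta <= 0) abort("tau_delta must be > 0")
  a <- k_in * tau_delta
  tibble(
    k_tr = a / (1 + a) * k_tp / delta_m,
    k_off = 1 / (1 + a) * k_tp / delta_m,
    k_on = 1 / tau_delta
  )
}

#' Bulk peloton size scale
#'
#' The steady-state peloton size in the bulk (infinite track) scales as
#' `(k_ip/k_tp)^(shadow/2)` -- a proportionality with unknown prefactor.
#' For transcription-scale parameters this is astronomically large, which
#' is why two motors that meet effectively stay together until termination.
#'
#' @param k_ip,k_tp hopping rates, 1/s.
#' @param shadow roadblock shadow, sites ([roadblock_shadow()]).
#' @return dimensionless scale (can overflow to `Inf` for large shadows).
#' @export
bulk_peloton_scale <- function(k_ip, k_tp, shadow) {
  (k_ip / k_tp)^(shadow / 2)
}

#' Analytic predictions for a parameter set
#'
#' Evaluates the closed-form theory in the initiation-limited regime:
#' effective rebinding time, roadblock shadow, peloton size and formation
#' distance, initial and bulk velocities, and the implied two-state burst
#' parameters (quoted per minute, the usual convention for promoter
#' kinetics).
#'
#' @param params a [model_params()].
#' @param v_bulk bulk velocity override; defaults to `k_tp`.
#' @return a tibble with columns `quantity`, `value`, `unit`.
#' @examples
#' predict_observables(params_table1(k_in = "0.6/min"))
#' @export
predict_observables <- function(params, v_bulk = NULL) {
  p <- params
  v_bulk <- v_bulk %||% p$k_tp
  td <- effective_rebinding_time(p$tau, p$delta_rb, p$k_tp)
  bp <- burst_parameters(p$k_in, td, p$k_tp, p$delta_m)
  xp <- if (p$k_in > 0 && p$k_ip > p$k_tp)
    peloton_formation_distance(p$k_in, p$k_tp, p$k_ip, td) else NA_real_
  v0 <- relative_profiles(0, p, v_bulk = v_bulk)$v_m
  tibble(
    quantity = c("tau_delta", "shadow", "n_p", "x_p", "v_m0", "v_m_final",
                 "k_on", "k_tr", "k_off"),
    value = c(td, roadblock_shadow(v_bulk, p$tau, p$delta_rb),
              peloton_size(p$k_in, td), xp, v0, v_bulk,
              bp$k_on * 60, bp$k_tr * 60, bp$k_off * 60),
    unit = c("s", "bp", "pol", "bp", "bp/s", "bp/s",
             "1/min", "1/min", "1/min")
  )
}
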