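#' Deterministic toy fixtures for tests and demonstrations
#'
#' Builds, in memory: (a) hand-constructed lattice states exercising the
#' stepping/eviction rules, (b) a small periodic Bus-Route-Model
#' trajectory, and (c) synthetic geometric and telegraph event samples
#' with known parameters. Everything is generated from `seed`.
#'
#' @param seed RNG seed.
#' @return a named list with elements `states` (list of
#'   [lattice_state()] + matching `model_params`), `brm` (a
#'   `peloton_traj`), `geometric` (list: gaps, p), `telegraph` (list:
#'   times, k_on, k_off, k_tr, t_max).
#' @export
make_fixtures <- function(seed = 1L) {
  states <- list(
    uniform = list(
      params = model_params(delta_m = 1, delta_rb = 1, k_ip = 10, k_tp = 3,
                            k_b = 0.1, L = 20, boundary = "periodic",
                            n_motors = 2),
      state = lattice_state(motors = c(5L, 12L), roadblocks = c(6L, 15L))
    ),
    dyad = list(
      params = model_params(delta_m = 2, delta_rb = 3, k_ip = 10, k_tp = 3,
                            k_in = 0.05, k_b = 0.1, L = 20,
                            boundary = "open", interaction = "dyad"),
      state = lattice_state(motors = c(0L, 6L), roadblocks = c(10L, 16L))
    )
  )
  brm_params <- model_params(delta_m = 1, delta_rb = 1, k_ip = 1, k_tp = 0.3,
                             k_b = 0.1, L = 60, boundary = "periodic",
                             n_motors = 6)
  brm <- simulate_traffic(brm_params, t_max = 400, dt_sample = 2,
                          burn_in = 100, seed = seed)
  set.seed(seed)
  geometric <- list(p = 0.25, gaps = rgeom_sample(2000, 0.25))
  telegraph <- list(k_on = 1 / 55, k_off = 0.02, k_tr = 0.08, t_max = 20000)
  telegraph$times <- simulate_telegraph(telegraph$k_on, telegraph$k_off,
                                        telegraph$k_tr, telegraph$t_max,
                                        seed = seed + 1L)
  list(states = states, brm = brm, geometric = geometric, telegraph = telegraph)
}

rgeom_sample <- function(n, p) as.integer(stats::rgeom(n, p))

#' Write the fixtures to plain-text files
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  fx <- make_fixtures(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(fx$brm, file.path(dir, "brm"))
  readr::write_tsv(tibble(gap = fx$geometric$gaps),
                   file.path(dir, "geometric_gaps.tsv"))
  readr::write_tsv(tibble(time_s = fx$telegraph$times),
                   file.path(dir, "telegraph_times.tsv"))
  jsonlite::write_json(
    list(geometric_p = fx$geometric$p,
         telegraph = fx$telegraph[c("k_on", "k_off", "k_tr", "t_max")],
         seed = seed),
    file.path(dir, "fixtures_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
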