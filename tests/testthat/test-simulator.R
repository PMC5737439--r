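test_that("identical seeds give identical event logs", {
  p <- model_params(delta_m = 2, delta_rb = 3, k_ip = 2, k_tp = 0.5,
                    k_in = 0.2, k_b = 0.2, L = 50, boundary = "open")
  a <- simulate_traffic(p, t_max = 100, dt_sample = 1, burn_in = 0, seed = 9)
  b <- simulate_traffic(p, t_max = 100, dt_sample = 1, burn_in = 0, seed = 9)
  expect_identical(a$events, b$events)
  expect_identical(a$snapshots, b$snapshots)
  c <- simulate_traffic(p, t_max = 100, dt_sample = 1, burn_in = 0, seed = 10)
  expect_false(identical(a$events, c$events))
})

test_that("a lone motor crosses a roadblock-free lattice at k_ip", {
  # k_b -> 0: pure Poisson stepping; transit time of L sites has mean L/k_ip
  L <- 200
  p <- model_params(delta_m = 1, delta_rb = 1, k_ip = 2, k_tp = 0.5,
                    k_in = 0.004, k_b = 1e-12, L = L, boundary = "open")
  tr <- simulate_traffic(p, t_max = 20000, dt_sample = 50, burn_in = 0,
                         seed = 14, record_events = FALSE)
  # pair each termination with its initiation (motors cannot overtake)
  n <- min(length(tr$initiation_times), length(tr$termination_times))
  transits <- tr$termination_times[seq_len(n)] - tr$initiation_times[seq_len(n)]
  expect_gt(n, 30)
  se <- sqrt(L / p$k_ip^2) / sqrt(n)
  expect_lt(abs(mean(transits) - L / p$k_ip), 4 * se + 1e-9)
})

test_that("replaying the event log through the rule layer reproduces snapshots", {
  cases <- list(
    model_params(delta_m = 1, delta_rb = 1, k_ip = 2, k_tp = 0.5, k_b = 0.5,
                 L = 12, boundary = "periodic", n_motors = 3),
    model_params(delta_m = 3, delta_rb = 7, k_ip = 5, k_tp = 1.5, k_in = 0.2,
                 k_b = 0.1, L = 60, boundary = "open", eviction = "traversal"),
    model_params(delta_m = 2, delta_rb = 5, k_ip = 5, k_tp = 1.5, k_in = 0.2,
                 k_b = 0.1, L = 50, boundary = "open", interaction = "dyad")
  )
  for (ci in seq_along(cases)) {
    p <- cases[[ci]]
    tr <- simulate_traffic(p, t_max = 60, dt_sample = 5, burn_in = 0,
                           seed = 20 + ci)
    st <- if (p$boundary == "periodic") {
      n <- p$n_motors
      lattice_state(as.integer(floor(seq(0, p$L - 1,
                                         length.out = n + 1)[seq_len(n)])))
    } else lattice_state()
    ev <- tr$events
    snap_times <- tr$snapshot_times
    si <- 1L
    check_snapshot <- function(state, ts) {
      ref <- dplyr::filter(tr$snapshots, .data$time == ts)
      expect_setequal(state$motors, ref$position[ref$kind == "motor"])
      expect_setequal(state$roadblocks, ref$position[ref$kind == "roadblock"])
    }
    for (r in seq_len(nrow(ev))) {
      while (si <= length(snap_times) && snap_times[si] < ev$time[r]) {
        check_snapshot(st, snap_times[si]); si <- si + 1L
      }
      st <- switch(as.character(ev$kind[r]),
        step = apply_step(st, match(ev$position[r], st$motors), p),
        terminate = apply_step(st, match(ev$position[r], st$motors), p),
        initiate = lattice_state(c(0L, st$motors), st$roadblocks),
        bind = lattice_state(st$motors, c(st$roadblocks, ev$position[r]))
      )
    }
    expect_setequal(st$motors, tr$final_state$motors)
    expect_setequal(st$roadblocks, tr$final_state$roadblocks)
  }
})

test_that("initiations minus terminations equals the motor count at all times", {
  p <- model_params(delta_m = 3, delta_rb = 5, k_ip = 3, k_tp = 1, k_in = 0.3,
                    k_b = 0.3, L = 80, boundary = "open")
  tr <- simulate_traffic(p, t_max = 300, dt_sample = 5, burn_in = 0, seed = 31,
                         record_events = FALSE)
  sn <- tr$snapshots
  for (ts in tr$snapshot_times) {
    n_mot <- sum(sn$time == ts & sn$kind == "motor")
    expect_equal(n_mot, sum(tr$initiation_times <= ts) -
                   sum(tr$termination_times <= ts))
  }
})

test_that("steady-state flux is uniform along the gene (continuity)", {
  p <- model_params(delta_m = 2, delta_rb = 4, k_ip = 4, k_tp = 2, k_in = 0.2,
                    k_b = 0.2, L = 120, boundary = "open")
  tr <- simulate_traffic(p, t_max = 6000, dt_sample = 10, seed = 8,
                         record_events = FALSE)
  T_obs <- tr$t_max - tr$burn_in
  flux <- tr$site_stats$steps / T_obs
  # compare windowed fluxes against the termination rate
  j_term <- sum(tr$termination_times > tr$burn_in) / T_obs
  for (win in list(10:40, 50:80, 85:115)) {
    expect_lt(abs(mean(flux[win]) - j_term) / j_term, 0.1)
  }
})

test_that("kymographs rasterize snapshots with motor precedence", {
  # no motors, no roadblock binding: empty matrix
  p0 <- model_params(delta_m = 2, delta_rb = 2, k_in = 0, k_b = 1e-12, L = 20,
                     boundary = "open")
  tr0 <- simulate_traffic(p0, t_max = 10, dt_sample = 1, burn_in = 0, seed = 1)
  k0 <- as_kymograph(tr0)
  expect_true(all(k0$matrix == 0L))
  expect_equal(dim(k0$matrix), c(10L, 20L))

  # a nearly immobile motor leaves a vertical band of width delta_m
  p1 <- model_params(delta_m = 3, delta_rb = 2, k_ip = 1e-9, k_tp = 1e-10,
                     k_b = 1e-12, L = 20, boundary = "periodic", n_motors = 1)
  tr1 <- simulate_traffic(p1, t_max = 50, dt_sample = 1, burn_in = 0, seed = 2)
  k1 <- as_kymograph(tr1)
  expect_true(all(colSums(k1$matrix == 2L)[1:3] == nrow(k1$matrix)))
  expect_true(all(k1$matrix[, 4:20] == 0L))

  # motor-code cells per time bin = delta_m x motors present in that snapshot
  p2 <- model_params(delta_m = 2, delta_rb = 3, k_ip = 2, k_tp = 0.5,
                     k_in = 0.3, k_b = 0.2, L = 40, boundary = "open")
  tr2 <- simulate_traffic(p2, t_max = 40, dt_sample = 1, burn_in = 0, seed = 3)
  k2 <- as_kymograph(tr2)
  sn <- tr2$snapshots
  for (b in seq_len(nrow(k2$matrix) - 1L)) {  # last bin absorbs the edge snapshot
    ts <- tr2$snapshot_times[b]
    n_mot <- sum(sn$time == ts & sn$kind == "motor")
    expect_equal(sum(k2$matrix[b, ] == 2L), 2L * n_mot)
  }
  expect_error(as_kymograph(tr2, t0 = -5, t1 = 100), "outside")
})

test_that("empirical stationary law matches the exactly solved master equation", {
  # periodic delta = 1 BRM small enough to solve in full: L = 6, 2 motors
  L <- 6; kip <- 2; ktp <- 0.5; kb <- 0.5
  pi_th <- brm_stationary(L, 2, kip, ktp, kb)
  p <- model_params(delta_m = 1, delta_rb = 1, k_ip = kip, k_tp = ktp,
                    k_b = kb, L = L, boundary = "periodic", n_motors = 2)
  tr <- simulate_traffic(p, t_max = 6e4, dt_sample = 0.5, burn_in = 500,
                         seed = 4, record_events = FALSE)
  sn <- tr$snapshots
  codes <- tapply(2^sn$position * ifelse(sn$kind == "motor", 1, 2^L), sn$time,
                  sum)
  emp <- table(factor(format(codes, scientific = FALSE, trim = TRUE),
                      levels = names(pi_th)))
  emp <- as.numeric(emp) / sum(emp)
  tv <- 0.5 * sum(abs(emp - pi_th))
  expect_lt(tv, 0.05)  # quick-run check; the full-depth version is in acceptance
})
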