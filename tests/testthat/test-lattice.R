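brm_params <- function(L = 20, n_motors = 2, ...) {
  model_params(delta_m = 1, delta_rb = 1, k_ip = 10, k_tp = 3, k_b = 0.1,
               L = L, boundary = "periodic", n_motors = n_motors, ...)
}

test_that("stepping rate follows exclusion and roadblock-hindrance rules", {
  p <- brm_params()
  st <- lattice_state(motors = c(5L, 12L), roadblocks = 6L)
  expect_equal(motor_step_rate(st, 1, p), p$k_tp)   # roadblock ahead
  expect_equal(motor_step_rate(st, 2, p), p$k_ip)   # free site ahead
  st2 <- lattice_state(motors = c(5L, 6L))
  expect_equal(motor_step_rate(st2, 1, p), 0)       # steric block
  expect_error(motor_step_rate(st, 5, p), "index")
})

test_that("dyad interaction impedes only at the dyad, at the renormalized rate", {
  p <- model_params(delta_m = 1, delta_rb = 3, k_ip = 10, k_tp = 3, k_b = 0.1,
                    k_in = 0.1, L = 20, boundary = "open", interaction = "dyad")
  # roadblock covers 10-12, dyad at 11
  st_at_9 <- lattice_state(motors = 9L, roadblocks = 10L)
  st_at_10 <- lattice_state(motors = 10L, roadblocks = 10L)
  expect_equal(motor_step_rate(st_at_9, 1, p), p$k_ip)       # entering site 10
  expect_equal(motor_step_rate(st_at_10, 1, p), dyad_rate(p)) # entering dyad 11
  # enumerate the rule across the lattice against the hand-coded oracle
  for (pos in 0:16) {
    st <- lattice_state(motors = pos, roadblocks = 10L)
    ok <- tryCatch({ validate_lattice_state(st, p); TRUE },
                   error = function(e) FALSE)
    if (!ok) next
    expect_equal(motor_step_rate(st, 1, p), oracle_step_rate(st, 1, p),
                 info = paste("motor at", pos))
  }
})

test_that("stepping moves the motor and applies the eviction convention", {
  p <- brm_params()
  st <- lattice_state(motors = c(5L, 12L), roadblocks = c(6L, 15L))
  out <- apply_step(st, 1, p)
  expect_equal(out$motors, c(6L, 12L))
  expect_equal(out$roadblocks, 15L)  # roadblock at 6 evicted on contact
  out2 <- apply_step(out, 2, p)      # no roadblock at 13
  expect_equal(out2$motors, c(6L, 13L))
  expect_equal(length(out2$roadblocks), 1L)
  expect_error(apply_step(lattice_state(motors = c(5L, 6L)), 1, p), "blocked")

  pd <- model_params(delta_m = 1, delta_rb = 3, k_ip = 10, k_tp = 3, k_b = 0.1,
                     k_in = 0.1, L = 20, boundary = "open", interaction = "dyad")
  st <- lattice_state(motors = 9L, roadblocks = 10L)
  s1 <- apply_step(st, 1, pd)             # onto non-dyad site 10
  expect_equal(s1$roadblocks, 10L)        # intact
  s2 <- apply_step(s1, 1, pd)             # onto dyad 11
  expect_equal(s2$roadblocks, integer())  # evicted
})

test_that("open-boundary termination removes the motor at the last site", {
  p <- model_params(delta_m = 2, delta_rb = 2, k_ip = 1, k_tp = 0.5,
                    k_in = 0.1, k_b = 0.1, L = 12, boundary = "open")
  st <- lattice_state(motors = 10L)  # front at 11 = L - 1
  out <- apply_step(st, 1, p)
  expect_equal(length(out$motors), 0L)
  expect_true(isTRUE(attr(out, "terminated")))
})

test_that("admissible binding positions match the exhaustive site scan", {
  # empty periodic lattice: every position admissible
  p <- model_params(delta_m = 1, delta_rb = 2, k_b = 0.1, L = 10,
                    boundary = "periodic", n_motors = 0)
  expect_length(roadblock_binding_positions(lattice_state(), p), 10L)
  # delta_rb = 1 lattice fully covered by motors: none
  pf <- model_params(delta_m = 1, delta_rb = 1, k_b = 0.1, L = 6,
                     boundary = "periodic", n_motors = 6)
  full <- lattice_state(motors = 0:5)
  expect_length(roadblock_binding_positions(full, pf), 0L)
  # open case with a motor and a roadblock: brute-force oracle
  po <- model_params(delta_m = 2, delta_rb = 3, k_in = 0.1, k_b = 0.1, L = 12,
                     boundary = "open")
  st <- lattice_state(motors = 4L, roadblocks = 8L)
  expect_equal(roadblock_binding_positions(st, po),
               oracle_binding_positions(st, po))
  # random states, both boundaries
  for (seed in 1:10) {
    pr <- model_params(delta_m = 3, delta_rb = 4, k_in = 0.1, k_b = 0.1,
                       L = 40, boundary = if (seed %% 2) "open" else "periodic",
                       n_motors = if (seed %% 2) NULL else 3)
    st <- random_state(pr, 3, 3, seed)
    expect_equal(sort(roadblock_binding_positions(st, pr)),
                 sort(oracle_binding_positions(st, pr)), info = seed)
  }
})

test_that("initiation requires a motor-free initiation footprint", {
  p <- model_params(delta_m = 3, delta_rb = 2, k_in = 0.2, k_b = 0.1, L = 20,
                    boundary = "open")
  expect_equal(initiation_rate(lattice_state(), p), 0.2)
  expect_equal(initiation_rate(lattice_state(motors = 0L), p), 0)
  expect_equal(initiation_rate(lattice_state(motors = 2L), p), 0)
  expect_equal(initiation_rate(lattice_state(motors = 3L), p), 0.2)
  pp <- brm_params()
  expect_error(initiation_rate(lattice_state(), pp), "open")
})

test_that("state invariants survive random event application", {
  p <- model_params(delta_m = 3, delta_rb = 5, k_ip = 2, k_tp = 0.5,
                    k_in = 0.5, k_b = 0.5, L = 60, boundary = "open")
  set.seed(42)
  st <- lattice_state()
  orders_ok <- TRUE
  for (step in 1:400) {
    ev <- enumerate_events(st, p)
    if (!nrow(ev)) break
    pick <- ev[sample.int(nrow(ev), 1, prob = ev$rate), ]
    st <- switch(as.character(pick$kind),
      step = {
        i <- match(pick$position, st$motors)
        prev <- st$motors
        out <- apply_step(st, i, p)
        # order preservation: dropping/advancing never reorders
        if (is.unsorted(out$motors)) orders_ok <- FALSE
        out
      },
      initiate = lattice_state(c(0L, st$motors), st$roadblocks, st$time),
      bind = lattice_state(st$motors, c(st$roadblocks, pick$position), st$time)
    )
    expect_no_error(validate_lattice_state(st, p))
  }
  expect_true(orders_ok)
})

test_that("with delta = 1 the event catalogue is exactly the Bus-Route Model", {
  p <- brm_params(L = 15, n_motors = 4)
  for (seed in 1:12) {
    st <- random_state(p, 4, 5, seed)
    ours <- enumerate_events(st, p) |> as.data.frame()
    ours <- ours[order(ours$kind, ours$position), ]
    brm <- oracle_brm_events(st, p)
    brm <- brm[order(brm$kind, brm$position), ]
    expect_equal(ours$kind, as.character(brm$kind), info = seed)
    expect_equal(ours$position, brm$position, info = seed)
    expect_equal(ours$rate, brm$rate, info = seed)
  }
})

test_that("without roadblocks the catalogue reduces to the plain TASEP", {
  p <- model_params(delta_m = 2, delta_rb = 3, k_ip = 4, k_tp = 1, k_b = 1e-12,
                    L = 30, boundary = "periodic", n_motors = 5)
  st <- lattice_state(motors = c(0L, 5L, 11L, 20L, 26L))
  ev <- enumerate_events(st, p)
  steps <- ev[ev$kind == "step", ]
  expect_true(all(steps$rate == p$k_ip))
  expect_true(all(ev$rate[ev$kind == "bind"] == 1e-12))
})
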