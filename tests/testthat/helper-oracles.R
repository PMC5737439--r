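# Independent oracles, deliberately written site-by-site (occupancy arrays and
# brute-force scans) rather than via the package's interval arithmetic.

# occupancy vectors for a state: 0 empty, 1 motor, 2 roadblock (by coverage)
oracle_occupancy <- function(state, params) {
  L <- params$L
  periodic <- params$boundary == "periodic"
  mot <- integer(L)
  rb <- integer(L)
  for (p in state$motors) {
    for (k in 0:(params$delta_m - 1L)) {
      s <- if (periodic) (p + k) %% L else p + k
      mot[s + 1L] <- mot[s + 1L] + 1L
    }
  }
  for (q in state$roadblocks) {
    for (k in 0:(params$delta_rb - 1L)) {
      s <- if (periodic) (q + k) %% L else q + k
      rb[s + 1L] <- rb[s + 1L] + 1L
    }
  }
  list(motor = mot, rb = rb)
}

# stepping rate by direct site inspection (contact/dyad conventions)
oracle_step_rate <- function(state, i, params) {
  L <- params$L
  periodic <- params$boundary == "periodic"
  occ <- oracle_occupancy(state, params)
  pos <- state$motors[i]
  nxt <- pos + params$delta_m
  if (!periodic && nxt > L - 1L) return(params$k_ip)
  if (periodic) nxt <- nxt %% L
  occ_other <- oracle_occupancy(
    lattice_state(state$motors[-i], state$roadblocks), params)
  if (occ_other$motor[nxt + 1L] > 0L) return(0)
  if (occ$rb[nxt + 1L] == 0L) return(params$k_ip)
  if (params$interaction == "uniform") return(params$k_tp)
  dyads <- (state$roadblocks + params$delta_rb %/% 2L)
  if (periodic) dyads <- dyads %% L
  if (nxt %in% dyads) dyad_rate(params) else params$k_ip
}

# admissible binding positions by exhaustive site scan
oracle_binding_positions <- function(state, params) {
  L <- params$L
  periodic <- params$boundary == "periodic"
  occ <- oracle_occupancy(state, params)
  blocked <- occ$motor + occ$rb
  cand <- if (periodic) 0:(L - 1L) else {
    if (L - params$delta_rb < params$delta_m) integer() else
      params$delta_m:(L - params$delta_rb)
  }
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    ok <- TRUE
    for (k in 0:(params$delta_rb - 1L)) {
      s <- if (periodic) (cand[j] + k) %% L else cand[j] + k
      if (blocked[s + 1L] > 0L) { ok <- FALSE; break }
    }
    keep[j] <- ok
  }
  cand[keep]
}

# event catalogue of the delta = 1 Bus-Route Model (periodic), hand-coded
oracle_brm_events <- function(state, params) {
  stopifnot(params$delta_m == 1L, params$delta_rb == 1L,
            params$boundary == "periodic")
  L <- params$L
  out <- list()
  for (m in state$motors) {
    tgt <- (m + 1L) %% L
    if (tgt %in% state$motors) next
    r <- if (tgt %in% state$roadblocks) params$k_tp else params$k_ip
    out[[length(out) + 1L]] <- data.frame(kind = "step", position = m, rate = r)
  }
  for (s in setdiff(0:(L - 1L), c(state$motors, state$roadblocks))) {
    out[[length(out) + 1L]] <- data.frame(kind = "bind", position = s,
                                          rate = params$k_b)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# brute-force gap list and peloton partition via site scans
oracle_gaps <- function(state, params) {
  L <- params$L
  periodic <- params$boundary == "periodic"
  m <- sort(state$motors)
  n <- length(m)
  if (n == 0L || (!periodic && n < 2L)) return(integer())
  lead <- if (periodic) c(m[-1], m[1] + L) else m[-1]
  trail <- if (periodic) m else m[-n]
  if (periodic && n == 1L) { trail <- m; lead <- m + L }
  as.integer(lead - trail - params$delta_m)
}

oracle_gap_types <- function(state, params) {
  L <- params$L
  periodic <- params$boundary == "periodic"
  occ <- oracle_occupancy(state, params)
  dyads <- (state$roadblocks + params$delta_rb %/% 2L)
  if (periodic) dyads <- dyads %% L
  m <- sort(state$motors)
  n <- length(m)
  if (n == 0L || (!periodic && n < 2L)) return(character())
  lead <- if (periodic) c(m[-1], m[1] + L) else m[-1]
  trail <- if (periodic) m else m[-n]
  if (periodic && n == 1L) { trail <- m; lead <- m + L }
  vapply(seq_along(trail), function(j) {
    sites <- seq.int(trail[j] + params$delta_m, lead[j] - 1L)
    if (length(sites) == 0L) return("intra")
    sites <- if (periodic) sites %% L else sites
    hit <- if (params$interaction == "uniform") {
      any(occ$rb[sites + 1L] > 0L)
    } else {
      any(sites %in% dyads)
    }
    if (hit) "trans" else "intra"
  }, character(1))
}

oracle_pelotons <- function(state, params) {
  m <- sort(state$motors)
  n <- length(m)
  if (n <= 1L) return(rep(1L, n))
  types <- oracle_gap_types(state, params)
  periodic <- params$boundary == "periodic"
  id <- cumsum(c(1L, as.integer(types[seq_len(n - 1L)] == "trans")))
  if (periodic && types[n] == "intra" && max(id) > 1L) {
    id[id == max(id)] <- 1L
  }
  as.integer(table(id))
}

# random valid states for fuzzing (uniform interaction)
random_state <- function(params, n_motors, n_rb, seed) {
  set.seed(seed)
  L <- params$L
  periodic <- params$boundary == "periodic"
  occupied <- logical(L)
  place <- function(w, n, lo = 0L) {
    pos <- integer()
    tries <- 0L
    while (length(pos) < n && tries < 500L) {
      tries <- tries + 1L
      q <- sample(lo:(if (periodic) L - 1L else L - w), 1L)
      sites <- if (periodic) (q + 0:(w - 1L)) %% L else q + 0:(w - 1L)
      if (!any(occupied[sites + 1L])) {
        occupied[sites + 1L] <<- TRUE
        pos <- c(pos, q)
      }
    }
    pos
  }
  motors <- place(params$delta_m, n_motors)
  rb_lo <- if (periodic) 0L else params$delta_m
  rbs <- place(params$delta_rb, n_rb, lo = rb_lo)
  lattice_state(sort(motors), rbs)
}

# exact stationary distribution of the delta = 1 periodic BRM by solving the
# full master equation; returns a named vector over integer state codes
# (sum of 2^site for motors plus 2^L * sum of 2^site for roadblocks)
brm_stationary <- function(L, n_motors, k_ip, k_tp, k_b) {
  enc <- function(motors, rbs) sum(2^motors) + 2^L * sum(2^rbs)
  states <- list()
  for (m in utils::combn(0:(L - 1L), n_motors, simplify = FALSE)) {
    free <- setdiff(0:(L - 1L), m)
    for (k in 0:length(free)) {
      combos <- if (k == 0L) list(integer()) else
        utils::combn(free, k, simplify = FALSE)
      for (rb in combos) states[[length(states) + 1L]] <- list(m = m, rb = rb)
    }
  }
  n <- length(states)
  code <- vapply(states, function(s) enc(s$m, s$rb), numeric(1))
  idx <- setNames(seq_len(n), format(code, scientific = FALSE, trim = TRUE))
  key <- function(x) format(x, scientific = FALSE, trim = TRUE)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- states[[i]]
    for (m in s$m) {
      tgt <- (m + 1L) %% L
      if (tgt %in% s$m) next
      if (tgt %in% s$rb) {
        j <- idx[[key(enc(sort(c(setdiff(s$m, m), tgt)), setdiff(s$rb, tgt)))]]
        Q[i, j] <- Q[i, j] + k_tp
      } else {
        j <- idx[[key(enc(sort(c(setdiff(s$m, m), tgt)), s$rb))]]
        Q[i, j] <- Q[i, j] + k_ip
      }
    }
    for (f in setdiff(0:(L - 1L), c(s$m, s$rb))) {
      j <- idx[[key(enc(s$m, sort(c(s$rb, f))))]]
      Q[i, j] <- Q[i, j] + k_b
    }
    Q[i, i] <- -sum(Q[i, -i])
  }
  A <- rbind(t(Q), rep(1, n))
  pi_th <- qr.solve(A, c(rep(0, n), 1))
  setNames(pi_th, key(code))
}
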