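#' Instantaneous lattice state
#'
#' Positions are 0-based leftmost occupied sites: a motor at `p` covers
#' `[p, p + delta_m - 1]`, a roadblock at `q` covers `[q, q + delta_rb - 1]`
#' (wrapping in periodic mode). Motors are kept in ascending (cyclic)
#' order, which is preserved over time since motors cannot overtake.
#'
#' @param motors integer vector of motor leftmost positions.
#' @param roadblocks integer vector of roadblock leftmost positions.
#' @param time time stamp in seconds.
#' @return an object of class `lattice_state`.
#' @export
lattice_state <- function(motors = integer(), roadblocks = integer(), time = 0) {
  s <- list(time = as.numeric(time),
            motors = as.integer(motors),
            roadblocks = as.integer(sort(roadblocks)))
  class(s) <- "lattice_state"
  s
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> t = %g s, %d motors, %d roadblocks\n",
              x$time, length(x$motors), length(x$roadblocks)))
  invisible(x)
}

# sites covered by a particle with leftmost position p and footprint w
covered_sites <- function(p, w, L, periodic) {
  s <- p + seq_len(w) - 1L
  if (periodic) s %% L else s
}

all_covered <- function(positions, w, L, periodic) {
  if (!length(positions)) return(integer())
  unlist(lapply(positions, covered_sites, w = w, L = L, periodic = periodic))
}

#' Validate lattice-state exclusion invariants
#'
#' Checks that no two motors overlap, no two roadblocks overlap, footprints
#' fit on the lattice (open mode), no roadblock overlaps the initiation
#' footprint `[0, delta_m - 1]` (open mode), and the motor/roadblock
#' interaction constraint holds: in uniform mode motors and roadblocks may
#' not overlap at all; in dyad mode a motor may never cover an intact
#' roadblock's dyad site.
#'
#' @param state a `lattice_state`.
#' @param params a `model_params`.
#' @return `state`, invisibly; errors on violation.
#' @export
validate_lattice_state <- function(state, params) {
  p <- params
  periodic <- p$boundary == "periodic"
  ms <- all_covered(state$motors, p$delta_m, p$L, periodic)
  rs <- all_covered(state$roadblocks, p$delta_rb, p$L, periodic)
  if (anyDuplicated(ms)) abort("motor footprints overlap")
  if (anyDuplicated(rs)) abort("roadblock footprints overlap")
  if (!periodic) {
    if (length(ms) && (min(ms) < 0L || max(ms) > p$L - 1L))
      abort("motor footprint outside the lattice")
    if (length(rs) && (min(rs) < 0L || max(rs) > p$L - 1L))
      abort("roadblock footprint outside the lattice")
    if (length(state$roadblocks) && any(state$roadblocks < p$delta_m))
      abort("roadblock overlaps the initiation footprint")
  }
  if (p$interaction == "uniform") {
    if (length(intersect(ms, rs))) abort("motor overlaps a roadblock footprint")
  } else {
    dy <- (state$roadblocks + dyad_offset(p))
    if (periodic) dy <- dy %% p$L
    if (length(intersect(ms, dy))) abort("motor covers an intact roadblock dyad")
  }
  ord <- state$motors
  if (!periodic && is.unsorted(ord)) abort("motors must be sorted ascending")
  invisible(state)
}

# leftmost position of the roadblock covering `site`, or NA
rb_covering <- function(site, roadblocks, delta_rb, L, periodic) {
  for (q in roadblocks) {
    s <- covered_sites(q, delta_rb, L, periodic)
    if (site %in% s) return(q)
  }
  NA_integer_
}

#' Stepping rate of one motor
#'
#' Implements the bulk rules: the site the motor's front would newly occupy
#' determines the rate. Occupied by another motor: blocked (rate 0, steric
#' exclusion). Uniform mode: `k_tp` if roadblock-covered, else `k_ip`.
#' Dyad mode: the renormalized [dyad_rate()] if the site is an intact
#' roadblock's dyad, else `k_ip` (other roadblock sites do not impede).
#' In open mode a motor whose front is at the last site exits at `k_ip`.
#'
#' @param state a `lattice_state`.
#' @param motor_index 1-based index into `state$motors`.
#' @param params a `model_params`.
#' @return the stepping rate in 1/s; `0` means blocked.
#' @export
motor_step_rate <- function(state, motor_index, params) {
  p <- params
  if (motor_index < 1L || motor_index > length(state$motors))
    abort("invalid motor index")
  periodic <- p$boundary == "periodic"
  pos <- state$motors[motor_index]
  nxt <- pos + p$delta_m
  if (!periodic && nxt > p$L - 1L) return(p$k_ip)  # exit step
  if (periodic) nxt <- nxt %% p$L
  other <- all_covered(state$motors[-motor_index], p$delta_m, p$L, periodic)
  if (nxt %in% other) return(0)
  q <- rb_covering(nxt, state$roadblocks, p$delta_rb, p$L, periodic)
  if (is.na(q)) return(p$k_ip)
  if (p$interaction == "uniform") return(p$k_tp)
  dy <- if (periodic) (q + dyad_offset(p)) %% p$L else q + dyad_offset(p)
  if (nxt == dy) dyad_rate(p) else p$k_ip
}

#' Advance one motor by a single site
#'
#' Moves the motor, evicts any roadblock whose interaction site is newly
#' covered by the motor front (uniform mode: any footprint site, i.e.
#' first contact; dyad mode: the dyad site), and in open mode removes the
#' motor when its front passes the last lattice site.
#'
#' @inheritParams motor_step_rate
#' @return the new `lattice_state`. If the motor terminated, the returned
#'   state has one fewer motor and carries attribute `terminated = TRUE`.
#' @export
apply_step <- function(state, motor_index, params) {
  p <- params
  if (motor_step_rate(state, motor_index, params) == 0)
    abort("cannot step a blocked motor")
  periodic <- p$boundary == "periodic"
  pos <- state$motors[motor_index]
  out <- state
  if (!periodic && pos + p$delta_m > p$L - 1L) {
    out$motors <- state$motors[-motor_index]
    attr(out, "terminated") <- TRUE
    return(out)
  }
  nxt <- if (periodic) (pos + p$delta_m) %% p$L else pos + p$delta_m
  q <- rb_covering(nxt, state$roadblocks, p$delta_rb, p$L, periodic)
  if (!is.na(q)) {
    # contact and traversal modes share first-contact removal (they differ
    # only in waiting times); dyad mode evicts when the front hits the dyad
    evict <- if (p$interaction == "dyad") {
      dy <- if (periodic) (q + dyad_offset(p)) %% p$L else q + dyad_offset(p)
      nxt == dy
    } else TRUE
    if (evict) out$roadblocks <- setdiff(out$roadblocks, q)
  }
  out$motors[motor_index] <- if (periodic) (pos + 1L) %% p$L else pos + 1L
  out
}

#' Admissible roadblock binding positions
#'
#' A leftmost position `q` is admissible when the full footprint
#' `[q, q + delta_rb - 1]` is free of motors and of other roadblocks; in
#' open mode positions whose footprint would overlap the initiation
#' footprint `[0, delta_m - 1]` are excluded (the initiation site is kept
#' roadblock-free), as are footprints extending past the lattice end.
#' Each admissible position binds at rate `k_b`.
#'
#' @param state a `lattice_state`.
#' @param params a `model_params`.
#' @return integer vector of admissible leftmost positions.
#' @export
roadblock_binding_positions <- function(state, params) {
  p <- params
  periodic <- p$boundary == "periodic"
  occupied <- c(all_covered(state$motors, p$delta_m, p$L, periodic),
                all_covered(state$roadblocks, p$delta_rb, p$L, periodic))
  cand <- if (periodic) 0:(p$L - 1L) else p$delta_m:(p$L - p$delta_rb)
  if (!periodic && p$L - p$delta_rb < p$delta_m) return(integer())
  ok <- vapply(cand, function(q) {
    !any(covered_sites(q, p$delta_rb, p$L, periodic) %in% occupied)
  }, logical(1))
  as.integer(cand[ok])
}

#' Initiation rate at the start of an open lattice
#'
#' Returns `k_in` when the initiation footprint `[0, delta_m - 1]` is free
#' of motors, and `0` (blocked) otherwise. The footprint is roadblock-free
#' by construction.
#'
#' @inheritParams roadblock_binding_positions
#' @return `k_in` or `0`.
#' @export
initiation_rate <- function(state, params) {
  if (params$boundary != "open") abort("initiation applies to open boundaries only")
  ms <- all_covered(state$motors, params$delta_m, params$L, FALSE)
  if (any(ms < params$delta_m)) 0 else params$k_in
}

#' Enumerate all possible events from a state
#'
#' The full event catalogue: one `step` per unblocked motor, one
#' `initiate` (open mode, when admissible), and one `bind` per admissible
#' roadblock position. Deterministic given the state.
#'
#' @inheritParams roadblock_binding_positions
#' @return a tibble with columns `kind`, `position`, `rate`.
#' @export
enumerate_events <- function(state, params) {
  rates <- vapply(seq_along(state$motors),
                  function(i) motor_step_rate(state, i, params), numeric(1))
  steps <- tibble(kind = "step", position = state$motors, rate = rates)
  steps <- steps[steps$rate > 0, ]
  out <- steps
  if (params$boundary == "open" && params$k_in > 0) {
    r <- initiation_rate(state, params)
    if (r > 0) out <- dplyr::bind_rows(out, tibble(kind = "initiate", position = 0L, rate = r))
  }
  qs <- roadblock_binding_positions(state, params)
  if (length(qs)) {
    out <- dplyr::bind_rows(out, tibble(kind = "bind", position = qs, rate = params$k_b))
  }
  out
}
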