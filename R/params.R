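#' Parse a rate given with a "/s" or "/min" suffix
#'
#' Rates in the transcription literature are quoted per minute (initiation
#' rates) or per second (elongation rates); accepting an explicit suffix
#' avoids unit mistakes. Bare numerics are taken to be per second.
#'
#' @param x a numeric, or a string like `"0.6/min"`, `"10/s"`.
#' @return rate in 1/s (numeric scalar).
#' @examples
#' parse_rate("0.6/min")  # 0.01
#' parse_rate(10)         # 10
#' @export
parse_rate <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) {
    abort("rate must be a numeric scalar or a string like '0.6/min'")
  }
  x <- gsub("\\s+", "", x)
  m <- regmatches(x, regexec("^([0-9.eE+-]+)(/s|/sec|/min)?$", x))[[1]]
  if (length(m) == 0L || m[2] == "") {
    abort(paste0("cannot parse rate '", x, "' (use e.g. '0.6/min' or '10/s')"))
  }
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val)) abort(paste0("cannot parse rate '", x, "'"))
  if (identical(m[3], "/min")) val / 60 else val
}

#' Model parameters for the motor-roadblock lattice gas
#'
#' Collects all microscopic rates and footprints plus the lattice and
#' boundary configuration. Motors (RNA polymerases) of footprint `delta_m`
#' hop one site at a time in the +x direction; roadblocks (nucleosomes) of
#' footprint `delta_rb` bind dynamically on free stretches and are evicted
#' by passing motors.
#'
#' Interaction and eviction conventions. In `"uniform"` interaction any
#' intact-roadblock-covered site ahead of a motor slows the step to `k_tp`;
#' with `eviction = "contact"` the roadblock is removed on first footprint
#' contact (the Bus-Route-Model convention, exact for `delta_rb = 1`), and
#' with `eviction = "traversal"` the roadblock is likewise removed on first
#' contact but the evicting motor keeps stepping at `k_tp` until its front
#' has traversed the remaining footprint length: it transcribes through the
#' nucleosome region at exactly the effective rate `k_tp` (bp/s) while
#' motors drafting behind it move at `k_ip`. State transitions are
#' identical in the two conventions; only waiting times differ.
#' `"traversal"` is the transcription convention used by
#' [params_table1()]. In `"dyad"`
#' interaction only the roadblock's central (dyad) site impedes, with the
#' dyad-passage rate renormalized to
#' \deqn{k_{dyad} = 1 / (\delta_{rb}/k_{tp} - (\delta_{rb}-1)/k_{ip})}
#' so the mean footprint-crossing time is preserved; note this concentrates
#' the slowdown in a single dwell and so exaggerates velocity fluctuations
#' relative to the distributed conventions. At `delta_rb = 1` all
#' conventions coincide.
#'
#' @param delta_m motor footprint (sites = bp), >= 1.
#' @param delta_rb roadblock footprint (sites), >= 1.
#' @param k_ip unhindered (intra-peloton) hopping rate, 1/s; accepts "/min".
#' @param k_tp roadblock-hindered (trans-peloton) effective hopping rate, 1/s.
#' @param k_in initiation rate (open boundary), 1/s; accepts e.g. `"0.6/min"`.
#' @param k_b roadblock binding-attempt rate per admissible leftmost
#'   position, 1/s.
#' @param tau roadblock equilibration time (s) used by the analytic layer;
#'   defaults to `1/k_b`. Set `tau = 0` for the fast-equilibration limit
#'   where the roadblock shadow is just the footprint.
#' @param L lattice length (sites), must exceed `delta_m + delta_rb`.
#' @param boundary `"open"` (initiation/termination) or `"periodic"`.
#' @param interaction `"uniform"` or `"dyad"`.
#' @param eviction `"contact"` or `"traversal"` (uniform interaction only;
#'   dyad interaction always evicts at the dyad).
#' @param n_motors motor count (periodic mode only).
#' @param seed optional default RNG seed used by [simulate_traffic()].
#' @return an object of class `model_params` (a named list).
#' @seealso [params_table1()] for the literature preset.
#' @export
model_params <- function(delta_m = 1L, delta_rb = 1L, k_ip = 1, k_tp = 1,
                         k_in = 0, k_b = 0.1, tau = NULL, L = 1000L,
                         boundary = c("open", "periodic"),
                         interaction = c("uniform", "dyad"),
                         eviction = c("contact", "traversal"),
                         n_motors = NULL, seed = NULL) {
  boundary <- match.arg(boundary)
  interaction <- match.arg(interaction)
  eviction <- match.arg(eviction)
  p <- list(
    delta_m = as.integer(delta_m), delta_rb = as.integer(delta_rb),
    k_ip = parse_rate(k_ip), k_tp = parse_rate(k_tp),
    k_in = parse_rate(k_in), k_b = parse_rate(k_b),
    tau = if (is.null(tau)) 1 / parse_rate(k_b) else as.numeric(tau),
    L = as.integer(L), boundary = boundary, interaction = interaction,
    eviction = if (interaction == "dyad") "dyad" else eviction,
    n_motors = if (is.null(n_motors)) NULL else as.integer(n_motors),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a `model_params` object
#'
#' Checks the structural invariants of the parameter set: positive
#' footprints, `0 < k_tp <= k_ip`, non-negative initiation rate, positive
#' binding rate, lattice long enough to hold one motor and one roadblock,
#' and a motor count in periodic mode that fits without overlap.
#'
#' @param p a `model_params` object.
#' @return `p`, invisibly, or an error naming the offending field.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$delta_m < 1L) abort("delta_m must be >= 1")
  if (p$delta_rb < 1L) abort("delta_rb must be >= 1")
  if (p$L <= p$delta_m + p$delta_rb) abort("L must exceed delta_m + delta_rb")
  if (!(p$k_tp > 0 && p$k_tp <= p$k_ip)) abort("need 0 < k_tp <= k_ip")
  if (p$k_in < 0) abort("k_in must be >= 0")
  if (p$k_b <= 0) abort("k_b must be > 0")
  if (p$tau < 0) abort("tau must be >= 0")
  if (p$boundary == "periodic") {
    if (is.null(p$n_motors)) abort("periodic boundary requires n_motors")
    if (p$n_motors < 0L) abort("n_motors must be >= 0")
    if (p$n_motors * p$delta_m > p$L) abort("n_motors motors do not fit on the lattice")
  }
  invisible(p)
}

#' Dyad offset of a roadblock
#'
#' The dyad is the central site of the roadblock footprint, at offset
#' `floor(delta_rb / 2)` from the leftmost covered site.
#'
#' @param p a `model_params` object.
#' @return integer offset (sites).
#' @export
dyad_offset <- function(p) p$delta_rb %/% 2L

#' Microscopic dyad-passage rate
#'
#' In dyad mode the entire nucleosomal slowdown is concentrated at the dyad
#' site: the dyad step fires at
#' `1 / (delta_rb/k_tp - (delta_rb - 1)/k_ip)` so that crossing the intact
#' footprint takes `delta_rb / k_tp` seconds on average, preserving `k_tp`
#' as the effective through-roadblock elongation rate. Equals `k_tp` when
#' `delta_rb = 1`.
#'
#' @param p a `model_params` object.
#' @return rate in 1/s.
#' @export
dyad_rate <- function(p) {
  1 / (p$delta_rb / p$k_tp - (p$delta_rb - 1) / p$k_ip)
}

#' Literature parameter preset for eukaryotic transcription
#'
#' The "table1" preset: RNAP footprint 35 bp, nucleosome-plus-linker
#' footprint 167 bp, bare-DNA elongation 10 bp/s, through-nucleosome
#' elongation 3 bp/s, nucleosome binding 0.02/s, dyad interaction, open
#' boundary. `tau` is set to 0: histones rebind on a sub-minute timescale
#' while clearing the footprint takes about a minute, so the roadblock
#' shadow is dominated by the footprint itself.
#'
#' @param k_in initiation rate; `"0.6/min"` to `"3/min"` spans highly
#'   transcribed genes.
#' @param L gene length in bp.
#' @param ... overrides passed to [model_params()].
#' @return a `model_params` object.
#' @examples
#' p <- params_table1(k_in = "0.6/min")
#' p$k_in  # 0.01 /s
#' @export
params_table1 <- function(k_in = "0.6/min", L = 3000L, ...) {
  defaults <- list(
    delta_m = 35L, delta_rb = 167L, k_ip = 10, k_tp = 3,
    k_in = parse_rate(k_in), k_b = 0.02, tau = 0, L = as.integer(L),
    boundary = "open", interaction = "uniform", eviction = "traversal"
  )
  do.call(model_params, modifyList(defaults, list(...)))
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  lattice: L = %d sites, %s boundary, %s interaction (%s eviction)\n",
              x$L, x$boundary, x$interaction, x$eviction))
  cat(sprintf("  footprints: motor %d, roadblock %d sites\n", x$delta_m, x$delta_rb))
  cat(sprintf("  rates (1/s): k_ip = %g, k_tp = %g, k_in = %g, k_b = %g\n",
              x$k_ip, x$k_tp, x$k_in, x$k_b))
  cat(sprintf("  tau = %g s", x$tau))
  if (x$interaction == "dyad") cat(sprintf(", dyad rate = %g /s", dyad_rate(x)))
  cat("\n")
  if (!is.null(x$n_motors)) cat(sprintf("  n_motors = %d\n", x$n_motors))
  invisible(x)
}

config_run_fields <- c("t_max", "dt_sample", "burn_in", "seed", "out_dir")
config_rate_fields <- c("k_ip", "k_tp", "k_in", "k_b")

#' Load a simulation configuration from YAML or JSON
#'
#' The file holds the [model_params()] fields plus optional run controls
#' (`t_max`, `dt_sample`, `burn_in`, `seed`, `out_dir`). A `preset: table1`
#' key applies the literature preset before overrides. Rates may be given
#' as strings with "/s" or "/min" suffixes. Unknown keys are an error.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml`/`.json`).
#' @return a list with elements `params` (`model_params`) and `run`
#'   (named list of run controls), of class `peloton_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yml" = , "yaml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("config must be .yaml/.yml or .json")
  )
  if (is.null(raw) || !length(raw)) abort("empty config file")
  param_fields <- setdiff(names(formals(model_params)), "...")
  known <- c(param_fields, config_run_fields, "preset")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  run <- raw[intersect(names(raw), config_run_fields)]
  pars <- raw[intersect(names(raw), param_fields)]
  params <- if (identical(raw$preset, "table1")) {
    do.call(params_table1, pars)
  } else {
    do.call(model_params, pars)
  }
  structure(list(params = params, run = run), class = "peloton_config")
}

#' Save a configuration to YAML or JSON
#'
#' Round-trips with [load_config()].
#'
#' @param params a `model_params` object.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @param run optional named list of run controls.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path, run = list()) {
  validate_params(params)
  x <- unclass(params)
  x <- x[!vapply(x, is.null, logical(1))]
  x <- c(x, run)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "yml" = , "yaml" = yaml::write_yaml(x, path),
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    abort("config must be .yaml/.yml or .json")
  )
  invisible(path)
}
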