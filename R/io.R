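#' Write a trajectory to a directory of plain-text files
#'
#' Writes `events.tsv` (time_s, kind, position), `snapshots.tsv` (long
#' format: time_s, kind, position), `site_stats.tsv`,
#' `termination_times.tsv`, `initiation_times.tsv`, and `meta.json`
#' (parameters, run controls and seed -- enough to replay the run).
#'
#' @param traj a `peloton_traj`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(traj$events)) {
    readr::write_tsv(dplyr::rename(traj$events, time_s = "time"),
                     file.path(dir, "events.tsv"))
  }
  readr::write_tsv(dplyr::rename(traj$snapshots, time_s = "time"),
                   file.path(dir, "snapshots.tsv"))
  readr::write_tsv(traj$site_stats, file.path(dir, "site_stats.tsv"))
  readr::write_tsv(tibble(time_s = traj$termination_times),
                   file.path(dir, "termination_times.tsv"))
  readr::write_tsv(tibble(time_s = traj$initiation_times),
                   file.path(dir, "initiation_times.tsv"))
  params <- unclass(traj$params)
  params <- params[!vapply(params, is.null, logical(1))]
  meta <- list(params = params,
               run = list(t_max = traj$t_max, burn_in = traj$burn_in,
                          dt_sample = traj$dt_sample, seed = traj$seed,
                          n_events = traj$n_events))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir directory path.
#' @return a `peloton_traj` (without the final state, which is not stored).
#' @export
read_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  params <- do.call(model_params, meta$params[setdiff(names(meta$params), "tau")] |>
                      c(list(tau = meta$params$tau)))
  ev_path <- file.path(dir, "events.tsv")
  events <- if (file.exists(ev_path)) {
    readr::read_tsv(ev_path, show_col_types = FALSE) |>
      dplyr::rename(time = "time_s") |>
      dplyr::mutate(kind = factor(.data$kind, levels = c("step", "initiate",
                                                         "terminate", "bind")))
  } else NULL
  snapshots <- readr::read_tsv(file.path(dir, "snapshots.tsv"),
                               show_col_types = FALSE) |>
    dplyr::rename(time = "time_s") |>
    dplyr::mutate(kind = factor(.data$kind, levels = c("motor", "roadblock")))
  out <- list(
    params = params, events = events, snapshots = snapshots,
    snapshot_times = unique(snapshots$time),
    site_stats = readr::read_tsv(file.path(dir, "site_stats.tsv"),
                                 show_col_types = FALSE),
    initiation_times = readr::read_tsv(file.path(dir, "initiation_times.tsv"),
                                       show_col_types = FALSE)$time_s,
    termination_times = readr::read_tsv(file.path(dir, "termination_times.tsv"),
                                        show_col_types = FALSE)$time_s,
    final_state = NULL,
    t_max = meta$run$t_max, burn_in = meta$run$burn_in,
    dt_sample = meta$run$dt_sample, seed = meta$run$seed,
    n_events = meta$run$n_events
  )
  class(out) <- "peloton_traj"
  out
}

#' Write a kymograph as CSV plus a JSON sidecar
#'
#' The matrix is written as an integer CSV (rows = time bins, columns =
#' lattice sites, codes 0/1/2 = empty/roadblock/motor); bin metadata goes
#' to `<path>.json`.
#'
#' @param kymo a `peloton_kymo`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  utils::write.table(kymo$matrix, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(t0 = kymo$t0, t1 = kymo$t1, dt_bin = kymo$dt_bin,
                            L = kymo$L, codes = list(empty = 0, roadblock = 1,
                                                     motor = 2)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a profile column as bedGraph-style text
#'
#' Four columns (chrom, start, end, value), 0-based half-open, suitable
#' for genome-browser-style visualization of density/velocity profiles.
#'
#' @param profile tibble from [estimate_profiles()].
#' @param path output path.
#' @param column profile column to export.
#' @param chrom chromosome/track name for the first column.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(profile, path, column = "rho_m", chrom = "lattice") {
  stopifnot(column %in% names(profile))
  step <- if (nrow(profile) > 1) diff(profile$x[1:2]) else 1
  df <- tibble(chrom = chrom, start = as.integer(profile$x),
               end = as.integer(profile$x + step),
               value = profile[[column]])
  df <- df[is.finite(df$value), ]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
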