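# Output writers: metrics/track CSVs, per-field snapshot CSVs and the
# JSON run manifest.

#' Write all artifacts of a hybrid run
#'
#' Writes `metrics.csv` (long format, unit-suffixed columns),
#' `tracks.csv`, one `snapshots/<field>_<index>.csv` per field and
#' snapshot (columns `r`, `theta`, `value`), and `manifest.json`
#' carrying the full configuration, seed and runtime, so the run can be
#' replayed bit-exactly. Files are written to a temporary name and
#' renamed into place; an existing non-empty directory is refused unless
#' `force = TRUE`.
#'
#' @param result [run_hybrid()] output
#' @param out_dir output directory (created if missing)
#' @param force overwrite an existing non-empty directory
#' @return invisibly, the vector of files written
#' @export
write_outputs <- function(result, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory ", out_dir,
         " exists and is not empty (use force = TRUE)", call. = FALSE)
  dir.create(file.path(out_dir, "snapshots"), recursive = TRUE,
             showWarnings = FALSE)
  written <- character()
  put_csv <- function(df, path) {
    tmp <- paste0(path, ".tmp")
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
    file.rename(tmp, path)
    written <<- c(written, path)
  }

  m <- result$metrics
  metrics_out <- data.frame(
    t_s = m$t, day = m$day, r_front_cm = m$r_front,
    L_ring_um = m$L_ring * 1e4, L_finger_um = m$L_finger * 1e4,
    L_overall_um = m$L_overall * 1e4, area_um2 = m$area * 1e8,
    pattern = m$pattern)
  put_csv(metrics_out, file.path(out_dir, "metrics.csv"))
  put_csv(result$tracks, file.path(out_dir, "tracks.csv"))

  grid <- result$manifest$config$grid
  r <- grid_radii(grid)
  for (s in seq_along(result$snapshots)) {
    st <- result$snapshots[[s]]
    nth <- ncol(st$Cp)
    theta <- if (nth == 1) 0 else (seq_len(nth) - 0.5) * grid_dtheta(grid)
    for (f in c("Cp", "n", "M", "f")) {
      df <- data.frame(r = rep(r, nth),
                       theta = rep(theta, each = length(r)),
                       value = as.vector(st[[f]]))
      put_csv(df, file.path(out_dir, "snapshots",
                            sprintf("%s_%03d.csv", f, s - 1)))
    }
  }

  manifest <- list(
    package = "tumorHDC",
    version = as.character(utils::packageVersion("tumorHDC")),
    seed = result$manifest$seed, dt_s = result$manifest$dt,
    r_front0_cm = result$manifest$r_front0,
    n_agents = result$manifest$n_agents,
    runtime_s = result$manifest$runtime_s,
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass_config(result$manifest$config))
  tmp <- file.path(out_dir, "manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  written <- c(written, file.path(out_dir, "manifest.json"))
  invisible(written)
}

unclass_config <- function(cfg) {
  lapply(unclass(cfg), function(sec) lapply(unclass(sec), identity))
}

#' Rebuild a configuration from a run manifest
#'
#' @param path `manifest.json` written by [write_outputs()]
#' @return the [hdc_config()] the run used; replaying it through
#'   [run_hybrid()] with the recorded seed reproduces the run
#' @export
config_from_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- man$config
  as_list <- function(x) {
    x <- as.list(x)
    x[!vapply(x, is.null, logical(1))]
  }
  grid <- as_list(cfg$grid)
  if (is.null(cfg$grid$dt)) grid["dt"] <- list(NULL)
  hdc_config(
    params = do.call(hdc_params, as_list(cfg$params)),
    boundary = do.call(hdc_boundary, as_list(cfg$boundary)),
    initial = do.call(hdc_initial,
                      as_list(cfg$initial)[names(as_list(cfg$initial)) !=
                                             "m_init"]),
    grid = do.call(hdc_grid, grid),
    hybrid = do.call(hdc_hybrid, as_list(cfg$hybrid)),
    synth = do.call(synth_spec, as_list(cfg$synth)))
}
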