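# Orchestration of the coupled simulation: continuum stepping with
# periodic shedding and walking of discrete cells, snapshotting and
# invasion metrics.

#' Run the coupled hybrid discrete-continuum simulation
#'
#' Interleaves the explicit continuum march with discrete-cell coupling
#' events: every `agent_stride` continuum steps the ring front sheds new
#' agents (probability proportional to local cell density and collagen
#' gradient) and all live agents take one walk step against the current
#' collagen field. Snapshots, agent tracks and invasion metrics are
#' recorded `snapshots_per_day` times per simulated day. All randomness
#' flows from `config$hybrid$seed` (or the `seed` argument), so a rerun
#' with the same configuration is bit-identical.
#'
#' @param config [hdc_config()]
#' @param seed overrides `config$hybrid$seed` if given
#' @param detail keep per-snapshot field states and agent tracks; with
#'   `FALSE` only the metrics time series, the final state and the final
#'   agents are retained (used by sweeps and calibration, where storing
#'   every snapshot would dominate the runtime)
#' @return an object of class `hdc_sim`: `snapshots` (list of
#'   `continuum_state`), `agents` (final agent table), `tracks`
#'   (`time_s`, `agent_id`, `r_cm`, `theta_rad`, `alive` at every
#'   snapshot), `metrics` (one row per snapshot, lengths in cm, plus
#'   `day`), and `manifest`
#' @export
run_hybrid <- function(config, seed = NULL, detail = TRUE) {
  validate_config(config)
  g <- config$grid
  hy <- config$hybrid
  if (is.null(seed)) seed <- hy$seed
  set.seed(seed)
  params <- config$params
  bc <- config$boundary
  dt0 <- resolve_dt(g, params)
  dr <- g$R / g$n_r

  # integer coupling events per snapshot; dt shrinks (never grows) so
  # the run lands exactly on t_end
  n_snap <- max(1L, as.integer(round(hy$snapshots_per_day *
                                       g$t_end / 86400)))
  events_per_snap <- max(1L, ceiling(
    g$t_end / dt0 / hy$agent_stride / n_snap))
  dt <- g$t_end / (events_per_snap * n_snap * hy$agent_stride)

  state <- init_state(config)
  agents <- make_agents()
  r_front0 <- ring_front_radius(state$Cp, g, hy$front_alpha)

  snap_track <- function(state, agents) {
    if (nrow(agents) == 0)
      return(data.frame(time_s = numeric(), agent_id = integer(),
                        r_cm = numeric(), theta_rad = numeric(),
                        alive = logical()))
    data.frame(time_s = state$t, agent_id = agents$id,
               r_cm = agent_radius(agents, g),
               theta_rad = (agents$k + 0.5) * grid_dtheta(g),
               alive = agents$alive)
  }

  snapshots <- if (detail) vector("list", n_snap + 1) else list()
  if (detail) snapshots[[1]] <- state
  metrics <- compute_metrics(state, agents, g, r_front0, hy$front_alpha,
                             hy$pattern_margin)
  tracks <- if (detail) snap_track(state, agents) else NULL
  t0 <- Sys.time()

  for (s in seq_len(n_snap)) {
    res <- cpp_hybrid_block(
      state$Cp, state$n, state$M, state$f, par_vec(params), bc$c_bc,
      bc$n0, bc$m0, if (bc$cell_bc == "zero_flux") 1L else 0L, dr,
      grid_dtheta(g), dt, agents$j, agents$k, as.integer(agents$alive),
      agents$age, g$n_theta, hy$shed_rate, hy$shed_base, hy$front_alpha,
      config$initial$f0, g$R, hy$max_agents, events_per_snap,
      hy$agent_stride)
    state$Cp <- res$Cp; state$n <- res$n; state$M <- res$M
    state$f <- res$f
    state$t <- state$t + events_per_snap * hy$agent_stride * dt
    agents <- make_agents(res$j, res$k, res$age, as.logical(res$alive))
    if (detail) snapshots[[s + 1]] <- state
    metrics <- rbind(metrics,
                     compute_metrics(state, agents, g, r_front0,
                                     hy$front_alpha, hy$pattern_margin))
    if (detail) tracks <- rbind(tracks, snap_track(state, agents))
  }
  if (!detail) snapshots <- list(state)

  metrics$day <- metrics$t / 86400
  structure(list(
    snapshots = snapshots, agents = agents, tracks = tracks,
    metrics = metrics,
    manifest = list(config = config, seed = seed, dt = dt,
                    r_front0 = r_front0,
                    n_agents = nrow(agents),
                    runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")))),
    class = "hdc_sim")
}

#' Sweep collagenase doses with replicate runs
#'
#' One hybrid run per dose and replicate. Replicates differ only by
#' seed (`seed_rep = root_seed + 1000 * (replicate - 1)`), so the same
#' replicate index shares its random stream across doses. Doses in
#' mg/mL are converted to the molar boundary value via
#' [dose_to_molar()]. A failed run is flagged in the output and the
#' sweep continues.
#'
#' @param config [hdc_config()]
#' @param doses collagenase doses (mg/mL)
#' @param replicates replicate count per dose
#' @param days optionally restrict the returned rows to these days
#' @param detail passed to [run_hybrid()]; sweeps default to the light
#'   mode since only the metrics table is returned
#' @return tidy long-format `data.frame`: `run_id`, `dose_mg_per_ml`,
#'   `replicate`, `day`, `L_ring_um`, `L_finger_um`, `L_overall_um`,
#'   `area_um2`, `pattern`, `ok`
#' @export
sweep_collagenase <- function(config, doses, replicates = 3, days = NULL,
                              detail = FALSE) {
  stopifnot(all(doses >= 0), replicates >= 1)
  root <- config$hybrid$seed
  out <- list()
  for (d in seq_along(doses)) {
    cfg <- config
    cfg$boundary$m0 <- dose_to_molar(doses[d], config$params$molar_mass)
    for (rep in seq_len(replicates)) {
      run_id <- sprintf("dose%g_rep%d_run%d", doses[d], rep, d)
      sim <- tryCatch(run_hybrid(cfg, seed = root + 1000L * (rep - 1L),
                                 detail = detail),
                      error = function(e) e)
      if (inherits(sim, "error")) {
        out[[length(out) + 1]] <- data.frame(
          run_id = run_id, dose_mg_per_ml = doses[d], replicate = rep,
          day = NA_real_, L_ring_um = NA_real_, L_finger_um = NA_real_,
          L_overall_um = NA_real_, area_um2 = NA_real_,
          pattern = NA_character_, ok = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      m <- sim$metrics
      out[[length(out) + 1]] <- data.frame(
        run_id = run_id, dose_mg_per_ml = doses[d], replicate = rep,
        day = m$day, L_ring_um = m$L_ring * 1e4,
        L_finger_um = m$L_finger * 1e4, L_overall_um = m$L_overall * 1e4,
        area_um2 = m$area * 1e8, pattern = m$pattern, ok = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(days))
    res <- res[is.na(res$day) | round(res$day, 6) %in% days, ]
  rownames(res) <- NULL
  res
}
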