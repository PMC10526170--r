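# Synthetic chip-experiment generator and the degradation-rate
# calibration harness.

#' Specification of a synthetic tumoroid-invasion experiment
#'
#' Encodes the design of the perfused-chip experiment: collagenase doses
#' applied through the surrounding channel, daily invasion-length
#' measurements over three days, and a small number of replicate
#' tumoroids per condition. The mean invasion curve is a Hill time
#' course with a dose-dependent time constant,
#' `L(dose, day) = plateau(dose) * day^h / (day^h + tau(dose)^h)`,
#' where `plateau` rises with dose but saturates between the two treated
#' doses (`g_L(dose) = dose/(dose + k_plateau)`) and
#' `tau(dose) = tau0 * (1 - tau_drop * dose/(dose + k_tau))` shortens
#' with dose, so treated tumoroids invade earlier but converge to nearly
#' the same plateau. This reproduces the observed significance
#' structure: no difference at day 0, a clear 0.01 vs 0.001 mg/mL
#' difference at day 1, and treated above untreated but 0.01 ~ 0.001 at
#' day 3. Noise is multiplicative lognormal with coefficient of
#' variation `cv`; day-0 measurements are an additive instrument floor.
#'
#' @param doses collagenase doses in mg/mL
#' @param days measurement days
#' @param replicates tumoroids per condition (>= 2)
#' @param base_length mean day-3 invasion length of the untreated
#'   condition (um)
#' @param dose_gain plateau gain at saturating dose
#' @param k_plateau dose scale of the plateau response (mg/mL)
#' @param tau0 untreated invasion time constant (days)
#' @param tau_drop maximal fractional shortening of `tau` with dose
#' @param k_tau dose scale of the time-constant response (mg/mL)
#' @param hill Hill exponent of the time course
#' @param cv coefficient of variation of the lognormal noise, in (0, 1)
#' @param day0_sd additive day-0 noise floor (um)
#' @param seed root seed
#' @return an object of class `synth_spec`
#' @export
synth_spec <- function(doses = c(0, 0.001, 0.01), days = 0:3,
                       replicates = 3, base_length = 300,
                       dose_gain = 1.5, k_plateau = 5e-6,
                       tau0 = 2, tau_drop = 0.7, k_tau = 1e-3,
                       hill = 6, cv = 0.15, day0_sd = 3, seed = 1L) {
  obj <- structure(list(doses = as.numeric(doses), days = as.numeric(days),
                        replicates = as.integer(replicates),
                        base_length = base_length, dose_gain = dose_gain,
                        k_plateau = k_plateau, tau0 = tau0,
                        tau_drop = tau_drop, k_tau = k_tau, hill = hill,
                        cv = cv, day0_sd = day0_sd,
                        seed = as.integer(seed)),
                   class = "synth_spec")
  e <- character()
  e <- fail_if(obj$replicates < 2, "replicates: must be >= 2", e)
  e <- fail_if(!(obj$cv > 0 && obj$cv < 1), "cv: must lie in (0, 1)", e)
  e <- fail_if(any(obj$doses < 0), "doses: must be >= 0", e)
  e <- fail_if(any(obj$days < 0), "days: must be >= 0", e)
  if (length(e)) stop("invalid synthetic-experiment spec:\n  ",
                      paste(e, collapse = "\n  "), call. = FALSE)
  obj
}

#' Mean invasion length of the synthetic model
#'
#' The noise-free mean curve of [generate_experiment()].
#'
#' @param spec [synth_spec()]
#' @param dose dose in mg/mL (vectorized)
#' @param day day (vectorized)
#' @return mean invasion length (um)
#' @export
synth_mean_length <- function(spec, dose, day) {
  g_l <- dose / (dose + spec$k_plateau)
  g_t <- dose / (dose + spec$k_tau)
  tau <- spec$tau0 * (1 - spec$tau_drop * g_t)
  h <- spec$hill
  norm <- 3^h / (3^h + spec$tau0^h)  # untreated day-3 reference
  spec$base_length * (1 + spec$dose_gain * g_l) / (1 + 0) *
    (day^h / (day^h + tau^h)) / norm
}

#' Generate a synthetic tumoroid-invasion dataset
#'
#' Draws `replicates` invasion-length measurements per dose and day from
#' the mean curve of [synth_mean_length()] with multiplicative lognormal
#' noise (`sdlog` chosen so the expectation equals the mean curve and
#' the coefficient of variation is `spec$cv`). Day-0 rows are an
#' additive half-normal instrument floor of scale `day0_sd`. The invaded
#' area is reported as the annulus `pi*((r0 + L)^2 - r0^2)` around a
#' nominal 200 um tumoroid radius. Deterministic given `spec$seed`.
#'
#' @param spec [synth_spec()]
#' @param seed overrides `spec$seed` if given
#' @return long-format `data.frame`: `dose`, `day`, `replicate`,
#'   `invasion_length` (um), `invasion_area` (um^2), with the spec and
#'   seed attached as attributes `spec` and `seed`
#' @export
generate_experiment <- function(spec = synth_spec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  grid <- expand.grid(replicate = seq_len(spec$replicates),
                      day = spec$days, dose = spec$doses)
  grid <- grid[, c("dose", "day", "replicate")]
  mu <- synth_mean_length(spec, grid$dose, grid$day)
  noise <- stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  len <- mu * noise
  floor_idx <- grid$day == 0
  len[floor_idx] <- abs(stats::rnorm(sum(floor_idx), 0, spec$day0_sd))
  r0 <- 200
  out <- data.frame(grid, invasion_length = len,
                    invasion_area = pi * ((r0 + len)^2 - r0^2))
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

#' Extract metrics rows nearest to the requested days
#'
#' Snapshot times are integer multiples of the coupling block, so they
#' need not fall exactly on whole days; this picks, per run, the
#' snapshot nearest each requested day and relabels it.
#'
#' @param tbl output of [sweep_collagenase()]
#' @param days requested days
#' @return the matched subset with `day` set to the requested values and
#'   the original snapshot day in `day_actual`
#' @export
metrics_at_days <- function(tbl, days) {
  out <- list()
  for (id in unique(tbl$run_id)) {
    sub <- tbl[tbl$run_id == id & !is.na(tbl$day), , drop = FALSE]
    if (!nrow(sub)) next
    for (d in days) {
      row <- sub[which.min(abs(sub$day - d)), , drop = FALSE]
      row$day_actual <- row$day
      row$day <- d
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the chip experiment with the hybrid model
#'
#' Runs the hybrid simulator over the dose grid (via
#' [sweep_collagenase()]), reads the overall invasion length at the
#' requested days and applies multiplicative lognormal measurement noise
#' — the simulator-side counterpart of [generate_experiment()], used for
#' parameter-recovery studies.
#'
#' @param config [hdc_config()] (its `hybrid$seed` is the simulation
#'   root seed)
#' @param doses doses in mg/mL
#' @param days measurement days
#' @param replicates replicates per dose
#' @param cv measurement noise coefficient of variation (0 disables)
#' @param noise_seed seed of the measurement-noise stream (kept separate
#'   from the simulation stream so the same runs can be re-measured)
#' @return long table: `dose`, `day`, `replicate`, `invasion_length`
#'   (um)
#' @export
simulate_experiment <- function(config, doses, days = 1:3, replicates = 2,
                                cv = 0.15, noise_seed = 1L) {
  sw <- sweep_collagenase(config, doses, replicates)
  m <- metrics_at_days(sw, days)
  set.seed(noise_seed)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- if (cv > 0)
    stats::rlnorm(nrow(m), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  else rep(1, nrow(m))
  data.frame(dose = m$dose_mg_per_ml, day = m$day,
             replicate = m$replicate,
             invasion_length = m$L_overall_um * noise)
}

#' Scaled-down configuration for parameter-recovery studies
#'
#' The calibration loop runs hundreds of hybrid simulations, so recovery
#' studies use a coarser radial grid (`n_r = 48`), a longer coupling
#' stride, and a higher shedding intensity with a raised agent cap (many
#' invading cells make the overall invasion length — a maximum statistic
#' — concentrate, which is what makes the calibration observable
#' usable). Everything else matches the package defaults.
#'
#' @param seed root seed of the configuration
#' @return an [hdc_config()]
#' @export
recovery_config <- function(seed = 1L) {
  hdc_config(grid = hdc_grid(n_r = 48),
             hybrid = hdc_hybrid(seed = as.integer(seed),
                                 shed_rate = 5000, max_agents = 4000))
}

#' Fit the collagen degradation rate from invasion curves
#'
#' Calibrates `delta` (or a scale factor on the boundary collagenase
#' concentration) by minimizing the squared error between observed
#' invasion-length means and hybrid-model predictions over a bounded
#' 1-D search on the log scale: a coarse grid followed by two zoom
#' stages, each re-gridding one coarse interval around the incumbent
#' minimum (final resolution about 4% of the value). Predictions reuse
#' the configuration's root seed, so when the data were produced by
#' [simulate_experiment()] with the same configuration the objective
#' compares like with like (common random numbers). The untreated dose
#' carries no information about `delta` and is ignored; a dataset with
#' no treated dose, or an objective that is flat across the search
#' range, raises a non-identifiability error. The confidence interval
#' bootstraps replicates within each dose/day cell and re-minimizes
#' over all cached prediction curves.
#'
#' @param dataset long table with `dose`, `day`, `replicate`,
#'   `invasion_length` (um) — from [simulate_experiment()] or real
#'   measurements
#' @param config [hdc_config()] describing the simulator used for
#'   predictions
#' @param free_param `"delta"` or `"m0_scale"`
#' @param lower,upper search bounds (on the free parameter)
#' @param n_grid log-grid resolution
#' @param n_boot bootstrap resamples (0 skips the interval)
#' @return list: `estimate`, `ci` (2.5/97.5 percentiles), `free_param`,
#'   `objective` (`data.frame` of grid values and SSE), `n_runs`
#' @export
fit_degradation_rate <- function(dataset, config,
                                 free_param = c("delta", "m0_scale"),
                                 lower = 1e-4, upper = 1, n_grid = 9,
                                 n_boot = 200) {
  free_param <- match.arg(free_param)
  doses <- sort(unique(dataset$dose[dataset$dose > 0]))
  if (length(doses) == 0)
    stop("non-identifiable: no treated dose in the dataset (the ",
         "degradation rate has no effect without enzyme)", call. = FALSE)
  days <- sort(unique(dataset$day))
  if (length(days) < 2)
    stop("need data at >= 2 days", call. = FALSE)
  reps <- max(dataset$replicate)

  obs <- stats::aggregate(invasion_length ~ dose + day,
                          data = dataset[dataset$dose > 0, ], FUN = mean)

  predict_curve <- function(value) {
    cfg <- config
    if (free_param == "delta") cfg$params$delta <- value
    else cfg$boundary$m0 <- cfg$boundary$m0 * value
    sw <- sweep_collagenase(cfg, doses, reps)
    m <- metrics_at_days(sw, days)
    stats::aggregate(L_overall_um ~ dose_mg_per_ml + day, data = m,
                     FUN = mean)
  }

  cache_vals <- numeric()
  cache_preds <- list()
  evaluate <- function(vals) {
    new <- setdiff(vals, cache_vals)
    for (v in new) {
      cache_preds[[length(cache_preds) + 1]] <<- predict_curve(v)
      cache_vals[length(cache_vals) + 1] <<- v
    }
  }
  sse_against <- function(obs_means) {
    vapply(cache_preds, function(p) {
      key_p <- paste(p$dose_mg_per_ml, p$day)
      key_o <- paste(obs_means$dose, obs_means$day)
      sum((obs_means$invasion_length - p$L_overall_um[match(key_o,
                                                            key_p)])^2)
    }, numeric(1))
  }
  argmin <- function(sse) cache_vals[which.min(sse)]

  # stage 1: coarse log grid; stages 2-3 re-grid one interval around
  # the incumbent minimum
  lv <- log(c(lower, upper))
  grid1 <- exp(seq(lv[1], lv[2], length.out = n_grid))
  step1 <- (lv[2] - lv[1]) / (n_grid - 1)
  evaluate(grid1)
  sse <- sse_against(obs)
  if (diff(range(sse)) <= 1e-9 * max(max(sse), 1))
    stop("non-identifiable: objective is flat across the search range",
         call. = FALSE)
  step <- step1
  for (stage in 1:3) {
    ctr <- log(argmin(sse_against(obs)))
    step <- step / 3
    zoom <- exp(seq(max(lv[1], ctr - 3 * step),
                    min(lv[2], ctr + 3 * step), by = step))
    evaluate(zoom)
    sse <- sse_against(obs)
  }
  estimate <- argmin(sse)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    cells <- split(seq_len(nrow(dataset)),
                   paste(dataset$dose, dataset$day))
    boots <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(cells, function(i)
        i[sample.int(length(i), replace = TRUE)]))
      dsb <- dataset[idx, , drop = FALSE]
      obs_b <- stats::aggregate(invasion_length ~ dose + day,
                                data = dsb[dsb$dose > 0, ], FUN = mean)
      boots[b] <- argmin(sse_against(obs_b))
    }
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  }

  ord <- order(cache_vals)
  list(estimate = estimate, ci = ci, free_param = free_param,
       objective = data.frame(value = cache_vals[ord], sse = sse[ord]),
       n_runs = length(cache_vals) * length(doses) * reps)
}
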