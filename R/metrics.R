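# Quantification of ring- and finger-type invasion, and the two-group
# comparison used on synthetic experiment tables.

#' Ring-front radius of a cell field
#'
#' The angular-mean radial profile of `Cp` is scanned from the outside
#' in; the front is the largest radius at which the profile reaches
#' `alpha` times its maximum, with linear sub-cell interpolation of the
#' threshold crossing (so slow front motion is resolved below the grid
#' spacing).
#'
#' @param Cp_field cell matrix (`n_r` x 1 or `n_r` x `n_theta`)
#' @param grid [hdc_grid()]
#' @param alpha front threshold fraction in (0, 1]
#' @return front radius in cm
#' @export
ring_front_radius <- function(Cp_field, grid, alpha = 0.05) {
  prof <- rowMeans(as.matrix(Cp_field))
  m <- max(prof)
  if (m <= 0) stop("all-zero cell field: no front", call. = FALSE)
  thr <- alpha * m
  r <- grid_radii(grid)
  idx <- which(prof >= thr)
  j <- max(idx)
  if (j == length(prof)) return(r[j])
  # interpolate the crossing between node j (>= thr) and j+1 (< thr)
  f1 <- prof[j]; f2 <- prof[j + 1]
  if (f1 == f2) return(r[j])
  r[j] + (r[j + 1] - r[j]) * (f1 - thr) / (f1 - f2)
}

#' Invasion metrics of a simulation state
#'
#' Computes the ring invasion length `L_ring = r_front(t) - r_front(0)`,
#' the finger length `L_finger = max(live agent radius) - r_front(0)`
#' (defaulting to `L_ring` when no live agent lies beyond the front, so
#' the overall length is always defined), the overall length
#' `L_overall = max(L_ring, L_finger)`, the invaded area
#' `pi * (r_front^2 - r_front0^2)` plus one local grid-cell area per
#' agent beyond the front, and a pattern label: `"finger"` when
#' `L_finger - L_ring` exceeds `margin * r_front0`, `"ring"` when no
#' agent leads the front, `"mixed"` otherwise.
#'
#' @param state [init_state()]
#' @param agents [make_agents()]
#' @param grid [hdc_grid()]
#' @param r_front0 front radius recorded at t = 0 (cm)
#' @param alpha front threshold fraction
#' @param margin pattern labelling margin (fraction of `r_front0`)
#' @return a one-row `data.frame` with columns `t`, `r_front`, `L_ring`,
#'   `L_finger`, `L_overall`, `area`, `pattern` (lengths in cm, area in
#'   cm^2)
#' @export
compute_metrics <- function(state, agents, grid, r_front0, alpha = 0.05,
                            margin = 0.1) {
  r_front <- ring_front_radius(state$Cp, grid, alpha)
  L_ring <- r_front - r_front0
  live <- agents[agents$alive, , drop = FALSE]
  rl <- agent_radius(live, grid)
  lead <- rl[rl > r_front]
  dr <- grid$R / grid$n_r
  dth <- grid_dtheta(grid)
  if (length(lead)) {
    L_finger <- max(rl) - r_front0
    area_agents <- sum(lead * dr * dth)
  } else {
    L_finger <- L_ring
    area_agents <- 0
  }
  L_overall <- max(L_ring, L_finger)
  pattern <- if (!length(lead)) "ring" else
    if (L_finger - L_ring > margin * r_front0) "finger" else "mixed"
  data.frame(t = state$t, r_front = r_front, L_ring = L_ring,
             L_finger = L_finger, L_overall = L_overall,
             area = pi * (r_front^2 - r_front0^2) + area_agents,
             pattern = pattern, stringsAsFactors = FALSE)
}

# Exact one/two-sided permutation p-value for a difference in means.
perm_test <- function(x, y, alternative) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  stat_obs <- mean(x) - mean(y)
  stats_all <- apply(idx, 2, function(i)
    mean(pooled[i]) - mean(pooled[-i]))
  eps <- 1e-12 * (abs(stat_obs) + max(abs(stats_all)))
  p <- switch(alternative,
    greater   = mean(stats_all >= stat_obs - eps),
    less      = mean(stats_all <= stat_obs + eps),
    two.sided = mean(abs(stats_all) >= abs(stat_obs) - eps))
  list(statistic = stat_obs, p.value = p, n_perm = ncol(idx))
}

#' Compare invasion lengths between two conditions
#'
#' Two-group comparison of a metric at a given day. With five or fewer
#' replicates per group the exact permutation distribution of the
#' difference in means is enumerated (granularity `1/choose(na+nb, na)`,
#' so at n = 3 the smallest one-sided p-value is 1/20); with more
#' replicates a Welch two-sample t-test is used. Dose-ordering hypotheses
#' are directional, so `alternative = "greater"` tests whether
#' `group_b` exceeds `group_a`.
#'
#' @param metrics_table long-format table with columns `dose`, `day`,
#'   and the metric (see [generate_experiment()] and
#'   [sweep_collagenase()])
#' @param group_a,group_b dose values selecting the two groups
#' @param day measurement day to compare at
#' @param metric column name to compare (default `invasion_length`)
#' @param alternative `"greater"` (is b > a), `"less"` or `"two.sided"`
#' @return list with `statistic` (mean(b) - mean(a)), `p.value`, `method`
#' @export
compare_conditions <- function(metrics_table, group_a, group_b, day,
                               metric = "invasion_length",
                               alternative = c("greater", "less",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  sel <- metrics_table$day == day
  a <- metrics_table[[metric]][sel & metrics_table$dose == group_a]
  b <- metrics_table[[metric]][sel & metrics_table$dose == group_b]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicates per group (got ", length(a), " and ",
         length(b), ")", call. = FALSE)
  if (max(length(a), length(b)) <= 5) {
    res <- perm_test(b, a, alternative)
    list(statistic = res$statistic, p.value = res$p.value,
         method = sprintf("exact permutation test (%d arrangements)",
                          res$n_perm))
  } else {
    tt <- stats::t.test(b, a, alternative = alternative, var.equal = FALSE)
    list(statistic = mean(b) - mean(a), p.value = unname(tt$p.value),
         method = "Welch two-sample t-test")
  }
}
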