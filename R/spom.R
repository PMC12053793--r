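# Spatially explicit stochastic patch-occupancy model (SPOM): a 1-D
# coastline of 5 x 5 m plots whose habitat, occupancy and abundance
# evolve by per-generation Bernoulli transitions. It generates
# two-snapshot survey datasets with the statistical structure the
# analysis assumes, with known ground truth for recovery tests.

#' Configuration for the patch-occupancy simulator
#'
#' Defaults emulate a 938 km coastline of 3500 plots surveyed twice,
#' three years (two generations) apart, in the crude-rate regime of a
#' coastal dune plant metapopulation: roughly one fifth of suitable
#' vacant plots colonised and one third of occupied plots going extinct
#' per interval, with habitat amount, local abundance and occupancy all
#' declining toward the range limit.
#'
#' Distance \code{d} below is the along-coast distance to the range
#' limit in km (0 at the limit). Model components:
#' \itemize{
#' \item habitat: suitable area drawn from a censored normal with mean
#'   \code{area_mean_core - area_decline_per_km * (coast_length_km - d)}
#'   and sd \code{area_sd}, clamped to [0, 25] m^2;
#' \item habitat dynamics: per generation a suitable plot loses its
#'   habitat to each cause (succession, wind, driftwood, water) with
#'   probability \code{invlogit(int + slope * d)}; several causes can
#'   strike together; an unsuitable plot recovers with probability
#'   \code{p_recover}, redrawing its area from the habitat model;
#' \item colonisation: a vacant suitable plot is colonised with
#'   probability \code{invlogit(col_int + col_area * A +
#'   col_local * log10(L + 1))} where \code{A} is its suitable area and
#'   \code{L} the mean abundance of all other plots within
#'   \code{radius_m};
#' \item extinction: an occupied plot goes extinct with probability
#'   \code{invlogit(ext_int - ext_abund * log10(N + 1) - ext_area * A)};
#'   extinction is certain if the plot's habitat was lost;
#' \item abundance: occupied plots redraw their count from a rounded
#'   lognormal whose median declines toward the limit,
#'   \code{abund_median_limit * exp(abund_log_slope * d)}, sdlog
#'   \code{abund_sdlog}.
#' }
#'
#' @param n_plots Number of plots along the coast.
#' @param coast_length_km Coastline length (km); the limit sits at 0.
#' @param generations Generations between the two survey snapshots.
#' @param burn_in Generations run before the first snapshot.
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the config.
#' @param init_occupancy Initial occupancy probability of suitable plots.
#' @param radius_m Local-abundance neighbourhood radius (m).
#' @param y_jitter_m Cross-shore plot jitter (m); kept small so the
#'   neighbourhood is effectively one-dimensional along the coast.
#' @param area_mean_core,area_decline_per_km,area_sd Habitat model.
#' @param succ_int,succ_slope,wind_int,wind_slope,drift_int,drift_slope,water_int,water_slope
#'   Cause-specific habitat-loss logits (intercept, per-km slope).
#' @param p_recover Per-generation recovery probability.
#' @param col_int,col_area,col_local Colonisation logit coefficients.
#' @param ext_int,ext_abund,ext_area Extinction logit coefficients
#'   (\code{ext_abund}, \code{ext_area} entered with negative sign).
#' @param abund_median_limit,abund_log_slope,abund_sdlog Abundance model.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_plots = 3500L,
                       coast_length_km = 938,
                       generations = 2L,
                       burn_in = 30L,
                       seed = 1L,
                       init_occupancy = 0.35,
                       radius_m = 500,
                       y_jitter_m = 200,
                       area_mean_core = 4.7,
                       area_decline_per_km = 0.0048,
                       area_sd = 4.5,
                       succ_int = -3.2, succ_slope = -0.0006,
                       wind_int = -4.2, wind_slope = 0.0004,
                       drift_int = -6.0, drift_slope = 0,
                       water_int = -6.6, water_slope = 0,
                       p_recover = 0.05,
                       col_int = -2.6, col_area = 0.093, col_local = 0.73,
                       ext_int = -1.15, ext_abund = 0.81, ext_area = 0.047,
                       abund_median_limit = 1.2,
                       abund_log_slope = 0.0026,
                       abund_sdlog = 1.0) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_plots < 1L) stop_mr("n_plots must be positive")
  if (cfg$coast_length_km <= 0) stop_mr("coast_length_km must be positive")
  if (cfg$generations < 1L) stop_mr("generations must be >= 1")
  if (cfg$p_recover < 0 || cfg$p_recover > 1)
    stop_mr("p_recover must be a probability")
  if (cfg$init_occupancy < 0 || cfg$init_occupancy > 1)
    stop_mr("init_occupancy must be a probability")
  lim_mean <- cfg$area_mean_core -
    cfg$area_decline_per_km * cfg$coast_length_km
  if (lim_mean < 0)
    stop_mr(paste("habitat gradient implies negative mean suitable area",
                  "at the limit (%.3f m^2); lower area_decline_per_km"),
            lim_mean)
  invisible(cfg)
}

#' Read a simulator configuration from YAML
#'
#' Fields are passed to [sim_config()]; unspecified fields keep their
#' defaults, unknown fields are an error.
#'
#' @param path YAML file path.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_mr("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop_mr("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

area_mean_at <- function(d_km, cfg) {
  cfg$area_mean_core -
    cfg$area_decline_per_km * (cfg$coast_length_km - d_km)
}

# censored-normal area draw; point masses at 0 (unsuitable) and 25
draw_area <- function(d_km, cfg) {
  pmin(pmax(stats::rnorm(length(d_km), area_mean_at(d_km, cfg), cfg$area_sd),
            0), 25)
}

# as draw_area but conditioned positive, for recovering plots
draw_area_positive <- function(d_km, cfg) {
  pmax(draw_area(d_km, cfg), 0.25)
}

draw_abundance <- function(d_km, cfg) {
  meanlog <- log(cfg$abund_median_limit) + cfg$abund_log_slope * d_km
  pmax(1L, as.integer(round(stats::rlnorm(length(d_km), meanlog,
                                          cfg$abund_sdlog))))
}

#' Generate the initial simulated landscape
#'
#' Plots are placed uniformly along the coast (with small cross-shore
#' jitter), areas drawn from the declining habitat gradient, and
#' initial occupancy seeded at \code{init_occupancy} among suitable
#' plots. Deterministic given \code{cfg$seed} when called through
#' [simulate_survey_pair()]; call \code{set.seed()} yourself when using
#' it directly.
#'
#' @param cfg A \code{sim_config}.
#' @return A \code{data.frame} simulator state: one row per plot with
#'   position, distance, suitable area, occupancy, abundance, and the
#'   cause memory of the latest habitat loss.
#' @export
generate_landscape <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_plots
  x <- sort(stats::runif(n, 0, cfg$coast_length_km * 1000))
  d_km <- x / 1000
  area <- draw_area(d_km, cfg)
  occupied <- area > 0 & stats::runif(n) < cfg$init_occupancy
  abundance <- integer(n)
  abundance[occupied] <- draw_abundance(d_km[occupied], cfg)
  state <- data.frame(
    plot_id = sprintf("P%05d", seq_len(n)),
    x_m = x,
    y_m = stats::runif(n, -cfg$y_jitter_m, cfg$y_jitter_m),
    dist_km = d_km,
    suitable_area_m2 = area,
    occupied = occupied,
    abundance = abundance,
    stringsAsFactors = FALSE
  )
  state$causes <- replicate(n, character(), simplify = FALSE)
  state
}

cause_probs <- function(d_km, cfg) {
  cbind(succession = invlogit(cfg$succ_int + cfg$succ_slope * d_km),
        wind = invlogit(cfg$wind_int + cfg$wind_slope * d_km),
        driftwood = invlogit(cfg$drift_int + cfg$drift_slope * d_km),
        water = invlogit(cfg$water_int + cfg$water_slope * d_km))
}

#' Advance the simulated metapopulation one generation
#'
#' Event order within a generation: (1) habitat transitions (cause-
#' specific losses, then recovery of unsuitable plots); (2) extinction
#' trials for occupied plots, certain where the habitat was just lost;
#' (3) colonisation trials for vacant suitable plots, with local
#' abundance computed from pre-step abundances; (4) abundance redraw
#' for all occupied plots.
#'
#' @param state Simulator state from [generate_landscape()].
#' @param cfg The \code{sim_config}.
#' @param record Attach the per-plot event probabilities used this
#'   generation as \code{attr(, "record")} (ground truth for tests).
#' @return The updated state.
#' @export
sim_step <- function(state, cfg, record = FALSE) {
  n <- nrow(state)
  d <- state$dist_km
  pre_abund <- state$abundance

  # (1) habitat transitions
  suitable <- state$suitable_area_m2 > 0
  pc <- cause_probs(d, cfg)
  hits <- matrix(stats::runif(n * 4) < pc, n, 4)
  hits[!suitable, ] <- FALSE
  lost <- rowSums(hits) > 0
  if (any(lost)) {
    state$suitable_area_m2[lost] <- 0
    state$causes[lost] <- lapply(which(lost), function(i)
      colnames(pc)[hits[i, ]])
  }
  recover <- !suitable & stats::runif(n) < cfg$p_recover
  if (any(recover)) {
    state$suitable_area_m2[recover] <- draw_area_positive(d[recover], cfg)
    state$causes[recover] <- replicate(sum(recover), character(),
                                       simplify = FALSE)
  }

  # (2) extinction trials (forced where habitat was lost)
  p_ext <- invlogit(cfg$ext_int - cfg$ext_abund * log10p1(state$abundance) -
                      cfg$ext_area * state$suitable_area_m2)
  p_ext[state$suitable_area_m2 == 0] <- 1
  p_ext_occ <- ifelse(state$occupied, p_ext, NA_real_)
  dies <- state$occupied & stats::runif(n) < p_ext

  # (3) colonisation trials for vacant suitable plots, L from pre-step
  # abundances; plots with no neighbour contribute L = 0
  if (cfg$col_local != 0 || record) {
    L <- local_mean(state$x_m, state$y_m, pre_abund, cfg$radius_m)
    L[is.na(L)] <- 0
  } else L <- numeric(n)
  p_col <- invlogit(cfg$col_int + cfg$col_area * state$suitable_area_m2 +
                      cfg$col_local * log10p1(L))
  p_col[state$suitable_area_m2 == 0] <- 0
  p_col_cand <- ifelse(!state$occupied & state$suitable_area_m2 > 0,
                       p_col, NA_real_)
  born <- !state$occupied & stats::runif(n) < p_col

  state$occupied <- (state$occupied & !dies) | born
  state$abundance <- integer(n)

  # (4) abundance redraw for occupied plots
  if (any(state$occupied))
    state$abundance[state$occupied] <-
      draw_abundance(d[state$occupied], cfg)

  if (record)
    attr(state, "record") <- data.frame(p_col = p_col_cand, p_ext = p_ext_occ)
  state
}

state_to_survey <- function(state, year) {
  causes <- state$causes
  causes[state$suitable_area_m2 > 0] <-
    replicate(sum(state$suitable_area_m2 > 0), character(), simplify = FALSE)
  as_survey(data.frame(
    plot_id = state$plot_id,
    year = as.integer(year),
    dist_km = state$dist_km,
    x_m = state$x_m,
    y_m = state$y_m,
    suitable_area_m2 = state$suitable_area_m2,
    abundance = state$abundance,
    stringsAsFactors = FALSE
  ), causes = causes, is_dune = rep(TRUE, nrow(state)))
}

#' Simulate a two-snapshot survey pair with known ground truth
#'
#' Runs the SPOM for \code{burn_in} generations, takes the first
#' snapshot, advances \code{generations} more, and takes the second.
#' The returned truth record carries the generator coefficients and,
#' for each inter-survey generation, the exact per-plot colonisation
#' and extinction probabilities the random draws used. When
#' \code{generations = 1} these are the interval-level event
#' probabilities of the candidate pools, from which
#' [true_event_curves()] computes the generator's true c(d), e(d) and
#' n*(d).
#'
#' @param cfg A \code{sim_config}.
#' @param years Survey-year labels for the two snapshots.
#' @return A list with \code{t1}, \code{t2} (survey \code{data.frame}s
#'   that round-trip through [write_survey()]/[read_survey()]) and
#'   \code{truth} (config, per-generation probability records, final
#'   pre-interval state).
#' @export
simulate_survey_pair <- function(cfg, years = c(2019L, 2022L)) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  state <- generate_landscape(cfg)
  for (g in seq_len(cfg$burn_in)) state <- sim_step(state, cfg)
  if (!any(state$occupied))
    stop_mr(paste("metapopulation went extinct during burn-in;",
                  "raise col_int or lower ext_int"))
  t1 <- state_to_survey(state, years[1])
  records <- vector("list", cfg$generations)
  for (g in seq_len(cfg$generations)) {
    state <- sim_step(state, cfg, record = TRUE)
    records[[g]] <- attr(state, "record")
    attr(state, "record") <- NULL
  }
  t2 <- state_to_survey(state, years[2])
  list(t1 = t1, t2 = t2,
       truth = list(config = unclass(cfg), records = records,
                    dist_km = state$dist_km))
}

#' Ground-truth colonisation, extinction and equilibrium curves
#'
#' For a single-generation simulation interval, fits logistic curves in
#' distance to the exact per-candidate event probabilities recorded by
#' the simulator (a binomial IRLS on fractional responses, i.e. the
#' best logistic-in-distance description of the true probabilities)
#' and returns the implied true equilibrium occupancy
#' \code{c(d) / (c(d) + e(d))}.
#'
#' @param sim Output of [simulate_survey_pair()] run with
#'   \code{generations = 1}.
#' @param grid Distances (km) at which to evaluate the curves; default
#'   200 points spanning the coast.
#' @return A \code{data.frame} with \code{dist_km}, \code{c_true},
#'   \code{e_true}, \code{n_star_true}.
#' @export
true_event_curves <- function(sim, grid = NULL) {
  if (sim$truth$config$generations != 1L)
    stop_mr(paste("exact truth curves are recorded only for",
                  "generations = 1 simulations"))
  rec <- sim$truth$records[[1]]
  d <- sim$truth$dist_km
  if (is.null(grid))
    grid <- seq(0, sim$truth$config$coast_length_km, length.out = 200L)
  fit_curve <- function(p) {
    keep <- !is.na(p)
    X <- cbind(`(Intercept)` = 1, dist_km = d[keep])
    co <- irls_fit(X, p[keep], "binomial")$coefficients
    invlogit(co[1] + co[2] * grid)
  }
  c_true <- fit_curve(rec$p_col)
  e_true <- fit_curve(rec$p_ext)
  data.frame(dist_km = grid, c_true = c_true, e_true = e_true,
             n_star_true = c_true / (c_true + e_true))
}
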