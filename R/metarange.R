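# The end-to-end metapopulation range-limit analysis, packaged in the
# classic modelling idiom: one fitting function returning a classed
# object with print / summary / coef / predict / plot methods.

#' Metapopulation range-limit analysis of a two-survey dataset
#'
#' Runs the full analysis on a pair of survey snapshots: pairing and
#' event classification, local abundance, crude rates, distance-only
#' binomial GLMs of colonisation and extinction, covariate models
#' (with an optional spatially correlated random effect and AICc
#' comparison), a post hoc distance-plus-covariates colonisation model,
#' Gaussian trends of the covariates against distance, classification
#' of extinction outcomes with cause-versus-distance models,
#' observed-occupancy models for both surveys, the Levins equilibrium
#' curve \code{n*(d) = c(d) / (c(d) + e(d))} with a bootstrap
#' confidence envelope, and the containment comparison of \code{n*}
#' against the observed-occupancy band.
#'
#' The distance-only event models that feed the equilibrium prediction
#' are plain GLMs; the spatial random effect is offered for the
#' covariate models, where residual autocorrelation is the concern.
#' Stages with an empty candidate pool are skipped and recorded in
#' \code{$skipped}.
#'
#' @param t1,t2 Survey \code{data.frame}s from [read_survey()] or
#'   [simulate_survey_pair()]; alternatively supply \code{pairs}.
#' @param pairs A prepared \code{plot_pairs} table (overrides
#'   \code{t1}/\code{t2}).
#' @param radius_m Local-abundance radius in metres.
#' @param B Bootstrap replicates for the envelope (0 to skip).
#' @param level Level for the envelope and observed band.
#' @param grid_n Number of evenly spaced grid distances from 0 to the
#'   maximum observed distance.
#' @param spatial Also fit the covariate models with the
#'   exponential-covariance random effect and compare AICc.
#' @param seed Seed for the bootstrap.
#' @param stages Character vector of stages to run; any of
#'   \code{"covariates"}, \code{"trends"}, \code{"causes"},
#'   \code{"bootstrap"}, \code{"comparison"}. Event summaries, the
#'   distance-only models and the equilibrium curve are always
#'   computed.
#' @return An object of class \code{metarange}.
#' @export
metarange <- function(t1 = NULL, t2 = NULL, pairs = NULL,
                      radius_m = 500, B = 1000L, level = 0.95,
                      grid_n = 200L, spatial = FALSE, seed = 1L,
                      stages = c("covariates", "trends", "causes",
                                 "bootstrap", "comparison")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(pairs)) {
    if (is.null(t1) || is.null(t2))
      stop_mr("supply either two surveys (t1, t2) or a pairs table")
    pairs <- pair_surveys(t1, t2)
  }
  pairs <- local_abundance(pairs, radius_m)
  fit <- list(pairs = pairs,
              pairing_log = attr(pairs, "pairing_log"),
              events = summarize_events(pairs),
              skipped = character(),
              config = list(radius_m = radius_m, B = B, level = level,
                            grid_n = grid_n, spatial = spatial, seed = seed,
                            stages = stages))
  skip <- function(what) fit$skipped <<- c(fit$skipped, what)

  col_pool <- pairs[pairs$colonisation_candidate, ]
  ext_pool <- pairs[pairs$extinction_candidate, ]
  col_pool$colonised <- as.numeric(col_pool$colonised)
  ext_pool$extinct <- as.numeric(ext_pool$extinct)

  # distance-only event models (feed the equilibrium prediction)
  if (nrow(col_pool)) {
    fit$c_dist <- fit_glm(colonised ~ dist_km, col_pool, "binomial")
    fit$c_dist_tests <- type2_tests(fit$c_dist)
  } else skip("colonisation model: empty pool")
  if (nrow(ext_pool)) {
    fit$e_dist <- fit_glm(extinct ~ dist_km, ext_pool, "binomial")
    fit$e_dist_tests <- type2_tests(fit$e_dist)
  } else skip("extinction model: empty pool")

  if ("covariates" %in% stages && nrow(col_pool) && nrow(ext_pool)) {
    fit$col_cov <- fit_glm(colonised ~ area_t2 * log10p1(L_t1),
                           col_pool, "binomial")
    fit$col_cov_tests <- type2_tests(fit$col_cov)
    fit$ext_cov <- fit_glm(extinct ~ log10p1(N_t1) * log10p1(L_t1) + area_t1,
                           ext_pool, "binomial")
    fit$ext_cov_tests <- type2_tests(fit$ext_cov)
    fit$col_posthoc <- fit_glm(
      colonised ~ dist_km + area_t2 * log10p1(L_t1), col_pool, "binomial")
    fit$col_posthoc_tests <- type2_tests(fit$col_posthoc)
    if (spatial) {
      fit$col_cov_sp <- fit_spatial_glmm(
        colonised ~ area_t2 * log10p1(L_t1), col_pool)
      fit$ext_cov_sp <- fit_spatial_glmm(
        extinct ~ log10p1(N_t1) * log10p1(L_t1) + area_t1, ext_pool)
      fit$aicc_comparison <- data.frame(
        model = c("colonisation", "extinction"),
        aicc_spatial = c(fit$col_cov_sp$aicc, fit$ext_cov_sp$aicc),
        aicc_plain = c(fit$col_cov$aicc, fit$ext_cov$aicc))
      fit$aicc_comparison$spatial_preferred <-
        fit$aicc_comparison$aicc_spatial < fit$aicc_comparison$aicc_plain
    }
  }

  if ("trends" %in% stages) {
    fit$trends <- lapply(
      stats::setNames(nm = c("area_t1", "area_t2", "N_t1", "L_t1")),
      fit_gaussian_trend, data = pairs)
    fit$trend_slopes <- data.frame(
      variable = names(fit$trends),
      slope = vapply(fit$trends, function(f) unname(coef(f)["dist_km"]), 0),
      p_value = vapply(fit$trends,
                       function(f) type2_tests(f)$p_value[1], 0))
  }

  if ("causes" %in% stages) {
    fit$ext_outcomes <- classify_extinction_outcomes(pairs)
    eo <- fit$ext_outcomes
    complete <- eo[!eo$cause_missing, ]
    if (nrow(complete) > 2 && stats::var(complete$still_suitable) > 0) {
      fit$still_suitable_model <- fit_glm(
        still_suitable ~ dist_km,
        transform(complete, still_suitable = as.numeric(still_suitable)),
        "binomial")
      env <- complete[!complete$still_suitable, ]
      if (nrow(env) > 2) {
        has <- function(k) vapply(env$causes, function(cs) k %in% cs, NA)
        fit$cause_models <- lapply(
          stats::setNames(nm = c("succession", "wind")),
          function(k) {
            y <- as.numeric(has(k))
            if (stats::var(y) == 0) return(NULL)
            fit_glm(y ~ dist_km, data.frame(y = y, dist_km = env$dist_km),
                    "binomial")
          })
      } else skip("cause-vs-distance models: too few environmental extinctions")
    } else skip("extinction-outcome model: too few complete extinction records")
  }

  grid <- seq(0, max(pairs$dist_km), length.out = grid_n)
  fit$obs_t2 <- observed_occupancy_model(pairs, "t2")
  fit$obs_t1 <- observed_occupancy_model(pairs, "t1")

  if (!is.null(fit$c_dist) && !is.null(fit$e_dist)) {
    if ("bootstrap" %in% stages && B >= 1) {
      fit$eq <- bootstrap_envelope(pairs, grid, B = B, level = level,
                                   seed = seed)
    } else {
      fit$eq <- equilibrium_curve(fit$c_dist, fit$e_dist, grid)
    }
    if ("comparison" %in% stages)
      fit$comparison <- compare_curves(fit$eq, fit$obs_t2, level)
  } else skip("equilibrium curve: event model missing")

  class(fit) <- "metarange"
  fit
}

#' @export
print.metarange <- function(x, ...) {
  cat("Metapopulation range-limit analysis\n")
  cat(sprintf("Paired dune plots: %d (t1-only %d, t2-only %d, non-dune %d dropped)\n",
              x$pairing_log$n_paired, x$pairing_log$n_t1_only,
              x$pairing_log$n_t2_only, x$pairing_log$n_non_dune))
  print(x$events)
  if (!is.null(x$c_dist))
    cat(sprintf("Colonisation ~ distance: b = %.4g log-odds/km (p = %.3g, n = %d)\n",
                coef(x$c_dist)["dist_km"], x$c_dist_tests$p_value[1],
                x$c_dist$n))
  if (!is.null(x$e_dist))
    cat(sprintf("Extinction   ~ distance: b = %.4g log-odds/km (p = %.3g, n = %d)\n",
                coef(x$e_dist)["dist_km"], x$e_dist_tests$p_value[1],
                x$e_dist$n))
  if (!is.null(x$comparison)) {
    ep <- x$comparison$endpoints
    cat(sprintf("Observed occupancy (t2):   %.3f at the limit -> %.3f at the core\n",
                ep$at_limit[ep$curve == "n_obs"], ep$at_core[ep$curve == "n_obs"]))
    cat(sprintf("Equilibrium prediction n*: %.3f at the limit -> %.3f at the core\n",
                ep$at_limit[ep$curve == "n_star"], ep$at_core[ep$curve == "n_star"]))
    cat(sprintf("Containment of n* in the observed band: %.3f\n",
                x$comparison$containment))
  }
  if (length(x$skipped))
    cat("Skipped stages:\n", paste(" -", x$skipped, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.metarange <- function(object, ...) {
  structure(list(fit = object), class = "summary.metarange")
}

#' @export
print.summary.metarange <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$col_cov)) {
    cat("\nColonisation covariate model (type II tests):\n")
    print(f$col_cov_tests, row.names = FALSE)
    cat("Extinction covariate model (type II tests):\n")
    print(f$ext_cov_tests, row.names = FALSE)
  }
  if (!is.null(f$aicc_comparison)) {
    cat("\nAICc, spatial random effect vs plain GLM:\n")
    print(f$aicc_comparison, row.names = FALSE)
  }
  if (!is.null(f$trend_slopes)) {
    cat("\nCovariate trends over distance (positive = increases toward core):\n")
    print(f$trend_slopes, row.names = FALSE)
  }
  if (!is.null(f$ext_outcomes)) {
    cat(sprintf("\nExtinct plots still suitable: %.1f%% (of %d with complete causes)\n",
                100 * attr(f$ext_outcomes, "prop_still_suitable"),
                attr(f$ext_outcomes, "n_complete")))
    cp <- attr(f$ext_outcomes, "cause_props")
    cat("Causes among environmental extinctions:",
        paste(sprintf("%s %.1f%%", names(cp), 100 * cp), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.metarange <- function(object, ...) {
  rbind(colonisation = coef(object$c_dist),
        extinction = coef(object$e_dist))
}

#' Predict equilibrium occupancy at new distances
#'
#' @param object A \code{metarange} fit.
#' @param dist_km Distances to the range limit (km); defaults to the
#'   fitted grid.
#' @param ... Unused.
#' @return A \code{data.frame} with \code{dist_km}, \code{c_hat},
#'   \code{e_hat}, \code{n_star}.
#' @export
predict.metarange <- function(object, dist_km = NULL, ...) {
  if (is.null(dist_km)) return(object$eq)
  out <- equilibrium_curve(object$c_dist, object$e_dist, dist_km)
  class(out) <- "data.frame"
  out
}

#' Plot the fitted occupancy geography
#'
#' Two panels: fitted colonisation and extinction curves, and the
#' equilibrium prediction \code{n*(d)} with its bootstrap envelope over
#' the observed-occupancy band. Following the field's plotting
#' convention the distance axis is reversed (the range core on the
#' left, the limit on the right) with the limit marked by a dashed
#' line.
#'
#' @param x A \code{metarange} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.metarange <- function(x, ...) {
  eq <- x$eq
  if (is.null(eq)) stop_mr("no equilibrium curve in this fit")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  xlim <- rev(range(eq$dist_km))
  graphics::plot(eq$dist_km, eq$c_hat, type = "l", col = "forestgreen",
                 xlim = xlim, ylim = c(0, max(eq$c_hat, eq$e_hat) * 1.3),
                 xlab = "Distance to range limit (km)", ylab = "Probability",
                 main = "Colonisation and extinction", ...)
  graphics::lines(eq$dist_km, eq$e_hat, col = "firebrick")
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topleft", c("c(d)", "e(d)"), lty = 1, bty = "n",
                   col = c("forestgreen", "firebrick"))
  graphics::plot(eq$dist_km, eq$n_star, type = "n", xlim = xlim,
                 ylim = c(0, 1), xlab = "Distance to range limit (km)",
                 ylab = "Occupancy", main = "Equilibrium vs observed", ...)
  if (!is.null(x$comparison)) {
    ob <- x$comparison$obs
    graphics::polygon(c(ob$dist_km, rev(ob$dist_km)), c(ob$lo, rev(ob$hi)),
                      col = grDevices::adjustcolor("grey60", 0.4), border = NA)
    graphics::lines(ob$dist_km, ob$n_obs, col = "grey30")
  }
  if (!is.null(eq$lo)) {
    graphics::lines(eq$dist_km, eq$lo, lty = 3, col = "steelblue")
    graphics::lines(eq$dist_km, eq$hi, lty = 3, col = "steelblue")
  }
  graphics::lines(eq$dist_km, eq$n_star, col = "steelblue", lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

glm_report <- function(fit, tests = NULL) {
  if (is.null(fit)) return(NULL)
  out <- list(coefficients = as.list(coef(fit)),
              se = as.list(fit$se),
              n = fit$n, loglik = fit$loglik, aic = fit$aic,
              aicc = fit$aicc, converged = fit$converged,
              separation = fit$separation)
  if (!is.null(fit$spatial))
    out$spatial <- list(sigma2 = fit$spatial$sigma2, rho_m = fit$spatial$rho,
                        boundary = fit$spatial$boundary)
  if (!is.null(tests)) out$type2_tests <- tests
  out
}

#' Write the analysis report bundle
#'
#' Writes a versioned JSON report of every fitted stage (coefficients,
#' standard errors, type II tests, AICc comparison, event counts,
#' containment) plus tidy CSVs: the paired-event table and the
#' equilibrium / observed curves.
#'
#' @param fit A \code{metarange} object.
#' @param dir Output directory (created if needed).
#' @return The report path, invisibly.
#' @export
write_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- fit$events
  report <- list(
    schema_version = "1.0",
    pairing = fit$pairing_log,
    events = unclass(ev),
    models = list(
      colonisation_distance = glm_report(fit$c_dist, fit$c_dist_tests),
      extinction_distance = glm_report(fit$e_dist, fit$e_dist_tests),
      colonisation_covariates = glm_report(fit$col_cov, fit$col_cov_tests),
      extinction_covariates = glm_report(fit$ext_cov, fit$ext_cov_tests),
      colonisation_posthoc = glm_report(fit$col_posthoc, fit$col_posthoc_tests),
      colonisation_covariates_spatial = glm_report(fit$col_cov_sp),
      extinction_covariates_spatial = glm_report(fit$ext_cov_sp),
      observed_occupancy_t1 = glm_report(fit$obs_t1),
      observed_occupancy_t2 = glm_report(fit$obs_t2),
      still_suitable = glm_report(fit$still_suitable_model)
    ),
    aicc_comparison = fit$aicc_comparison,
    trend_slopes = fit$trend_slopes,
    extinction_outcomes = if (!is.null(fit$ext_outcomes)) list(
      n_extinct = attr(fit$ext_outcomes, "n_extinct"),
      n_complete = attr(fit$ext_outcomes, "n_complete"),
      prop_still_suitable = attr(fit$ext_outcomes, "prop_still_suitable"),
      cause_props = as.list(attr(fit$ext_outcomes, "cause_props"))
    ),
    bootstrap = if (!is.null(attr(fit$eq, "B"))) list(
      B = attr(fit$eq, "B"), n_failed = attr(fit$eq, "n_failed"),
      seed = attr(fit$eq, "seed"), level = attr(fit$eq, "level")
    ),
    containment = if (!is.null(fit$comparison)) fit$comparison$containment,
    endpoints = fit$comparison$endpoints,
    skipped = fit$skipped,
    config = fit$config
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  write_pairs(fit$pairs, file.path(dir, "pairs.csv"))
  if (!is.null(fit$eq)) {
    curves <- as.data.frame(fit$eq)
    if (!is.null(fit$comparison)) {
      curves$n_obs <- fit$comparison$obs$n_obs
      curves$obs_lo <- fit$comparison$obs$lo
      curves$obs_hi <- fit$comparison$obs$hi
    }
    utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
  }
  invisible(path)
}
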