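# Levins equilibrium occupancy n* = c / (c + e), its geographic curve
# from fitted colonisation and extinction models, the bootstrap
# confidence envelope, and the comparison against observed occupancy.

#' Levins equilibrium occupancy
#'
#' For constant per-interval colonisation probability \code{c} of
#' vacant patches and extinction probability \code{e} of occupied
#' patches, the stationary occupied fraction of the two-state patch
#' chain \code{n' = n(1 - e) + (1 - n)c} is \code{c / (c + e)}.
#'
#' @param c,e Probabilities in [0, 1], recycled; \code{c + e} must be
#'   positive.
#' @return The equilibrium occupied fraction.
#' @examples
#' levins_equilibrium(0.190, 0.306)  # 0.383
#' @export
levins_equilibrium <- function(c, e) {
  if (any(c < 0 | c > 1 | e < 0 | e > 1, na.rm = TRUE))
    stop_mr("c and e must be probabilities in [0, 1]")
  if (any(c + e == 0, na.rm = TRUE))
    stop_mr("equilibrium undefined where c = e = 0")
  c / (c + e)
}

#' Equilibrium-occupancy curve over distance
#'
#' Evaluates the fitted colonisation and extinction models on a
#' distance grid and applies the Levins formula pointwise.
#'
#' @param c_fit,e_fit \code{mr_glm} binomial fits with the distance
#'   predictor \code{dist_km}.
#' @param grid Distances (km) at which to evaluate.
#' @return An object of class \code{equilibrium_curve}: a
#'   \code{data.frame} with \code{dist_km}, \code{c_hat}, \code{e_hat},
#'   \code{n_star} (and, after [bootstrap_envelope()], \code{lo} and
#'   \code{hi}).
#' @export
equilibrium_curve <- function(c_fit, e_fit, grid) {
  if (!c_fit$converged || !e_fit$converged)
    stop_mr("both event models must have converged")
  nd <- data.frame(dist_km = grid)
  c_hat <- predict(c_fit, nd, type = "response")
  e_hat <- predict(e_fit, nd, type = "response")
  out <- data.frame(dist_km = grid, c_hat = c_hat, e_hat = e_hat,
                    n_star = levins_equilibrium(c_hat, e_hat))
  class(out) <- c("equilibrium_curve", "data.frame")
  out
}

#' Bootstrap confidence envelope for the equilibrium curve
#'
#' Resamples the colonisation pool (vacant-at-first-survey, suitable-
#' at-second) and the extinction pool (occupied-at-first-survey)
#' independently with replacement at the plot level -- the pools are
#' disjoint, so this is equivalent to a joint plot-level bootstrap --
#' refits the two distance-only binomial GLMs on each replicate, and
#' recomputes \code{n*(d)} over the grid. The envelope is the pointwise
#' empirical \code{(1-level)/2} and \code{1-(1-level)/2} percentile
#' band. Replicates where either refit fails to converge or separates
#' are dropped and counted; more than 5\% failures is an error.
#' Deterministic given \code{seed}.
#'
#' @param pairs A \code{plot_pairs} data.frame with event flags.
#' @param grid Distance grid (km).
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Envelope level (default 0.95).
#' @param seed Integer seed.
#' @return An \code{equilibrium_curve} with \code{lo}/\code{hi} columns
#'   and attributes \code{B}, \code{n_failed}, \code{seed}.
#' @export
bootstrap_envelope <- function(pairs, grid, B = 1000L, level = 0.95,
                               seed = 1L) {
  stopifnot(B >= 1L, level > 0, level < 1)
  col_pool <- pairs[pairs$colonisation_candidate, c("dist_km", "colonised")]
  ext_pool <- pairs[pairs$extinction_candidate, c("dist_km", "extinct")]
  col_pool <- col_pool[stats::complete.cases(col_pool), ]
  ext_pool <- ext_pool[stats::complete.cases(ext_pool), ]
  if (!nrow(col_pool) || !nrow(ext_pool))
    stop_mr("empty candidate pool; cannot bootstrap")

  fit0 <- function(d, y) irls_fit(cbind(`(Intercept)` = 1, dist_km = d),
                                  as.numeric(y), "binomial")
  curve_of <- function(fit) invlogit(fit$coefficients[1] +
                                       fit$coefficients[2] * grid)
  cfit <- fit0(col_pool$dist_km, col_pool$colonised)
  efit <- fit0(ext_pool$dist_km, ext_pool$extinct)
  point <- levins_equilibrium(curve_of(cfit), curve_of(efit))

  set.seed(seed)
  reps <- matrix(NA_real_, B, length(grid))
  n_failed <- 0L
  for (b in seq_len(B)) {
    ic <- sample.int(nrow(col_pool), replace = TRUE)
    ie <- sample.int(nrow(ext_pool), replace = TRUE)
    fc <- fit0(col_pool$dist_km[ic], col_pool$colonised[ic])
    fe <- fit0(ext_pool$dist_km[ie], ext_pool$extinct[ie])
    if (!fc$converged || !fe$converged || fc$separation || fe$separation) {
      n_failed <- n_failed + 1L
      next
    }
    reps[b, ] <- levins_equilibrium(curve_of(fc), curve_of(fe))
  }
  if (n_failed > 0.05 * B)
    stop_mr(paste("%d of %d bootstrap refits failed;",
                  "candidate pools are too small or too sparse"),
            n_failed, B)
  alpha <- (1 - level) / 2
  qs <- apply(reps[stats::complete.cases(reps), , drop = FALSE], 2,
              stats::quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(dist_km = grid,
                    c_hat = curve_of(cfit), e_hat = curve_of(efit),
                    n_star = point, lo = qs[1, ], hi = qs[2, ])
  class(out) <- c("equilibrium_curve", "data.frame")
  attr(out, "B") <- B
  attr(out, "n_failed") <- n_failed
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  out
}

#' Observed-occupancy model for suitable plots
#'
#' Binomial GLM of plot occupancy on distance to the range limit,
#' restricted to plots suitable at the chosen survey (and within the
#' range, \code{dist_km >= 0}).
#'
#' @param pairs A \code{plot_pairs} data.frame.
#' @param survey \code{"t2"} (default) or \code{"t1"}.
#' @return An \code{mr_glm} binomial fit of occupancy on \code{dist_km}.
#' @export
observed_occupancy_model <- function(pairs, survey = c("t2", "t1")) {
  survey <- match.arg(survey)
  keep <- pairs[[paste0("suitable_", survey)]] & pairs$dist_km >= 0
  d <- data.frame(occupied = as.numeric(pairs[[paste0("occupied_", survey)]][keep]),
                  dist_km = pairs$dist_km[keep])
  fit_glm(occupied ~ dist_km, d, family = "binomial")
}

#' Compare predicted equilibrium and observed occupancy
#'
#' Lays the equilibrium curve \code{n*(d)} over the pointwise Wald
#' confidence band of the observed-occupancy model and reports the
#' containment fraction: the share of grid points at which \code{n*}
#' lies inside the band. Endpoint values of both curves (at the limit
#' and at the far end of the grid) are reported alongside.
#'
#' @param eq An \code{equilibrium_curve}.
#' @param obs_fit The observed-occupancy \code{mr_glm} from
#'   [observed_occupancy_model()].
#' @param level Band level (default 0.95).
#' @return An object of class \code{occupancy_comparison}: list with
#'   the band (\code{obs}), \code{containment}, and curve endpoints.
#' @export
compare_curves <- function(eq, obs_fit, level = 0.95) {
  band <- wald_band(obs_fit, data.frame(dist_km = eq$dist_km), level)
  inside <- eq$n_star >= band$lo & eq$n_star <= band$hi
  i_lim <- which.min(eq$dist_km); i_core <- which.max(eq$dist_km)
  out <- list(
    obs = data.frame(dist_km = eq$dist_km, n_obs = band$fit,
                     lo = band$lo, hi = band$hi),
    eq = eq,
    containment = mean(inside),
    level = level,
    endpoints = data.frame(
      curve = c("n_star", "n_obs"),
      at_limit = c(eq$n_star[i_lim], band$fit[i_lim]),
      at_core = c(eq$n_star[i_core], band$fit[i_core]))
  )
  class(out) <- "occupancy_comparison"
  out
}

#' @export
print.occupancy_comparison <- function(x, ...) {
  cat(sprintf("Containment of n* within the %.0f%% observed-occupancy band: %.3f\n",
              100 * x$level, x$containment))
  cat("Endpoints (limit -> core):\n")
  print(transform(x$endpoints, at_limit = round(at_limit, 3),
                  at_core = round(at_core, 3)))
  invisible(x)
}
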