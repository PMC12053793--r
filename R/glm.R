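# Binomial (logit) and Gaussian (identity) GLM fitting by iteratively
# reweighted least squares, written out in full so the likelihood trace,
# separation diagnostics and term tests are under the package's control.
# stats::glm is used only as an independent cross-check in the tests.

#' Fit a binomial or Gaussian generalised linear model
#'
#' Maximum-likelihood fitting by iteratively reweighted least squares
#' with step-halving, so the log-likelihood is non-decreasing across
#' iterations. Convergence is declared when the relative change in
#' log-likelihood falls below \code{tol} (default 1e-10, at most
#' \code{maxit} iterations). Rows with missing values in the response
#' or any predictor are dropped (complete-case filtering) and the
#' number used is reported as \code{n}.
#'
#' Standard errors come from the observed information at the optimum.
#' For the binomial family, coefficients larger than 30 in absolute
#' value on the logit scale are flagged as (quasi-)complete separation.
#' Rank-deficient design matrices are an error naming the collinear
#' columns.
#'
#' @param formula Model formula; main effects and pairwise interactions.
#' @param data A \code{data.frame}.
#' @param family \code{"binomial"} (logit link, 0/1 response) or
#'   \code{"gaussian"} (identity link).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class \code{mr_glm}: coefficients, standard
#'   errors, covariance matrix, log-likelihood (with per-iteration
#'   trace), deviance, AIC and AICc, \code{n} used, and convergence /
#'   separation flags.
#' @examples
#' d <- data.frame(y = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), x = 1:10)
#' fit <- fit_glm(y ~ 1, d, family = "binomial")
#' coef(fit)  # logit(0.3)
#' @export
fit_glm <- function(formula, data, family = c("binomial", "gaussian"),
                    tol = 1e-10, maxit = 100L) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  n_dropped <- nrow(data) - nrow(mf)
  trm <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(trm, mf)
  if (nrow(X) < 1L) stop_mr("no complete-case rows to fit on")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop_mr("binomial response must be coded 0/1")

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_mr("design matrix is rank deficient; collinear term(s): %s",
            paste(dropped, collapse = ", "))
  }

  core <- irls_fit(X, y, family, tol = tol, maxit = maxit)
  p <- ncol(X)
  k <- if (family == "gaussian") p + 1L else p  # gaussian counts sigma^2
  n <- nrow(X)
  fit <- c(core, list(
    family = family, terms = trm, formula = formula,
    model = mf, n = n, n_dropped = n_dropped, k = k,
    aic = -2 * core$loglik + 2 * k,
    aicc = if (n > k + 1) aicc(core$loglik, k, n) else NA_real_,
    var_ranges = variable_ranges(mf),
    call = match.call()
  ))
  class(fit) <- "mr_glm"
  fit
}

# IRLS core on an explicit design matrix (also used for the submodel
# refits in type2_tests, where columns are selected by term).
irls_fit <- function(X, y, family, tol = 1e-10, maxit = 100L) {
  n <- nrow(X); p <- ncol(X)
  if (family == "gaussian") {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    res <- y - X %*% beta
    rss <- sum(res^2)
    sigma2_mle <- rss / n
    loglik <- -n / 2 * (log(2 * pi * sigma2_mle) + 1)
    disp <- rss / max(n - p, 1L)
    XtX_inv <- chol2inv(chol(crossprod(X)))
    vcov <- XtX_inv * disp
    return(list(coefficients = beta, vcov = vcov,
                se = sqrt(diag(vcov)), loglik = loglik,
                loglik_trace = loglik, deviance = rss,
                null_deviance = sum((y - mean(y))^2),
                fitted = drop(X %*% beta), dispersion = disp,
                converged = TRUE, n_iter = 1L, separation = FALSE))
  }

  # binomial logit
  beta <- numeric(p)
  if ("(Intercept)" %in% colnames(X)) {
    pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
    beta[match("(Intercept)", colnames(X))] <- logit(pbar)
  }
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  loglik <- ll(beta)
  trace <- loglik
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- invlogit(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    beta_new <- tryCatch(
      stats::lm.wfit(X, z, w)$coefficients,
      error = function(e) stop_mr("IRLS weighted solve failed: %s",
                                  conditionMessage(e)))
    # step-halve toward the previous iterate if the likelihood drops
    ll_new <- ll(beta_new)
    halvings <- 0L
    while (ll_new < loglik - 1e-12 && halvings < 30L) {
      beta_new <- (beta_new + beta) / 2
      ll_new <- ll(beta_new)
      halvings <- halvings + 1L
    }
    delta <- abs(ll_new - loglik) / (abs(ll_new) + 0.1)
    beta <- beta_new
    loglik <- ll_new
    trace <- c(trace, loglik)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- invlogit(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  dev_resid <- -2 * (y * log(pmax(mu, 1e-300)) +
                       (1 - y) * log(pmax(1 - mu, 1e-300)))
  pbar <- mean(y)
  null_dev <- -2 * sum(y * log(max(pbar, 1e-300)) +
                         (1 - y) * log(max(1 - pbar, 1e-300)))
  list(coefficients = stats::setNames(beta, colnames(X)), vcov = vcov,
       se = sqrt(diag(vcov)), loglik = loglik, loglik_trace = trace,
       deviance = sum(dev_resid), null_deviance = null_dev,
       fitted = mu, dispersion = 1,
       converged = converged, n_iter = length(trace) - 1L,
       separation = any(abs(beta) > 30) ||
         all(mu > 1 - 1e-6) || all(mu < 1e-6))
}

variable_ranges <- function(mf) {
  vars <- mf[, -1L, drop = FALSE]
  num <- vapply(vars, is.numeric, NA)
  lapply(vars[num], range)
}

#' Small-sample corrected Akaike information criterion
#'
#' \code{AIC = -2 logLik + 2k}; \code{AICc = AIC + 2k(k+1)/(n-k-1)}.
#' Undefined (an error) when \code{n <= k + 1}.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop_mr("AICc undefined for n <= k + 1 (n = %d, k = %d)", n, k)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
coef.mr_glm <- function(object, ...) object$coefficients

#' @export
vcov.mr_glm <- function(object, ...) object$vcov

#' @export
logLik.mr_glm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.mr_glm <- function(x, ...) {
  cat(if (is.null(x$spatial)) "GLM" else "Spatial GLMM (exponential covariance)",
      sprintf("[%s], n = %d\n", x$family, x$n))
  print(deparse(x$formula))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 5))
  if (!is.null(x$spatial))
    cat(sprintf("sigma2 = %.4f, rho = %.1f m\n",
                x$spatial$sigma2, x$spatial$rho))
  cat(sprintf("logLik = %.3f, AIC = %.2f, AICc = %.2f\n",
              x$loglik, x$aic, x$aicc))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (isTRUE(x$separation)) cat("WARNING: possible complete separation\n")
  invisible(x)
}

#' @export
summary.mr_glm <- function(object, ...) {
  zval <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.mr_glm"
  out
}

#' @export
print.summary.mr_glm <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Predict from a fitted model
#'
#' Population-level prediction: the inverse link applied to the linear
#' predictor at the fixed effects; for spatial fits the random effect is
#' set to its zero mean. Standard errors (\code{se.fit = TRUE}) are
#' Wald, computed on the link scale and delta-transformed for
#' \code{type = "response"}. Prediction beyond the fitted range of a
#' numeric predictor is allowed but logged with a message.
#'
#' @param object An \code{mr_glm} fit.
#' @param newdata Data frame of predictor values; omit for fitted values.
#' @param type \code{"response"} (default) or \code{"link"}.
#' @param se.fit Return standard errors as well.
#' @param ... Unused.
#' @return A numeric vector, or a list with \code{fit} and \code{se.fit}.
#' @export
predict.mr_glm <- function(object, newdata = NULL,
                           type = c("response", "link"),
                           se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- stats::model.matrix(object$terms, object$model)
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass)
    X <- stats::model.matrix(tt, mf)
    for (v in names(object$var_ranges)) {
      if (v %in% names(mf)) {
        r <- object$var_ranges[[v]]
        if (any(mf[[v]] < r[1] | mf[[v]] > r[2], na.rm = TRUE))
          message("predicting beyond the fitted range of `", v, "`")
      }
    }
  }
  eta <- drop(X %*% object$coefficients)
  linkinv <- if (object$family == "binomial") invlogit else identity
  if (!se.fit)
    return(if (type == "response") linkinv(eta) else eta)
  se_eta <- sqrt(pmax(rowSums((X %*% object$vcov) * X), 0))
  if (type == "link") return(list(fit = eta, se.fit = se_eta))
  mu <- linkinv(eta)
  dmu <- if (object$family == "binomial") mu * (1 - mu) else rep(1, length(eta))
  list(fit = mu, se.fit = se_eta * dmu)
}

# Pointwise Wald band on the response scale, computed on the linear
# predictor and back-transformed (keeps probability bands inside [0,1]).
wald_band <- function(fit, newdata, level = 0.95) {
  pr <- predict.mr_glm(fit, newdata, type = "link", se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  linkinv <- if (fit$family == "binomial") invlogit else identity
  data.frame(fit = linkinv(pr$fit),
             lo = linkinv(pr$fit - z * pr$se.fit),
             hi = linkinv(pr$fit + z * pr$se.fit))
}

#' Type II significance tests for all model terms
#'
#' For each term, compares the model containing all other terms that
#' respect marginality against the model without that term: a main
#' effect is tested with its own interactions excluded from both models
#' (e.g. in \code{y ~ A + B + A:B}, the test of \code{A} compares
#' \code{A + B} against \code{B}). Plain GLMs use likelihood-ratio
#' chi-square tests (refitting the nested pair on the same rows);
#' spatial fits use Wald chi-square statistics at the estimated
#' covariance parameters.
#'
#' @param fit An \code{mr_glm} fit.
#' @param test \code{"LR"} or \code{"Wald"}; defaults to LR for plain
#'   GLMs and Wald for spatial fits.
#' @return A \code{data.frame} with one row per term: \code{term},
#'   \code{chisq}, \code{df}, \code{p_value}, \code{test}.
#' @export
type2_tests <- function(fit, test = NULL) {
  if (is.null(test)) test <- if (is.null(fit$spatial)) "LR" else "Wald"
  test <- match.arg(test, c("LR", "Wald"))
  trm <- fit$terms
  labels <- attr(trm, "term.labels")
  if (!length(labels)) stop_mr("model has no terms to test")
  X <- stats::model.matrix(trm, fit$model)
  y <- stats::model.response(fit$model)
  asgn <- attr(X, "assign")
  fac <- attr(trm, "factors")

  contains <- function(a, b) { # does term b strictly contain term a?
    va <- rownames(fac)[fac[, a] > 0]
    vb <- rownames(fac)[fac[, b] > 0]
    all(va %in% vb) && length(vb) > length(va)
  }

  rows <- lapply(seq_along(labels), function(i) {
    t_i <- labels[i]
    higher <- labels[vapply(labels, function(b) contains(t_i, b), NA)]
    with_t <- setdiff(labels, higher)
    without_t <- setdiff(with_t, t_i)
    idx_with <- which(asgn %in% c(0L, match(with_t, labels)))
    idx_without <- which(asgn %in% c(0L, match(without_t, labels)))
    df <- length(idx_with) - length(idx_without)
    if (test == "LR") {
      ll1 <- irls_fit(X[, idx_with, drop = FALSE], y, fit$family)$loglik
      ll0 <- irls_fit(X[, idx_without, drop = FALSE], y, fit$family)$loglik
      stat <- max(2 * (ll1 - ll0), 0)
    } else {
      idx <- which(asgn == i)
      b <- fit$coefficients[idx]
      V <- fit$vcov[idx, idx, drop = FALSE]
      stat <- drop(t(b) %*% solve(V, b))
      df <- length(idx)
    }
    data.frame(term = t_i, chisq = stat, df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE),
               test = test, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gaussian trend of a covariate against distance to the range limit
#'
#' Fits the covariate to a Gaussian GLM with distance as the sole
#' predictor, to ask whether habitat and population structure decline
#' toward the limit. Abundance covariates (\code{N_t1}, \code{L_t1})
#' are transformed as \code{log10(x + 1)}. A positive slope means the
#' covariate increases toward the range core.
#'
#' @param variable One of \code{"area_t1"}, \code{"area_t2"},
#'   \code{"N_t1"}, \code{"L_t1"} (or any numeric column of
#'   \code{data}).
#' @param data A \code{plot_pairs} data.frame.
#' @param log_transform Apply \code{log10(x + 1)}; defaults to TRUE for
#'   the abundance covariates.
#' @return An \code{mr_glm} Gaussian fit of the (possibly transformed)
#'   covariate on \code{dist_km}.
#' @export
fit_gaussian_trend <- function(variable, data,
                               log_transform = variable %in% c("N_t1", "L_t1")) {
  if (!variable %in% names(data)) stop_mr("no column `%s` in data", variable)
  y <- data[[variable]]
  if (log_transform) y <- log10p1(y)
  fit_glm(y ~ dist_km, data.frame(y = y, dist_km = data$dist_km),
          family = "gaussian")
}
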