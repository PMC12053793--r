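# Binomial GLMM with one spatially correlated Gaussian random effect per
# plot, cov(b_i, b_j) = sigma2 * exp(-h_ij / rho) for planar distance
# h_ij in metres. Fitted by maximizing the Laplace-approximate marginal
# likelihood: an inner Newton optimization of the joint log-density over
# (beta, b), block-eliminated so each step costs one dense Cholesky of
# an n x n matrix, inside an outer Nelder-Mead search over
# (log sigma2, log rho).

#' Fit a binomial GLM with a spatially correlated random effect
#'
#' Adds one Gaussian random effect per plot with exponential-decay
#' covariance \eqn{\sigma^2 \exp(-h/\rho)} (distance \eqn{h} in metres)
#' to the linear predictor, to absorb residual spatial autocorrelation.
#' Fixed effects and the random effects are maximized jointly in an
#' inner Newton loop; \eqn{(\sigma^2, \rho)} by an outer quasi-Newton-free
#' simplex search over their logs; the reported log-likelihood is the
#' Laplace approximation to the marginal likelihood, and AICc counts
#' \eqn{\sigma^2} and \eqn{\rho} as two extra parameters.
#'
#' A \eqn{\hat\sigma^2} estimated at (effectively) zero is returned with
#' a \code{boundary} note: the model then reduces to the plain GLM of
#' [fit_glm()]. Fixed-effect standard errors are conditional on the
#' estimated covariance parameters.
#'
#' @param formula Model formula (binomial 0/1 response).
#' @param data A \code{data.frame} containing the model variables and
#'   the coordinate columns.
#' @param coords Names of the projected planar coordinate columns in
#'   metres (default \code{c("x_m", "y_m")}).
#' @param dense_cap Refuse to build the dense covariance above this
#'   many rows (default 4000).
#' @param control List: \code{maxit_outer}, \code{reltol_outer},
#'   \code{maxit_inner}, \code{tol_inner}, \code{nugget}.
#' @return An \code{mr_glm} object whose \code{$spatial} element holds
#'   \code{sigma2}, \code{rho} (metres), the random-effect modes
#'   \code{b}, and convergence notes.
#' @export
fit_spatial_glmm <- function(formula, data, coords = c("x_m", "y_m"),
                             dense_cap = 4000, control = list()) {
  ctl <- utils::modifyList(list(maxit_outer = 200L, reltol_outer = 1e-7,
                                maxit_inner = 50L, tol_inner = 1e-9,
                                nugget = 1e-6), control)
  if (!all(coords %in% names(data)))
    stop_mr("coordinate column(s) not found: %s",
            paste(setdiff(coords, names(data)), collapse = ", "))
  vars <- unique(c(all.vars(formula), coords))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  if (n > dense_cap)
    stop_mr("n = %d exceeds the dense-solver cap (%d)", n, dense_cap)
  mf <- stats::model.frame(formula, d)
  trm <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop_mr("binomial response must be coded 0/1")
  X <- stats::model.matrix(trm, mf)
  p <- ncol(X)
  D <- as.matrix(stats::dist(as.matrix(d[, coords])))

  # warm starts carried across outer evaluations
  state <- new.env(parent = emptyenv())
  state$beta <- irls_fit(X, y, "binomial")$coefficients
  state$b <- numeric(n)

  obj <- function(theta) {
    if (theta[1] < -12 || theta[1] > 6 ||
        theta[2] < log(1) || theta[2] > log(1e7)) return(1e10)
    sigma2 <- exp(theta[1]); rho <- exp(theta[2])
    lap <- tryCatch(
      laplace_fit(y, X, D, sigma2, rho, nugget = ctl$nugget,
                  beta0 = state$beta, b0 = state$b,
                  maxit = ctl$maxit_inner, tol = ctl$tol_inner),
      error = function(e) NULL)
    if (is.null(lap) || !is.finite(lap$marg_ll)) return(1e10)
    state$beta <- lap$beta; state$b <- lap$b
    -lap$marg_ll
  }

  med_h <- stats::median(D[upper.tri(D)])
  theta0 <- c(log(0.5), log(max(med_h / 10, 10)))
  opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit_outer,
                                     reltol = ctl$reltol_outer))
  # one simplex restart from the optimum guards against premature collapse
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit_outer,
                                     reltol = ctl$reltol_outer))
  sigma2 <- exp(opt$par[1]); rho <- exp(opt$par[2])
  lap <- laplace_fit(y, X, D, sigma2, rho, nugget = ctl$nugget,
                     beta0 = state$beta, b0 = state$b,
                     maxit = ctl$maxit_inner, tol = ctl$tol_inner)
  boundary <- sigma2 < 1e-4
  k <- p + 2L
  fit <- list(
    coefficients = stats::setNames(lap$beta, colnames(X)),
    vcov = lap$vcov_beta, se = sqrt(diag(lap$vcov_beta)),
    loglik = lap$marg_ll, loglik_trace = lap$marg_ll,
    deviance = NA_real_, null_deviance = NA_real_,
    fitted = invlogit(drop(X %*% lap$beta + lap$b)),
    dispersion = 1,
    converged = opt$convergence == 0 && lap$converged,
    n_iter = lap$n_iter,
    separation = any(abs(lap$beta) > 30),
    family = "binomial", terms = trm, formula = formula,
    model = mf, n = n, n_dropped = nrow(data) - n, k = k,
    aic = -2 * lap$marg_ll + 2 * k,
    aicc = aicc(lap$marg_ll, k, n),
    var_ranges = variable_ranges(mf),
    call = match.call(),
    spatial = list(sigma2 = sigma2, rho = rho, b = lap$b,
                   boundary = boundary,
                   outer_convergence = opt$convergence,
                   note = if (boundary)
                     "sigma2 at zero boundary: model reduces to the plain GLM"
                   else NULL)
  )
  dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  names(fit$se) <- colnames(X)
  class(fit) <- "mr_glm"
  fit
}

# Joint Newton maximization of the penalized binomial log-likelihood
# over (beta, b) and the resulting Laplace marginal log-likelihood.
# Block elimination: the (p + n) Newton system is solved through one
# Cholesky of Q = W + Sigma^{-1} per iteration.
laplace_fit <- function(y, X, D, sigma2, rho, nugget = 1e-6,
                        beta0 = NULL, b0 = NULL, maxit = 50L, tol = 1e-9,
                        fixed_beta = NULL) {
  n <- length(y); p <- ncol(X)
  Sigma <- sigma2 * (exp(-D / rho) + nugget * diag(n))
  cS <- chol(Sigma)
  Sigma_inv <- chol2inv(cS)
  logdet_Sigma <- 2 * sum(log(diag(cS)))

  profile_beta <- is.null(fixed_beta)
  beta <- if (profile_beta) (beta0 %||% numeric(p)) else fixed_beta
  b <- b0 %||% numeric(n)

  pen_ll <- function(beta, b) {
    eta <- drop(X %*% beta + b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * drop(crossprod(b, Sigma_inv %*% b))
  }

  ll <- pen_ll(beta, b)
  converged <- FALSE
  cQ <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta + b)
    mu <- invlogit(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    r <- y - mu
    gb <- r - drop(Sigma_inv %*% b)
    Q <- Sigma_inv
    diag(Q) <- diag(Q) + w
    cQ <- chol(Q)
    if (profile_beta) {
      gbeta <- drop(crossprod(X, r))
      B <- X * w                      # n x p block, = W X
      QiB <- backsolve(cQ, forwardsolve(t(cQ), B))
      Qigb <- backsolve(cQ, forwardsolve(t(cQ), gb))
      A <- crossprod(X * sqrt(w))
      S <- A - crossprod(B, QiB)
      dbeta <- solve(S, gbeta - drop(crossprod(B, Qigb)))
      db <- Qigb - QiB %*% dbeta
      step <- 1
      repeat {
        beta_new <- beta + step * dbeta
        b_new <- b + step * drop(db)
        ll_new <- pen_ll(beta_new, b_new)
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
        step <- step / 2
        if (step < 1e-8) { ll_new <- ll; beta_new <- beta; b_new <- b; break }
      }
      beta <- beta_new; b <- b_new
    } else {
      db <- backsolve(cQ, forwardsolve(t(cQ), gb))
      step <- 1
      repeat {
        b_new <- b + step * db
        ll_new <- pen_ll(beta, b_new)
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
        step <- step / 2
        if (step < 1e-8) { ll_new <- ll; b_new <- b; break }
      }
      b <- b_new
    }
    delta <- abs(ll_new - ll) / (abs(ll_new) + 0.1)
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # curvature at the mode for the Laplace determinant and Wald vcov
  eta <- drop(X %*% beta + b)
  mu <- invlogit(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  Q <- Sigma_inv
  diag(Q) <- diag(Q) + w
  cQ <- chol(Q)
  logdet_Q <- 2 * sum(log(diag(cQ)))
  marg_ll <- ll - 0.5 * logdet_Sigma - 0.5 * logdet_Q

  vcov_beta <- if (profile_beta) {
    B <- X * w
    QiB <- backsolve(cQ, forwardsolve(t(cQ), B))
    A <- crossprod(X * sqrt(w))
    solve(A - crossprod(B, QiB))
  } else matrix(NA_real_, p, p)

  list(beta = beta, b = b, marg_ll = marg_ll, vcov_beta = vcov_beta,
       converged = converged, n_iter = it)
}

# Laplace approximation to log integral p(y | beta, b) N(b; 0, Sigma) db
# at *fixed* fixed effects and covariance -- the quantity checked
# against low-dimensional adaptive quadrature in the tests.
laplace_marginal <- function(y, X, beta, Sigma) {
  n <- length(y)
  cS <- chol(Sigma)
  Sigma_inv <- chol2inv(cS)
  logdet_Sigma <- 2 * sum(log(diag(cS)))
  b <- numeric(n)
  pen_ll <- function(b) {
    eta <- drop(X %*% beta + b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * drop(crossprod(b, Sigma_inv %*% b))
  }
  ll <- pen_ll(b)
  for (it in 1:100) {
    eta <- drop(X %*% beta + b)
    mu <- invlogit(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    gb <- (y - mu) - drop(Sigma_inv %*% b)
    Q <- Sigma_inv; diag(Q) <- diag(Q) + w
    cQ <- chol(Q)
    db <- backsolve(cQ, forwardsolve(t(cQ), gb))
    step <- 1
    repeat {
      b_new <- b + step * db
      ll_new <- pen_ll(b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { b_new <- b; ll_new <- ll; break }
    }
    conv <- abs(ll_new - ll) < 1e-12 * (abs(ll) + 0.1)
    b <- b_new; ll <- ll_new
    if (conv) break
  }
  eta <- drop(X %*% beta + b)
  mu <- invlogit(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  Q <- Sigma_inv; diag(Q) <- diag(Q) + w
  ll - 0.5 * logdet_Sigma - 0.5 * (2 * sum(log(diag(chol(Q)))))
}
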