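# Fixtures are built in code: small surveys assembled directly, larger
# ones drawn from the package's own simulator.

make_survey <- function(plot_id, area, abundance, dist_km = seq_along(plot_id),
                        x_m = 1000 * seq_along(plot_id), y_m = 0,
                        year = 2019L, causes = NULL, is_dune = TRUE) {
  n <- length(plot_id)
  if (is.null(causes)) causes <- replicate(n, character(), simplify = FALSE)
  metarange:::as_survey(
    data.frame(plot_id = as.character(plot_id), year = year,
               dist_km = dist_km, x_m = x_m, y_m = rep_len(y_m, n),
               suitable_area_m2 = area, abundance = abundance,
               stringsAsFactors = FALSE),
    causes = causes, is_dune = rep_len(is_dune, n))
}

# candidate pools with exact event counts: n_col colonisation candidates
# of which k_col colonised, n_ext extinction candidates of which k_ext
# went extinct
pool_pairs <- function(n_col, k_col, n_ext, k_ext) {
  n <- n_col + n_ext
  id <- sprintf("P%04d", seq_len(n))
  occ1 <- rep(c(FALSE, TRUE), c(n_col, n_ext))
  N1 <- ifelse(occ1, 2L, 0L)
  N2 <- c(rep(1:0, c(k_col, n_col - k_col)),
          rep(0:1, c(k_ext, n_ext - k_ext)))
  t1 <- make_survey(id, area = 5, abundance = N1, dist_km = seq_len(n) / 10,
                    x_m = 100 * seq_len(n))
  t2 <- make_survey(id, area = 5, abundance = N2, dist_km = seq_len(n) / 10,
                    x_m = 100 * seq_len(n), year = 2022L)
  pair_surveys(t1, t2)
}

# brute-force O(n^2) oracle for local abundance
local_mean_bruteforce <- function(x, y, value, radius) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    keep <- sqrt((x - x[i])^2 + (y - y[i])^2) <= radius
    keep[i] <- FALSE
    if (any(keep)) out[i] <- mean(value[keep])
  }
  out
}

# binomial observations over a spatially correlated Gaussian field with
# covariance sigma2 * exp(-h / rho_m)
sim_spatial_binomial <- function(n, sigma2, rho_m, beta0 = -0.3, beta1 = 0.5,
                                 extent_m = 100e3) {
  d <- data.frame(x_m = stats::runif(n, 0, extent_m),
                  y_m = stats::runif(n, 0, 200),
                  z = stats::rnorm(n))
  D <- as.matrix(stats::dist(d[, c("x_m", "y_m")]))
  b <- if (sigma2 > 0) {
    drop(crossprod(chol(sigma2 * exp(-D / rho_m) + 1e-8 * diag(n)),
                   stats::rnorm(n)))
  } else numeric(n)
  d$y <- stats::rbinom(n, 1, plogis(beta0 + beta1 * d$z + b))
  d
}

# Gauss-Hermite nodes/weights by Golub-Welsch
gh_rule <- function(k) {
  i <- sqrt(seq_len(k - 1) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1), 2:k)] <- i
  J[cbind(2:k, seq_len(k - 1))] <- i
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
}

# independent oracle for the mixed-model marginal likelihood at fixed
# parameters: adaptive Gauss-Hermite product quadrature of the exact
# n-dimensional integral, centred and scaled at the joint mode
quadrature_marginal <- function(y, X, beta, Sigma, nodes = 20) {
  n <- length(y)
  Sinv <- solve(Sigma)
  f <- function(b) {
    eta <- drop(X %*% beta + b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * drop(t(b) %*% Sinv %*% b)
  }
  opt <- stats::optim(rep(0, n), function(b) -f(b), method = "BFGS",
                      hessian = TRUE)
  gh <- gh_rule(nodes)
  grid <- as.matrix(do.call(expand.grid, rep(list(gh$x), n)))
  wts <- apply(as.matrix(do.call(expand.grid, rep(list(gh$w), n))), 1, prod)
  Cinv <- chol(solve(opt$hessian))
  bs <- t(opt$par + sqrt(2) * t(Cinv) %*% t(grid))
  fv <- apply(bs, 1, f)
  log_jac <- (n / 2) * log(2) - 0.5 * determinant(opt$hessian)$modulus
  u2 <- rowSums(grid^2)
  m <- max(fv + u2)
  as.numeric(m + log(sum(wts * exp(fv + u2 - m))) + log_jac -
               0.5 * determinant(Sigma)$modulus - (n / 2) * log(2 * pi))
}
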