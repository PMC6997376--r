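#' Method-of-moments dispersion estimation
#'
#' Per-gene NB dispersion `alpha` (variance = m + alpha m^2) from the
#' group-wise residual variance of normalized counts: within each design
#' cell the sample mean and variance of `y/s` are computed, and `alpha` is
#' the df-weighted least-squares solution of `E[v_c] = m_c * mean(1/s) +
#' alpha * m_c^2`, floored at `floor_alpha`. Optionally shrunk halfway (in
#' log space) toward a lowess mean-dispersion trend.
#'
#' @param counts Count matrix, genes in rows.
#' @param groups Factor of design cells (e.g. exposure x sex x week).
#' @param size_factors Optional per-sample size factors (default all 1).
#' @param floor_alpha Lower bound for the estimate.
#' @param trend Shrink toward a fitted mean-dispersion curve.
#' @return Named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, groups, size_factors = NULL,
                                floor_alpha = 1e-8, trend = FALSE) {
  counts <- validate_counts(counts, allow_real = TRUE)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  z <- sweep(counts, 2, size_factors, "/")
  inv_s <- mean(1 / size_factors)
  G <- stats::model.matrix(~ 0 + groups)
  n_c <- colSums(G)
  if (all(n_c < 2)) stop("need at least one design cell with >= 2 samples")
  means <- (z %*% G) %*% diag(1 / n_c, ncol(G))
  ss_within <- (z^2 %*% G) - sweep(means^2, 2, n_c, "*")
  df_c <- pmax(n_c - 1, 0)
  use <- df_c > 0
  # alpha solving sum_c SS_c = sum_c df_c (m_c/s + alpha m_c^2)
  num <- rowSums(ss_within[, use, drop = FALSE]) -
    inv_s * (means[, use, drop = FALSE] %*% df_c[use])
  den <- (means[, use, drop = FALSE]^2) %*% df_c[use]
  alpha <- pmax(floor_alpha, as.numeric(num) / pmax(as.numeric(den), 1e-300))
  alpha[as.numeric(den) == 0] <- floor_alpha
  if (trend) {
    m_all <- rowMeans(z)
    ok <- m_all > 0 & alpha > floor_alpha
    if (sum(ok) > 10) {
      fit <- stats::lowess(log(m_all[ok]), log(alpha[ok]), f = 0.5)
      trended <- exp(stats::approx(fit$x, fit$y, xout = log(pmax(m_all, min(m_all[ok]))),
                                   rule = 2)$y)
      alpha <- pmax(floor_alpha, exp((log(alpha) + log(trended)) / 2))
    }
  }
  alpha <- stats::setNames(alpha, rownames(counts))
  attr(alpha, "df") <- sum(df_c[use])
  alpha
}

#' Fit a negative-binomial GLM with log link
#'
#' Iteratively reweighted least squares at fixed dispersion `alpha`
#' (variance `mu + alpha mu^2`), with an offset for log size factors.
#' Convergence when the largest coefficient change drops below `tol`;
#' coefficients are capped at +/-30 on the linear-predictor scale so
#' degenerate genes (e.g. all-zero counts) are handled without error.
#'
#' @param y Integer response vector (counts of one gene).
#' @param X Model matrix (full column rank).
#' @param dispersion NB dispersion alpha (>= 0; values below 1e-12 are
#'   treated as Poisson).
#' @param offset Linear-predictor offset, typically `log(size_factors)`.
#' @param max_iter,tol IRLS controls.
#' @return List: `coefficients`, `fitted` (means), `loglik`, `leverage`,
#'   `se` (coefficient standard errors), `converged`, `iterations`,
#'   `dispersion`.
#' @export
fit_nb_glm <- function(y, X, dispersion, offset = NULL,
                       max_iter = 100, tol = 1e-8) {
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  if (qr(X)$rank < p) stop("model matrix is not of full column rank")
  if (is.null(offset)) offset <- rep(0, n)
  cap <- 30
  alpha <- dispersion
  mu0 <- pmax(y, 0.5)
  beta <- qr.solve(X, log(mu0) - offset)
  beta <- pmin(pmax(beta, -cap), cap)
  converged <- FALSE
  iter <- 0
  A <- NULL
  w <- rep(1, n)
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -cap), cap)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    A <- crossprod(X, w * X)
    beta_new <- tryCatch(solve(A, crossprod(X, w * z)),
                         error = function(e) solve(A + diag(1e-10, p),
                                                   crossprod(X, w * z)))
    beta_new <- pmin(pmax(drop(beta_new), -cap), cap)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -cap), cap)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  A <- crossprod(X, w * X)
  Ainv <- tryCatch(solve(A), error = function(e) solve(A + diag(1e-10, p)))
  B <- sqrt(w) * X
  h <- rowSums(B * t(Ainv %*% t(B)))
  ll <- nb_loglik(y, mu, alpha)
  names(beta) <- colnames(X)
  list(coefficients = beta, fitted = mu, loglik = ll, leverage = h,
       se = stats::setNames(sqrt(pmax(diag(Ainv), 0)), colnames(X)),
       converged = converged, iterations = iter, dispersion = alpha)
}

nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-12) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
}
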