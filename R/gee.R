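#' Cluster sandwich covariance from score contributions
#'
#' Computes the robust covariance B^-1 (sum_c s_c s_c') B^-T where s_c is the
#' summed estimating-function contribution of cluster c and B is the bread
#' (derivative) matrix. With one observation per cluster and a linear model
#' this reduces to the textbook HC0 heteroskedasticity-robust covariance.
#' The output is symmetrized to guard against round-off.
#'
#' @param scores list (or matrix with one row per cluster) of per-cluster
#'   summed score vectors
#' @param bread bread matrix B (p x p), e.g. sum of -d(score)/d(beta)
#' @return p x p covariance matrix
#' @export
sandwich_covariance <- function(scores, bread) {
  if (is.list(scores)) scores <- do.call(rbind, scores)
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) {
    ge_error("sandwich_covariance needs at least 2 clusters",
             "genentry_fit_error")
  }
  meat <- crossprod(scores)
  binv <- solve(bread)
  v <- binv %*% meat %*% t(binv)
  (v + t(v)) / 2
}

# family helpers: mean, variance and d(mu)/d(eta) for the two canonical links
ge_family <- function(family) {
  switch(family,
    binomial = list(linkinv = stats::plogis,
                    variance = function(mu) mu * (1 - mu),
                    mu_eta = function(mu) mu * (1 - mu)),
    poisson = list(linkinv = exp,
                   variance = function(mu) mu,
                   mu_eta = function(mu) mu),
    ge_error(sprintf("unsupported family: %s", family), "genentry_fit_error"))
}

#' Generalized estimating equations with cluster sandwich variance
#'
#' Fits a marginal mean model g(mu) = X beta with canonical link (logit for
#' `"binomial"`, log for `"poisson"`) by iterating the GEE fixed-point with an
#' exchangeable (or independence) working correlation across observations of
#' the same cluster, then computes the cluster sandwich covariance. The
#' Poisson variant uses the Poisson mean-variance working model; with the
#' sandwich variance this remains valid under overdispersion.
#'
#' The exchangeable correlation is estimated by the usual moment estimator
#' from Pearson residuals; its inverse is applied in closed form
#' (R^-1 = (I - a/(1+(n-1)a) J) / (1-a)), so no per-cluster matrix inversion
#' is performed.
#'
#' @param X model matrix (with intercept column)
#' @param y response vector
#' @param cluster cluster identifiers
#' @param family `"binomial"` or `"poisson"`
#' @param corstr `"exchangeable"` or `"independence"`
#' @param maxit,tol iteration control
#' @return list with `coefficients`, `vcov` (sandwich), `alpha` (working
#'   correlation), `phi` (dispersion), `n`, `n_clusters`, `converged`
#' @export
gee_fit <- function(X, y, cluster, family = c("poisson", "binomial"),
                    corstr = c("exchangeable", "independence"),
                    maxit = 100L, tol = 1e-9) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  cl <- as.character(cluster)
  ucl <- unique(cl)
  if (length(ucl) < 2) {
    ge_error("gee_fit needs at least 2 clusters", "genentry_fit_error")
  }
  idx <- split(seq_len(n), factor(cl, levels = ucl))
  fam <- ge_family(family)

  init <- suppressWarnings(stats::glm.fit(
    X, y, family = if (family == "binomial") stats::binomial() else
      stats::poisson()))
  beta <- init$coefficients
  if (anyNA(beta)) {
    ge_error("gee_fit: singular model matrix (aliased coefficients)",
             "genentry_fit_error")
  }

  alpha <- 0
  phi <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    if (family == "binomial" &&
        (any(mu > 1 - 1e-12) || any(mu < 1e-12))) {
      ge_error(paste0("gee_fit: fitted probabilities numerically 0 or 1 ",
                      "(possible complete separation); max|eta| = ",
                      format(max(abs(eta)))), "genentry_fit_error")
    }
    vr <- fam$variance(mu)
    pearson <- (y - mu) / sqrt(vr)
    phi <- sum(pearson^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0
      den <- 0
      for (ii in idx) {
        e <- pearson[ii]
        ni <- length(e)
        if (ni > 1) {
          num <- num + (sum(e)^2 - sum(e^2)) / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      alpha <- if (den > p) num / phi / (den - p) else 0
      if (!is.finite(alpha)) alpha <- 0
      alpha <- min(max(alpha, 0), 0.95)
    }

    # estimating function and bread under the working correlation
    U <- numeric(p)
    H <- matrix(0, p, p)
    w <- fam$mu_eta(mu)      # canonical link: D = diag(w) X, A = diag(vr)
    r <- y - mu
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      wi <- w[ii]
      si <- sqrt(vr[ii])
      Di <- Xi * wi
      # V^-1 z = A^-1/2 R^-1 A^-1/2 z  (phi cancels at the solution)
      rinv <- function(z) {
        if (corstr == "independence" || length(z) == 1 || alpha == 0) return(z)
        ni <- length(z)
        (z - (alpha / (1 + (ni - 1) * alpha)) * sum(z)) / (1 - alpha)
      }
      DtVinv <- t(Di / si)            # p x ni, rows of A^-1/2 D transposed
      DtVinv <- t(apply(DtVinv, 1, rinv))
      if (p == 1) DtVinv <- matrix(DtVinv, nrow = 1)
      DtVinv <- DtVinv / rep(si, each = p)  # divide columns by sqrt(vr)
      dim(DtVinv) <- c(p, length(ii))
      U <- U + DtVinv %*% r[ii]
      H <- H + DtVinv %*% Di
    }
    step <- tryCatch(drop(solve(H, U)), error = function(e) {
      ge_error(sprintf("gee_fit: singular working information matrix (%s)",
                       conditionMessage(e)), "genentry_fit_error")
    })
    # damp oversized steps; genuine divergence (separation) still trips the
    # fitted-probability guard above
    if (max(abs(step)) > 4) step <- step * 4 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    ge_error(sprintf("gee_fit did not converge in %d iterations (last step %g)",
                     maxit, max(abs(step))), "genentry_fit_error")
  }

  eta <- drop(X %*% beta)
  mu <- fam$linkinv(eta)
  vr <- fam$variance(mu)
  w <- fam$mu_eta(mu)
  r <- y - mu
  scores <- matrix(0, length(idx), p)
  H <- matrix(0, p, p)
  for (k in seq_along(idx)) {
    ii <- idx[[k]]
    Xi <- X[ii, , drop = FALSE]
    si <- sqrt(vr[ii])
    Di <- Xi * w[ii]
    rinv <- function(z) {
      if (corstr == "independence" || length(z) == 1 || alpha == 0) return(z)
      ni <- length(z)
      (z - (alpha / (1 + (ni - 1) * alpha)) * sum(z)) / (1 - alpha)
    }
    DtVinv <- t(Di / si)
    DtVinv <- t(apply(DtVinv, 1, rinv))
    if (p == 1) DtVinv <- matrix(DtVinv, nrow = 1)
    DtVinv <- DtVinv / rep(si, each = p)
    dim(DtVinv) <- c(p, length(ii))
    scores[k, ] <- DtVinv %*% r[ii]
    H <- H + DtVinv %*% Di
  }
  vcov <- tryCatch(sandwich_covariance(scores, H), error = function(e) {
    if (inherits(e, "genentry_error")) stop(e)
    ge_error(sprintf("gee_fit: singular bread matrix (%s)",
                     conditionMessage(e)), "genentry_fit_error")
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(drop(beta), colnames(X)), vcov = vcov,
       alpha = alpha, phi = phi, n = n, n_clusters = length(idx),
       converged = converged, family = family, corstr = corstr)
}
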