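## Negative-binomial GLM machinery.
##
## Parameterization throughout: variance = mu + phi * mu^2 (phi >= 0), so
## phi = 0 is the Poisson limit and `size` in dnbinom() is 1/phi. All models
## use a log link with known offsets (log allele-column library sizes).

MAX_ETA <- 50  # clamp on the linear predictor; exp(50) is far beyond any count

nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  if (phi <= 0) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

## Generic single-response Fisher-scoring fit, any design matrix.
## Returns beta, mu, log-likelihood, Cox-Reid 0.5*logdet(X'WX), convergence flag.
nb_glm_fit <- function(y, X, offset, phi, maxit = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- numeric(p)
  # moment start for the intercept (assumes column 1 is the intercept)
  beta[1] <- log((sum(y) + 0.5) / sum(exp(offset)))
  eta <- pmin(offset + drop(X %*% beta), MAX_ETA)
  mu <- exp(eta)
  ll <- nb_loglik(y, mu, phi)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    r <- (y - mu) / (1 + phi * mu)
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, r)
    step <- tryCatch(solve(XtWX + diag(1e-8, p), score),
                     error = function(e) matrix(0, p, 1))
    ll_new <- -Inf
    for (h in 0:20) {        # step-halving
      beta_try <- beta + drop(step) / 2^h
      eta <- pmin(offset + drop(X %*% beta_try), MAX_ETA)
      mu_try <- exp(eta)
      ll_new <- nb_loglik(y, mu_try, phi)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    if (!is.finite(ll_new) || ll_new < ll) break
    beta <- beta_try
    mu <- mu_try
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  w <- mu / (1 + phi * mu)
  XtWX <- crossprod(X, X * w)
  d <- det(XtWX)
  cr <- if (d > 0) 0.5 * log(d) else 0.5 * log(.Machine$double.xmin)
  list(beta = beta, mu = mu, loglik = ll, cr_adj = cr, converged = converged)
}

#' Negative-binomial GLM likelihood-ratio test for allelic imbalance
#'
#' Fits, for one gene within one cross group, the log-linear model
#' `log mu = offset + b0 + b1 * [allele == Cast]` by Fisher scoring at a known
#' dispersion, and compares it with the null model (`b1 = 0`) via a 1-df
#' likelihood-ratio test against the chi-square distribution.
#'
#' @param b6 integer vector of B6-allele counts, one per sample in the group.
#' @param cast integer vector of Cast-allele counts, same samples and order.
#' @param offsets numeric offsets (log library sizes) for the `c(b6, cast)`
#'   observation vector; either length `2 * length(b6)` or a single value
#'   recycled to all observations.
#' @param phi NB dispersion (variance = mu + phi mu^2); `phi = 0` gives the
#'   Poisson limit.
#' @return list with `stat` (LRT statistic, >= 0), `p_value`, `direction`
#'   (sign of the Cast-vs-B6 log-fold-change; +1 Cast-up, -1 B6-up, 0 none),
#'   `lfc` (natural-log fold change Cast/B6), and `converged`.
#' @export
#' @examples
#' nb_glm_lrt(c(10, 10, 10), c(20, 20, 20), offsets = 0, phi = 0)
nb_glm_lrt <- function(b6, cast, offsets = 0, phi = 0) {
  stopifnot(length(b6) == length(cast), length(b6) >= 1, phi >= 0)
  y <- c(b6, cast)
  n <- length(y)
  if (length(offsets) == 1L) offsets <- rep(offsets, n)
  stopifnot(length(offsets) == n)
  allele <- rep(c(0, 1), each = length(b6))
  full <- nb_glm_fit(y, cbind(1, allele), offsets, phi)
  null <- nb_glm_fit(y, matrix(1, n, 1), offsets, phi)
  stat <- max(0, 2 * (full$loglik - null$loglik))
  lfc <- unname(full$beta[2])
  list(stat = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       direction = if (abs(lfc) < 1e-12) 0 else sign(lfc),
       lfc = lfc,
       converged = full$converged && null$converged)
}

## ---- vectorized fits across genes (shared two-column design) ----
##
## Y: genes x n count matrix; a: binary allele indicator of length n;
## offset: length n; phi: scalar or per-gene vector. Used by the dispersion
## grid and the main per-group test, where every gene shares the design.

.ll_mat <- function(Y, MU, phi) {
  MU <- pmax(MU, 1e-300)
  G <- nrow(Y)
  if (length(phi) == 1L) {
    if (phi <= 0) return(rowSums(stats::dpois(Y, MU, log = TRUE)))
    return(rowSums(stats::dnbinom(Y, size = 1 / phi, mu = MU, log = TRUE)))
  }
  L <- matrix(0, G, ncol(Y))
  pois <- phi <= 0
  if (any(pois)) L[pois, ] <- stats::dpois(Y[pois, , drop = FALSE],
                                           MU[pois, , drop = FALSE], log = TRUE)
  if (any(!pois)) {
    S <- matrix(1 / phi[!pois], sum(!pois), ncol(Y))
    L[!pois, ] <- stats::dnbinom(Y[!pois, , drop = FALSE], size = S,
                                 mu = MU[!pois, , drop = FALSE], log = TRUE)
  }
  rowSums(L)
}

## Fit log mu = offset + b0 (+ b1*a). Returns per-gene coefficients,
## log-likelihoods and the Cox-Reid adjustment. `two_group = FALSE` fits
## the intercept-only null.
nb_fit_vec <- function(Y, a, offset, phi, two_group = TRUE,
                       maxit = 100L, tol = 1e-10) {
  Y <- as.matrix(Y)
  G <- nrow(Y); n <- ncol(Y)
  OFF <- matrix(offset, G, n, byrow = TRUE)
  tot <- rowSums(Y)
  b0 <- log((tot + 0.5) / sum(exp(offset)))
  b1 <- numeric(G)
  A <- matrix(a, G, n, byrow = TRUE)
  mu_of <- function(b0, b1) exp(pmin(OFF + b0 + if (two_group) outer(b1, a) else 0,
                                     MAX_ETA))
  MU <- mu_of(b0, b1)
  ll <- .ll_mat(Y, MU, phi)
  active <- rep(TRUE, G)
  for (it in seq_len(maxit)) {
    W <- MU / (1 + phi * MU)
    R <- (Y - MU) / (1 + phi * MU)
    S11 <- rowSums(W) + 1e-10
    s1 <- rowSums(R)
    if (two_group) {
      S12 <- rowSums(W * A) + 1e-10
      s2 <- rowSums(R * A)
      dt <- pmax(S11 * S12 - S12 * S12, 1e-300)
      d0 <- (S12 * s1 - S12 * s2) / dt
      d1 <- (S11 * s2 - S12 * s1) / dt
    } else {
      d0 <- s1 / S11
      d1 <- 0
    }
    d0[!active] <- 0; d1[!active] <- 0
    step <- 1
    repeat {
      b0_try <- b0 + step * d0
      b1_try <- b1 + step * d1
      MU_try <- mu_of(b0_try, b1_try)
      ll_try <- .ll_mat(Y, MU_try, phi)
      bad <- active & (!is.finite(ll_try) | ll_try < ll - 1e-12)
      if (!any(bad) || step < 1e-6) break
      # halve only the offending genes
      d0[bad] <- d0[bad] / 2; d1[bad] <- d1[bad] / 2
      step <- if (step == 1) 1 else step  # per-gene halving via d0/d1
      if (max(abs(d0[bad]), abs(d1[bad])) < 1e-12) break
    }
    keep <- is.finite(ll_try) & ll_try >= ll - 1e-12
    b0[keep] <- b0_try[keep]; b1[keep] <- b1_try[keep]
    MU[keep, ] <- MU_try[keep, , drop = FALSE]
    moved <- abs(ll_try - ll) >= tol * (abs(ll) + 1)
    ll[keep] <- ll_try[keep]
    active <- active & keep & moved
    if (!any(active)) break
  }
  W <- MU / (1 + phi * MU)
  S11 <- rowSums(W)
  if (two_group) {
    S12 <- rowSums(W * A)
    dt <- pmax(S11 * S12 - S12 * S12, .Machine$double.xmin)
    cr <- 0.5 * log(dt)
  } else {
    cr <- 0.5 * log(pmax(S11, .Machine$double.xmin))
  }
  list(b0 = b0, b1 = b1, loglik = ll, cr_adj = cr)
}

## Cox-Reid adjusted profile log-likelihood of phi, per gene, on a grid.
## Rows of Y that are all zero give NA (dispersion undefined).
apl_grid <- function(Y, a, offset, phi_grid) {
  Y <- as.matrix(Y)
  G <- nrow(Y)
  out <- matrix(NA_real_, G, length(phi_grid))
  nz <- rowSums(Y) > 0
  if (!any(nz)) return(out)
  Yn <- Y[nz, , drop = FALSE]
  for (j in seq_along(phi_grid)) {
    f <- nb_fit_vec(Yn, a, offset, phi_grid[j], two_group = TRUE)
    out[nz, j] <- f$loglik - f$cr_adj
  }
  out
}

## quadratic interpolation of the argmax on the log10(phi) grid
argmax_quad <- function(lg, v) {
  i <- which.max(v)
  if (i == 1L || i == length(v)) return(lg[i])
  num <- v[i - 1] - v[i + 1]
  den <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (!is.finite(den) || den >= 0) return(lg[i])
  lg[i] + 0.5 * (lg[i + 1] - lg[i]) * num / den
}
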