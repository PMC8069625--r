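# Restricted (natural) cubic spline basis and a ridge-stabilized IRLS
# logistic fitter. The spline is the truncated-power restricted basis:
# piecewise cubic between the knots and exactly linear beyond the boundary
# knots, contributing k - 1 design columns per covariate for k knots.

#' Knot locations for a restricted cubic spline
#'
#' Places `nKnots` knots at empirical quantiles of `x` (defaults: 0.1, 0.5,
#' 0.9 for three knots — the standard spacing for so few knots). If fewer
#' than three distinct values (or non-distinct knots) are available the
#' covariate cannot support a spline and `NULL` is returned with a warning,
#' which downstream code treats as "use the linear term only".
#'
#' @param x numeric vector of training values.
#' @param nKnots number of knots (>= 3).
#' @param probs quantile positions; default equally informative spread.
#' @return numeric vector of knots, or NULL when x is degenerate.
#' @export
rcsKnots <- function(x, nKnots = 3L,
                     probs = if (nKnots == 3L) c(0.1, 0.5, 0.9)
                     else seq(0.05, 0.95, length.out = nKnots)) {
  if (length(unique(x)) < 3L) {
    warning("fewer than 3 distinct values; falling back to a linear term")
    return(NULL)
  }
  k <- unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
  if (length(unique(k)) < length(k)) {
    warning("non-distinct knots; falling back to a linear term")
    return(NULL)
  }
  k
}

#' Restricted cubic spline basis
#'
#' Truncated-power construction: for knots `t_1 < ... < t_k`, column 1 is
#' `x` itself and column `j + 1` (j = 1 .. k - 2) is
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'       + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2,}
#' which is linear (indeed zero in the left tail) beyond the boundary
#' knots. With 3 knots each covariate contributes 2 columns. The
#' `(t_k - t_1)^2` divisor keeps the nonlinear column on the scale of `x`.
#'
#' @param x numeric vector.
#' @param knots numeric knot vector from [rcsKnots()]; NULL gives the
#'   linear column only.
#' @return a matrix with `length(knots) - 1` columns (or 1 when NULL).
#' @export
rcsBasis <- function(x, knots) {
  if (is.null(knots)) return(matrix(x, ncol = 1L, dimnames = list(NULL, "lin")))
  k <- length(knots)
  if (k < 3L) wd_config_error("restricted cubic splines need at least 3 knots")
  tk <- knots[k]; tk1 <- knots[k - 1L]; t1 <- knots[1L]
  p3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (p3(x - tj) -
                        p3(x - tk1) * (tk - tj) / (tk - tk1) +
                        p3(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  }
  colnames(out) <- c("lin", if (k > 2L) paste0("rcs", seq_len(k - 2L)))
  out
}

# Expand a feature matrix column-wise with per-feature RCS bases.
# `knotsList` is a named list (NULL entries = linear only).
rcs_expand <- function(m, knotsList) {
  cols <- lapply(names(knotsList), function(f) {
    b <- rcsBasis(m[, f], knotsList[[f]])
    colnames(b) <- paste(f, colnames(b), sep = ".")
    b
  })
  do.call(cbind, cols)
}

# Fit per-feature knots on a training feature matrix.
rcs_fit_knots <- function(m, nKnots = 3L) {
  out <- lapply(colnames(m), function(f)
    withCallingHandlers(rcsKnots(m[, f], nKnots),
                        warning = function(w) invokeRestart("muffleWarning")))
  names(out) <- colnames(m)
  out
}

# Iteratively reweighted least squares for (optionally ridge-penalized)
# logistic regression, with step-halving when a step would increase the
# penalized deviance and convergence on the relative deviance change (the
# same safeguards stats::glm uses, so quasi-separated designs plateau
# instead of oscillating). The intercept is never penalized; ridge = 0 is
# the maximum-likelihood fit. X excludes the intercept column.
irls_logistic <- function(X, y, ridge = 1e-6, maxit = 100L, tol = 1e-8) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  pdev <- function(beta) {
    mu <- pmin(pmax(stats::plogis(drop(X1 %*% beta)), 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)) + ridge * sum(beta[-1L]^2)
  }
  beta <- rep(0, p)
  dev <- pdev(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- tryCatch(
      drop(solve(XtW %*% X1 + pen, XtW %*% z)),
      error = function(e) wd_convergence_error(
        sprintf("IRLS normal equations singular at iteration %d: %s", it,
                conditionMessage(e))))
    dev_new <- pdev(beta_new)
    half <- 0L
    while (!is.finite(dev_new) || dev_new > dev + 1e-10) {
      half <- half + 1L
      if (half > 30L) break
      beta_new <- (beta_new + beta) / 2
      dev_new <- pdev(beta_new)
    }
    done <- abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol
    beta <- beta_new
    dev <- dev_new
    if (done) {
      names(beta) <- colnames(X1)
      return(list(beta = beta, iterations = it, converged = TRUE,
                  deviance = dev))
    }
  }
  wd_convergence_error(sprintf(
    "IRLS did not converge in %d iterations (deviance %.6g); consider a larger ridge",
    maxit, dev))
}
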