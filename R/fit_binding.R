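#' Fit the cooperative lattice-binding isotherm by weighted ODR
#'
#' Estimates the association constant `K` and cooperativity `omega` of the
#' McGhee-von Hippel model from titration points `(c, d)` — free protein
#' concentration versus fractional saturation — by weighted orthogonal
#' distance regression against the implicit manifold
#' \deqn{F(c, d; K, \omega) = d/n - \vartheta(c; K, \omega, n) = 0.}
#' The site size `n` is held fixed (30 bp for H-NS). `K` and `omega` are
#' positivity-constrained by optimising `log K` and `log omega`; standard
#' errors are mapped back by the delta method.
#'
#' When only coverage-axis weights are supplied (the default), the orthogonal
#' distance collapses to a weighted vertical residual in `d` and the fit is a
#' weighted nonlinear least squares on `d` versus the model curve. When
#' `weight_c` (inverse variance of `c`) is also finite, each point's latent
#' concentration is profiled out by an inner one-dimensional minimisation, so
#' error in both axes is honoured as in classical ODR.
#'
#' @param points Data frame with columns `c` (uM), `d` (fractional
#'   saturation) and optionally `weight_d`, `weight_c` (inverse variances) or
#'   `sd_d`, `sd_c` (standard deviations, converted to weights). Missing
#'   weights default to 1 for `d` and none (no c-error) for `c`.
#' @param n_fixed Binding-site size held fixed during regression (default 30).
#' @param init Optional list/vector with starting `K` and `omega`. By default
#'   `K0` is the reciprocal of the concentration at half-saturation and
#'   `omega0 = 1`.
#' @return An object of class `mvh_fit` with components `K_hat`, `omega_hat`,
#'   `se_K`, `se_omega`, `n_fixed`, `converged`, `residual_norm`, `n_points`,
#'   `vcov_log` (covariance of `(log K, log omega)`), `points` (the accepted
#'   data with fitted values) and `params` (a [lattice_params()] of the
#'   estimates).
#' @examples
#' p <- lattice_params(K = 0.1, omega = 10, n = 30)
#' cgrid <- 10^seq(-2.5, 1, length.out = 12)
#' pts <- data.frame(c = cgrid, d = 30 * mvh_coverage(cgrid, p))
#' fit <- fit_binding(pts, n_fixed = 30)
#' coef(fit)
#' @export
fit_binding <- function(points, n_fixed = 30, init = NULL) {
  pts <- .validate_points(points, n_fixed)
  n <- as.integer(n_fixed)

  # starting values: K0 = 1/c at half saturation, omega0 = 1
  if (is.null(init)) {
    c_half <- stats::approx(pts$d, pts$c, xout = 0.5, ties = mean, rule = 2)$y
    if (!is.finite(c_half) || c_half <= 0) c_half <- stats::median(pts$c[pts$c > 0])
    init <- c(K = 1 / c_half, omega = 1)
  } else {
    init <- c(K = init[["K"]], omega = init[["omega"]])
    if (any(!is.finite(init)) || any(init <= 0))
      stop("`init` must give positive finite K and omega")
  }

  has_c_err <- "weight_c" %in% names(pts) && any(is.finite(pts$weight_c) & pts$weight_c > 0)
  obj <- function(p) .odr_objective(p, pts, n, has_c_err)$ss

  p0 <- log(init)
  # global-ish start with Nelder-Mead, then tight local refinement
  nm <- stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
  ref <- stats::nlminb(nm$par, obj,
                       control = list(rel.tol = 1e-14, x.tol = 1e-14,
                                      abs.tol = 0, iter.max = 500))
  p_hat <- ref$par
  converged <- is.finite(ref$objective) &&
    (ref$convergence == 0 || nm$convergence == 0 || ref$objective <= nm$value + 1e-12)

  final <- .odr_objective(p_hat, pts, n, has_c_err)
  # Gauss-Newton covariance in log-parameter space
  J <- .model_jacobian(p_hat, pts, n, has_c_err)
  W <- final$w_eff
  dof <- max(nrow(pts) - 2L, 1L)
  s2 <- final$ss / dof
  JtWJ <- crossprod(J * sqrt(W))
  vcov_log <- tryCatch(solve(JtWJ) * s2,
                       error = function(e) matrix(NA_real_, 2, 2))
  K_hat <- exp(p_hat[[1]]); omega_hat <- exp(p_hat[[2]])
  se_log <- sqrt(pmax(diag(vcov_log), 0))
  pts$d_fit <- n * mvh_coverage(pts$c, lattice_params(K_hat, omega_hat, n))

  structure(list(
    K_hat = K_hat, omega_hat = omega_hat,
    se_K = K_hat * se_log[1], se_omega = omega_hat * se_log[2],
    n_fixed = n, converged = converged,
    residual_norm = final$ss, n_points = nrow(pts),
    vcov_log = vcov_log,
    points = pts,
    params = lattice_params(K_hat, omega_hat, n),
    has_c_err = has_c_err
  ), class = "mvh_fit")
}

.validate_points <- function(points, n_fixed) {
  points <- as.data.frame(points)
  if (!all(c("c", "d") %in% names(points)))
    stop("`points` needs columns `c` and `d`")
  if (!("weight_d" %in% names(points)) && "sd_d" %in% names(points))
    points$weight_d <- 1 / points$sd_d^2
  if (!("weight_c" %in% names(points)) && "sd_c" %in% names(points))
    points$weight_c <- 1 / points$sd_c^2
  if (!("weight_d" %in% names(points))) points$weight_d <- 1
  if (any(!is.finite(points$c)) || any(points$c < 0))
    stop("concentrations must be finite and >= 0")
  if (any(!is.finite(points$d)))
    stop("coverages must be finite")
  if (any(!is.finite(points$weight_d)) || any(points$weight_d <= 0))
    stop("weights must be positive and finite")
  if (nrow(points) < 3L)
    stop("insufficient data: at least 3 titration points are required")
  interior <- sum(points$d > 0 & points$d < 1)
  if (interior < 2L)
    stop("degenerate data: need at least 2 points with coverage strictly between 0 and 1")
  if (stats::sd(points$d) < 1e-12)
    stop("degenerate data: all coverages identical")
  points
}

# profile objective: sum of weighted orthogonal distances at (logK, logomega)
.odr_objective <- function(p, pts, n, has_c_err) {
  par <- lattice_params(exp(p[[1]]), exp(p[[2]]), n)
  if (!has_c_err) {
    d_hat <- n * mvh_coverage(pts$c, par)
    r <- pts$d - d_hat
    return(list(ss = sum(pts$weight_d * r^2), w_eff = pts$weight_d))
  }
  # profile out the latent concentration per point
  ss <- 0
  w_eff <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    wi_c <- pts$weight_c[i]; wi_d <- pts$weight_d[i]
    if (!is.finite(wi_c) || wi_c <= 0) {
      r <- pts$d[i] - n * mvh_coverage(pts$c[i], par)
      ss <- ss + wi_d * r^2
      w_eff[i] <- wi_d
      next
    }
    f <- function(ch) {
      wi_d * (pts$d[i] - n * mvh_coverage(ch, par))^2 + wi_c * (pts$c[i] - ch)^2
    }
    up <- max(pts$c[i] * 4, pts$c[i] + 4 / sqrt(wi_c), 1e-8)
    opt <- stats::optimize(f, lower = 0, upper = up, tol = 1e-12)
    ss <- ss + opt$objective
    # effective weight for the GN covariance: orthogonal-distance weight
    w_eff[i] <- wi_d
  }
  list(ss = ss, w_eff = w_eff)
}

# numerical Jacobian of model-predicted d wrt (logK, logomega)
.model_jacobian <- function(p, pts, n, has_c_err, h = 1e-6) {
  pred <- function(pp) {
    par <- lattice_params(exp(pp[[1]]), exp(pp[[2]]), n)
    n * mvh_coverage(pts$c, par)
  }
  J <- matrix(0, nrow(pts), 2L)
  for (j in 1:2) {
    hp <- p; hm <- p
    hp[j] <- hp[j] + h; hm[j] <- hm[j] - h
    J[, j] <- (pred(hp) - pred(hm)) / (2 * h)
  }
  J
}

#' @export
print.mvh_fit <- function(x, ...) {
  cat("McGhee-von Hippel cooperative binding fit (weighted ODR)\n")
  cat(sprintf("  n fixed at %d bp, %d points, %s\n", x$n_fixed, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  K     = %.4g /uM  (se %.3g)\n", x$K_hat, x$se_K))
  cat(sprintf("  omega = %.4g      (se %.3g)\n", x$omega_hat, x$se_omega))
  cat(sprintf("  weighted residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' @export
summary.mvh_fit <- function(object, ...) {
  est <- c(K = object$K_hat, omega = object$omega_hat)
  se <- c(K = object$se_K, omega = object$se_omega)
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `CI95 lo` = est * exp(-1.96 * se / est),
               `CI95 hi` = est * exp(1.96 * se / est))
  out <- list(coefficients = tab, n_fixed = object$n_fixed,
              converged = object$converged,
              residual_norm = object$residual_norm,
              n_points = object$n_points)
  class(out) <- "summary.mvh_fit"
  out
}

#' @export
print.summary.mvh_fit <- function(x, ...) {
  cat("McGhee-von Hippel cooperative binding fit\n")
  cat(sprintf("  site size n = %d bp (fixed), %d points, %s\n",
              x$n_fixed, x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("  weighted residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' @export
coef.mvh_fit <- function(object, ...) {
  c(K = object$K_hat, omega = object$omega_hat)
}

#' @export
vcov.mvh_fit <- function(object, ...) {
  # delta method from (logK, logomega) to (K, omega)
  g <- diag(c(object$K_hat, object$omega_hat))
  v <- g %*% object$vcov_log %*% g
  dimnames(v) <- list(c("K", "omega"), c("K", "omega"))
  v
}

#' Predicted fractional saturation from a binding fit
#'
#' @param object An `mvh_fit`.
#' @param newdata Optional data frame with column `c` (uM) or a numeric
#'   vector of concentrations; defaults to the fitted points.
#' @param ... Unused.
#' @return Numeric vector of predicted fractional saturations `d`.
#' @export
predict.mvh_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$points$c
        else if (is.numeric(newdata)) newdata
        else newdata$c
  object$n_fixed * mvh_coverage(cc, object$params)
}

#' @export
residuals.mvh_fit <- function(object, ...) {
  object$points$d - object$points$d_fit
}

#' Simulate titrations from a fitted binding model
#'
#' Draws new coverage values at the fitted curve plus Gaussian noise with
#' per-point standard deviation `1/sqrt(weight_d)`.
#'
#' @param object An `mvh_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated `d` values.
#' @export
simulate.mvh_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$points$d_fit
  sd <- 1 / sqrt(object$points$weight_d)
  out <- as.data.frame(replicate(nsim, stats::rnorm(length(mu), mu, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a binding fit
#'
#' Coverage points with the fitted isotherm on a log-concentration axis.
#'
#' @param x An `mvh_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mvh_fit <- function(x, ...) {
  pts <- x$points
  pos <- pts$c > 0
  cgrid <- 10^seq(log10(min(pts$c[pos])), log10(max(pts$c)), length.out = 200)
  graphics::plot(pts$c[pos], pts$d[pos], log = "x",
                 xlab = "free protein concentration (uM)",
                 ylab = "fractional saturation d", ylim = c(0, 1), ...)
  graphics::lines(cgrid, predict(x, cgrid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Export a binding fit as JSON
#'
#' Writes estimates, standard errors, convergence and residuals in a
#' machine-readable report alongside an optional fitted-curve table.
#'
#' @param fit An `mvh_fit`.
#' @param path Output JSON path.
#' @param curve_path Optional CSV path for a fitted curve (c grid, predicted d).
#' @param curve_points Number of grid points for the fitted curve.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, curve_path = NULL, curve_points = 100) {
  rep <- list(
    K = fit$K_hat, omega = fit$omega_hat,
    se_K = fit$se_K, se_omega = fit$se_omega,
    n_fixed = fit$n_fixed, converged = fit$converged,
    residual_norm = fit$residual_norm, n_points = fit$n_points,
    residuals = residuals(fit)
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(curve_path)) {
    pos <- fit$points$c[fit$points$c > 0]
    cgrid <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = curve_points)
    utils::write.csv(data.frame(c_uM = cgrid, d = predict(fit, cgrid)),
                     curve_path, row.names = FALSE)
  }
  invisible(path)
}
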