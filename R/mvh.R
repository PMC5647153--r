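#' Lattice-binding parameter set
#'
#' Bundle and validate the parameters of the McGhee-von Hippel cooperative
#' lattice-binding model: the intrinsic association constant `K` (per uM free
#' protein), the nearest-neighbour cooperativity `omega` (dimensionless,
#' `omega > 1` favours contiguous filaments) and the binding-site size `n`
#' (lattice sites, i.e. base pairs, covered by one bound protomer).
#'
#' @param K Association constant, 1/uM. Must be positive.
#' @param omega Cooperativity parameter, dimensionless, positive.
#' @param n Binding-site size in lattice sites (integer >= 1).
#' @return An object of class `lattice_params` (a named list).
#' @examples
#' lattice_params(K = 0.1, omega = 10, n = 30)
#' @export
lattice_params <- function(K, omega, n) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("`K` must be a single positive finite number (1/uM)")
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("`omega` must be a single positive finite number")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      abs(n - round(n)) > 1e-8)
    stop("`n` must be a single integer >= 1")
  structure(list(K = K, omega = omega, n = as.integer(round(n))),
            class = "lattice_params")
}

#' @export
print.lattice_params <- function(x, ...) {
  cat(sprintf("McGhee-von Hippel parameters: K = %g /uM, omega = %g, n = %d bp\n",
              x$K, x$omega, x$n))
  invisible(x)
}

.as_lattice_params <- function(params) {
  if (inherits(params, "lattice_params")) return(params)
  if (is.list(params) && all(c("K", "omega", "n") %in% names(params)))
    return(lattice_params(params$K, params$omega, params$n))
  stop("`params` must be a lattice_params object or a list with K, omega, n")
}

# omega values closer to 1 than this are evaluated with the non-cooperative
# closed form (the cooperative bracket is 0/0 at omega == 1)
.OMEGA_SINGULAR_TOL <- 1e-8

#' Free concentration from bound-ligand density (McGhee-von Hippel)
#'
#' Evaluates the cooperative large-ligand lattice isotherm in its natural
#' direction: given the bound-ligand density per lattice site
#' \eqn{\vartheta} (so fractional saturation is \eqn{d = n\vartheta}), return
#' the free protein concentration `c` at which the infinite-lattice model is
#' in equilibrium,
#' \deqn{\vartheta/c = K(1-n\vartheta)\left[\frac{(2\omega-1)(1-n\vartheta)+\vartheta-R}
#'   {2(\omega-1)(1-n\vartheta)}\right]^{n-1}
#'   \left[\frac{1-(n+1)\vartheta+R}{2(1-n\vartheta)}\right]^2,}
#' \deqn{R = \sqrt{(1-(n+1)\vartheta)^2 + 4\omega\vartheta(1-n\vartheta)}.}
#' At `omega == 1` (within 1e-8) the singular bracket is replaced by the
#' algebraic non-cooperative limit
#' \eqn{\vartheta/c = K(1-n\vartheta)\,[(1-n\vartheta)/(1-(n-1)\vartheta)]^{n-1}}.
#'
#' `c(theta)` is strictly increasing on `[0, 1/n)`, which is what makes the
#' numerical inversion in [mvh_coverage()] a simple bisection.
#'
#' @param theta Bound-ligand density per lattice site, in `[0, 1/n)`.
#'   Vectorised.
#' @param params A [lattice_params()] object (or list with `K`, `omega`, `n`).
#' @return Free concentration(s) in uM, same length as `theta`.
#' @seealso [mvh_coverage()] for the inverse, [finite_lattice_coverage()] for
#'   the exact finite-lattice reference.
#' @examples
#' p <- lattice_params(K = 2, omega = 1, n = 1)
#' mvh_concentration(0.5, p)  # Langmuir: theta/(K(1-theta)) = 0.5
#' @export
mvh_concentration <- function(theta, params) {
  params <- .as_lattice_params(params)
  n <- params$n; K <- params$K; omega <- params$omega
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("`theta` must be finite and >= 0")
  if (any(theta >= 1 / n))
    stop(sprintf("`theta` must be < 1/n = %g (full saturation is unreachable)", 1 / n))
  d <- n * theta
  free <- 1 - d                       # fraction of free lattice sites
  if (abs(omega - 1) < .OMEGA_SINGULAR_TOL) {
    # non-cooperative large-ligand limit
    rate <- K * free * (free / (1 - (n - 1) * theta))^(n - 1)
  } else {
    R <- sqrt((1 - (n + 1) * theta)^2 + 4 * omega * theta * free)
    b1 <- ((2 * omega - 1) * free + theta - R) / (2 * (omega - 1) * free)
    b2 <- (1 - (n + 1) * theta + R) / (2 * free)
    rate <- K * free * b1^(n - 1) * b2^2
  }
  out <- theta / rate
  out[theta == 0] <- 0
  out
}

#' Bound-ligand density at a given free concentration
#'
#' Inverts [mvh_concentration()] by bisection on `theta` in `[0, 1/n)`,
#' exploiting strict monotonicity of `c(theta)`. The bisection runs until the
#' implied concentration matches the target to better than 1e-13 relative or
#' the bracketing interval is exhausted at machine precision, so the
#' round-trip `mvh_concentration(mvh_coverage(c)) == c` holds to well below
#' 1e-9 relative even near saturation.
#'
#' @param c Free protein concentration(s), uM, `>= 0`. Vectorised.
#' @param params A [lattice_params()] object.
#' @return `theta`, bound-ligand density per site, in `[0, 1/n)`.
#' @examples
#' p <- lattice_params(K = 2, omega = 1, n = 1)
#' mvh_coverage(0.5, p)  # Langmuir Kc/(1+Kc) = 0.5
#' @export
mvh_coverage <- function(c, params) {
  params <- .as_lattice_params(params)
  n <- params$n
  if (any(!is.finite(c)) || any(c < 0))
    stop("`c` must be finite and >= 0")
  m <- length(c)
  lo <- numeric(m)
  hi <- rep((1 - 1e-12) / n, m)
  # frozen upper bound: c(hi) may be Inf-ish but finite; bisection only needs order
  active <- c > 0
  if (!any(active)) return(numeric(m))
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    cm <- mvh_concentration(mid[active], params)
    below <- cm < c[active]
    lo[active][below] <- mid[active][below]
    hi[active][!below] <- mid[active][!below]
    # converged where implied c matches or interval exhausted
    done_c <- abs(cm - c[active]) <= 1e-13 * c[active]
    done_w <- (hi[active] - lo[active]) <= .Machine$double.eps * hi[active]
    done <- done_c | done_w
    if (any(done)) {
      # freeze converged entries at their midpoint
      idx <- which(active)[done]
      lo[idx] <- hi[idx] <- mid[idx]
      active[idx] <- FALSE
    }
    if (!any(active)) break
  }
  (lo + hi) / 2
}

#' Exact coverage on a finite linear lattice (transfer matrix)
#'
#' Independent reference for the infinite-lattice McGhee-von Hippel isotherm:
#' the grand-canonical partition function of a linear lattice of `M` sites on
#' which each bound ligand covers `n` contiguous sites with statistical
#' weight `K*c`, and each pair of ligands in immediate contact gains an extra
#' factor `omega`. The recursion over the position of the last covered site,
#' \deqn{E(m) = E(m-1) + L(m-1), \quad
#'       L(m) = Kc\,[E(m-n) + \omega L(m-n)],}
#' (`E`: site `m` empty; `L`: a ligand ends exactly at `m`) is accumulated
#' with per-step rescaling so arbitrarily large `M` and `Kc` cannot overflow.
#' The mean number of bound ligands is obtained from the simultaneous
#' recursion for the derivative with respect to `log(Kc)`.
#'
#' @param M Lattice length in sites (integer >= 1).
#' @param c Free concentration(s), uM. Vectorised.
#' @param params A [lattice_params()] object.
#' @return `theta_exact` = expected bound ligands / `M`, in `[0, 1/n]`.
#' @examples
#' p <- lattice_params(K = 1, omega = 5, n = 2)
#' finite_lattice_coverage(4, 1, p)
#' @export
finite_lattice_coverage <- function(M, c, params) {
  params <- .as_lattice_params(params)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || abs(M - round(M)) > 1e-8)
    stop("`M` must be a single integer >= 1")
  M <- as.integer(round(M))
  if (any(!is.finite(c)) || any(c < 0))
    stop("`c` must be finite and >= 0")
  vapply(c, function(ci) .finite_lattice_theta(M, ci, params), numeric(1))
}

.finite_lattice_theta <- function(M, c, params) {
  n <- params$n; K <- params$K; omega <- params$omega
  if (c == 0 || M < n) return(0)
  Kc <- K * c
  # ring buffers over the last n+1 positions of (E, L, dE, dL)
  # index i in 1..(n+1) holds position m - (i-1)
  width <- n + 1L
  # ring buffers holding positions m-1 .. m-n plus the current one
  Ebuf <- numeric(width); Lbuf <- numeric(width)
  dEbuf <- numeric(width); dLbuf <- numeric(width)
  # Ebuf[(m %% width)+1] holds values at position m
  set_at <- function(buf, m, v) { buf[(m %% width) + 1L] <- v; buf }
  at <- function(buf, m) buf[(m %% width) + 1L]
  Ebuf <- set_at(Ebuf, 0L, 1); Lbuf <- set_at(Lbuf, 0L, 0)
  dEbuf <- set_at(dEbuf, 0L, 0); dLbuf <- set_at(dLbuf, 0L, 0)
  for (m in 1:M) {
    Em1 <- at(Ebuf, m - 1L); Lm1 <- at(Lbuf, m - 1L)
    dEm1 <- at(dEbuf, m - 1L); dLm1 <- at(dLbuf, m - 1L)
    Em <- Em1 + Lm1
    dEm <- dEm1 + dLm1
    if (m >= n) {
      Emn <- at(Ebuf, m - n); Lmn <- at(Lbuf, m - n)
      dEmn <- at(dEbuf, m - n); dLmn <- at(dLbuf, m - n)
      Lm <- Kc * (Emn + omega * Lmn)
      # d/dlog(Kc): product rule -> Lm itself plus propagated derivative
      dLm <- Lm + Kc * (dEmn + omega * dLmn)
    } else {
      Lm <- 0; dLm <- 0
    }
    # rescale all buffers to keep magnitudes bounded; ratios are invariant
    s <- Em + Lm
    if (s > 1e100 || (s > 0 && s < 1e-100)) {
      Ebuf <- Ebuf / s; Lbuf <- Lbuf / s
      dEbuf <- dEbuf / s; dLbuf <- dLbuf / s
      Em <- Em / s; Lm <- Lm / s; dEm <- dEm / s; dLm <- dLm / s
    }
    Ebuf <- set_at(Ebuf, m, Em); Lbuf <- set_at(Lbuf, m, Lm)
    dEbuf <- set_at(dEbuf, m, dEm); dLbuf <- set_at(dLbuf, m, dLm)
  }
  Z <- at(Ebuf, M) + at(Lbuf, M)
  dZ <- at(dEbuf, M) + at(dLbuf, M)
  (dZ / Z) / M
}
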