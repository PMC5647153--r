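#' TPM bead-excursion calibration model
#'
#' The empirical calibration linking the root-mean-square (RMS) excursion of
#' a tethered bead to the apparent persistence length `Lp` of its DNA tether,
#' \deqn{RMS = a - b\,(1 + \alpha L_p)^{-\beta},}
#' with defaults `a = 233` nm, `b = 156` nm, `alpha = 0.08` /nm and
#' `beta = 0.45` for a 685-bp tether. RMS rises monotonically with tether
#' stiffness from `a - b` (floppy limit) towards the asymptote `a`; H-NS
#' filament formation stiffens the DNA and so raises RMS.
#'
#' @param a Asymptotic RMS, nm.
#' @param b Amplitude, nm (`0 < b < a`).
#' @param alpha Persistence-length scale, 1/nm.
#' @param beta Exponent magnitude (positive).
#' @return An object of class `tpm_calibration`.
#' @examples
#' tpm_calibration()
#' @export
tpm_calibration <- function(a = 233, b = 156, alpha = 0.08, beta = 0.45) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(alpha), is.numeric(beta))
  if (!(a > b && b > 0)) stop("calibration requires a > b > 0")
  if (alpha <= 0 || beta <= 0) stop("calibration requires alpha > 0 and beta > 0")
  structure(list(a = a, b = b, alpha = alpha, beta = beta),
            class = "tpm_calibration")
}

#' @export
print.tpm_calibration <- function(x, ...) {
  cat(sprintf("TPM calibration: RMS = %g - %g (1 + %g Lp)^(-%g)  [nm]\n",
              x$a, x$b, x$alpha, x$beta))
  cat(sprintf("  admissible RMS range: (%g, %g) nm\n", x$a - x$b, x$a))
  invisible(x)
}

#' Persistence length to RMS excursion
#'
#' @param Lp Apparent persistence length(s), nm, `>= 0`.
#' @param model A [tpm_calibration()].
#' @return RMS excursion(s), nm, in `[a - b, a)`.
#' @examples
#' lp_to_rms(0)    # 77 nm with default constants
#' lp_to_rms(1e9)  # approaches the 233 nm asymptote
#' @export
lp_to_rms <- function(Lp, model = tpm_calibration()) {
  if (any(!is.finite(Lp)) || any(Lp < 0))
    stop("`Lp` must be finite and >= 0")
  model$a - model$b * (1 + model$alpha * Lp)^(-model$beta)
}

#' RMS excursion to persistence length
#'
#' Closed-form inverse of [lp_to_rms()]:
#' \eqn{L_p = ([(a - RMS)/b]^{-1/\beta} - 1)/\alpha}.
#'
#' @param rms RMS excursion(s), nm; must lie strictly inside `(a - b, a)`.
#' @param model A [tpm_calibration()].
#' @return Persistence length(s), nm.
#' @export
rms_to_lp <- function(rms, model = tpm_calibration()) {
  lo <- model$a - model$b
  bad <- !is.finite(rms) | rms <= lo | rms >= model$a
  if (any(bad))
    stop(sprintf(
      "RMS value(s) %s outside the calibration range (%g, %g) nm",
      paste(signif(rms[bad], 4), collapse = ", "), lo, model$a))
  (((model$a - rms) / model$b)^(-1 / model$beta) - 1) / model$alpha
}

# dLp/drms, used for delta-method error propagation
.dlp_drms <- function(rms, model) {
  u <- (model$a - rms) / model$b
  u^(-1 / model$beta - 1) / (model$alpha * model$beta * model$b)
}

#' Fractional coverage from apparent persistence length
#'
#' Reciprocal interpolation between the naked-DNA and protein-saturated
#' persistence lengths:
#' \deqn{d = \frac{1/L_{p,meas} - 1/L_{p,naked}}{1/L_{p,sat} - 1/L_{p,naked}}.}
#' Values pushed outside `[0, 1]` by noise are clipped, with the raw value
#' kept in the `"raw"` attribute and a warning when the excursion is large.
#'
#' @param Lp_measured Apparent persistence length(s), nm.
#' @param Lp_naked Persistence length of the bare tether, nm.
#' @param Lp_saturated Persistence length at binding saturation, nm.
#' @param tol Excursions beyond `[0 - tol, 1 + tol]` trigger a warning.
#' @return Coverage value(s) in `[0, 1]` with attribute `raw`.
#' @examples
#' coverage_from_lp(50, 50, 300)   # 0
#' coverage_from_lp(300, 50, 300)  # 1
#' @export
coverage_from_lp <- function(Lp_measured, Lp_naked, Lp_saturated, tol = 0.05) {
  if (any(c(Lp_measured, Lp_naked, Lp_saturated) <= 0))
    stop("all persistence lengths must be positive")
  if (abs(Lp_naked - Lp_saturated) < 1e-12)
    stop("degenerate calibration: Lp_naked == Lp_saturated")
  raw <- (1 / Lp_measured - 1 / Lp_naked) / (1 / Lp_saturated - 1 / Lp_naked)
  if (any(raw < -tol | raw > 1 + tol))
    warning(sprintf("%d coverage value(s) outside [0,1] by more than %g; clipped",
                    sum(raw < -tol | raw > 1 + tol), tol))
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "raw") <- raw
  out
}

#' Read a TPM titration table
#'
#' Expects columns `c_uM`, `rms_nm`, `sd_nm`, `n_beads` and optionally `role`
#' (`naked`, `titration` or `saturated`).
#'
#' @param path CSV file path.
#' @return A data frame of class `tpm_dataset`.
#' @export
read_tpm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("c_uM", "rms_nm", "sd_nm", "n_beads")
  if (!all(need %in% names(df)))
    stop("TPM CSV needs columns: ", paste(need, collapse = ", "))
  if (!("role" %in% names(df))) df$role <- "titration"
  class(df) <- c("tpm_dataset", class(df))
  df
}

#' Infer cooperative binding parameters from a TPM titration
#'
#' The full inference chain for a tethered-particle-motion titration of a
#' lattice-binding protein: per-condition RMS excursions are converted to
#' apparent persistence lengths with the calibration model, persistence
#' lengths to fractional coverage by reciprocal interpolation between the
#' naked and saturated reference states, measurement error is propagated by
#' the delta method (variance of the mean RMS, `sd^2/n_beads`, through both
#' transforms) into inverse-variance coverage weights, and the resulting
#' `(c, d)` points are fitted with [fit_binding()] at fixed site size.
#'
#' Reference states default to the rows flagged `role == "naked"` and
#' `role == "saturated"` (averaged). Reference rows pin the coverage scale
#' and are excluded from the regression itself; rows whose RMS falls outside
#' the calibration range are excluded altogether and reported in `rejects`.
#'
#' @param data A data frame as from [read_tpm_csv()] or
#'   [gen_tpm_dataset()]: columns `c_uM`, `rms_nm`, `sd_nm`, `n_beads`,
#'   optional `role`.
#' @param model A [tpm_calibration()].
#' @param Lp_naked,Lp_saturated Optional reference persistence lengths (nm);
#'   derived from the flagged rows when missing.
#' @param n_fixed Binding-site size, bp (default 30 for H-NS).
#' @param init Optional starting values passed to [fit_binding()].
#' @return An object of class `c("tpm_fit", "mvh_fit")`: the binding fit plus
#'   `coverage` (per-condition series with `Lp`, `d`, raw `d`, weights),
#'   `rejects` (excluded rows with reasons) and the reference `Lp` values.
#' @examples
#' spec <- tpm_gen_spec(noise_sd = 0)
#' fit <- fit_tpm(gen_tpm_dataset(spec))
#' coef(fit)
#' @export
fit_tpm <- function(data, model = tpm_calibration(),
                    Lp_naked = NULL, Lp_saturated = NULL,
                    n_fixed = 30, init = NULL) {
  df <- as.data.frame(data)
  need <- c("c_uM", "rms_nm", "sd_nm", "n_beads")
  if (!all(need %in% names(df)))
    stop("TPM data needs columns: ", paste(need, collapse = ", "))
  if (!("role" %in% names(df))) df$role <- "titration"
  if (any(df$n_beads < 1)) stop("`n_beads` must be >= 1")

  lo <- model$a - model$b
  ok <- df$rms_nm > lo & df$rms_nm < model$a
  rejects <- df[!ok, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- sprintf(
    "RMS outside calibration range (%g, %g) nm", lo, model$a)
  acc <- df[ok, , drop = FALSE]
  if (!nrow(acc)) stop("no TPM rows inside the calibration range")

  acc$Lp <- rms_to_lp(acc$rms_nm, model)
  if (is.null(Lp_naked)) {
    nk <- acc$Lp[acc$role == "naked"]
    if (!length(nk)) stop("no `naked` rows and no `Lp_naked` supplied")
    Lp_naked <- mean(nk)
  }
  if (is.null(Lp_saturated)) {
    st <- acc$Lp[acc$role == "saturated"]
    if (!length(st)) stop("no `saturated` rows and no `Lp_saturated` supplied")
    Lp_saturated <- mean(st)
  }

  d <- coverage_from_lp(acc$Lp, Lp_naked, Lp_saturated)
  acc$d_raw <- attr(d, "raw")
  acc$d <- as.numeric(d)

  # delta method: Var(d) = (dd/dLp * dLp/drms)^2 * sd^2/n_beads
  dd_dlp <- (-1 / acc$Lp^2) / (1 / Lp_saturated - 1 / Lp_naked)
  dlp_dr <- .dlp_drms(acc$rms_nm, model)
  var_d <- (dd_dlp * dlp_dr)^2 * acc$sd_nm^2 / acc$n_beads
  acc$weight_d <- 1 / pmax(var_d, 1e-12)

  # reference rows define the coverage scale; only titration rows are fitted
  tit <- acc[!(acc$role %in% c("naked", "saturated")), , drop = FALSE]
  fit <- fit_binding(
    data.frame(c = tit$c_uM, d = tit$d, weight_d = tit$weight_d),
    n_fixed = n_fixed, init = init)
  fit$coverage <- acc
  fit$rejects <- rejects
  fit$Lp_naked <- Lp_naked
  fit$Lp_saturated <- Lp_saturated
  fit$calibration <- model
  class(fit) <- c("tpm_fit", class(fit))
  fit
}

#' @export
print.tpm_fit <- function(x, ...) {
  cat("TPM titration inference\n")
  cat(sprintf("  Lp naked = %.4g nm, Lp saturated = %.4g nm, %d rejected row(s)\n",
              x$Lp_naked, x$Lp_saturated, nrow(x$rejects)))
  NextMethod()
}
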