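#' Specification for a synthetic TPM titration
#'
#' Defines the ground truth for [gen_tpm_dataset()]: the cooperative binding
#' parameters, the concentration grid, the naked and saturated persistence
#' lengths, and the measurement-noise model. Defaults mirror a typical H-NS
#' stiffening titration on a 685-bp tether: `K = 0.1`/uM, `omega = 10`,
#' `n = 30` bp, naked-DNA `Lp = 50` nm rising to 300 nm at saturation, a
#' per-bead RMS standard deviation of 4 nm and 70 tethers per condition.
#' The grid must span fractional saturation from below 0.1 to above 0.9
#' under the true parameters, so the titration constrains both `K` and
#' `omega`.
#'
#' @param K,omega,n True binding parameters (see [lattice_params()]).
#' @param c_grid Titration concentrations, uM.
#' @param Lp_naked,Lp_saturated Reference persistence lengths, nm.
#' @param noise_sd Per-bead RMS standard deviation, nm (the per-condition
#'   mean is perturbed by `noise_sd/sqrt(n_beads)`).
#' @param n_beads Tethers measured per condition.
#' @param n_ref Number of naked and of saturated reference rows.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return An object of class `tpm_gen_spec`.
#' @export
tpm_gen_spec <- function(K = 0.1, omega = 10, n = 30,
                         c_grid = 10^seq(-2.5, 1.5, length.out = 14),
                         Lp_naked = 50, Lp_saturated = 300,
                         noise_sd = 4, n_beads = 70, n_ref = 2, seed = 1) {
  params <- lattice_params(K, omega, n)
  if (any(c_grid < 0)) stop("concentrations must be >= 0")
  if (Lp_naked <= 0 || Lp_saturated <= 0 || Lp_naked == Lp_saturated)
    stop("reference persistence lengths must be positive and distinct")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  d <- n * mvh_coverage(c_grid, params)
  if (min(d) >= 0.1 || max(d) <= 0.9)
    stop(sprintf(
      "concentration grid must span d < 0.1 to d > 0.9 under the true parameters (got %.3f-%.3f)",
      min(d), max(d)))
  structure(list(params = params, c_grid = c_grid, Lp_naked = Lp_naked,
                 Lp_saturated = Lp_saturated, noise_sd = noise_sd,
                 n_beads = n_beads, n_ref = as.integer(n_ref),
                 seed = as.integer(seed)),
            class = "tpm_gen_spec")
}

#' Generate a synthetic TPM titration table
#'
#' Runs the forward model of the TPM analysis chain: fractional saturation
#' from the McGhee-von Hippel isotherm at each concentration, persistence
#' length by reciprocal interpolation between the naked and saturated
#' references, RMS excursion through the calibration model, plus Gaussian
#' noise on the per-condition mean with standard deviation
#' `noise_sd/sqrt(n_beads)`. Reference rows (`role` `naked`/`saturated`) are
#' emitted alongside the titration rows.
#'
#' @param spec A [tpm_gen_spec()].
#' @param model A [tpm_calibration()].
#' @return A data frame of class `tpm_dataset` with columns `c_uM`,
#'   `rms_nm`, `sd_nm`, `n_beads`, `role` and the ground-truth columns
#'   `d_true`, `Lp_true`.
#' @examples
#' head(gen_tpm_dataset(tpm_gen_spec(noise_sd = 0)))
#' @export
gen_tpm_dataset <- function(spec, model = tpm_calibration()) {
  if (!inherits(spec, "tpm_gen_spec")) stop("`spec` must be a tpm_gen_spec")
  p <- spec$params
  d <- p$n * mvh_coverage(spec$c_grid, p)
  inv_lp <- 1 / spec$Lp_naked + d * (1 / spec$Lp_saturated - 1 / spec$Lp_naked)
  Lp <- 1 / inv_lp
  c_ref <- max(spec$c_grid) * 3
  df <- data.frame(
    c_uM = c(rep(0, spec$n_ref), spec$c_grid, rep(c_ref, spec$n_ref)),
    Lp_true = c(rep(spec$Lp_naked, spec$n_ref), Lp,
                rep(spec$Lp_saturated, spec$n_ref)),
    d_true = c(rep(0, spec$n_ref), d, rep(1, spec$n_ref)),
    role = c(rep("naked", spec$n_ref), rep("titration", length(spec$c_grid)),
             rep("saturated", spec$n_ref)),
    stringsAsFactors = FALSE)
  rms <- lp_to_rms(df$Lp_true, model)
  set.seed(spec$seed)
  rms <- rms + stats::rnorm(length(rms), 0, spec$noise_sd / sqrt(spec$n_beads))
  lo <- model$a - model$b
  if (any(rms <= lo | rms >= model$a))
    stop("generated RMS outside the calibration range; adjust Lp bounds or noise")
  df$rms_nm <- rms
  df$sd_nm <- spec$noise_sd
  df$n_beads <- spec$n_beads
  df <- df[, c("c_uM", "rms_nm", "sd_nm", "n_beads", "role", "d_true", "Lp_true")]
  class(df) <- c("tpm_dataset", class(df))
  df
}

#' Generate synthetic DNA-bridging scintillation counts
#'
#' Simulates a bridging titration at the counting scale of a
#' \eqn{{}^{32}}P-labelled 685-bp prey DNA assay (~8000 cpm of input DNA):
#' for each condition the expected signal is
#' `background + recovery/100 * (total - background)` and observed
#' counts-per-minute are Poisson draws around it, in `replicates` technical
#' replicates. Background rows (no bridging protein) and reference rows (the
#' full labelled DNA input) are included so [recovery_percent()] can be
#' applied exactly as to real data.
#'
#' @param axis Numeric vector of condition values (e.g. MgCl2 in mM).
#' @param recovery Programmed recovery per condition, percent in `[0, 100]`
#'   (recycled to `length(axis)`).
#' @param axis_name Name of the condition variable.
#' @param total_cpm Expected reference (input DNA) counts per minute.
#' @param background_cpm Expected background counts per minute.
#' @param replicates Technical replicates per row.
#' @param seed RNG seed.
#' @return A data frame with columns `condition`, `role`
#'   (`sample`/`background`/`reference`), `replicate`, `cpm` and the
#'   ground-truth `recovery_true`; the axis name is kept in
#'   `attr(, "axis_name")`.
#' @examples
#' counts <- gen_bridging_counts(axis = 0:6, recovery = seq(0, 60, 10), seed = 7)
#' head(counts)
#' @export
gen_bridging_counts <- function(axis, recovery, axis_name = "MgCl2_mM",
                                total_cpm = 8000, background_cpm = 250,
                                replicates = 3, seed = 1) {
  if (any(recovery < 0 | recovery > 100))
    stop("programmed recovery must be in [0, 100] percent")
  if (total_cpm <= background_cpm)
    stop("`total_cpm` must exceed `background_cpm`")
  recovery <- rep_len(recovery, length(axis))
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_along(axis)) {
    mu <- background_cpm + recovery[i] / 100 * (total_cpm - background_cpm)
    rows[[i]] <- data.frame(
      condition = axis[i], role = "sample", replicate = seq_len(replicates),
      cpm = stats::rpois(replicates, mu), recovery_true = recovery[i])
  }
  bg <- data.frame(condition = NA_real_, role = "background",
                   replicate = seq_len(replicates),
                   cpm = stats::rpois(replicates, background_cpm),
                   recovery_true = NA_real_)
  rf <- data.frame(condition = NA_real_, role = "reference",
                   replicate = seq_len(replicates),
                   cpm = stats::rpois(replicates, total_cpm),
                   recovery_true = NA_real_)
  out <- do.call(rbind, c(rows, list(bg, rf)))
  attr(out, "axis_name") <- axis_name
  out
}
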