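#' DNA recovery from scintillation counts
#'
#' Background-corrected, reference-normalised recovery of prey DNA:
#' \deqn{recovery = 100\,\frac{cpm_{sample} - cpm_{background}}
#'   {cpm_{reference} - cpm_{background}}}
#' where the background is a sample lacking the bridging protein and the
#' reference carries the full labelled DNA input. Negative corrected counts
#' are floored at 0 for reporting; the unfloored value is kept in the
#' `"raw"` attribute for statistics.
#'
#' @param sample_cpm Sample counts per minute (vectorised).
#' @param background_cpm Background counts per minute.
#' @param reference_cpm Reference counts per minute; must exceed the
#'   background.
#' @return Recovery in percent, floored at 0, with attribute `raw`.
#' @examples
#' recovery_percent(c(250, 8000, 3350), 250, 8000)
#' @export
recovery_percent <- function(sample_cpm, background_cpm, reference_cpm) {
  if (any(sample_cpm < 0) || background_cpm < 0 || reference_cpm < 0)
    stop("counts must be non-negative")
  if (reference_cpm <= background_cpm)
    stop("invalid reference: reference_cpm must exceed background_cpm")
  raw <- 100 * (sample_cpm - background_cpm) / (reference_cpm - background_cpm)
  out <- pmax(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' Aggregate a bridging-count table into a recovery curve
#'
#' Computes per-condition recovery (mean and sd across replicates) from a
#' long table of counts as produced by [gen_bridging_counts()] or read from
#' a CSV with columns `condition`, `role` (`sample`/`background`/
#' `reference`), `replicate`, `cpm`. Background and reference counts are
#' averaged across their replicates before normalisation, so the replicate
#' mean of recoveries equals the recovery of mean counts.
#'
#' @param counts Data frame of counts.
#' @param axis_name Condition-variable name for reporting (taken from the
#'   table's `axis_name` attribute when present).
#' @return A data frame of class `recovery_curve`: `condition`, `recovery`
#'   (percent, floored), `recovery_raw`, `sd` across replicates, `n`.
#' @export
recovery_curve <- function(counts, axis_name = NULL) {
  need <- c("condition", "role", "cpm")
  if (!all(need %in% names(counts)))
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  bg <- mean(counts$cpm[counts$role == "background"])
  rf <- mean(counts$cpm[counts$role == "reference"])
  if (!is.finite(bg) || !is.finite(rf))
    stop("counts table must contain background and reference rows")
  smp <- counts[counts$role == "sample", , drop = FALSE]
  conds <- unique(smp$condition)
  rows <- lapply(conds, function(cd) {
    cc <- smp$cpm[smp$condition == cd]
    rec <- recovery_percent(cc, bg, rf)
    data.frame(condition = cd, recovery = mean(rec),
               recovery_raw = mean(attr(rec, "raw")),
               sd = stats::sd(attr(rec, "raw")), n = length(cc))
  })
  out <- do.call(rbind, rows)
  attr(out, "axis_name") <- axis_name %||% attr(counts, "axis_name") %||% "condition"
  class(out) <- c("recovery_curve", class(out))
  out
}

#' Characterise a titration transition with a 4-parameter logistic
#'
#' Fits \eqn{y = A + (B - A)/(1 + e^{-k(x - m)})} (floor `A`, ceiling `B`,
#' midpoint `m`, rate `k > 0`) to recovery versus the condition variable by
#' least squares, and summarises the transition: `midpoint` (`m`),
#' `direction` (sign of `B - A`: +1 for recovery rising with the axis
#' variable, -1 for falling) and `width`, the axis interval between 10% and
#' 90% of the amplitude (`log(81)/k`). A curve whose amplitude is below 5
#' percentage points is reported as having no transition rather than fitted.
#'
#' @param curve A [recovery_curve()] or data frame with `condition` and
#'   `recovery`.
#' @return An object of class `titration_fit`: `midpoint`, `width`,
#'   `direction`, `floor`, `ceiling`, `rate`, `transition` (logical),
#'   `fitted` values and the data.
#' @examples
#' x <- seq(0, 12, 1)
#' y <- 60 / (1 + exp(-2.2 * (x - 5)))
#' titration_transition(data.frame(condition = x, recovery = y))
#' @export
titration_transition <- function(curve) {
  df <- as.data.frame(curve)
  if (!all(c("condition", "recovery") %in% names(df)))
    stop("curve needs columns `condition` and `recovery`")
  df <- df[order(df$condition), , drop = FALSE]
  if (nrow(df) < 5)
    stop("need at least 5 conditions spanning both plateaus")
  x <- df$condition; y <- df$recovery
  amp <- max(y) - min(y)
  if (amp < 5) {
    out <- list(transition = FALSE, midpoint = NA_real_, width = NA_real_,
                direction = 0, floor = mean(y), ceiling = mean(y),
                rate = NA_real_, fitted = rep(mean(y), length(y)), data = df)
    class(out) <- "titration_fit"
    return(out)
  }
  # rising or falling start values from the data ends
  rising <- mean(y[x >= stats::quantile(x, 0.8)]) >
    mean(y[x <= stats::quantile(x, 0.2)])
  A0 <- if (rising) min(y) else max(y)
  B0 <- if (rising) max(y) else min(y)
  m0 <- stats::approx(y, x, xout = (min(y) + max(y)) / 2, ties = mean)$y
  if (!is.finite(m0)) m0 <- stats::median(x)
  k0 <- 4 / max(diff(range(x)) / 4, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      recovery ~ A + (B - A) / (1 + exp(-exp(logk) * (condition - m))),
      data = df, start = list(A = A0, B = B0, m = m0, logk = log(k0)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a direct least-squares search
    obj <- function(p) sum((y - (p[1] + (p[2] - p[1]) /
                                   (1 + exp(-exp(p[4]) * (x - p[3])))))^2)
    op <- stats::optim(c(A0, B0, m0, log(k0)), obj,
                       control = list(maxit = 5000, reltol = 1e-14))
    cf <- c(A = op$par[1], B = op$par[2], m = op$par[3], logk = op$par[4])
    fitted <- cf["A"] + (cf["B"] - cf["A"]) /
      (1 + exp(-exp(cf["logk"]) * (x - cf["m"])))
  } else {
    cf <- stats::coef(fit)
    fitted <- stats::fitted(fit)
  }
  k <- exp(cf[["logk"]])
  out <- list(transition = TRUE, midpoint = cf[["m"]], width = log(81) / k,
              direction = sign(cf[["B"]] - cf[["A"]]),
              floor = cf[["A"]], ceiling = cf[["B"]], rate = k,
              fitted = as.numeric(fitted), data = df)
  class(out) <- "titration_fit"
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  if (!x$transition) {
    cat("Titration: no transition (amplitude < 5 percentage points)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Titration transition: midpoint %.4g, 10-90%% width %.4g, direction %+d\n",
    x$midpoint, x$width, x$direction))
  cat(sprintf("  plateaus: %.3g%% -> %.3g%% recovery\n", x$floor, x$ceiling))
  invisible(x)
}

#' @export
plot.titration_fit <- function(x, ...) {
  graphics::plot(x$data$condition, x$data$recovery,
                 xlab = "condition", ylab = "recovery (%)", ...)
  ord <- order(x$data$condition)
  graphics::lines(x$data$condition[ord], x$fitted[ord], col = "firebrick",
                  lwd = 2)
  invisible(x)
}
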