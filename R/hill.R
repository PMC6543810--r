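#' Fractional current block
#'
#' `block = 1 - I_drug / I_control`: 0 means no inhibition, 1 full block.
#' Currents must share sign and the control must be non-zero.
#'
#' @param control_current control current level (e.g. pA).
#' @param drug_current current level with the test compound.
#' @return fractional block (vectorized).
#' @export
fractional_block <- function(control_current, drug_current) {
  if (any(control_current == 0)) stop("control current must be non-zero")
  1 - drug_current / control_current
}

hill_block <- function(conc, ic50, h) {
  r <- (conc / ic50)^h
  r / (1 + r)
}

#' Fit the Hill equation to dose-response data
#'
#' Least-squares fit of `B([D]) = ([D]/IC50)^h / (1 + ([D]/IC50)^h)` to
#' fractional-block data, with the bottom fixed at 0 and the top at 1
#' (responses are normalized to control).  Default fit target is the
#' per-dose mean block with inverse-SE^2 weights; replicate-level and
#' unweighted modes are available.
#'
#' @param table data.frame with columns `conc` (micromolar, > 0) and
#'   `block`; replicate rows share a `conc` value.  A `kir_dose_table` from
#'   [gen_dose_response()] works directly.
#' @param weighting `"se"` (per-dose means weighted by 1/SE^2; falls back
#'   to unweighted means when SEs are degenerate), `"none"` (unweighted
#'   means), or `"replicates"` (all replicate points, unweighted).
#' @param start optional list with `ic50` and `h` initial values; defaults
#'   to the geometric-mean dose and h = 1.
#' @return object of class `kir_hill`: fitted `ic50` (micromolar), `h`,
#'   their standard errors, residual sum of squares, `converged`, and the
#'   underlying `nls` fit.
#' @export
fit_hill <- function(table, weighting = c("se", "none", "replicates"),
                     start = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("conc", "block") %in% names(table)))
  if (any(table$conc <= 0)) stop("concentrations must be positive")
  doses <- sort(unique(table$conc))
  if (length(doses) < 3L) stop("need at least 3 distinct concentrations")
  if (all(table$block <= 1e-9) || all(table$block >= 1 - 1e-9))
    stop("responses are all at one asymptote; IC50 is not identifiable")

  if (weighting == "replicates") {
    dat <- data.frame(conc = table$conc, y = table$block)
    w <- rep(1, nrow(dat))
  } else {
    agg_m <- tapply(table$block, table$conc, mean)
    agg_n <- tapply(table$block, table$conc, length)
    agg_s <- tapply(table$block, table$conc, sd)
    se <- as.numeric(agg_s) / sqrt(as.numeric(agg_n))
    dat <- data.frame(conc = as.numeric(names(agg_m)), y = as.numeric(agg_m))
    w <- rep(1, nrow(dat))
    if (weighting == "se" && all(is.finite(se)) && all(se > 1e-8))
      w <- 1 / se^2
  }
  if (is.null(start))
    start <- list(ic50 = exp(mean(log(doses))), h = 1)
  fit <- minpack.lm::nlsLM(
    y ~ (conc / ic50)^h / (1 + (conc / ic50)^h),
    data = dat, weights = w,
    start = list(ic50 = start$ic50, h = start$h),
    lower = c(ic50 = 1e-6, h = 1e-3), upper = c(ic50 = 1e4, h = 5),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  ses <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(list(ic50 = unname(est["ic50"]), h = unname(est["h"]),
                 ic50_se = unname(ses[1]), h_se = unname(ses[2]),
                 rss = sum(residuals(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 weighting = weighting, n_doses = length(doses), fit = fit),
            class = "kir_hill")
}

#' @export
print.kir_hill <- function(x, ...) {
  cat(sprintf("<kir_hill> IC50 = %.4g +/- %.2g uM, h = %.3g +/- %.2g (%s, %d doses)%s\n",
              x$ic50, x$ic50_se, x$h, x$h_se, x$weighting, x$n_doses,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' @export
summary.kir_hill <- function(object, ...) {
  out <- data.frame(parameter = c("IC50 (uM)", "Hill coefficient"),
                    estimate = c(object$ic50, object$h),
                    se = c(object$ic50_se, object$h_se))
  cat(sprintf("Hill fit (%s weighting), RSS = %.4g, converged = %s\n",
              object$weighting, object$rss, object$converged))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.kir_hill <- function(object, ...) c(ic50 = object$ic50, h = object$h)

#' @export
predict.kir_hill <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$fit$m$getEnv()$conc else
    if (is.data.frame(newdata)) newdata$conc else as.numeric(newdata)
  hill_block(conc, object$ic50, object$h)
}

#' @export
plot.kir_hill <- function(x, table = NULL, ...) {
  conc <- exp(seq(log(1e-2), log(1e3), length.out = 200))
  plot(conc, predict(x, conc), log = "x", type = "l",
       xlab = "[D] (uM)", ylab = "fractional block", ylim = c(0, 1), ...)
  if (!is.null(table)) graphics::points(table$conc, table$block)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Drug-induced rectification index and paired comparison
#'
#' Compares outward (+50 mV) and inward (-80 mV) fractional block.  The
#' index is `mean(block_outward) / mean(block_inward)`; a paired two-tailed
#' t-test over the per-patch differences declares the compound "rectifying"
#' when the index exceeds 1 at significance `alpha`.
#'
#' @param block_outward,block_inward fractional-block vectors; equal length
#'   and paired by patch when `paired = TRUE` (the standard design).
#' @param paired paired test (default TRUE).
#' @param alpha significance level (default 0.001, the stringent threshold
#'   used for reporting rectification).
#' @return list of class `kir_rectification`: `index`, `t`, `p`,
#'   `rectifying`, sample size `n`.
#' @export
rectification <- function(block_outward, block_inward, paired = TRUE,
                          alpha = 0.001) {
  if (paired && length(block_outward) != length(block_inward))
    stop("paired test needs equal-length samples")
  n <- length(block_outward)
  if (n < 2L) stop("need at least 2 observations for the test")
  mi <- mean(block_inward)
  index <- if (abs(mi) < 1e-12) Inf else mean(block_outward) / mi
  d <- block_outward - block_inward
  if (paired && sd(d) < 1e-12) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(block_outward, block_inward, paired = paired)
  }
  structure(list(index = index, t = unname(tt$statistic), p = tt$p.value,
                 rectifying = is.finite(index) && index > 1 && tt$p.value < alpha,
                 n = n, alpha = alpha),
            class = "kir_rectification")
}

#' @export
print.kir_rectification <- function(x, ...) {
  cat(sprintf("<kir_rectification> index = %.3g, t = %.3g, p = %.3g -> %s (alpha = %g, n = %d)\n",
              x$index, x$t, x$p,
              if (x$rectifying) "rectifying" else "not rectifying", x$alpha, x$n))
  invisible(x)
}
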