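# Boltzmann constant in kJ/(mol K)
kB_kj <- 0.0083145

#' Construct an umbrella window
#'
#' @param center restraint center xi_i in nm.
#' @param k harmonic force constant in kJ/(mol nm^2) (> 0 for a biased
#'   window; 0 denotes an unbiased window).
#' @param samples reaction-coordinate time series in nm.
#' @return list of class `kir_window`.
#' @export
umbrella_window <- function(center, k, samples) {
  samples <- as.numeric(samples)
  if (k < 0) stop("force constant must be >= 0")
  if (length(samples) < 1L) stop("window needs at least one sample")
  if (!all(is.finite(samples))) stop("window samples must be finite")
  structure(list(center = center, k = k, samples = samples),
            class = "kir_window")
}

#' Read umbrella windows from pull-coordinate files
#'
#' Reads one two-column whitespace/comma text file per window (time,
#' reaction coordinate in nm) plus a metadata table giving each window's
#' restraint center and force constant.  The first `equil_fraction` of each
#' series is dropped as equilibration (default 10%, matching a 10 ns window
#' with 1 ns equilibration).
#'
#' @param metadata data.frame (or CSV path) with columns `file`, `center`,
#'   `k`.
#' @param dir directory the `file` column is relative to.
#' @param equil_fraction initial fraction of each series to discard.
#' @return list of `kir_window`.
#' @export
read_umbrella_windows <- function(metadata, dir = ".", equil_fraction = 0.1) {
  if (is.character(metadata)) metadata <- read.csv(metadata, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "center", "k") %in% names(metadata)))
  lapply(seq_len(nrow(metadata)), function(i) {
    tab <- read.table(file.path(dir, metadata$file[i]), header = FALSE,
                      comment.char = "#")
    xi <- as.numeric(tab[[min(2L, ncol(tab))]])
    drop <- floor(length(xi) * equil_fraction)
    if (drop > 0) xi <- xi[-seq_len(drop)]
    umbrella_window(metadata$center[i], metadata$k[i], xi)
  })
}

# shared histogram machinery: common breaks covering all windows
wham_breaks <- function(windows, bin_width) {
  rng <- range(unlist(lapply(windows, `[[`, "samples")))
  lo <- floor(rng[1] / bin_width) * bin_width
  hi <- ceiling(rng[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi + 1e-12, by = bin_width)
}

window_histogram <- function(w, breaks) {
  h <- hist(w$samples, breaks = breaks, plot = FALSE)
  h$counts
}

#' Weighted histogram analysis of umbrella-sampling windows
#'
#' Solves the WHAM self-consistency equations for the unbiased probability
#' `P(xi_b)` and per-window free energies `F_i`:
#' `P(b) = sum_i n_i(b) / sum_j N_j exp(-beta (w_j(b) - F_j))` and
#' `exp(-beta F_j) = sum_b P(b) exp(-beta w_j(b))` with harmonic biases
#' `w_j(xi) = k_j (xi - xi_j)^2 / 2`, iterated until the largest change in
#' any `F_j` falls below `tol`.  The profile `W = -kB T log P` is anchored
#' to zero at the largest-xi populated bin (the ligand-in-bulk reference, so
#' the solvent plateau sits at zero).
#'
#' @param windows list of `kir_window`.
#' @param temperature_K temperature in K (default 310).
#' @param bin_width histogram bin width in nm (default 0.02).
#' @param tol convergence tolerance on free-energy updates, kJ/mol.
#' @param max_iter iteration cap.
#' @param breaks optional explicit histogram breaks (nm); used by the
#'   bootstrap so resamples share the point estimate's grid.
#' @param anchor `"bulk"` (zero at largest-xi populated bin), `"min"`
#'   (zero at the minimum) or a numeric xi value whose bin is zeroed.
#' @return object of class `kir_pmf`: bin centers `xi` (nm), free energy
#'   `W` (kJ/mol, NA for unpopulated bins), standard errors `se` (NA until
#'   bootstrapped), window free energies `F`, `converged`, `iterations`.
#' @export
wham <- function(windows, temperature_K = 310, bin_width = 0.02, tol = 1e-6,
                 max_iter = 1e5, breaks = NULL, anchor = "bulk") {
  if (length(windows) == 0L) stop("need at least one window")
  if (temperature_K <= 0) stop("temperature must be positive")
  beta <- 1 / (kB_kj * temperature_K)
  if (is.null(breaks)) breaks <- wham_breaks(windows, bin_width)
  xi <- (head(breaks, -1) + breaks[-1]) / 2
  counts <- t(vapply(windows, window_histogram, numeric(length(xi)), breaks = breaks))
  N <- rowSums(counts)
  ntot <- colSums(counts)

  # adjacency diagnostic: consecutive windows (by center) must share support
  if (length(windows) > 1L) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    for (i in seq_len(length(ord) - 1L)) {
      a <- counts[ord[i], ] > 0; b <- counts[ord[i + 1L], ] > 0
      if (!any(a & b))
        stop(sprintf("umbrella windows at centers %.4g and %.4g nm do not overlap",
                     windows[[ord[i]]]$center, windows[[ord[i + 1L]]]$center))
    }
  }

  w_bias <- t(vapply(windows, function(w) 0.5 * w$k * (xi - w$center)^2,
                     numeric(length(xi))))      # S x B, kJ/mol
  ew <- exp(-beta * w_bias)
  Fj <- numeric(length(windows))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # N and Fj have length S; recycling down the rows of the S x B matrix ew
    # applies the per-window factors to every bin
    denom <- colSums(N * exp(beta * Fj) * ew)
    P <- ifelse(denom > 0, ntot / denom, 0)
    Z <- as.numeric(ew %*% P)
    Fnew <- -log(Z) / beta
    Fnew <- Fnew - Fnew[1]
    delta <- max(abs(Fnew - Fj))
    Fj <- Fnew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  P <- P / sum(P)
  W <- ifelse(P > 0, -log(P) / beta, NA_real_)
  anchor_idx <- pmf_anchor_index(W, xi, anchor)
  W <- W - W[anchor_idx]
  structure(list(xi = xi, W = W, se = rep(NA_real_, length(W)), F = Fj,
                 temperature = temperature_K, converged = converged,
                 iterations = iter, breaks = breaks, anchor_index = anchor_idx,
                 counts = counts),
            class = "kir_pmf")
}

pmf_anchor_index <- function(W, xi, anchor) {
  populated <- which(!is.na(W))
  if (identical(anchor, "bulk")) populated[which.max(xi[populated])]
  else if (identical(anchor, "min")) populated[which.min(W[populated])]
  else populated[which.min(abs(xi[populated] - as.numeric(anchor)))]
}

#' @export
print.kir_pmf <- function(x, ...) {
  ok <- !is.na(x$W)
  cat(sprintf("<kir_pmf> %d bins over %.4g-%.4g nm, T=%g K, %s after %d iterations\n",
              sum(ok), min(x$xi[ok]), max(x$xi[ok]), x$temperature,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  depth (min W): %.3f kJ/mol at xi=%.3f nm\n",
              min(x$W, na.rm = TRUE), x$xi[which.min(x$W)]))
  invisible(x)
}

#' @export
plot.kir_pmf <- function(x, ...) {
  ok <- !is.na(x$W)
  plot(x$xi[ok], x$W[ok], type = "l", xlab = "reaction coordinate (nm)",
       ylab = "W (kJ/mol)", ...)
  if (any(!is.na(x$se))) {
    up <- x$W + x$se; lo <- x$W - x$se
    oks <- ok & !is.na(x$se)
    polygon(c(x$xi[oks], rev(x$xi[oks])), c(up[oks], rev(lo[oks])),
            border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
    graphics::lines(x$xi[ok], x$W[ok])
  }
  invisible(x)
}

#' Export a PMF profile as CSV (xi, W, SE)
#' @param x a `kir_pmf`.
#' @param file output path.
#' @export
write_pmf <- function(x, file) {
  write.csv(data.frame(xi = x$xi, W = x$W, se = x$se), file, row.names = FALSE)
  invisible(file)
}

#' Bootstrap error bands for a WHAM profile
#'
#' Resamples every window's sample set with replacement `n_boot` times,
#' reruns WHAM on the point estimate's histogram grid, and reports the
#' per-bin standard deviation of the bootstrap profiles as the error band.
#'
#' @param windows list of `kir_window`.
#' @param n_boot number of bootstrap resamples (>= 2; 100 is the
#'   conventional budget).
#' @param seed integer seed (required: bootstrap results must be
#'   reproducible).
#' @param ... passed to [wham()] (temperature, bin width, tolerance, ...).
#' @return the point-estimate `kir_pmf` with `se` filled in and the
#'   bootstrap mean profile in `boot_mean`.
#' @export
bootstrap_pmf <- function(windows, n_boot = 100L, seed, ...) {
  if (missing(seed) || is.null(seed)) stop("bootstrap_pmf requires an explicit seed")
  if (n_boot < 2L) stop("n_boot must be >= 2")
  point <- wham(windows, ...)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rw <- lapply(windows, function(w)
        umbrella_window(w$center, w$k,
                        sample(w$samples, length(w$samples), replace = TRUE)))
      wham(rw, ..., breaks = point$breaks)$W
    }, numeric(length(point$W)))
  })
  boot <- matrix(boot, nrow = length(point$W))
  point$se <- apply(boot, 1, sd, na.rm = TRUE)
  point$boot_mean <- rowMeans(boot, na.rm = TRUE)
  point
}

#' Pairwise histogram overlap between umbrella windows
#'
#' Overlap of two windows is the integral of the minimum of their
#' normalized sample histograms (1 = identical, 0 = disjoint).  Adjacent
#' windows (consecutive centers) with overlap below `threshold` trigger a
#' warning, signalling that intermediate windows should be added.
#'
#' @param windows list of `kir_window` (>= 2).
#' @param bin_width histogram bin width in nm.
#' @param threshold minimal acceptable adjacent overlap (default 0.05).
#' @return matrix of pairwise overlap fractions (window order as given),
#'   with attribute `warnings` (character vector).
#' @export
window_overlap <- function(windows, bin_width = 0.02, threshold = 0.05) {
  if (length(windows) < 2L) stop("need at least two windows")
  breaks <- wham_breaks(windows, bin_width)
  p <- t(vapply(windows, function(w) {
    cnt <- window_histogram(w, breaks)
    cnt / sum(cnt)
  }, numeric(length(breaks) - 1L)))
  S <- length(windows)
  ov <- matrix(1, S, S)
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
    ov[i, j] <- ov[j, i] <- sum(pmin(p[i, ], p[j, ]))
  }
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  warn <- character()
  for (i in seq_len(S - 1L)) {
    o <- ov[ord[i], ord[i + 1L]]
    if (o < threshold)
      warn <- c(warn, sprintf("adjacent windows at %.4g and %.4g nm overlap only %.3f",
                              windows[[ord[i]]]$center,
                              windows[[ord[i + 1L]]]$center, o))
  }
  for (w in warn) warning(w, call. = FALSE)
  structure(ov, warnings = warn)
}
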