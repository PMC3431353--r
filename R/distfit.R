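# Multimodal velocity-distribution fitting: sum of four Gaussians with free
# amplitudes, centers and widths, initialized at the ~250 nm/s mode spacing.

#' Fit a sum of four Gaussians to a velocity histogram
#'
#' Nonlinear least squares of
#' `sum_m A_m exp(-(v - c_m)^2 / (2 sigma_m^2))` to the (max-normalized)
#' histogram, by Levenberg-Marquardt with box bounds `A_m >= 0`,
#' `sigma_m > 0`. Default initialization places the centers at multiples
#' of `spacing` (250 nm/s, the empirical mode spacing of melanosome
#' segmental velocities) with amplitudes read off the histogram.
#'
#' @param hist a `velocity_histogram`, or a data frame / list with
#'   elements `mids` and `weights`.
#' @param init optional numeric vector of initial centers (nm/s).
#' @param spacing default center spacing (nm/s) when `init` is missing.
#' @param n_modes number of Gaussian components (4 for melanosome
#'   velocity distributions).
#' @param min_bins fewest non-empty bins required.
#' @param center_window half-width (nm/s) of the box constraint keeping
#'   each center near its initialization; the default (half the mode
#'   spacing) preserves mode identity -- component m stays the m-th
#'   velocity mode -- which keeps amplitude ratios well defined. Use
#'   `Inf` for fully free centers.
#' @return an object of class `multigauss_fit` with `A`, `center`,
#'   `sigma` (all sorted by ascending center), `eff_A` (each component's
#'   peak contribution within the histogram support -- a component pushed
#'   outside the data can carry an arbitrary `A` while contributing
#'   nothing), `vcov`, `resid_norm`, `degenerate` and the initialization
#'   used.
#' @export
fit_four_gaussians <- function(hist, init = NULL, spacing = 250,
                               n_modes = 4, min_bins = 12,
                               center_window = spacing / 2,
                               shared_sigma = FALSE) {
  x <- hist$mids; y <- hist$weights
  if (length(x) == 0 || isTRUE(hist$empty)) stop("empty histogram")
  if (sum(y > 0) < min_bins)
    stop("histogram has fewer than ", min_bins, " non-empty bins")
  ymax <- max(y)
  y <- y / ymax
  centers0 <- if (!is.null(init)) init else spacing * seq_len(n_modes)
  if (length(centers0) != n_modes)
    stop("init must supply ", n_modes, " centers")
  amp0 <- vapply(centers0,
                 function(c0) max(y[which.min(abs(x - c0))], 0.05), 0)
  n_sig <- if (shared_sigma) 1L else n_modes
  start <- c(amp0, centers0, rep(spacing / 3, n_sig))
  model <- function(p, x) {
    A <- p[seq_len(n_modes)]
    cc <- p[n_modes + seq_len(n_modes)]
    s <- p[2 * n_modes + seq_len(n_sig)]
    if (shared_sigma) s <- rep(s, n_modes)
    rowSums(vapply(seq_len(n_modes),
                   function(m) A[m] * exp(-(x - cc[m])^2 / (2 * s[m]^2)),
                   numeric(length(x))))
  }
  bw <- hist$bin_width %||% diff(x)[1]
  clo <- pmax(centers0 - center_window, min(x) - spacing)
  chi <- pmin(centers0 + center_window, max(x) + spacing)
  chi <- pmax(chi, clo + bw)
  # a component narrower than one bin is below the resolution of the
  # binned data and only ever fits single-bin noise
  lower <- c(rep(0, n_modes), clo, rep(bw, n_sig))
  upper <- c(rep(Inf, n_modes), chi,
             rep(diff(range(x)) + spacing, n_sig))
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) y - model(p, x),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 9))
    stop("four-Gaussian fit did not converge (init centers: ",
         paste(signif(centers0, 4), collapse = ", "), ")")
  p <- fit$par
  A <- p[seq_len(n_modes)] * ymax
  cc <- p[n_modes + seq_len(n_modes)]
  s <- abs(p[2 * n_modes + seq_len(n_sig)])
  if (shared_sigma) s <- rep(s, n_modes)
  ord <- order(cc)
  vc <- tryCatch({
    dof <- max(length(x) - length(start), 1)
    (fit$deviance / dof) * solve(fit$hessian)
  }, error = function(e) NULL)
  # peak contribution of each component within the histogram support
  eff_A <- vapply(seq_len(n_modes), function(m)
    max(A[m] * exp(-(x - cc[m])^2 / (2 * s[m]^2))), 0)
  structure(list(A = unname(A[ord]), center = unname(cc[ord]),
                 sigma = unname(s[ord]), eff_A = unname(eff_A[ord]),
                 order = ord, vcov = vc, scale = ymax,
                 resid_norm = sqrt(fit$deviance) * ymax,
                 degenerate = unname(eff_A[ord] < 1e-3 * max(eff_A)),
                 init_centers = centers0, n_modes = n_modes,
                 converged = TRUE),
            class = "multigauss_fit")
}

#' @export
print.multigauss_fit <- function(x, ...) {
  cat("multigauss_fit:\n")
  for (m in seq_len(x$n_modes))
    cat(sprintf("  mode %d: A = %.3g, center = %.1f nm/s, sigma = %.1f nm/s%s\n",
                m, x$A[m], x$center[m], x$sigma[m],
                if (x$degenerate[m]) " (degenerate)" else ""))
  invisible(x)
}

#' Amplitude ratio of two fitted modes
#'
#' The peak amplitude of mode `m` is read as the height of the fitted
#' distribution at that mode's center (`type = "curve"`, the default):
#' this matches the convention of quoting the ratio of the first and
#' second peak amplitudes and is insensitive to how overlapping
#' components share the mass between modes. `type = "component"` uses
#' the raw component amplitudes `A_i / A_j` instead.
#'
#' @param fit a `multigauss_fit`.
#' @param i,j mode indices (by ascending center).
#' @param type `"curve"` (fitted-curve heights at the mode centers) or
#'   `"component"` (raw component amplitudes).
#' @return list with `ratio`, a delta-method `se` (NA when the fit
#'   covariance is unavailable), and a `flag` (`"ok"` or
#'   `"undefined_denominator"` when the denominator amplitude is ~ 0).
#' @export
amplitude_ratio <- function(fit, i = 2, j = 1,
                            type = c("curve", "component")) {
  type <- match.arg(type)
  curve_height <- function(v)
    sum(fit$A * exp(-(v - fit$center)^2 / (2 * fit$sigma^2)))
  Ai <- if (type == "curve") curve_height(fit$center[i]) else fit$A[i]
  Aj <- if (type == "curve") curve_height(fit$center[j]) else fit$A[j]
  if (!is.finite(Aj) || Aj < 1e-3 * max(fit$A, Ai))
    return(list(ratio = NA_real_, se = NA_real_,
                flag = "undefined_denominator"))
  se <- NA_real_
  if (type == "component" && !is.null(fit$vcov)) {
    # indices in the unsorted parameter vector
    ii <- fit$order[i]; jj <- fit$order[j]
    vAi <- fit$vcov[ii, ii]; vAj <- fit$vcov[jj, jj]
    cij <- fit$vcov[ii, jj]
    ai <- fit$A[i] / fit$scale; aj <- fit$A[j] / fit$scale
    r <- ai / aj
    se <- abs(r) * sqrt(max(vAi / ai^2 + vAj / aj^2 - 2 * cij / (ai * aj), 0))
  } else if (type == "curve" && !is.null(fit$vcov)) {
    # numeric delta method on the unsorted parameter vector
    npar <- nrow(fit$vcov)
    n <- fit$n_modes
    unsorted <- function(p) {
      A <- p[seq_len(n)]; cc <- p[n + seq_len(n)]
      s <- if (npar == 2 * n + 1) rep(p[2 * n + 1], n)
           else p[2 * n + seq_len(n)]
      h <- function(v) sum(A * exp(-(v - cc)^2 / (2 * s^2)))
      ci <- cc[order(cc)][i]; cj <- cc[order(cc)][j]
      h(ci) / h(cj)
    }
    p0 <- c(fit$A[order(fit$order)] / fit$scale,
            fit$center[order(fit$order)],
            if (npar == 2 * n + 1) fit$sigma[1]
            else fit$sigma[order(fit$order)])
    g <- tryCatch(vapply(seq_len(npar), function(k) {
      h <- pmax(abs(p0[k]) * 1e-5, 1e-7)
      pp <- p0; pp[k] <- pp[k] + h
      pm <- p0; pm[k] <- pm[k] - h
      (unsorted(pp) - unsorted(pm)) / (2 * h)
    }, 0), error = function(e) NULL)
    if (!is.null(g)) se <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
  }
  list(ratio = Ai / Aj, se = se, flag = "ok")
}

#' Count resolvable modes of a fitted mixture
#'
#' Modes are clustered when their centers are closer than `min_sep`
#' (overlapping components describing a single peak) and a cluster counts
#' when its summed amplitude reaches `amp_tol` of the largest cluster.
#' Used to classify distributions as unimodal vs multimodal.
#'
#' @param fit a `multigauss_fit`.
#' @param amp_tol relative amplitude threshold for a countable mode.
#' @param min_sep center separation (nm/s) under which components merge.
#' @return integer number of distinct modes.
#' @export
count_modes <- function(fit, amp_tol = 0.1, min_sep = 125) {
  ord <- order(fit$center)
  cc <- fit$center[ord]
  A <- (fit$eff_A %||% fit$A)[ord]
  cl <- cumsum(c(1, diff(cc) >= min_sep))
  amp <- tapply(A, cl, sum)
  sum(amp >= amp_tol * max(amp))
}

#' Mean spacing of resolvable mode centers
#'
#' Mean difference between consecutive fitted centers, restricted to
#' components whose peak contribution reaches `amp_tol` of the largest.
#'
#' @param fit a `multigauss_fit`.
#' @param amp_tol relative amplitude threshold for a countable mode.
#' @return mean center spacing (nm/s); `NA` with fewer than two modes.
#' @export
mode_spacing <- function(fit, amp_tol = 0.1) {
  ord <- order(fit$center)
  cc <- fit$center[ord]
  A <- (fit$eff_A %||% fit$A)[ord]
  keep <- A >= amp_tol * max(A)
  if (sum(keep) < 2) return(NA_real_)
  mean(diff(cc[keep]))
}
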