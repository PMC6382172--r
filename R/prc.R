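#' Bin barrage pulses by intra-period phase
#'
#' Divides each interspike interval (ISI) into `n_bins` equal phase bins
#' (bin `j` centered at phase `(j - 0.5) / n_bins`; the bin width in ms
#' scales with the ISI duration) and counts the stimulus pulses falling in
#' each bin of each ISI. A pulse landing exactly on a spike time opens the
#' following ISI (intervals are half-open, `[spike_n, spike_n+1)`). Pulses
#' before the first or at/after the last spike are dropped and counted.
#'
#' @param spikes a [spike_train()].
#' @param pulses a [pulse_train()].
#' @param n_bins number of phase bins per ISI (default 50).
#' @return An object of class `"binned_pulses"`: a list with the count
#'   matrix `counts` (ISIs x bins), its grand-mean-subtracted counterpart
#'   `delta`, the ISI durations `isis` (ms), bin-center phases `phi`, and
#'   `n_dropped`.
#' @export
bin_pulses <- function(spikes, pulses, n_bins = 50L) {
  stopifnot(inherits(spikes, "spike_train"), inherits(pulses, "pulse_train"),
            n_bins >= 1L)
  st <- spikes$times
  if (length(st) < 2L) stop("need at least 2 spikes (one ISI) to bin pulses")
  n_isi <- length(st) - 1L
  isis <- diff(st)
  on <- pulses$onsets
  inside <- on >= st[1] & on < st[length(st)]
  n_dropped <- sum(!inside)
  on <- on[inside]
  counts <- matrix(0L, nrow = n_isi, ncol = n_bins)
  if (length(on)) {
    a <- findInterval(on, st)            # ISI index; onset == spike opens next ISI
    phase <- (on - st[a]) / isis[a]
    j <- pmin(floor(phase * n_bins) + 1L, n_bins)
    for (k in seq_along(on)) counts[a[k], j[k]] <- counts[a[k], j[k]] + 1L
  }
  structure(list(counts = counts, delta = counts - mean(counts),
                 isis = isis, phi = (seq_len(n_bins) - 0.5) / n_bins,
                 n_dropped = n_dropped),
            class = "binned_pulses")
}

#' @export
print.binned_pulses <- function(x, ...) {
  cat(sprintf("Binned pulses: %d ISIs x %d phase bins, %d pulses (%d dropped)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$n_dropped))
  invisible(x)
}

#' Estimate a phase response curve by multiple regression
#'
#' Regresses the ISI durations on the mean-subtracted per-bin pulse counts
#' (ordinary least squares with an intercept). The regression coefficients
#' `b_j` (ms of ISI change per pulse in bin `j`) are converted to phase
#' units: `Z(phi_j) = -b_j / Tbar`, where `Tbar` is the fitted intercept
#' (the mean ISI at zero pulse excess), so a pulse that shortens the ISI
#' yields a positive phase advance. Bins that never receive a pulse give a
#' rank-deficient design; their columns are dropped and reported as `NA`
#' coefficients. Raw estimates may be negative near phases 0 and 1 (period
#' jitter); no clipping is applied.
#'
#' @param binned a [bin_pulses()] result.
#' @param isis ISI durations in ms (defaults to those stored in `binned`).
#' @return An object of class `"prc_estimate"`: list with bin phases `phi`,
#'   coefficients `z` (phase advance per pulse), standard errors `se`,
#'   the intercept `mean_isi_ms`, and `n_isi`.
#' @export
estimate_prc <- function(binned, isis = binned$isis) {
  stopifnot(inherits(binned, "binned_pulses"),
            length(isis) == nrow(binned$counts))
  n_isi <- length(isis)
  if (n_isi < 200L)
    warning(sprintf("only %d ISIs; PRC regression is poorly constrained below ~200",
                    n_isi))
  X <- binned$delta
  empty <- colSums(binned$counts) == 0L
  if (any(empty))
    warning(sprintf("%d phase bin(s) never received a pulse; dropped from the regression",
                    sum(empty)))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, !empty, drop = FALSE]),
                       isis)
  cf <- fit$coefficients
  tbar <- unname(cf[1L])
  b <- rep(NA_real_, ncol(X))
  b[!empty] <- cf[-1L]
  # standard errors from the unscaled covariance of the QR fit
  dof <- n_isi - fit$rank
  s2 <- sum(fit$residuals^2) / dof
  R <- qr.R(fit$qr)
  cov_unscaled <- chol2inv(R)
  se_all <- sqrt(s2 * diag(cov_unscaled))
  se <- rep(NA_real_, ncol(X))
  se[!empty] <- se_all[-1L]
  structure(list(phi = binned$phi, z = -b / tbar, se = se / abs(tbar),
                 mean_isi_ms = tbar, n_isi = n_isi),
            class = "prc_estimate")
}

#' @export
print.prc_estimate <- function(x, ...) {
  cat(sprintf("PRC estimate: %d phase bins from %d ISIs (mean ISI %.3g ms)\n",
              length(x$phi), x$n_isi, x$mean_isi_ms))
  cat(sprintf("  peak raw Z = %.3g at phi = %.2f\n",
              max(x$z, na.rm = TRUE), x$phi[which.max(x$z)]))
  invisible(x)
}

#' @export
plot.prc_estimate <- function(x, ...) {
  graphics::plot(x$phi, x$z, xlab = "phase", ylab = "Z (phase advance / pulse)",
                 pch = 16, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Triangular phase response curve
#'
#' An acute triangle on the unit phase interval: zero-offset unit form rises
#' linearly from (0, 0) to a peak of 1 at phase `theta`, then falls linearly
#' to (1, 0). The curve evaluated by [predict.triangular_prc()] is
#' `offset + amp * unit_triangle(phi)`.
#'
#' @param theta peak phase, strictly inside (0, 1).
#' @param amp peak amplitude `A` (phase advance per unit stimulus).
#' @param offset vertical offset `C` (0 pins the curve at (0,0) and (1,0)).
#' @param tabulated optional raw regression estimate attached for reference.
#' @return An object of class `"triangular_prc"`.
#' @examples
#' z <- triangular_prc(theta = 0.75)
#' predict(z, c(0, 0.75, 1))
#' @export
triangular_prc <- function(theta, amp = 1, offset = 0, tabulated = NULL) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0, theta < 1,
            is.numeric(amp), length(amp) == 1L, is.finite(amp),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  structure(list(theta = theta, amp = amp, offset = offset,
                 tabulated = tabulated),
            class = "triangular_prc")
}

#' @export
print.triangular_prc <- function(x, ...) {
  cat(sprintf("Triangular PRC: theta = %.4g, A = %.4g, C = %.4g\n",
              x$theta, x$amp, x$offset))
  invisible(x)
}

#' Evaluate a triangular PRC
#'
#' @param object a [triangular_prc()].
#' @param phi phases in `[0, 1]` (values outside are wrapped mod 1).
#' @param ... unused.
#' @return Numeric vector `offset + amp * unit_triangle(phi)`.
#' @export
predict.triangular_prc <- function(object, phi, ...) {
  p <- phi %% 1
  u <- ifelse(p <= object$theta, p / object$theta,
              (1 - p) / (1 - object$theta))
  object$offset + object$amp * u
}

#' Fit an acute triangle to a tabulated PRC
#'
#' Least-squares fit of the triangle `(theta, A, C)` to tabulated PRC values
#' at given phases. The peak location `theta` is profiled: for each
#' candidate `theta` the amplitude and offset are solved linearly, and the
#' residual sum of squares is minimized over `theta` by a grid scan refined
#' with [stats::optimize()]. With `force_zero_ends = TRUE` the offset is
#' fixed at 0, pinning the curve at (0, 0) and (1, 0) as phase theory
#' requires at the spike threshold.
#'
#' @param z a [estimate_prc()] result, or a numeric vector of PRC values.
#' @param phi phases of the tabulated values (required when `z` is numeric;
#'   taken from the estimate otherwise).
#' @param force_zero_ends logical; fix the offset `C` at zero.
#' @return A [triangular_prc()] with the tabulated input attached.
#' @export
fit_triangle <- function(z, phi = NULL, force_zero_ends = FALSE) {
  if (inherits(z, "prc_estimate")) {
    phi <- z$phi
    z <- z$z
  }
  stopifnot(is.numeric(z), !is.null(phi), length(phi) == length(z))
  keep <- is.finite(z)
  z <- z[keep]; phi <- phi[keep]
  if (length(z) < 3L) stop("need at least 3 finite PRC values")
  if (stats::var(z) == 0)
    stop("flat PRC values: the triangle peak location is not identifiable")
  sse <- function(theta) {
    u <- ifelse(phi <= theta, phi / theta, (1 - phi) / (1 - theta))
    if (force_zero_ends) {
      a <- sum(u * z) / sum(u^2)
      sum((z - a * u)^2)
    } else {
      f <- stats::lm.fit(cbind(1, u), z)
      sum(f$residuals^2)
    }
  }
  grid <- seq(0.005, 0.995, length.out = 199L)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  theta <- stats::optimize(sse, c(lo, hi), tol = 1e-10)$minimum
  u <- ifelse(phi <= theta, phi / theta, (1 - phi) / (1 - theta))
  if (force_zero_ends) {
    amp <- sum(u * z) / sum(u^2)
    off <- 0
  } else {
    cf <- stats::lm.fit(cbind(1, u), z)$coefficients
    off <- cf[1L]
    amp <- cf[2L]
  }
  triangular_prc(theta = theta, amp = unname(amp), offset = unname(off),
                 tabulated = data.frame(phi = phi, z = z))
}

#' Fourier coefficients of the unit triangular PRC
#'
#' Coefficients of the zero-offset, unit-amplitude triangle with peak at
#' `theta`, under the convention `Zhat_k = integral_0^1 Z(phi) *
#' exp(-2*pi*i*k*phi) dphi`:
#' `Zhat_0 = 1/2` and, for `k != 0`,
#' `Zhat_k = (exp(-2*pi*i*k*theta) - 1) / (4*pi^2*theta*(1-theta)*k^2)`.
#' Since the PRC is real, `Zhat_{-k} = Conj(Zhat_k)`. Scaling by a peak
#' amplitude `A` is left to the caller.
#'
#' @param prc a [triangular_prc()] or a numeric peak phase `theta`.
#' @param k integer mode index (vectorized; may be negative).
#' @return Complex vector of coefficients.
#' @examples
#' triangle_fourier(0.5, 0:2)
#' @export
triangle_fourier <- function(prc, k) {
  theta <- if (inherits(prc, "triangular_prc")) prc$theta else prc
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0, theta < 1,
            all(k == round(k)))
  out <- complex(length.out = length(k))
  nz <- k != 0
  out[!nz] <- 0.5 + 0i
  kk <- k[nz]
  out[nz] <- (exp(-2i * pi * kk * theta) - 1) /
    (4 * pi^2 * theta * (1 - theta) * kk^2)
  out
}

#' Channelrhodopsin photocurrent kinetics
#'
#' Double-exponential kernel `A * (exp(-t / tau_rise) - exp(-t / tau_decay))`
#' for the average somatic current evoked by a brief light pulse. With
#' `tau_rise < tau_decay` the bracket is negative for `t > 0`, so an
#' inward-positive (plotted-positive) current corresponds to `amp < 0`; the
#' printed functional form is kept and the sign of `amp` carries the
#' polarity. The kernel vanishes at `t = 0` and has a single interior
#' extremum at `t* = tau_rise * tau_decay / (tau_decay - tau_rise) *
#' log(tau_decay / tau_rise)` (see [chr2_peak_time()]).
#'
#' @param amp scale `A` (free sign; see Details).
#' @param tau_rise faster time constant in ms.
#' @param tau_decay slower time constant in ms (`!= tau_rise`).
#' @return An object of class `"chr2_kinetics"`.
#' @export
chr2_kinetics <- function(amp, tau_rise, tau_decay) {
  stopifnot(is.numeric(amp), length(amp) == 1L, is.finite(amp),
            tau_rise > 0, tau_decay > 0, tau_rise != tau_decay)
  if (tau_rise > tau_decay) {
    # relabel so tau_rise names the faster edge; kernel is antisymmetric
    # under the swap, so flip the sign of A to keep the same curve
    tmp <- tau_rise; tau_rise <- tau_decay; tau_decay <- tmp
    amp <- -amp
  }
  structure(list(amp = amp, tau_rise = tau_rise, tau_decay = tau_decay),
            class = "chr2_kinetics")
}

#' @export
print.chr2_kinetics <- function(x, ...) {
  cat(sprintf("ChR2 kinetics: |A| = %.4g (%s), tau_rise = %.3g ms, tau_decay = %.3g ms\n",
              abs(x$amp), if (x$amp <= 0) "inward-positive" else "inward-negative",
              x$tau_rise, x$tau_decay))
  invisible(x)
}

#' Evaluate a ChR2 photocurrent kernel
#'
#' @param t time in ms from pulse onset (values `< 0` give 0).
#' @param kin a [chr2_kinetics()].
#' @return Kernel values `A * (exp(-t/tau_rise) - exp(-t/tau_decay))`.
#' @export
chr2_kernel <- function(t, kin) {
  stopifnot(inherits(kin, "chr2_kinetics"))
  out <- kin$amp * (exp(-t / kin$tau_rise) - exp(-t / kin$tau_decay))
  out[t < 0] <- 0
  out
}

#' Time of the ChR2 kernel extremum
#'
#' Closed form for the interior extremum of the double-exponential kernel:
#' `t* = tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)`.
#'
#' @param kin a [chr2_kinetics()].
#' @return Peak time in ms.
#' @export
chr2_peak_time <- function(kin) {
  stopifnot(inherits(kin, "chr2_kinetics"))
  with(kin, tau_rise * tau_decay / (tau_decay - tau_rise) *
         log(tau_decay / tau_rise))
}

#' Fit ChR2 kinetics to an average pulse response
#'
#' Nonlinear least squares of the double-exponential kernel to a
#' baseline-subtracted average current response, starting at pulse onset.
#' The amplitude sign is free so either polarity of the recorded current is
#' accommodated; time constants are relabeled so `tau_rise < tau_decay`.
#'
#' @param avg_response data frame with columns `time_ms` (from pulse onset)
#'   and `value`.
#' @param start optional named list of starting values (`amp`, `tau_rise`,
#'   `tau_decay`); by default derived from the response extremum.
#' @return A [chr2_kinetics()].
#' @export
fit_chr2_kernel <- function(avg_response, start = NULL) {
  stopifnot(is.data.frame(avg_response),
            all(c("time_ms", "value") %in% names(avg_response)))
  t <- avg_response$time_ms
  v <- avg_response$value
  if (any(t < 0)) stop("response must start at pulse onset (time_ms >= 0)")
  if (is.null(start)) {
    ipk <- which.max(abs(v))
    tpk <- max(t[ipk], 2 * min(diff(sort(unique(t)))))
    tr0 <- tpk / 3
    td0 <- tpk * 1.5
    kpk <- exp(-tpk / tr0) - exp(-tpk / td0)
    start <- list(amp = v[ipk] / kpk, tau_rise = tr0, tau_decay = td0)
  }
  d <- data.frame(t = t, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ amp * (exp(-t / tau_rise) - exp(-t / tau_decay)),
                      data = d, start = start,
                      lower = c(amp = -Inf, tau_rise = 1e-3, tau_decay = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf("ChR2 kernel fit did not converge: %s (residual scale %.3g)",
                   conditionMessage(e), stats::sd(v)), call. = FALSE))
  cf <- stats::coef(fit)
  chr2_kinetics(amp = cf[["amp"]], tau_rise = cf[["tau_rise"]],
                tau_decay = cf[["tau_decay"]])
}
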