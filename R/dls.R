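# Stretched-exponential (KWW) analysis of DLS autocorrelation traces.
#
# Model: g(t) = g0 * exp[-(t/tau)^alpha], alpha in (0, 1]. The stretching
# exponent alpha < 1 reflects a broad distribution of relaxation times, as
# expected for polydisperse self-assembled structures; tau tracks the
# slowing down of network relaxation on cooling.

#' Evaluate the normalized stretched-exponential relaxation
#'
#' `g(t)/g(0) = exp[-(t/tau)^alpha]`. At `t = tau` the value is `exp(-1)`
#' for every alpha.
#'
#' @param t lag time, seconds; >= 0 (vectorized).
#' @param tau relaxation time, seconds; > 0.
#' @param alpha stretching exponent in (0, 1].
#' @return normalized correlation value(s).
#' @export
eval_stretched_exp <- function(t, tau, alpha) {
  if (!is.finite(tau) || tau <= 0) stop_input("tau must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop_input("alpha must lie in (0, 1]")
  if (any(!is.finite(t)) || any(t < 0)) stop_input("t must be >= 0")
  exp(-(t / tau)^alpha)
}

#' Fit the stretched-exponential model to a correlation trace
#'
#' Least-squares fit of `g0 * exp[-(t/tau)^alpha]` on the raw trace
#' (uniform weights unless the trace carries uncertainties). The initial
#' tau is the lag at which the normalized trace first drops below
#' `exp(-1)` (linear interpolation); alpha starts at 0.6 when free.
#'
#' @param trace a [correlation_trace()].
#' @param alpha_mode `"free"` (bounds (0.1, 1]) or a fixed numeric value in
#'   (0, 1]; `alpha_mode = 1` reduces to a plain exponential fit.
#' @return An object of class `dls_fit`: `tau`, `alpha`, `g0`,
#'   `uncertainties`, `chi2_reduced`, `converged`, and `non_decaying`
#'   (TRUE when the trace shows no decay; tau is then pinned at the upper
#'   bound and the result flagged).
#' @export
fit_dls <- function(trace, alpha_mode = "free") {
  stopifnot(inherits(trace, "correlation_trace"))
  t <- trace$lag; g <- trace$g
  w <- if (is.null(trace$sigma)) rep(1, length(t)) else 1 / trace$sigma
  alpha_fixed <- NULL
  if (is.numeric(alpha_mode)) {
    if (alpha_mode <= 0 || alpha_mode > 1)
      stop_input("fixed alpha must lie in (0, 1]")
    alpha_fixed <- alpha_mode
  } else if (!identical(alpha_mode, "free")) {
    stop_input("alpha_mode must be \"free\" or a numeric value in (0, 1]")
  }

  g0_init <- stats::median(g[seq_len(min(5L, length(g)))])
  if (g0_init <= 0) g0_init <- max(g, 1e-12)
  gn <- g / g0_init
  tau_upper <- 1e6 * max(t)
  below <- which(gn < exp(-1))
  non_decaying <- length(below) == 0L ||
    min(stats::runmed(gn, min(5L, length(gn)))) > 0.9
  tau_init <- if (length(below)) {
    i <- below[1]
    if (i == 1L) t[1]
    else t[i - 1] + (t[i] - t[i - 1]) *
      (gn[i - 1] - exp(-1)) / (gn[i - 1] - gn[i])
  } else max(t)

  if (non_decaying) {
    warning("trace does not decay; tau pinned at upper bound", call. = FALSE)
    return(structure(list(
      tau = tau_upper, alpha = if (is.null(alpha_fixed)) NA_real_ else alpha_fixed,
      g0 = g0_init,
      uncertainties = c(g0 = NA_real_, tau = NA_real_, alpha = NA_real_),
      chi2_reduced = NA_real_, converged = FALSE, non_decaying = TRUE),
      class = "dls_fit"))
  }

  free_alpha <- is.null(alpha_fixed)
  p0 <- c(g0 = g0_init, tau = max(tau_init, 1e-12),
          if (free_alpha) c(alpha = 0.6))
  lower <- c(1e-12, 1e-12, if (free_alpha) 0.1)
  upper <- c(Inf, tau_upper, if (free_alpha) 1)
  model <- function(p) {
    a <- if (free_alpha) p[3] else alpha_fixed
    p[1] * exp(-(t / p[2])^a)
  }
  fit <- tryCatch(
    .lm_fit(p0, lower, upper, function(p) (g - model(p)) * w),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  if (is.null(fit))
    stop_input("DLS fit failed to evaluate")
  p <- fit$par
  k <- length(p); npt <- length(t)
  chi2_red <- fit$deviance / max(npt - k, 1L)
  unc <- rep(NA_real_, 3); names(unc) <- c("g0", "tau", "alpha")
  cov <- tryCatch(chi2_red * solve(fit$hessian) * 2, error = function(e) NULL)
  if (!is.null(cov)) {
    dg <- diag(cov)
    se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    unc[c("g0", "tau", if (free_alpha) "alpha")] <- se
  }
  structure(list(
    tau = unname(p[2]),
    alpha = if (free_alpha) unname(p[3]) else alpha_fixed,
    g0 = unname(p[1]),
    uncertainties = unc, chi2_reduced = chi2_red,
    converged = converged, non_decaying = FALSE),
    class = "dls_fit")
}

#' @export
print.dls_fit <- function(x, ...) {
  cat(sprintf("<dls_fit> tau = %.4g s, alpha = %.3f, g0 = %.4g%s%s\n",
              x$tau, x$alpha, x$g0,
              if (!x$converged) " (NOT converged)" else "",
              if (x$non_decaying) " [non-decaying]" else ""))
  invisible(x)
}

#' Relaxation time versus temperature for a series of traces
#'
#' Fits each trace and tabulates `(T, tau, alpha)` sorted by temperature
#' (stable for ties). The `"monotone_fraction"` attribute reports the
#' fraction of adjacent temperature pairs for which tau decreases as T
#' increases (1 when tau is strictly ordered the way network rigidification
#' on cooling predicts). Individual fit failures are recorded per row, not
#' fatal.
#'
#' @param traces list of [correlation_trace()] objects spanning >= 2
#'   temperatures.
#' @param alpha_mode passed to [fit_dls()].
#' @return data.frame with columns `temperature`, `tau`, `alpha`,
#'   `converged`, `error`; attribute `monotone_fraction`.
#' @export
tau_series <- function(traces, alpha_mode = "free") {
  if (!is.list(traces) || length(traces) < 2L)
    stop_input("tau_series needs a list of traces")
  temps <- vapply(traces, function(x) as.numeric(x$temperature), numeric(1))
  if (length(unique(temps)) < 2L)
    stop_input("tau_series needs at least 2 distinct temperatures")
  rows <- lapply(traces, function(tr) {
    f <- tryCatch(fit_dls(tr, alpha_mode), error = function(e) e)
    if (inherits(f, "error"))
      data.frame(temperature = tr$temperature, tau = NA_real_,
                 alpha = NA_real_, converged = FALSE,
                 error = conditionMessage(f))
    else
      data.frame(temperature = tr$temperature, tau = f$tau, alpha = f$alpha,
                 converged = f$converged, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  ok <- !is.na(out$tau)
  tt <- out$tau[ok]
  frac <- if (sum(ok) >= 2L) mean(diff(tt) < 0) else NA_real_
  attr(out, "monotone_fraction") <- frac
  out
}
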