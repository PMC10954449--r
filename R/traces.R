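#' Normalize a stopped-flow fluorescence trace to a bound fraction
#'
#' Applies the control-based normalization
#' `[T:P]/[T]_tot = (F_mix - F_TP) / (F_T - F_TP)`, where `F_T` is the
#' free-target control and `F_TP` the pre-annealed duplex control. Because
#' 2-aminopurine is quenched in a double helix, `F_mix = F_TP` maps to 0 and
#' `F_mix = F_T` to 1; the `orientation` flag selects whether that value is
#' reported as the bound fraction (`"as_printed"`, default) or flipped to
#' `1 - x` (`"quench"`, the photophysical reading in which signal loss means
#' binding).
#'
#' @param F_mix numeric vector, the mixture trace.
#' @param F_T free-target control (scalar or vector along the trace).
#' @param F_TP duplex control (scalar or vector).
#' @param orientation `"as_printed"` or `"quench"`.
#' @param clip values outside `[-0.05, 1.05]` are clipped with a warning.
#' @return numeric vector of fractions.
#' @export
normalize_trace <- function(F_mix, F_T, F_TP,
                            orientation = c("as_printed", "quench"),
                            clip = c(-0.05, 1.05)) {
  orientation <- match.arg(orientation)
  if (all(abs(F_T - F_TP) < .Machine$double.eps * 100))
    stop("F_T equals F_TP: no dynamic range")
  x <- (F_mix - F_TP) / (F_T - F_TP)
  if (orientation == "quench") x <- 1 - x
  if (any(x < clip[1] | x > clip[2])) {
    warning(sprintf("%d points outside [%.2f, %.2f] clipped",
                    sum(x < clip[1] | x > clip[2]), clip[1], clip[2]))
    x <- pmin(pmax(x, clip[1]), clip[2])
  }
  x
}

# reversible bimolecular bound fraction of the limiting strand vs time
.bimolecular_frac <- function(t, k_on, k_off, conc_a, conc_b) {
  y0 <- c(B = 0)
  rhs <- function(t, y, p) {
    list(k_on * (conc_a - y) * (conc_b - y) - k_off * y)
  }
  out <- deSolve::lsoda(y0, t, rhs, parms = NULL, rtol = 1e-10, atol = 1e-16)
  as.vector(out[, "B"]) / min(conc_a, conc_b)
}

#' Fit a bimolecular association model to a bound-fraction trace
#'
#' Least-squares fit of the two-species association ODE
#' `d[AB]/dt = k_on [A][B] - k_off [AB]` (optionally irreversible) to a
#' normalized bound-fraction trace, with a seeded multistart over
#' `k_on in [1e5, 1e9]` 1/(M s). The first `dead_time` seconds are excluded
#' (stopped-flow mixing dead time).
#'
#' @param time seconds, strictly increasing.
#' @param frac bound fraction of the limiting strand.
#' @param conc_a,conc_b total strand concentrations, mol/L.
#' @param include_koff fit a reversible model; `NULL` (default) decides from
#'   the trace: reversible when it plateaus below 95% bound.
#' @param dead_time seconds excluded at the start (default 0.05).
#' @param n_starts number of multistart points (>= 5).
#' @param seed integer seed.
#' @return object of class `hk_fit` with `estimate` (`k_on`, optionally
#'   `k_off`), `se`, `r_squared`, `rmse_pct`, `residuals`, `converged`.
#' @export
fit_bimolecular <- function(time, frac, conc_a, conc_b,
                            include_koff = NULL, dead_time = 0.05,
                            n_starts = 5, seed = 1L) {
  stopifnot(conc_a > 0, conc_b > 0, length(time) == length(frac))
  keep <- time >= dead_time
  time_f <- time[keep]; y <- frac[keep]
  if (length(time_f) < 20L) stop("at least 20 usable points are required")
  if (diff(range(y)) < 1e-3)
    stop("flat trace: no association signal to fit")
  if (is.null(include_koff)) include_koff <- max(y) < 0.95

  set.seed(seed %% .Machine$integer.max)
  starts <- 10^seq(5, 9, length.out = n_starts) *
    10^runif(n_starts, -0.2, 0.2)
  model <- function(theta) {
    k_on <- 10^theta[1]
    k_off <- if (include_koff) 10^theta[2] else 0
    .bimolecular_frac(c(0, time_f), k_on, k_off, conc_a, conc_b)[-1]
  }
  best <- NULL
  for (s in starts) {
    th0 <- if (include_koff) c(log10(s), -2) else log10(s)
    fit <- tryCatch(
      optim(th0, function(th) sum((y - model(th))^2),
            method = if (include_koff) "Nelder-Mead" else "Brent",
            lower = if (!include_koff) 3 else -Inf,
            upper = if (!include_koff) 11 else Inf,
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("all multistarts failed to converge")
  pred <- model(best$par)
  res <- y - pred
  est <- c(k_on = 10^best$par[1])
  if (include_koff) est["k_off"] <- 10^best$par[2]
  # standard errors from the quadratic approximation on the log10 scale
  se <- tryCatch({
    h <- optimHess(best$par, function(th) sum((y - model(th))^2))
    s2 <- sum(res^2) / (length(y) - length(best$par))
    se_log <- sqrt(pmax(diag(solve(h / (2 * s2))), 0))
    est * log(10) * se_log
  }, error = function(e) rep(NA_real_, length(est)))
  at_bound <- !include_koff && (best$par[1] <= 3 + 1e-6)
  structure(list(estimate = est, se = setNames(se, names(est)),
                 r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
                 rmse_pct = NA_real_, residuals = res,
                 fitted = pred, time = time_f,
                 converged = !at_bound,
                 note = if (at_bound) "k_on at lower search bound",
                 model = if (include_koff) "reversible" else "irreversible"),
            class = "hk_fit")
}

#' @export
print.hk_fit <- function(x, ...) {
  cat(sprintf("<hk_fit> %s model%s\n", x$model,
              if (!x$converged) " [diagnostic flag set]" else ""))
  for (nm in names(x$estimate))
    cat(sprintf("  %s = %.4g +/- %.2g\n", nm, x$estimate[[nm]],
                x$se[[nm]]))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
#' @method coef hk_fit
coef.hk_fit <- function(object, ...) object$estimate

# two-state bound fraction of the limiting strand at temperature Tk
.melt_frac <- function(Tk, dH, dS, conc_a, conc_b) {
  KD <- exp((dH * 1000 - Tk * dS) / (.R_KCAL * 1000 * Tk))
  s <- conc_a + conc_b + KD
  TP <- (s - sqrt(s^2 - 4 * conc_a * conc_b)) / 2
  TP / min(conc_a, conc_b)
}

#' Fit two-state melting curves and extrapolate K_D to 25 C
#'
#' Each curve is fitted independently to a two-state van't Hoff model with
#' linear upper and lower baselines
#' (`signal = f * low(T) + (1 - f) * high(T)` with `f` the bound fraction);
#' the fitted enthalpy and entropy give `K_D` at 25 C. The aggregate over
#' curves is the lognormal mean and standard deviation of the per-curve
#' dissociation constants.
#'
#' @param curves a list of melting curves; each a list/data.frame with
#'   `temperature` (degrees C, strictly increasing, >= 20 points), `signal`,
#'   and total strand concentrations `conc_a`, `conc_b` (mol/L).
#' @param baseline `"linear"` (default) or `"constant"`.
#' @return object of class `hk_meltfit`: per-curve `K_D_25`, `dH`, `dS`,
#'   failures recorded per curve, and the lognormal aggregate
#'   (`K_D_mean`, `K_D_sd`).
#' @export
fit_melt <- function(curves, baseline = c("linear", "constant")) {
  baseline <- match.arg(baseline)
  if (inherits(curves, "data.frame") || !is.null(curves$temperature))
    curves <- list(curves)
  stopifnot(length(curves) >= 1L)
  fit_one <- function(cu) {
    tempc <- cu$temperature; sig <- cu$signal
    stopifnot(length(tempc) >= 20L, all(diff(tempc) > 0))
    Tk <- .kelvin(tempc)
    ca <- cu$conc_a[1]; cb <- cu$conc_b[1]
    # starting values: Tm from the signal midpoint, generic duplex enthalpy
    smin <- min(sig); smax <- max(sig)
    mid <- (smin + smax) / 2
    Tm0 <- .kelvin(tempc[which.min(abs(sig - mid))])
    if (Tm0 <= min(Tk) + 1 || Tm0 >= max(Tk) - 1)
      stop("transition outside the temperature window")
    dH0 <- -80
    dS0 <- dH0 * 1000 / Tm0 - .R_KCAL * 1000 *
      log(max(ca, cb) - min(ca, cb) / 2)
    rising <- sig[length(sig)] > sig[1]  # melting releases the fluorophore
    lo0 <- if (rising) smin else smax
    hi0 <- if (rising) smax else smin
    st <- list(dH = dH0, dS = dS0, lo0 = lo0, hi0 = hi0)
    if (baseline == "linear") st <- c(st, list(lo1 = 0, hi1 = 0))
    frm <- if (baseline == "linear") {
      signal ~ .melt_frac(Tk, dH, dS, ca, cb) * (lo0 + lo1 * (Tk - 298.15)) +
        (1 - .melt_frac(Tk, dH, dS, ca, cb)) * (hi0 + hi1 * (Tk - 298.15))
    } else {
      signal ~ .melt_frac(Tk, dH, dS, ca, cb) * lo0 +
        (1 - .melt_frac(Tk, dH, dS, ca, cb)) * hi0
    }
    dat <- list(signal = sig, Tk = Tk, ca = ca, cb = cb)
    fit <- minpack.lm::nlsLM(frm, data = dat, start = st,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    cf <- coef(fit)
    # the fitted transition must actually run its course inside the window
    f_ends <- .melt_frac(range(Tk), cf[["dH"]], cf[["dS"]], ca, cb)
    if (f_ends[1] < 0.75 || f_ends[2] > 0.25)
      stop("transition outside the temperature window")
    dG25 <- cf[["dH"]] - 298.15 * cf[["dS"]] / 1000
    list(dH = cf[["dH"]], dS = cf[["dS"]],
         K_D_25 = exp(dG25 / (.R_KCAL * 298.15)))
  }
  res <- lapply(seq_along(curves), function(i) {
    tryCatch(fit_one(curves[[i]]),
             error = function(e) list(error = conditionMessage(e)))
  })
  ok <- !vapply(res, function(r) !is.null(r$error), logical(1))
  if (!any(ok)) stop("all curves failed to fit: ",
                     res[[1]]$error)
  kds <- vapply(res[ok], `[[`, numeric(1), "K_D_25")
  lg <- log(kds)
  s2 <- if (sum(ok) > 1) stats::var(lg) else 0
  structure(list(per_curve = res, ok = ok, K_D_25 = kds,
                 K_D_mean = exp(mean(lg)),
                 K_D_sd = sqrt((exp(s2) - 1) * exp(2 * mean(lg) + s2)),
                 K_D_sd_log = sqrt(s2)),
            class = "hk_meltfit")
}

#' @export
print.hk_meltfit <- function(x, ...) {
  cat(sprintf("<hk_meltfit> %d/%d curves fitted\n", sum(x$ok), length(x$ok)))
  cat(sprintf("  K_D(25 C): lognormal mean %.3g M (sd of log K_D: %.3g)\n",
              x$K_D_mean, x$K_D_sd_log))
  invisible(x)
}

#' @export
#' @method coef hk_meltfit
coef.hk_meltfit <- function(object, ...) {
  c(K_D_25 = object$K_D_mean)
}

#' Comparison statistics for predicted vs measured values
#'
#' The coefficient of determination `R^2 = 1 - SS_res/SS_tot` and the
#' percentage error statistic
#' `RMSE = (100/m) * sum( sqrt((yhat_i - y_i)^2) / y_i )` — as printed, a
#' mean absolute percentage deviation; it is implemented exactly in that
#' form.
#'
#' @param predicted,measured numeric vectors of equal length (>= 2);
#'   `measured` must be nonzero for the RMSE.
#' @return list with `r_squared` and `rmse_pct`.
#' @export
comparison_stats <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured), length(measured) >= 2L)
  if (any(measured == 0)) {
    stop(sprintf("measured value at index %d is zero: RMSE undefined",
                 which(measured == 0)[1]))
  }
  ss_res <- sum((measured - predicted)^2)
  ss_tot <- sum((measured - mean(measured))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse_pct = 100 / length(measured) *
         sum(sqrt((predicted - measured)^2) / measured))
}
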