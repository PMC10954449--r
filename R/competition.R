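#' Define a probe/target/competitor mixture
#'
#' A three-strand competition system: probe P, perfectly pairing target T and
#' defect-bearing competitor C, with hybridization rate constants for the
#' T:P and C:P duplexes, an optional toehold-free strand-displacement channel
#' (`C:P + T <-> T:P + C`), and an optional pseudo-bimolecular
#' extension/ligation channel turning bound duplexes into reacted species.
#' The reverse displacement rate is derived from thermodynamic consistency,
#' `k_sd_fwd / k_sd_rev = K_D(C:P) / K_D(T:P)`.
#'
#' @param conc_T,conc_C,conc_P total strand concentrations, mol/L.
#' @param kon_TP,koff_TP,kon_CP,koff_CP duplex rate constants (1/(M s), 1/s).
#' @param k_sd strand-displacement rate constant for `C:P + T -> T:P + C`,
#'   1/(M s); `0` disables the channel (DNA default; for toehold-free RNA a
#'   measured lower bound of about 1 /(M s) is typical).
#' @param substrate substrate concentration for the reaction channel, mol/L.
#' @param k_react_TP,k_react_CP bimolecular rate constants for extension or
#'   ligation of the T:P and C:P duplexes by the substrate, 1/(M s).
#' @param substrate_depletion if `TRUE` the substrate is consumed; default
#'   keeps it in excess (constant).
#' @param temperature degrees C (book-keeping only).
#' @return object of class `hk_mixture`.
#' @export
mixture_system <- function(conc_T, conc_C, conc_P,
                           kon_TP, koff_TP, kon_CP, koff_CP,
                           k_sd = 0, substrate = 0,
                           k_react_TP = 0, k_react_CP = 0,
                           substrate_depletion = FALSE,
                           temperature = 25) {
  stopifnot(conc_T >= 0, conc_C >= 0, conc_P >= 0,
            kon_TP > 0, kon_CP > 0, koff_TP >= 0, koff_CP >= 0,
            k_sd >= 0, substrate >= 0)
  KD_TP <- koff_TP / kon_TP
  KD_CP <- koff_CP / kon_CP
  k_sd_rev <- if (k_sd > 0) {
    if (KD_CP <= 0 || KD_TP <= 0)
      stop("displacement requires finite positive K_D for both duplexes")
    k_sd * KD_TP / KD_CP
  } else 0
  structure(list(conc_T = conc_T, conc_C = conc_C, conc_P = conc_P,
                 kon_TP = kon_TP, koff_TP = koff_TP,
                 kon_CP = kon_CP, koff_CP = koff_CP,
                 KD_TP = KD_TP, KD_CP = KD_CP,
                 k_sd = k_sd, k_sd_rev = k_sd_rev,
                 substrate = substrate, k_react_TP = k_react_TP,
                 k_react_CP = k_react_CP,
                 substrate_depletion = substrate_depletion,
                 temperature = temperature),
            class = "hk_mixture")
}

#' @export
print.hk_mixture <- function(x, ...) {
  cat(sprintf("<hk_mixture> T/C/P totals: %.3g / %.3g / %.3g M\n",
              x$conc_T, x$conc_C, x$conc_P))
  cat(sprintf("  T:P k_on %.3g, k_off %.3g (K_D %.3g M); C:P k_on %.3g, k_off %.3g (K_D %.3g M)\n",
              x$kon_TP, x$koff_TP, x$KD_TP, x$kon_CP, x$koff_CP, x$KD_CP))
  if (x$k_sd > 0)
    cat(sprintf("  strand displacement: %.3g fwd / %.3g rev /M/s\n",
                x$k_sd, x$k_sd_rev))
  if (x$k_react_TP > 0 || x$k_react_CP > 0)
    cat(sprintf("  reaction channel: substrate %.3g M, k_react %.3g (T:P) / %.3g (C:P) /M/s\n",
                x$substrate, x$k_react_TP, x$k_react_CP))
  invisible(x)
}

#' Initial binding accuracy from the kinetic partition of association rates
#'
#' Just after mixing equimolar target and competitor with the probe, before
#' any dissociation, the fraction of correctly bound probe is set by the
#' relative association rates: `theta_in = kon_TP / (kon_TP + kon_CP)`.
#' Equals 0.5 at equal rates and tends to 1 as `kon_CP -> 0`.
#'
#' @param kon_TP,kon_CP association rates of the two duplexes, 1/(M s) (> 0).
#' @return probability.
#' @export
theta_in <- function(kon_TP, kon_CP) {
  if (any(kon_TP <= 0) || any(kon_CP <= 0)) stop("rates must be positive")
  kon_TP / (kon_TP + kon_CP)
}

#' Exact equilibrium of the two-duplex competition
#'
#' Solves the competitive binding equilibrium for three strands with
#' dissociation constants `K_D(T:P)` and `K_D(C:P)` by a bracketed monotone
#' root in the free-probe concentration, and returns the equilibrium binding
#' accuracy `theta_eq = [T:P] / ([T:P] + [C:P])` together with all species.
#'
#' @param system an [mixture_system()]; alternatively pass totals and K_Ds.
#' @param KD_TP,KD_CP,conc_T,conc_C,conc_P scalars overriding the system's.
#' @return list with `theta_eq` and equilibrium species concentrations.
#' @export
equilibrium_accuracy <- function(system = NULL, KD_TP = NULL, KD_CP = NULL,
                                 conc_T = NULL, conc_C = NULL,
                                 conc_P = NULL) {
  if (!is.null(system)) {
    stopifnot(inherits(system, "hk_mixture"))
    if (is.null(KD_TP)) KD_TP <- system$KD_TP
    if (is.null(KD_CP)) KD_CP <- system$KD_CP
    if (is.null(conc_T)) conc_T <- system$conc_T
    if (is.null(conc_C)) conc_C <- system$conc_C
    if (is.null(conc_P)) conc_P <- system$conc_P
  }
  stopifnot(KD_TP > 0, KD_CP > 0, conc_T >= 0, conc_C >= 0, conc_P >= 0)
  if (conc_P == 0) {
    return(list(theta_eq = NA_real_, T = conc_T, C = conc_C, P = 0,
                TP = 0, CP = 0))
  }
  # bound probe is monotone increasing in free probe, so f is monotone
  f <- function(P) P + conc_T * P / (KD_TP + P) +
    conc_C * P / (KD_CP + P) - conc_P
  sol <- uniroot(f, c(0, conc_P), tol = conc_P * 1e-15,
                 extendInt = "no")
  P <- sol$root
  TP <- conc_T * P / (KD_TP + P)
  CP <- conc_C * P / (KD_CP + P)
  theta <- if (TP + CP > 0) TP / (TP + CP) else NA_real_
  list(theta_eq = theta, T = conc_T - TP, C = conc_C - CP, P = P,
       TP = TP, CP = CP)
}

#' Integrate the mass-action dynamics of a competition mixture
#'
#' Stiff-capable integration (lsoda) of the hybridization, dissociation,
#' optional strand-displacement and optional extension/ligation channels.
#' Returns species trajectories, the binding accuracy
#' `theta(t) = [T:P]/([T:P] + [C:P])` and the reacted fractions.
#'
#' @param system an [mixture_system()].
#' @param t_grid increasing time grid starting at 0, seconds.
#' @param init optional named initial concentrations (defaults: all strands
#'   free and unreacted).
#' @param rtol,atol integrator tolerances.
#' @return data.frame of class `hk_timecourse` with columns `time`, species
#'   (`T`, `C`, `P`, `TP`, `CP`, `TPr`, `CPr`, `S`), `theta`,
#'   `reacted_T`, `reacted_C`.
#' @export
simulate_mixture <- function(system, t_grid, init = NULL,
                             rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(system, "hk_mixture"))
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must increase from 0")
  y0 <- c(T = system$conc_T, C = system$conc_C, P = system$conc_P,
          TP = 0, CP = 0, TPr = 0, CPr = 0, S = system$substrate)
  if (!is.null(init)) y0[names(init)] <- init
  sys <- system
  rhs <- function(t, y, parms) {
    S_eff <- if (sys$substrate_depletion) y["S"] else sys$substrate
    v_TP <- sys$kon_TP * y["T"] * y["P"] - sys$koff_TP * y["TP"]
    v_CP <- sys$kon_CP * y["C"] * y["P"] - sys$koff_CP * y["CP"]
    v_sd <- sys$k_sd * y["CP"] * y["T"] - sys$k_sd_rev * y["TP"] * y["C"]
    v_rT <- sys$k_react_TP * y["TP"] * S_eff
    v_rC <- sys$k_react_CP * y["CP"] * S_eff
    list(c(T = -v_TP - v_sd,
           C = -v_CP + v_sd,
           P = -v_TP - v_CP,
           TP = v_TP + v_sd - v_rT,
           CP = v_CP - v_sd - v_rC,
           TPr = v_rT,
           CPr = v_rC,
           S = if (sys$substrate_depletion) -v_rT - v_rC else 0))
  }
  out <- deSolve::lsoda(y0, t_grid, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("integrator failed; see diagnostics")
  out <- as.data.frame(out)
  if (min(out[-1]) < -atol * 1e3) stop("negative concentrations beyond tolerance")
  bound <- out$TP + out$CP
  out$theta <- ifelse(bound > 0, out$TP / bound, NA_real_)
  tT <- system$conc_T; tC <- system$conc_C
  out$reacted_T <- if (tT > 0) out$TPr / tT else 0
  out$reacted_C <- if (tC > 0) out$CPr / tC else 0
  class(out) <- c("hk_timecourse", "data.frame")
  attr(out, "system") <- system
  out
}

#' @export
#' @method plot hk_timecourse
plot.hk_timecourse <- function(x, ...) {
  plot(x$time, x$theta, type = "l", log = "x", xlab = "time (s)",
       ylab = expression(theta(t)), ylim = c(0, 1), ...)
  invisible(x)
}

#' Equilibration half-life of the transient mis-paired duplex
#'
#' The time at which the off-target duplex concentration `[C:P](t)` has
#' moved halfway (interpolating linearly on log time) from its early maximum
#' to its equilibrium value — the lifetime of the transient low-accuracy
#' state.
#'
#' @param tc an [simulate_mixture()] time course.
#' @param cp_eq equilibrium `[C:P]`; defaults to the value from
#'   [equilibrium_accuracy()] on the attached system.
#' @param tol relative tolerance below which the transient is considered
#'   absent.
#' @return half-life in seconds.
#' @export
equilibration_halflife <- function(tc, cp_eq = NULL, tol = 1e-3) {
  stopifnot(inherits(tc, "hk_timecourse"))
  if (is.null(cp_eq)) {
    sys <- attr(tc, "system")
    if (is.null(sys)) stop("no system attached; supply cp_eq")
    cp_eq <- equilibrium_accuracy(sys)$CP
  }
  i_max <- which.max(tc$CP)
  cp_max <- tc$CP[i_max]
  if (abs(cp_max - cp_eq) <= tol * max(cp_eq, cp_max))
    stop("no transient: the system is already at equilibrium")
  half <- (cp_max + cp_eq) / 2
  after <- tc[i_max:nrow(tc), ]
  # first crossing of the half level on the way to equilibrium
  dir <- sign(cp_eq - cp_max)
  crossed <- if (dir < 0) after$CP <= half else after$CP >= half
  if (!any(crossed))
    stop("half point not reached: integrate over a longer time window")
  k <- which(crossed)[1]
  if (k == 1L) return(after$time[1])
  t1 <- after$time[k - 1L]; t2 <- after$time[k]
  y1 <- after$CP[k - 1L]; y2 <- after$CP[k]
  if (t1 <= 0) return(t2)
  10^(log10(t1) + (half - y1) / (y2 - y1) * (log10(t2) - log10(t1)))
}

#' Reaction yields in a competition with an extension/ligation channel
#'
#' Convenience wrapper around [simulate_mixture()] returning the reacted
#' fraction of target and competitor over time. The competitor yield is
#' non-decreasing and plateaus once the transient C:P population is removed
#' by equilibration.
#'
#' @param system an [mixture_system()] with a reaction channel set.
#' @param t_grid increasing time grid from 0, seconds.
#' @return data.frame with `time`, `reacted_T`, `reacted_C`.
#' @export
reaction_yields <- function(system, t_grid) {
  stopifnot(inherits(system, "hk_mixture"))
  if (system$k_react_TP <= 0 && system$k_react_CP <= 0)
    stop("no reaction channel: set k_react_TP / k_react_CP")
  tc <- simulate_mixture(system, t_grid)
  tc[, c("time", "reacted_T", "reacted_C")]
}
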