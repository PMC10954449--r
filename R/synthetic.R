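#' Simulate a stopped-flow association trace
#'
#' Integrates the reversible bimolecular association ODE, maps the bound
#' fraction to a 2-aminopurine-like signal (high when free, low when
#' duplexed) and adds seeded Gaussian noise expressed as a fraction of the
#' signal dynamic range. The generating bound-fraction curve is attached as
#' ground truth.
#'
#' @param k_on,k_off rate constants (1/(M s), 1/s).
#' @param conc_a,conc_b total strand concentrations, mol/L (the reference
#'   measurements used 0.5-5 uM).
#' @param noise_sd Gaussian noise SD as a fraction of the dynamic range
#'   (default 0.02).
#' @param n_points number of points; `t_max` trace end, seconds.
#' @param F_T,F_TP free- and bound-state signal levels.
#' @param seed integer seed.
#' @return data.frame with `time`, `signal` plus attributes `truth`
#'   (bound-fraction curve) and the generating parameters.
#' @export
gen_stopped_flow <- function(k_on, k_off = 0, conc_a = 1e-6, conc_b = 1e-6,
                             noise_sd = 0.02, n_points = 200,
                             t_max = NULL, F_T = 1, F_TP = 0.2, seed = 1L) {
  stopifnot(k_on > 0, k_off >= 0, conc_a > 0, conc_b > 0, n_points >= 20)
  if (is.null(t_max)) t_max <- 10 / (k_on * min(conc_a, conc_b))
  time <- seq(0, t_max, length.out = n_points)
  frac <- .bimolecular_frac(time, k_on, k_off, conc_a, conc_b)
  set.seed(seed %% .Machine$integer.max)
  signal <- F_T + (F_TP - F_T) * frac +
    rnorm(n_points, 0, noise_sd * abs(F_T - F_TP))
  out <- data.frame(time = time, signal = signal)
  attr(out, "truth") <- data.frame(time = time, frac = frac)
  attr(out, "params") <- list(k_on = k_on, k_off = k_off, conc_a = conc_a,
                              conc_b = conc_b, F_T = F_T, F_TP = F_TP,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate two-state melting curves at several concentrations
#'
#' Two-state occupancy against temperature from the supplied enthalpy and
#' entropy, linear baselines, seeded Gaussian noise. The ground-truth
#' `K_D(25 C)` is attached.
#'
#' @param dH kcal/mol; `dS` cal/(mol K).
#' @param conc_list per-curve total strand concentration (mol/L, equal for
#'   the two strands).
#' @param t_range temperature range, degrees C.
#' @param baseline list with `lo0`, `lo1`, `hi0`, `hi1` (signal = bound
#'   fraction times the low line plus the rest times the high line).
#' @param noise_sd noise SD as fraction of dynamic range.
#' @param n_points per curve; `seed` integer seed.
#' @return list of curves (each `temperature`, `signal`, `conc_a`, `conc_b`)
#'   with attribute `K_D_25`.
#' @export
gen_melt_curves <- function(dH, dS, conc_list = c(5e-7, 1e-6, 5e-6),
                            t_range = c(10, 95),
                            baseline = list(lo0 = 0.2, lo1 = 0.001,
                                            hi0 = 1.0, hi1 = 0.002),
                            noise_sd = 0.01, n_points = 120, seed = 1L) {
  stopifnot(dH < 0, n_points >= 20)
  set.seed(seed %% .Machine$integer.max)
  curves <- lapply(seq_along(conc_list), function(i) {
    cc <- conc_list[i]
    tempc <- seq(t_range[1], t_range[2], length.out = n_points)
    Tk <- .kelvin(tempc)
    f <- .melt_frac(Tk, dH, dS, cc, cc)
    if (f[1] < 0.9 || f[length(f)] > 0.1)
      warning(sprintf("curve %d: transition partly outside window", i))
    lo <- baseline$lo0 + baseline$lo1 * (Tk - 298.15)
    hi <- baseline$hi0 + baseline$hi1 * (Tk - 298.15)
    rng <- abs(baseline$hi0 - baseline$lo0)
    data.frame(temperature = tempc,
               signal = f * lo + (1 - f) * hi +
                 rnorm(n_points, 0, noise_sd * rng),
               conc_a = cc, conc_b = cc)
  })
  dG25 <- dH - 298.15 * dS / 1000
  attr(curves, "K_D_25") <- exp(dG25 / (.R_KCAL * 298.15))
  attr(curves, "params") <- list(dH = dH, dS = dS, seed = seed)
  curves
}

#' Simulate a three-strand competition experiment
#'
#' Runs [simulate_mixture()] and maps the target-bound fraction to a
#' 2Ap-like signal with seeded noise; the true time course is attached.
#'
#' @param system an [mixture_system()] (the reference competition used
#'   200 nM of each strand).
#' @param t_grid time grid, seconds.
#' @param noise_sd noise SD as fraction of dynamic range.
#' @param F_T,F_TP free/bound signal levels; `seed` integer seed.
#' @return data.frame `time`, `signal` with attribute `truth` (the full
#'   [simulate_mixture()] time course).
#' @export
gen_competition_experiment <- function(system, t_grid, noise_sd = 0.02,
                                       F_T = 1, F_TP = 0.2, seed = 1L) {
  tc <- simulate_mixture(system, t_grid)
  bound_T <- if (system$conc_T > 0) (tc$TP + tc$TPr) / system$conc_T else 0
  set.seed(seed %% .Machine$integer.max)
  signal <- F_T + (F_TP - F_T) * bound_T +
    rnorm(nrow(tc), 0, noise_sd * abs(F_T - F_TP))
  out <- data.frame(time = tc$time, signal = signal)
  attr(out, "truth") <- tc
  out
}

#' Uniform random nucleotide pool
#'
#' @param L pool length (>= 1).
#' @param seed integer seed.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return an [hk_seq].
#' @export
gen_random_pool <- function(L, seed = 1L, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(L >= 1)
  set.seed(seed %% .Machine$integer.max)
  hk_seq(paste(sample(.alphabet_bases(alphabet), L, replace = TRUE),
               collapse = ""), alphabet, NULL, name = "random_pool")
}

#' Reference 12-mer probe/target panel
#'
#' The fixed probe 5'-CACGCATCACCA-3', its perfect 12-nt target
#' 5'-TGGTGATGCGTG-3' (the t12 control), and systematically edited
#' competitor panels: single mismatches m_1..m_12, single bulges b_2..b_11
#' (terminal deletions do not create a bulge), and a documented set of
#' double mismatches including m_4,9 and m_1,12. RNA twins substitute U for
#' T throughout. Substituted bases are chosen by the deterministic
#' low-self-complementarity rule of [make_variant()]; the exact substitutions
#' of any particular experimental panel can be reproduced by passing explicit
#' `substituted_base` values instead.
#'
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param seed integer seed for the substitution tie-break rule.
#' @return list with `probe`, `target`, and named lists `single_mismatch`,
#'   `double_mismatch`, `bulge` of competitor [hk_seq] objects, plus
#'   `defects`, the per-variant defect declarations.
#' @export
t12_panel <- function(alphabet = c("DNA", "RNA"), seed = 1L) {
  alphabet <- match.arg(alphabet)
  probe <- hk_seq("CACGCATCACCA", "DNA", NULL, name = "P")
  target <- hk_seq("TGGTGATGCGTG", "DNA", NULL, name = "t12")
  # non-adjacent pairs only: tandem mismatches are outside the NN tables
  doubles <- list(c(1L, 12L), c(2L, 11L), c(4L, 9L), c(3L, 10L))
  defs <- c(
    lapply(1:12, function(p) list(defect("mismatch", p))),
    lapply(doubles, function(pp) list(defect("mismatch", pp[1]),
                                      defect("mismatch", pp[2]))),
    lapply(2:11, function(p) list(defect("bulge", p))))
  variants <- lapply(defs, function(d) make_variant(target, probe, d, seed))
  if (alphabet == "RNA") {
    probe <- as_rna(probe); target <- as_rna(target)
    variants <- lapply(variants, as_rna)
  }
  names(variants) <- vapply(variants, `[[`, "", "name")
  kinds <- c(rep("single_mismatch", 12), rep("double_mismatch", 4),
             rep("bulge", 10))
  list(probe = probe, target = target,
       single_mismatch = variants[kinds == "single_mismatch"],
       double_mismatch = variants[kinds == "double_mismatch"],
       bulge = variants[kinds == "bulge"],
       defects = setNames(defs, names(variants)))
}
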