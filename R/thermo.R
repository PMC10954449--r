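#' Duplex thermodynamics from the nearest-neighbor model
#'
#' Sums nearest-neighbor stack terms over adjacent Watson-Crick pairs,
#' mismatch-context doublet terms at declared mismatches (terminal-mismatch
#' table at duplex ends), single-base bulge-loop increments (the stack of the
#' flanking pairs is retained), duplex initiation terms charged on the
#' outermost Watson-Crick pair of each end, a symmetry correction for
#' self-complementary duplexes, and the 2-aminopurine penalty per marked
#' position. Unresolvable parameter contexts (e.g. a tandem mismatch absent
#' from the tables) raise an error naming the context; there is no silent
#' fallback.
#'
#' @param dup an [duplex()] object.
#' @param temperature temperature in degrees C (0-100).
#' @param params an [thermo_params()] object matching the duplex alphabet.
#' @param conc_a,conc_b total strand concentrations (mol/L) recorded in the
#'   condition record and used for the reported melting temperature.
#' @return An object of class `hk_thermo_result`: `dH` (kcal/mol), `dS`
#'   (cal/mol/K), `dG` (kcal/mol at `temperature`), `K_D` (mol/L), `Tm`
#'   (degrees C at the stated concentrations) and the condition record.
#' @examples
#' p <- hk_seq("CACGCATCACCA"); t <- hk_seq("TGGTGATGCGTG")
#' duplex_thermo(duplex(t, p), 25, thermo_params("DNA"))
#' @export
duplex_thermo <- function(dup, temperature = 25, params = NULL,
                          conc_a = 1e-6, conc_b = 1e-6) {
  stopifnot(inherits(dup, "hk_duplex"))
  if (is.null(params)) params <- thermo_params(dup$a$alphabet)
  if (params$alphabet != dup$a$alphabet)
    stop("parameter set alphabet does not match the duplex")
  if (temperature < 0 || temperature > 100)
    stop("temperature must be within [0, 100] C")
  hs <- .duplex_dHdS(dup, params)
  Tk <- .kelvin(temperature)
  dG <- hs[["dH"]] - Tk * hs[["dS"]] / 1000
  structure(list(dH = hs[["dH"]], dS = hs[["dS"]], dG = dG,
                 K_D = exp(dG / (.R_KCAL * Tk)),
                 Tm = .tm_solve(hs[["dH"]], hs[["dS"]], conc_a, conc_b),
                 temperature = temperature, salt = "1 M NaCl",
                 conc_a = conc_a, conc_b = conc_b,
                 n_pairs = nrow(dup$pairs)),
            class = "hk_thermo_result")
}

#' @export
print.hk_thermo_result <- function(x, ...) {
  cat(sprintf("<hk_thermo_result> %d bp at %.1f C, %s\n", x$n_pairs,
              x$temperature, x$salt))
  cat(sprintf("  dH = %.2f kcal/mol, dS = %.2f cal/(mol K)\n", x$dH, x$dS))
  cat(sprintf("  dG(%.0f C) = %.2f kcal/mol, K_D = %.3g M, Tm = %.1f C (%.2g/%.2g M strands)\n",
              x$temperature, x$dG, x$K_D, x$Tm, x$conc_a, x$conc_b))
  invisible(x)
}

# total (dH, dS) of a duplex; dH in kcal/mol, dS in cal/(mol K)
.duplex_dHdS <- function(dup, params) {
  p <- dup$pairs[order(dup$pairs$b_pos), ]
  m <- nrow(p)
  ach <- .seq_chars(dup$a); bch <- .seq_chars(dup$b)
  tot <- c(dH = 0, dS = 0)
  if (m == 0L) stop("duplex has no aligned pairs")

  for (k in seq_len(max(m - 1L, 0L))) {
    top <- bch[c(p$b_pos[k], p$b_pos[k + 1L])]
    bottom <- ach[c(p$a_pos[k], p$a_pos[k + 1L])]
    gap <- (p$b_pos[k + 1L] - p$b_pos[k] - 1L) +
      (abs(p$a_pos[k] - p$a_pos[k + 1L]) - 1L)
    n_mm <- sum(p$mismatch[c(k, k + 1L)])
    if (gap > 0L) {
      if (gap > 1L) stop("only single-base bulge loops are supported")
      if (n_mm > 0L) stop("bulge adjacent to a mismatch is not tabulated")
      tot <- tot + params$bulge["bulge1", ] + .stack_term(params, top, bottom)
    } else if (n_mm == 0L) {
      tot <- tot + .stack_term(params, top, bottom)
    } else {
      terminal <- (k == 1L && p$mismatch[1L]) ||
        (k == m - 1L && p$mismatch[m])
      tot <- tot + .mismatch_term(params, top, bottom, n_mm, terminal)
    }
  }

  if (params$alphabet == "RNA") {
    for (k in which(p$mismatch))
      tot <- tot + .rna_pair_term(params, bch[p$b_pos[k]], ach[p$a_pos[k]])
  }

  wc <- which(!p$mismatch)
  if (!length(wc)) stop("duplex has no Watson-Crick pair")
  if (params$alphabet == "RNA") tot <- tot + params$init["init", ]
  for (k in c(wc[1L], wc[length(wc)]))
    tot <- tot + .init_term(params, bch[p$b_pos[k]], ach[p$a_pos[k]])

  if (dup$a$bases == dup$b$bases &&
      dup$a$bases == reverse_complement(dup$a)$bases)
    tot <- tot + params$init["sym", ]

  n_ap2 <- length(dup$a$ap2_positions) + length(dup$b$ap2_positions)
  if (n_ap2 > 0L && params$ap2_ddg != 0)
    tot[["dS"]] <- tot[["dS"]] - n_ap2 * params$ap2_ddg * 1000 / 298.15

  if (!is.null(params$salt_correction)) tot <- params$salt_correction(tot)
  tot
}

# two-state melting temperature in C for a non-self-complementary pair at
# total strand concentrations ca, cb: at the midpoint half of the limiting
# strand is bound, so K_D(Tm) = c_excess - c_limiting/2.
.tm_solve <- function(dH, dS, conc_a, conc_b) {
  stopifnot(conc_a > 0, conc_b > 0)
  ceff <- max(conc_a, conc_b) - min(conc_a, conc_b) / 2
  f <- function(Tk) (dH * 1000 - Tk * dS) / (.R_KCAL * 1000 * Tk) - log(ceff)
  lo <- 150; hi <- 550
  if (f(lo) * f(hi) > 0)
    stop(sprintf("no melting transition in [%.0f, %.0f] K (f(lo)=%.2f, f(hi)=%.2f)",
                 lo, hi, f(lo), f(hi)))
  uniroot(f, c(lo, hi), tol = 1e-10)$root - 273.15
}

#' Two-state melting temperature of a duplex
#'
#' Solves `K_D(Tm) = [A]_free [B]_free / [AB]` at half-dissociation of the
#' limiting strand for a non-self-complementary pair; monotone increasing in
#' concentration.
#'
#' @inheritParams duplex_thermo
#' @param conc_a,conc_b total strand concentrations in mol/L (> 0).
#' @return Tm in degrees C.
#' @examples
#' p <- hk_seq("CACGCATCACCA"); t <- hk_seq("TGGTGATGCGTG")
#' melting_temperature(duplex(t, p), 1e-6, 1e-6)   # about 57 C
#' @export
melting_temperature <- function(dup, conc_a = 1e-6, conc_b = 1e-6,
                                params = NULL) {
  stopifnot(inherits(dup, "hk_duplex"))
  if (is.null(params)) params <- thermo_params(dup$a$alphabet)
  hs <- .duplex_dHdS(dup, params)
  .tm_solve(hs[["dH"]], hs[["dS"]], conc_a, conc_b)
}

#' Equilibrium dissociation constant of a duplex
#'
#' `K_D = exp(dG / RT)` with `dG` the hybridization free energy at the stated
#' temperature; strictly increasing in `dG`.
#' @inheritParams duplex_thermo
#' @return K_D in mol/L.
#' @export
kd_at <- function(dup, temperature = 25, params = NULL) {
  duplex_thermo(dup, temperature, params)$K_D
}

#' Nucleation-segment free energy
#'
#' Free energy of the n-base nucleation mini-duplex starting at position `i`
#' on strand A and `j` on strand B (both 5'->3'). Returns `+Inf` unless
#' `A[i..i+n-1]` is fully antiparallel-complementary to `B[j..j+n-1]`
#' (`A[i+k]` pairs `B[j+n-1-k]`); otherwise the nearest-neighbor mini-duplex
#' hybridization free energy including initiation terms at the stated
#' temperature. If the parameter set carries a `dg_lookup` hook, it is called
#' with the two segment strings instead, so externally computed nucleation
#' free energies can be injected.
#'
#' @param strand_a,strand_b [hk_seq] objects.
#' @param i,j 1-based segment start positions.
#' @param n segment length.
#' @param temperature degrees C.
#' @param params an [thermo_params()].
#' @return kcal/mol, or `+Inf`.
#' @export
nucleation_dg <- function(strand_a, i, strand_b, j, n = 3, temperature = 25,
                          params = NULL) {
  a <- hk_seq(strand_a); b <- hk_seq(strand_b)
  if (is.null(params)) params <- thermo_params(a$alphabet)
  i <- as.integer(i); j <- as.integer(j); n <- as.integer(n)
  if (i < 1L || i > length(a) - n + 1L) stop("i out of range")
  if (j < 1L || j > length(b) - n + 1L) stop("j out of range")
  ach <- .seq_chars(a); bch <- .seq_chars(b)
  k <- 0:(n - 1L)
  if (!all(.complement_base(ach[i + k], a$alphabet) == bch[j + n - 1L - k]))
    return(Inf)
  seg_a <- substr(a$bases, i, i + n - 1L)
  seg_b <- substr(b$bases, j, j + n - 1L)
  if (!is.null(params$dg_lookup)) return(params$dg_lookup(seg_a, seg_b))
  ap2_a <- a$ap2_positions[a$ap2_positions >= i & a$ap2_positions < i + n] - i + 1L
  ap2_b <- b$ap2_positions[b$ap2_positions >= j & b$ap2_positions < j + n] - j + 1L
  sub <- duplex(hk_seq(seg_a, a$alphabet, NULL, ap2_a),
                hk_seq(seg_b, b$alphabet, NULL, ap2_b))
  hs <- .duplex_dHdS(sub, params)
  hs[["dH"]] - .kelvin(temperature) * hs[["dS"]] / 1000
}
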