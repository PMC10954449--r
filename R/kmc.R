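#' Configuration for the zippering kinetic Monte Carlo simulator
#'
#' @param k_uni unimolecular attempt rate for adding one base pair at a
#'   duplex end, 1/s (default 4.2e8).
#' @param mismatch_barrier additional activation free energy for the move
#'   that steps the zipper across a declared mismatch, kcal/mol
#'   (default 2.49). Applied symmetrically to the pairing and unpairing move
#'   so detailed balance is preserved. Bulge crossing carries no barrier.
#' @param temperature degrees C.
#' @param concentration strand concentration used in the first-step rate
#'   assembly, mol/L.
#' @param n_trajectories number of stochastic trajectories.
#' @param seed integer RNG seed.
#' @param k_nuc_bi bimolecular nucleation-entry rate, 1/(M s).
#' @param entry_mode `"per_site"` (default: `k_nuc_bi` is the entry rate into
#'   each single-pair nucleation state, so the total collision rate scales
#'   with the number of sites) or `"total"` (`k_nuc_bi` is the total
#'   collision rate, split evenly over sites).
#' @return object of class `hk_kmc_config`.
#' @export
kmc_config <- function(k_uni = 4.2e8, mismatch_barrier = 2.49,
                       temperature = 25, concentration = 1e-6,
                       n_trajectories = 1e4, seed = 1L,
                       k_nuc_bi = 2e6, entry_mode = c("per_site", "total")) {
  stopifnot(k_uni > 0, n_trajectories >= 1, concentration > 0, k_nuc_bi > 0)
  structure(list(k_uni = k_uni, mismatch_barrier = mismatch_barrier,
                 temperature = temperature, concentration = concentration,
                 n_trajectories = as.integer(n_trajectories),
                 seed = as.integer(seed), k_nuc_bi = k_nuc_bi,
                 entry_mode = match.arg(entry_mode)),
            class = "hk_kmc_config")
}

# sub-duplex over pair rows a..b of the alignment (bulged probe bases between
# the flanking pairs are retained)
.slice_duplex <- function(dup, a, b) {
  p <- dup$pairs[order(dup$pairs$b_pos), ]
  rows <- p[a:b, ]
  b_lo <- min(rows$b_pos); b_hi <- max(rows$b_pos)
  a_lo <- min(rows$a_pos); a_hi <- max(rows$a_pos)
  sub_b <- hk_seq(substr(dup$b$bases, b_lo, b_hi), dup$b$alphabet, NULL,
                  dup$b$ap2_positions[dup$b$ap2_positions >= b_lo &
                                        dup$b$ap2_positions <= b_hi] - b_lo + 1L)
  sub_a <- hk_seq(substr(dup$a$bases, a_lo, a_hi), dup$a$alphabet, NULL,
                  dup$a$ap2_positions[dup$a$ap2_positions >= a_lo &
                                        dup$a$ap2_positions <= a_hi] - a_lo + 1L)
  pairs <- data.frame(a_pos = rows$a_pos - a_lo + 1L,
                      b_pos = rows$b_pos - b_lo + 1L,
                      mismatch = rows$mismatch)
  structure(list(a = sub_a, b = sub_b, pairs = pairs,
                 bulge_b_pos = dup$bulge_b_pos[dup$bulge_b_pos > b_lo &
                                                 dup$bulge_b_pos < b_hi] - b_lo + 1L,
                 defects = list()),
            class = "hk_duplex")
}

#' Build the zippering Markov chain of a duplex
#'
#' Enumerates all contiguous bound intervals of the pairing register that
#' contain at least one Watson-Crick pair (intervals made solely of
#' mismatched pairs are excluded from the state space), plus the dissociated
#' state. Interval free energies come from the same nearest-neighbor engine
#' as [duplex_thermo()] applied to the corresponding sub-duplex; a
#' single-pair interval carries initiation-only energy. Transition rates
#' follow the Metropolis rule at `k_uni`, with the configured mismatch
#' barrier multiplying (symmetrically) both directions of any move that adds
#' or removes a mismatched pair.
#'
#' @param dup an [duplex()] object.
#' @param config an [kmc_config()].
#' @param params an [thermo_params()].
#' @return object of class `hk_zipper_chain`: `states` (data.frame `a`, `b`,
#'   `G`), `edges`, indices of the full-duplex and dissociated states, and
#'   adjacency structures used by the samplers.
#' @export
build_chain <- function(dup, config = kmc_config(), params = NULL) {
  stopifnot(inherits(dup, "hk_duplex"))
  if (is.null(params)) params <- thermo_params(dup$a$alphabet)
  p <- dup$pairs[order(dup$pairs$b_pos), ]
  m <- nrow(p)
  mm <- p$mismatch
  if (all(mm)) stop("no complementary position to nucleate at")

  iv <- expand.grid(a = seq_len(m), b = seq_len(m))
  iv <- iv[iv$a <= iv$b, ]
  keep <- vapply(seq_len(nrow(iv)), function(r) any(!mm[iv$a[r]:iv$b[r]]),
                 logical(1))
  iv <- iv[keep, ]
  iv <- iv[order(iv$a, iv$b), ]
  rownames(iv) <- NULL
  S <- nrow(iv)
  idx <- matrix(NA_integer_, m, m)
  idx[cbind(iv$a, iv$b)] <- seq_len(S)

  rt <- .rt(config$temperature)
  Tk <- .kelvin(config$temperature)
  G <- vapply(seq_len(S), function(s) {
    hs <- .duplex_dHdS(.slice_duplex(dup, iv$a[s], iv$b[s]), params)
    hs[["dH"]] - Tk * hs[["dS"]] / 1000
  }, numeric(1))

  id_diss <- S + 1L
  id_full <- idx[1L, m]

  # edges: one row per unordered neighbor pair; "grow" direction adds `pos`
  from <- integer(0); to <- integer(0); pos <- integer(0)
  for (s in seq_len(S)) {
    a <- iv$a[s]; b <- iv$b[s]
    if (a > 1L && !is.na(idx[a - 1L, b])) {
      from <- c(from, s); to <- c(to, idx[a - 1L, b]); pos <- c(pos, a - 1L)
    }
    if (b < m && !is.na(idx[a, b + 1L])) {
      from <- c(from, s); to <- c(to, idx[a, b + 1L]); pos <- c(pos, b + 1L)
    }
    if (a == b) {  # detach the last pair
      from <- c(from, s); to <- c(to, id_diss); pos <- c(pos, a)
    }
  }
  # rate_grow is the rate of the from->to move (pair addition, except for
  # the detach edges into the dissociated state); rate_shrink the reverse.
  Gall <- c(G, 0)  # dissociated state at zero
  dG_grow <- Gall[to] - Gall[from]
  mm_edge <- mm[pos]
  grow0 <- config$k_uni * pmin(1, exp(-dG_grow / rt))
  shrink0 <- config$k_uni * pmin(1, exp(dG_grow / rt))
  fac <- ifelse(mm_edge, exp(-config$mismatch_barrier / rt), 1)

  edges <- data.frame(from = from, to = to, pos = pos, mm = mm_edge,
                      dG_grow = dG_grow,
                      rate_grow0 = grow0, rate_shrink0 = shrink0,
                      rate_grow = grow0 * fac, rate_shrink = shrink0 * fac)
  # for the detach edges, from=[a,a] -> dissociated is a shrink move
  structure(list(duplex = dup, config = config, states = iv, G = G,
                 edges = edges, m = m, mismatch = mm,
                 id_full = id_full, id_diss = id_diss,
                 start_sites = idx[cbind(which(!mm), which(!mm))],
                 start_pos = which(!mm), rt = rt),
            class = "hk_zipper_chain")
}

#' @export
print.hk_zipper_chain <- function(x, ...) {
  cat(sprintf("<hk_zipper_chain> %d aligned pairs, %d states (+1 dissociated), %d edges\n",
              x$m, nrow(x$states), nrow(x$edges)))
  cat(sprintf("  k_uni = %.3g /s, mismatch barrier = %.2f kcal/mol, T = %g C\n",
              x$config$k_uni, x$config$mismatch_barrier, x$config$temperature))
  invisible(x)
}

#' Outgoing transition rates of a chain state
#'
#' @param chain an [build_chain()] object.
#' @param state either `c(a, b)` (interval of bound pairs) or
#'   `"dissociated"`.
#' @return data.frame with target state labels and rates (1/s). The
#'   dissociated state has no unimolecular outgoing transitions.
#' @export
transition_rates <- function(chain, state) {
  stopifnot(inherits(chain, "hk_zipper_chain"))
  if (identical(state, "dissociated")) {
    return(data.frame(a = integer(0), b = integer(0), rate = numeric(0)))
  }
  s <- which(chain$states$a == state[1] & chain$states$b == state[2])
  if (!length(s)) stop("unknown state")
  e <- chain$edges
  out_grow <- e[e$from == s, ]
  out_shrink <- e[e$to == s & e$to != chain$id_diss, ]
  lab <- function(id) {
    if (id == chain$id_diss) c(NA_integer_, NA_integer_)
    else c(chain$states$a[id], chain$states$b[id])
  }
  res <- rbind(
    if (nrow(out_grow)) data.frame(t(vapply(out_grow$to, lab, integer(2))),
                                   rate = out_grow$rate_grow),
    if (nrow(out_shrink)) data.frame(t(vapply(out_shrink$from, lab,
                                              integer(2))),
                                     rate = out_shrink$rate_shrink))
  names(res)[1:2] <- c("a", "b")
  res
}

# adjacency list over all states (1..S transient/absorbing handled by caller)
.chain_adjacency <- function(chain, absorbing = integer(0), rates = NULL) {
  e <- chain$edges
  if (is.null(rates)) rates <- list(grow = e$rate_grow, shrink = e$rate_shrink)
  S <- nrow(chain$states) + 1L
  targets <- vector("list", S); rr <- vector("list", S)
  add <- function(i, j, r) {
    targets[[i]] <<- c(targets[[i]], j); rr[[i]] <<- c(rr[[i]], r)
  }
  for (k in seq_len(nrow(e))) {
    if (!(e$from[k] %in% absorbing)) add(e$from[k], e$to[k], rates$grow[k])
    if (e$to[k] != chain$id_diss && !(e$to[k] %in% absorbing))
      add(e$to[k], e$from[k], rates$shrink[k])
  }
  list(targets = targets, rates = rr)
}

#' Exact absorbing-chain solution for zippering success
#'
#' Linear solve over the transient states for the probability of reaching
#' the fully zipped duplex before dissociating, and the conditional mean
#' first-passage times of the success and failure branches, from every
#' single-pair nucleation state. Deterministic oracle for
#' [simulate_first_step()].
#'
#' @param chain an [build_chain()] object (state count <= 1e4).
#' @param barrier optional mismatch barrier (kcal/mol) overriding the
#'   chain's configured value.
#' @return data.frame with one row per nucleation site: `pos` (alignment
#'   position), `p_success`, `mfpt_success`, `mfpt_failure` (s).
#' @export
exact_passage <- function(chain, barrier = NULL) {
  stopifnot(inherits(chain, "hk_zipper_chain"))
  S <- nrow(chain$states)
  if (S > 1e4) stop("state count exceeds 1e4")
  e <- chain$edges
  if (!is.null(barrier)) {
    fac <- ifelse(e$mm, exp(-barrier / chain$rt), 1)
    e$rate_grow <- e$rate_grow0 * fac
    e$rate_shrink <- e$rate_shrink0 * fac
  }
  trans <- setdiff(seq_len(S), chain$id_full)
  pos_of <- match(seq_len(S), trans)  # S index -> transient index
  n <- length(trans)
  A <- matrix(0, n, n)
  r_full <- numeric(n); r_diss <- numeric(n)
  put <- function(i, j, rate) {
    # i transient S-index, j target S-index or id_diss
    ii <- pos_of[i]
    A[ii, ii] <<- A[ii, ii] - rate
    if (j == chain$id_diss) r_diss[ii] <<- r_diss[ii] + rate
    else if (j == chain$id_full) r_full[ii] <<- r_full[ii] + rate
    else A[ii, pos_of[j]] <<- A[ii, pos_of[j]] + rate
  }
  for (k in seq_len(nrow(e))) {
    if (e$from[k] != chain$id_full) put(e$from[k], e$to[k], e$rate_grow[k])
    if (e$to[k] != chain$id_diss && e$to[k] != chain$id_full)
      put(e$to[k], e$from[k], e$rate_shrink[k])
  }
  h <- tryCatch(solve(A, -r_full),
                error = function(err) stop("singular system: chain disconnected"))
  w <- solve(A, -h)
  g <- 1 - h
  u <- solve(A, -g)
  si <- pos_of[chain$start_sites]
  data.frame(pos = chain$start_pos,
             p_success = h[si],
             mfpt_success = ifelse(h[si] > 0, w[si] / h[si], NA_real_),
             mfpt_failure = ifelse(g[si] > 0, u[si] / g[si], NA_real_))
}

#' First-step kinetic Monte Carlo estimate of the association rate
#'
#' Seeded Gillespie trajectories are started from the single-pair nucleation
#' states (chosen uniformly) and run until they are absorbed at the fully
#' zipped duplex (success) or at dissociation (failure). The association
#' rate at the configured concentration is assembled from the success
#' probability and the conditional first-passage times in the first-step
#' fashion: with collision rate `k_coll * c`, the expected time to the first
#' successful zippering is
#' `T = 1/(p k_coll c) + E[t|fail] (1-p)/p + E[t|succ]` and
#' `k_on = 1/(c T)` (numerically `~ k_coll * p`, since the microscopic
#' passage times are negligible against the diffusive collision time).
#'
#' @param chain an [build_chain()] object.
#' @param config an [kmc_config()]; defaults to the chain's.
#' @return object of class `hk_rate_estimate` with `k_on`, `se`,
#'   `p_success`, conditional MFPTs and the trajectory count.
#' @export
simulate_first_step <- function(chain, config = NULL) {
  stopifnot(inherits(chain, "hk_zipper_chain"))
  if (is.null(config)) config <- chain$config
  ntraj <- config$n_trajectories
  if (ntraj < 1) stop("at least one trajectory is required")
  starts <- chain$start_sites
  if (!length(starts)) stop("no complementary position to nucleate at")
  adj <- .chain_adjacency(chain, absorbing = chain$id_full)
  totals <- vapply(adj$rates, function(r) if (length(r)) sum(r) else 0,
                   numeric(1))
  id_full <- chain$id_full; id_diss <- chain$id_diss

  set.seed(config$seed %% .Machine$integer.max)
  start_draw <- starts[sample.int(length(starts), ntraj, replace = TRUE)]
  success <- logical(ntraj); tau <- numeric(ntraj)
  for (tr in seq_len(ntraj)) {
    s <- start_draw[tr]; t_acc <- 0
    repeat {
      if (s == id_full) { success[tr] <- TRUE; break }
      if (s == id_diss) { success[tr] <- FALSE; break }
      tot <- totals[s]
      t_acc <- t_acc + rexp(1, tot)
      rr <- adj$rates[[s]]
      s <- adj$targets[[s]][sample.int(length(rr), 1L, prob = rr)]
    }
    tau[tr] <- t_acc
  }
  p <- mean(success)
  k_site <- if (config$entry_mode == "per_site") config$k_nuc_bi
            else config$k_nuc_bi / length(starts)
  k_coll <- k_site * length(starts)
  cc <- config$concentration
  t_succ <- if (any(success)) mean(tau[success]) else NA_real_
  t_fail <- if (any(!success)) mean(tau[!success]) else 0
  k_on <- if (p == 0) 0 else {
    Tbar <- 1 / (p * k_coll * cc) + (1 - p) / p * t_fail +
      (if (is.na(t_succ)) 0 else t_succ)
    1 / (cc * Tbar)
  }
  se_p <- sqrt(p * (1 - p) / ntraj)
  structure(list(k_on = k_on, se = k_coll * se_p, p_success = p,
                 se_p = se_p, mfpt_success = t_succ, mfpt_failure = t_fail,
                 n_trajectories = ntraj, k_coll = k_coll,
                 concentration = cc),
            class = "hk_rate_estimate")
}

#' @export
print.hk_rate_estimate <- function(x, ...) {
  cat(sprintf("<hk_rate_estimate> k_on = %.3g +/- %.2g /M/s (p_success = %.3f +/- %.3f, %d trajectories)\n",
              x$k_on, x$se, x$p_success, x$se_p, x$n_trajectories))
  invisible(x)
}

#' Time-weighted equilibrium occupancy of the non-absorbing zipper chain
#'
#' Runs the zippering chain with dissociation disabled and the full duplex
#' non-absorbing; the time-weighted occupancy converges to the Boltzmann
#' distribution over interval free energies (detailed-balance check).
#'
#' @param chain an [build_chain()] object.
#' @param n_steps number of jump events.
#' @param seed RNG seed.
#' @return data.frame of states with `G`, `occupancy` (time-weighted) and
#'   `boltzmann` (normalized weights `exp(-G/RT)`).
#' @export
kmc_equilibrium_occupancy <- function(chain, n_steps = 2e5, seed = 1L) {
  stopifnot(inherits(chain, "hk_zipper_chain"))
  e <- chain$edges
  keep <- e$to != chain$id_diss
  S <- nrow(chain$states)
  targets <- vector("list", S); rr <- vector("list", S)
  for (k in which(keep)) {
    targets[[e$from[k]]] <- c(targets[[e$from[k]]], e$to[k])
    rr[[e$from[k]]] <- c(rr[[e$from[k]]], e$rate_grow[k])
    targets[[e$to[k]]] <- c(targets[[e$to[k]]], e$from[k])
    rr[[e$to[k]]] <- c(rr[[e$to[k]]], e$rate_shrink[k])
  }
  totals <- vapply(rr, sum, numeric(1))
  set.seed(seed %% .Machine$integer.max)
  occ <- numeric(S)
  s <- chain$start_sites[1]
  for (step in seq_len(n_steps)) {
    dwell <- rexp(1, totals[s])
    occ[s] <- occ[s] + dwell
    s <- targets[[s]][sample.int(length(rr[[s]]), 1L, prob = rr[[s]])]
  }
  w <- exp(-chain$G / chain$rt)
  data.frame(a = chain$states$a, b = chain$states$b, G = chain$G,
             occupancy = occ / sum(occ), boltzmann = w / sum(w))
}

#' Fit the zippering simulator to measured association rates
#'
#' Two-parameter fit — a bimolecular nucleation-entry scale and the mismatch
#' zippering barrier — on `log10(k_on)`, using the exact absorbing-chain
#' solution (not stochastic sampling) for speed and determinism. Mismatches
#' are assumed to affect only the zippering, not the formation of the
#' initial nucleus, so a single entry scale is shared by all records. With
#' no mismatched duplex among the records the barrier is unidentifiable and
#' reported as `NA`.
#'
#' @param duplexes list of [duplex()] objects.
#' @param k_on measured association rates, 1/(M s).
#' @param config an [kmc_config()] (temperature, `k_uni`, entry mode).
#' @param params an [thermo_params()].
#' @param barrier_range search interval for the barrier, kcal/mol.
#' @return object of class `hk_kmcfit` with `k_nuc_bi`, `mismatch_barrier`,
#'   `fitted`, `residuals`.
#' @export
fit_kmc <- function(duplexes, k_on, config = kmc_config(), params = NULL,
                    barrier_range = c(0, 8)) {
  stopifnot(length(duplexes) == length(k_on), all(k_on > 0))
  if (is.null(params)) params <- thermo_params(duplexes[[1]]$a$alphabet)
  chains <- lapply(duplexes, build_chain, config = config, params = params)
  has_mm <- any(vapply(chains, function(ch) any(ch$mismatch), logical(1)))
  lobs <- log10(k_on)

  sum_p <- function(barrier) {
    vapply(chains, function(ch) {
      ep <- exact_passage(ch, barrier = barrier)
      if (config$entry_mode == "per_site") sum(ep$p_success)
      else mean(ep$p_success)
    }, numeric(1))
  }
  obj <- function(barrier) {
    s <- sum_p(barrier)
    lk <- mean(lobs - log10(s))
    sum((lobs - (lk + log10(s)))^2)
  }
  if (has_mm) {
    opt <- optimize(obj, barrier_range, tol = 1e-4)
    barrier <- opt$minimum
  } else {
    barrier <- NA_real_
  }
  s <- sum_p(if (is.na(barrier)) 0 else barrier)
  k_nuc_bi <- 10^mean(lobs - log10(s))
  fitted_l <- log10(k_nuc_bi) + log10(s)
  structure(list(k_nuc_bi = k_nuc_bi, mismatch_barrier = barrier,
                 fitted = 10^fitted_l, residuals = lobs - fitted_l,
                 entry_mode = config$entry_mode,
                 barrier_identifiable = has_mm),
            class = "hk_kmcfit")
}

#' @export
print.hk_kmcfit <- function(x, ...) {
  cat(sprintf("<hk_kmcfit> nucleation entry scale = %.3g /M/s (%s)\n",
              x$k_nuc_bi, x$entry_mode))
  if (x$barrier_identifiable)
    cat(sprintf("  mismatch zippering barrier = %.2f kcal/mol\n",
                x$mismatch_barrier))
  else cat("  mismatch barrier unidentifiable (no mismatched records)\n")
  invisible(x)
}

#' @export
#' @method coef hk_kmcfit
coef.hk_kmcfit <- function(object, ...) {
  c(k_nuc_bi = object$k_nuc_bi, mismatch_barrier = object$mismatch_barrier)
}
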