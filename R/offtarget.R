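#' Off-target site query
#'
#' Describes the search for partially complementary binding sites of a probe
#' of length `n` in a random-sequence pool of length `L`: sites are windows
#' whose content complements the probe within a defect budget of at most
#' `max_mismatch` mismatches and at most `max_bulge` bulges (a bulge is a
#' single-base deletion of the probe, deletion positions 2..n, so `n - 1`
#' distinct deleted probes; only budgets of 0 or 1 bulge are supported).
#' One pool orientation is searched by default; set `both_strands` to double
#' `L`.
#'
#' @param n probe length, nt (>= 1).
#' @param L pool length, nt (>= n).
#' @param max_mismatch,max_bulge defect budgets (>= 0).
#' @param both_strands search both pool orientations.
#' @return object of class `hk_offtarget_query`.
#' @export
offtarget_query <- function(n, L, max_mismatch = 0, max_bulge = 0,
                            both_strands = FALSE) {
  stopifnot(n >= 1, L >= n, max_mismatch >= 0, max_bulge >= 0)
  if (max_bulge > 1) stop("bulge budgets above 1 are not supported")
  structure(list(n = as.integer(n), L = as.numeric(L),
                 max_mismatch = as.integer(max_mismatch),
                 max_bulge = as.integer(max_bulge),
                 both_strands = isTRUE(both_strands)),
            class = "hk_offtarget_query")
}

#' Expected number of off-target sites in random sequence
#'
#' Exact combinatorial expectation (no approximation beyond window
#' independence): the mismatch-only term is
#' `(L - n + 1) * sum_{k<=d_m} C(n,k) (3/4)^k (1/4)^(n-k)`, and the
#' single-bulge term matches windows of length `n - 1` against the distinct
#' single-deletion patterns of the probe, still allowing the mismatch
#' budget. Deleting two positions inside one run of identical bases yields
#' the same pattern, so for a uniform random probe the expected number of
#' distinct patterns over deletion positions 2..n is `(3n - 2)/4` (one per
#' maximal base run intersecting those positions), which is the multiplicity
#' used here.
#'
#' @param query an [offtarget_query()].
#' @return expected site count.
#' @export
expected_sites <- function(query) {
  stopifnot(inherits(query, "hk_offtarget_query"))
  n <- query$n
  L <- query$L * if (query$both_strands) 2 else 1
  p_within <- function(len, d) {
    k <- 0:min(d, len)
    sum(choose(len, k) * (3 / 4)^k * (1 / 4)^(len - k))
  }
  e <- (L - n + 1) * p_within(n, query$max_mismatch)
  if (query$max_bulge >= 1L && n >= 2L && L >= n - 1) {
    e <- e + (L - (n - 1) + 1) * (3 * n - 2) / 4 *
      p_within(n - 1L, query$max_mismatch)
  }
  e
}

#' Probability of at least one off-target site
#'
#' `P = 1 - exp(-E)` with `E` from [expected_sites()] (Poisson aggregation
#' over windows); `exact = TRUE` uses the per-window product form
#' `1 - (1 - p)^w` instead, appropriate for small pools. Monotone increasing
#' in `L` and in the defect budgets.
#'
#' @param query an [offtarget_query()].
#' @param exact use the product form rather than the Poisson form.
#' @return probability.
#' @export
site_probability <- function(query, exact = FALSE) {
  e <- expected_sites(query)
  if (!exact) return(1 - exp(-e))
  n <- query$n
  L <- query$L * if (query$both_strands) 2 else 1
  w <- (L - n + 1) + if (query$max_bulge >= 1L && n >= 2L)
    (L - n + 2) * (3 * n - 2) / 4 else 0
  1 - (1 - e / w)^w
}

#' Monte Carlo validation of the off-target site probability
#'
#' Samples random pools and random probes (i.i.d. uniform bases, seeded) and
#' scans every window with a budgeted Hamming comparison (plus single-probe-
#' base-deletion variants when bulges are allowed), returning the empirical
#' probability that a pool contains at least one qualifying site.
#'
#' @param query an [offtarget_query()].
#' @param trials number of (pool, probe) draws (>= 1).
#' @param seed integer seed.
#' @return list with `p_hat`, `se` and `trials`.
#' @export
mc_validate <- function(query, trials, seed = 1L) {
  stopifnot(inherits(query, "hk_offtarget_query"))
  trials <- as.integer(trials)
  if (trials < 1L) stop("at least one trial is required")
  n <- query$n
  L <- query$L * if (query$both_strands) 2 else 1
  if (n * L * trials > 1e10)
    stop("guard exceeded: > 1e10 window comparisons requested")
  set.seed(seed %% .Machine$integer.max)
  dm <- query$max_mismatch
  probes_del <- if (query$max_bulge >= 1L && n >= 2L) 2:n else integer(0)

  hits <- logical(trials)
  for (tr in seq_len(trials)) {
    pool <- sample.int(4L, L, replace = TRUE)
    probe <- sample.int(4L, n, replace = TRUE)
    target <- 5L - rev(probe)  # complement of the probe, pool orientation
    found <- .scan_hamming(pool, target, dm)
    if (!found) {
      for (d in probes_del) {
        # deleting probe position d removes target position n - d + 1
        found <- .scan_hamming(pool, target[-(n - d + 1L)], dm)
        if (found) break
      }
    }
    hits[tr] <- found
  }
  p <- mean(hits)
  list(p_hat = p, se = sqrt(p * (1 - p) / trials), trials = trials)
}

# TRUE iff some window of `pool` matches `patt` with <= dm mismatches
.scan_hamming <- function(pool, patt, dm) {
  m <- length(patt)
  W <- length(pool) - m + 1L
  if (W < 1L) return(FALSE)
  mism <- integer(W)
  for (k in seq_len(m)) {
    mism <- mism + (pool[k:(k + W - 1L)] != patt[k])
    # early exit is not worth the bookkeeping at these sizes
  }
  any(mism <= dm)
}
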