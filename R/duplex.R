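#' Annotate an antiparallel duplex with declared defects
#'
#' Builds the pairing register between `strand_a` and the probe `strand_b`
#' implied by a declared list of defects, and validates it: mismatch positions
#' must align non-complementary bases, bulge positions are unpaired probe
#' bases (one per single-base deletion in `strand_a`) flanked by paired bases,
#' and every other aligned pair must be Watson-Crick. Defects are declared,
#' never inferred: no alignment search is performed.
#'
#' @param strand_a [hk_seq] (or string): the target/competitor strand.
#' @param strand_b [hk_seq] (or string): the probe; defect positions refer to
#'   this strand, 1-based, 5'->3'.
#' @param defects list of [defect()] objects (or `NULL` for a perfect duplex).
#' @return An object of class `hk_duplex` with the aligned index pairs
#'   (`pairs$a_pos`, `pairs$b_pos`, both 5'->3' on their own strand, the
#'   register strictly antiparallel), mismatch flags and bulge positions.
#' @examples
#' p <- hk_seq("CACGCATCACCA"); t <- hk_seq("TGGTGATGCGTG")
#' duplex(t, p)                              # perfect 12-bp duplex
#' c49 <- make_variant(t, p, list(defect("mismatch", 4), defect("mismatch", 9)))
#' duplex(c49, p, list(defect("mismatch", 4), defect("mismatch", 9)))
#' @export
duplex <- function(strand_a, strand_b, defects = NULL) {
  a <- hk_seq(strand_a); b <- hk_seq(strand_b)
  if (a$alphabet != b$alphabet) stop("strands must share an alphabet")
  defects <- .as_defect_list(defects)
  kinds <- vapply(defects, `[[`, "", "kind")
  pos <- vapply(defects, `[[`, 1L, "probe_position")
  if (anyDuplicated(pos)) stop("duplicate defect positions")
  if (any(pos > length(b))) stop("defect position beyond probe length")
  b_pos_bulge <- sort(pos[kinds == "bulge"])
  b_pos_mm <- sort(pos[kinds == "mismatch"])
  La <- length(a); Lb <- length(b)
  if (La != Lb - length(b_pos_bulge))
    stop(sprintf(
      "length difference (%d) inconsistent with declared bulge count (%d)",
      Lb - La, length(b_pos_bulge)))

  paired_b <- setdiff(seq_len(Lb), b_pos_bulge)
  n_bulge_before <- vapply(paired_b,
                           function(q) sum(b_pos_bulge < q), integer(1))
  a_pos <- La - (paired_b - 1L - n_bulge_before)
  pairs <- data.frame(a_pos = a_pos, b_pos = paired_b)

  if (length(b_pos_bulge)) {
    if (any(b_pos_bulge == 1L | b_pos_bulge == Lb) ||
        any(b_pos_bulge %in% c(b_pos_mm - 1L, b_pos_mm + 1L)) ||
        any(diff(b_pos_bulge) == 1L))
      stop("bulges must be flanked by paired bases")
  }

  ach <- .seq_chars(a); bch <- .seq_chars(b)
  comp <- .complement_base(ach[pairs$a_pos], a$alphabet) == bch[pairs$b_pos]
  mm_flag <- pairs$b_pos %in% b_pos_mm
  if (any(mm_flag & comp)) {
    q <- pairs$b_pos[mm_flag & comp][1]
    stop(sprintf("declared mismatch at probe position %d is complementary", q))
  }
  if (any(!mm_flag & !comp)) {
    q <- pairs$b_pos[!mm_flag & !comp][1]
    stop(sprintf("undeclared non-complementary pair at probe position %d", q))
  }
  pairs$mismatch <- mm_flag
  structure(list(a = a, b = b, pairs = pairs, bulge_b_pos = b_pos_bulge,
                 defects = defects),
            class = "hk_duplex")
}

#' @rdname duplex
#' @export
annotate_duplex <- duplex

#' @export
print.hk_duplex <- function(x, ...) {
  cat(sprintf("<hk_duplex> %s, %d aligned pairs (%d mismatch), %d bulge(s)\n",
              x$a$alphabet, nrow(x$pairs), sum(x$pairs$mismatch),
              length(x$bulge_b_pos)))
  cat(sprintf("  A: 5'-%s-3'%s\n  B: 5'-%s-3'%s\n", x$a$bases,
              if (is.null(x$a$name)) "" else paste0(" (", x$a$name, ")"),
              x$b$bases,
              if (is.null(x$b$name)) "" else paste0(" (", x$b$name, ")")))
  invisible(x)
}

#' Defect class of a duplex
#'
#' Classifies a duplex for the kinetic model: `perfect`, `single_mismatch`,
#' `double_mismatch` or `bulge`. Duplexes mixing bulges and mismatches take
#' the mismatch class (the reference designs contain no mixed variants).
#' @param dup an [duplex()] object.
#' @return character scalar.
#' @export
defect_class <- function(dup) {
  stopifnot(inherits(dup, "hk_duplex"))
  n_mm <- sum(dup$pairs$mismatch)
  if (n_mm >= 2L) "double_mismatch"
  else if (n_mm == 1L) "single_mismatch"
  else if (length(dup$bulge_b_pos)) "bulge"
  else "perfect"
}

#' Swap the strand roles of a duplex
#'
#' Returns the same physical duplex with `strand_a` and `strand_b` exchanged;
#' model predictions are invariant under this swap.
#' @param dup an [duplex()] object.
#' @return an `hk_duplex`.
#' @export
swap_strands <- function(dup) {
  stopifnot(inherits(dup, "hk_duplex"))
  La <- length(dup$a)
  # bulges on the b side stay unpaired bases of the new strand_b = old a? No:
  # the unpaired base lives on the old probe; after the swap it is a bulge of
  # the new strand_a, which the defect convention cannot name. Rebuild the
  # register directly instead of re-annotating.
  pairs <- data.frame(a_pos = dup$pairs$b_pos, b_pos = dup$pairs$a_pos,
                      mismatch = dup$pairs$mismatch)
  pairs <- pairs[order(pairs$b_pos), ]
  rownames(pairs) <- NULL
  structure(list(a = dup$b, b = dup$a, pairs = pairs,
                 bulge_b_pos = integer(), bulge_a_pos = dup$bulge_b_pos,
                 defects = dup$defects),
            class = "hk_duplex")
}
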