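#' Oligonucleotide sequence objects
#'
#' `hk_seq()` builds a validated single-stranded oligonucleotide from a 5'->3'
#' character string. The fluorescent adenine analogue 2-aminopurine (2Ap) pairs
#' like adenine; positions carrying it are recorded separately and may be
#' written in the input with a marker character (default `"2"`).
#'
#' @param bases character scalar, 5'->3', over A/C/G/T (DNA) or A/C/G/U (RNA).
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param ap2_marker single character in `bases` marking a 2Ap position
#'   (stored as A), or `NULL` to disable marker parsing.
#' @param ap2_positions integer vector of 1-based 2Ap positions (must sit at
#'   an A); merged with marker-derived positions.
#' @param name optional label.
#' @return An object of class `hk_seq` with fields `bases`, `alphabet`,
#'   `ap2_positions` and `name`.
#' @examples
#' hk_seq("TGGTGATGCGTG", "DNA")
#' hk_seq("TGGTG2TGCGTG", "DNA")   # 2Ap at position 6
#' @export
hk_seq <- function(bases, alphabet = c("DNA", "RNA"), ap2_marker = "2",
                   ap2_positions = integer(), name = NULL) {
  if (inherits(bases, "hk_seq")) return(bases)
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(gsub("[[:space:]]", "", bases))
  if (!nzchar(bases)) stop("empty sequence")
  chars <- strsplit(bases, "")[[1]]
  if (!is.null(ap2_marker)) {
    marked <- which(chars == ap2_marker)
    chars[marked] <- "A"
    ap2_positions <- sort(unique(c(as.integer(ap2_positions), marked)))
  } else {
    ap2_positions <- sort(unique(as.integer(ap2_positions)))
  }
  legal <- .alphabet_bases(alphabet)
  bad <- which(!chars %in% legal)
  if (length(bad)) {
    stop(sprintf("illegal %s base '%s' at position %d", alphabet,
                 chars[bad[1]], bad[1]))
  }
  if (length(ap2_positions)) {
    if (any(ap2_positions < 1L | ap2_positions > length(chars)))
      stop("ap2 position out of range")
    if (any(chars[ap2_positions] != "A"))
      stop("2Ap positions must sit at an A")
  }
  structure(list(bases = paste(chars, collapse = ""), alphabet = alphabet,
                 ap2_positions = ap2_positions, name = name),
            class = "hk_seq")
}

#' @rdname hk_seq
#' @param text character scalar to parse (alias of `bases`).
#' @export
parse_sequence <- function(text, alphabet = c("DNA", "RNA"), ap2_marker = "2",
                           name = NULL) {
  hk_seq(text, alphabet, ap2_marker = ap2_marker, name = name)
}

.alphabet_bases <- function(alphabet) {
  if (alphabet == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
}

.seq_chars <- function(x) strsplit(x$bases, "")[[1]]

#' @export
print.hk_seq <- function(x, ...) {
  lab <- if (is.null(x$name)) "" else paste0(" ", x$name)
  cat(sprintf("<hk_seq%s> %s 5'-%s-3' (%d nt)\n", lab, x$alphabet, x$bases,
              nchar(x$bases)))
  if (length(x$ap2_positions))
    cat("  2Ap at:", paste(x$ap2_positions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.hk_seq <- function(x) nchar(x$bases)

#' Watson-Crick complementarity of two bases
#'
#' @param a,b single bases (character), legal in `alphabet`.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param wobble if `TRUE`, the G-U wobble pair counts as complementary
#'   (RNA only; default off, so wobble pairs are treated as defects).
#' @return logical.
#' @export
is_complementary <- function(a, b, alphabet = c("DNA", "RNA"), wobble = FALSE) {
  alphabet <- match.arg(alphabet)
  legal <- .alphabet_bases(alphabet)
  if (!all(c(a, b) %in% legal)) stop("base not legal in alphabet")
  comp <- .complement_base(a, alphabet) == b
  if (wobble && alphabet == "RNA")
    comp <- comp | (a == "G" & b == "U") | (a == "U" & b == "G")
  comp
}

.complement_base <- function(x, alphabet) {
  map <- if (alphabet == "DNA") {
    c(A = "T", C = "G", G = "C", T = "A")
  } else {
    c(A = "U", C = "G", G = "C", U = "A")
  }
  unname(map[x])
}

#' Reverse complement of a sequence
#'
#' 2Ap positions are dropped (the complement carries no 2Ap).
#' @param x an [hk_seq] or character scalar.
#' @inheritParams hk_seq
#' @return an `hk_seq`.
#' @export
reverse_complement <- function(x, alphabet = c("DNA", "RNA")) {
  if (!inherits(x, "hk_seq")) x <- hk_seq(x, match.arg(alphabet))
  chars <- rev(.complement_base(.seq_chars(x), x$alphabet))
  hk_seq(paste(chars, collapse = ""), x$alphabet, ap2_marker = NULL,
         name = if (!is.null(x$name)) paste0(x$name, "_rc"))
}

#' Convert a DNA sequence and annotations to its RNA twin (T -> U)
#' @param x an [hk_seq].
#' @return an `hk_seq` with `alphabet = "RNA"`.
#' @export
as_rna <- function(x) {
  stopifnot(inherits(x, "hk_seq"))
  if (x$alphabet == "RNA") return(x)
  hk_seq(gsub("T", "U", x$bases), "RNA", ap2_marker = NULL,
         ap2_positions = x$ap2_positions, name = x$name)
}

#' Declare a duplex defect
#'
#' Defects are named by their position along the probe strand counted 1-based
#' in the 5'->3' direction, matching the m_i / b_i naming convention: `m_3` is
#' a mismatch opposite probe position 3, `b_4` a bulge (unpaired probe base)
#' at probe position 4 caused by a deletion in the partner strand.
#'
#' @param kind `"mismatch"` or `"bulge"`.
#' @param probe_position 1-based index on the probe, 5'->3'.
#' @param substituted_base optional replacement base for the partner strand
#'   (mismatch only).
#' @return an object of class `hk_defect`.
#' @export
defect <- function(kind = c("mismatch", "bulge"), probe_position,
                   substituted_base = NULL) {
  kind <- match.arg(kind)
  probe_position <- as.integer(probe_position)
  stopifnot(length(probe_position) == 1L, probe_position >= 1L)
  if (kind == "bulge" && !is.null(substituted_base))
    stop("a bulge is a deletion and carries no substituted base")
  structure(list(kind = kind, probe_position = probe_position,
                 substituted_base = substituted_base), class = "hk_defect")
}

.as_defect_list <- function(defects) {
  if (is.null(defects)) return(list())
  if (inherits(defects, "hk_defect")) return(list(defects))
  stopifnot(all(vapply(defects, inherits, TRUE, "hk_defect")))
  defects
}

#' Edit a target sequence to create a defect-bearing competitor
#'
#' Starting from a target fully complementary to the probe, introduces the
#' requested mismatches (base substitutions in the target) and bulges
#' (single-base deletions in the target) at the stated probe positions.
#' When a mismatch's substituted base is not given it is chosen greedily among
#' the three non-complementary candidates to minimize a self-complementarity
#' score (the count of antiparallel self-complementary trinucleotide pairings
#' within the edited sequence); ties are broken by a base order drawn from
#' `seed`, so the choice is deterministic for a given seed.
#'
#' @param target [hk_seq] fully complementary to `probe`.
#' @param probe [hk_seq].
#' @param defects list of [defect()] objects with distinct positions.
#' @param seed integer controlling tie-breaking for unspecified mismatch bases.
#' @return an `hk_seq` competitor named in the m_/b_ convention (e.g. "m_4,9").
#' @export
make_variant <- function(target, probe, defects, seed = 1L) {
  target <- hk_seq(target); probe <- hk_seq(probe)
  defects <- .as_defect_list(defects)
  L <- length(probe)
  if (length(target) != L ||
      reverse_complement(probe)$bases != target$bases)
    stop("target must be fully complementary to probe")
  if (!length(defects)) return(target)
  pos <- vapply(defects, `[[`, 1L, "probe_position")
  if (any(pos > L)) stop("defect position out of range")
  if (anyDuplicated(pos)) stop("duplicate defect positions")

  chars <- .seq_chars(target)
  alphabet <- target$alphabet
  base_order <- .alphabet_bases(alphabet)
  set.seed(seed %% .Machine$integer.max)
  base_order <- sample(base_order)

  mm_pos <- sort(pos[vapply(defects, `[[`, "", "kind") == "mismatch"])
  b_pos <- sort(pos[vapply(defects, `[[`, "", "kind") == "bulge"])

  for (d in defects) {
    if (d$kind != "mismatch") next
    ti <- L - d$probe_position + 1L       # target index opposite probe pos
    probe_base <- .seq_chars(probe)[d$probe_position]
    comp <- .complement_base(probe_base, alphabet)
    if (!is.null(d$substituted_base)) {
      sub <- toupper(d$substituted_base)
      if (sub == comp) stop("substituted base is complementary to the probe")
      chars[ti] <- sub
    } else {
      cand <- setdiff(base_order, comp)
      scores <- vapply(cand, function(b) {
        trial <- chars; trial[ti] <- b
        .self_comp_score(trial, alphabet)
      }, numeric(1))
      chars[ti] <- cand[which.min(scores)]
    }
  }
  # deletions applied 3'->5' so earlier target indices stay valid
  del_ti <- sort(L - b_pos + 1L, decreasing = TRUE)
  for (ti in del_ti) chars <- chars[-ti]

  nm <- c(if (length(mm_pos)) paste0("m_", paste(mm_pos, collapse = ",")),
          if (length(b_pos)) paste0("b_", paste(b_pos, collapse = ",")))
  ap2 <- target$ap2_positions
  if (length(ap2)) {
    # shift annotations across deletions; drop any that were deleted/mutated
    keep <- setdiff(seq_len(L), L - b_pos + 1L)
    ap2 <- match(ap2, keep)
    ap2 <- ap2[!is.na(ap2) & chars[ap2[!is.na(ap2)]] == "A"]
  }
  hk_seq(paste(chars, collapse = ""), alphabet, ap2_marker = NULL,
         ap2_positions = ap2, name = paste(nm, collapse = "+"))
}

# number of antiparallel self-complementary trinucleotide pairings
.self_comp_score <- function(chars, alphabet) {
  n <- length(chars)
  if (n < 3L) return(0)
  comp <- .complement_base(chars, alphabet)
  score <- 0L
  for (i in seq_len(n - 2L)) {
    for (j in seq_len(n - 2L)) {
      if (chars[i] == comp[j + 2L] && chars[i + 1L] == comp[j + 1L] &&
          chars[i + 2L] == comp[j]) score <- score + 1L
    }
  }
  score
}
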