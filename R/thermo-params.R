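#' Nearest-neighbor thermodynamic parameter sets
#'
#' Loads the versioned nearest-neighbor tables shipped with the package:
#' the unified DNA Watson-Crick stack set with its initiation terms, the DNA
#' internal- and terminal-mismatch doublet sets, the RNA Watson-Crick set
#' with duplex initiation and per-terminal-AU penalty, a context-independent
#' RNA internal-mismatch penalty table, and single-base bulge-loop increments.
#' All parameters refer to 1 M NaCl; no salt correction is applied by default
#' (a `salt_correction` hook exists but ships disabled, i.e. identity).
#'
#' The 2-aminopurine substitution is handled as a pure free-energy penalty at
#' 25 C (`+0.9` kcal/mol in DNA, `0` in RNA), implemented as an entropic term
#' so that the enthalpy is unchanged.
#'
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param ap2_ddg 2Ap destabilization at 25 C in kcal/mol (default 0.9 for
#'   DNA, 0 for RNA).
#' @param dg_lookup optional function `(bases_a, bases_b) -> kcal/mol` used by
#'   [nucleation_dg()] in place of the internal mini-duplex engine, so that
#'   externally computed nucleation free energies (e.g. from a
#'   partition-function tool) can be injected for bit-compatible reproduction.
#' @param salt_correction optional function applied to the `(dH, dS)` sums;
#'   `NULL` (default) leaves the native 1 M NaCl reference values untouched.
#' @return An object of class `hk_thermo_params`.
#' @export
thermo_params <- function(alphabet = c("DNA", "RNA"),
                          ap2_ddg = NULL, dg_lookup = NULL,
                          salt_correction = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(ap2_ddg)) ap2_ddg <- if (alphabet == "DNA") 0.9 else 0
  ext <- function(f) system.file("extdata", f, package = "hybrikin",
                                 mustWork = TRUE)
  if (alphabet == "DNA") {
    nn <- read.csv(ext("nn_dna_v1.csv"), stringsAsFactors = FALSE)
    imm <- read.csv(ext("nn_dna_mismatch_v1.csv"), stringsAsFactors = FALSE)
    tmm <- read.csv(ext("nn_dna_terminal_mismatch_v1.csv"),
                    stringsAsFactors = FALSE)
    mm_pair <- NULL
  } else {
    nn <- read.csv(ext("nn_rna_v1.csv"), stringsAsFactors = FALSE)
    imm <- NULL
    tmm <- NULL
    mm_pair <- read.csv(ext("nn_rna_mismatch_v1.csv"),
                        stringsAsFactors = FALSE)
  }
  tab <- function(df, norm = TRUE) {
    if (is.null(df)) return(NULL)
    m <- as.matrix(df[, c("dH", "dS")])
    # store all doublet contexts in the T spelling so DNA/RNA share lookups
    rownames(m) <- if (norm) gsub("U", "T", df[[1]]) else df[[1]]
    m
  }
  structure(list(alphabet = alphabet,
                 stacks = tab(nn[nn$kind == "stack", ]),
                 init = tab(nn[nn$kind %in% c("init", "init0", "sym"), ]),
                 bulge = tab(nn[nn$kind == "loop", ]),
                 imm = tab(imm), tmm = tab(tmm),
                 mm_pair = tab(mm_pair, norm = FALSE),
                 ap2_ddg = ap2_ddg, dg_lookup = dg_lookup,
                 salt_correction = salt_correction,
                 set_id = paste0("nn_", tolower(alphabet), "_v1")),
            class = "hk_thermo_params")
}

#' @export
print.hk_thermo_params <- function(x, ...) {
  cat(sprintf("<hk_thermo_params> set %s (1 M NaCl reference), 2Ap ddG = %+.1f kcal/mol\n",
              x$set_id, x$ap2_ddg))
  invisible(x)
}

# --- doublet lookups ------------------------------------------------------
# A doublet is 5'-X1X2-3' on the top strand paired with 3'-Y1Y2-5' on the
# bottom strand, written "X1X2/Y1Y2". The tables store one orientation; the
# other is obtained by reading the duplex from the opposite strand,
# "rev(Y)/rev(X)".

.flip_ctx <- function(top, bottom) {
  paste0(paste(rev(bottom), collapse = ""), "/",
         paste(rev(top), collapse = ""))
}

.lookup_ctx <- function(tabm, top, bottom) {
  key <- paste0(paste(top, collapse = ""), "/", paste(bottom, collapse = ""))
  if (key %in% rownames(tabm)) return(tabm[key, ])
  key2 <- .flip_ctx(top, bottom)
  if (key2 %in% rownames(tabm)) return(tabm[key2, ])
  NULL
}

.u2t <- function(x) ifelse(x == "U", "T", x)

# stack term for a fully Watson-Crick doublet
.stack_term <- function(params, top, bottom) {
  v <- .lookup_ctx(params$stacks, .u2t(top), .u2t(bottom))
  if (is.null(v)) stop(sprintf("no stack entry for context %s/%s",
                               paste(top, collapse = ""),
                               paste(bottom, collapse = "")))
  v
}

# mismatch-containing doublet; `terminal` marks a duplex-terminal mismatch
.mismatch_term <- function(params, top, bottom, n_mm, terminal = FALSE) {
  if (params$alphabet == "DNA") {
    tabm <- if (terminal && n_mm == 1L) params$tmm else params$imm
    v <- .lookup_ctx(tabm, top, bottom)
    if (is.null(v) && terminal) v <- .lookup_ctx(params$imm, top, bottom)
    if (is.null(v))
      stop(sprintf("no %s mismatch entry for context %s/%s%s",
                   params$alphabet, paste(top, collapse = ""),
                   paste(bottom, collapse = ""),
                   if (n_mm == 2L) " (tandem mismatch)" else ""))
    return(v)
  }
  # RNA: context-independent per-pair penalty, charged once per mismatched
  # pair (on its 5'-side doublet so it is counted exactly once).
  c(dH = 0, dS = 0)
}

.rna_pair_term <- function(params, a, b) {
  key <- paste(sort(c(a, b)), collapse = ".")
  if (!key %in% rownames(params$mm_pair))
    stop(sprintf("no RNA mismatch entry for pair %s", key))
  params$mm_pair[key, ]
}

.init_term <- function(params, top_base, bottom_base) {
  key <- if (.u2t(top_base) %in% c("A", "T") &&
             .u2t(bottom_base) %in% c("A", "T")) "init_A/T" else "init_G/C"
  params$init[key, ]
}
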