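#' Read and write oligonucleotide FASTA files
#'
#' FASTA I/O for [hk_seq] objects. 2Ap positions are preserved through the
#' marker character (default `"2"`), so a write/read round trip is the
#' identity on bases, names and 2Ap annotations.
#'
#' @param path file path.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param ap2_marker marker character for 2Ap positions, or `NULL`.
#' @return `read_fasta`: a list of `hk_seq`. `write_fasta`: `path`, invisibly.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA"), ap2_marker = "2") {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- tryCatch(
      hk_seq(as.character(set[[i]]), alphabet, ap2_marker = ap2_marker,
             name = names(set)[i]),
      error = function(e) stop(sprintf("record %d ('%s'): %s", i,
                                       names(set)[i], conditionMessage(e)),
                               call. = FALSE))
  }
  out
}

#' @rdname read_fasta
#' @param sequences a list of [hk_seq] (or a single one).
#' @export
write_fasta <- function(sequences, path, ap2_marker = "2") {
  if (inherits(sequences, "hk_seq")) sequences <- list(sequences)
  txt <- vapply(sequences, function(s) {
    chars <- .seq_chars(s)
    if (length(s$ap2_positions) && !is.null(ap2_marker))
      chars[s$ap2_positions] <- ap2_marker
    paste(chars, collapse = "")
  }, character(1))
  nms <- vapply(seq_along(sequences), function(i) {
    nm <- sequences[[i]]$name
    if (is.null(nm)) sprintf("seq%d", i) else nm
  }, character(1))
  set <- Biostrings::BStringSet(setNames(txt, nms))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
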