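# 21-letter alphabet: the 20 amino acids plus the gap symbol.  'X' (and any
# other nonstandard letter) is spread uniformly over the 20 amino acids when
# counting, so no 22nd symbol is ever needed.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP <- "-"
ALPHABET <- c(AA, GAP)
N_ALPHA <- length(ALPHABET) # 21

#' @keywords internal
#' @noRd
letter_index <- function(ch) match(ch, ALPHABET)

# Encode one sequence as an nchar x 21 row-stochastic matrix: point mass for
# standard letters and gap, uniform 1/20 over amino acids for anything else.
#' @keywords internal
#' @noRd
encode_sequence <- function(seq_chars) {
  n <- length(seq_chars)
  enc <- matrix(0, n, N_ALPHA, dimnames = list(NULL, ALPHABET))
  idx <- letter_index(seq_chars)
  known <- !is.na(idx)
  enc[cbind(which(known), idx[known])] <- 1
  if (any(!known)) enc[!known, seq_len(20)] <- 1 / 20
  enc
}

# nseq x (21 * ncol) stacked one-hot encoding of a whole MSA; column blocks
# of 21 correspond to MSA columns.
#' @keywords internal
#' @noRd
encode_msa <- function(msa) {
  mats <- lapply(msa$sequences, function(s) {
    t(encode_sequence(strsplit(s, "", fixed = TRUE)[[1]]))
  })
  out <- matrix(0, msa$nseq, N_ALPHA * msa$ncol)
  for (s in seq_len(msa$nseq)) out[s, ] <- as.vector(mats[[s]])
  out
}
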