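#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or A3M file into an `msa` object.  In the A3M
#' dialect, lowercase letters mark insert columns relative to the query; those
#' characters are removed so that all retained sequences have equal length.
#' `.` characters (A3M insert gaps) are removed as well.
#'
#' @param path Path to the alignment file.
#' @param format Either `"fasta"` (aligned FASTA) or `"a3m"`.
#' @return An object of class `msa`: a list with `sequences` (uppercase,
#'   equal-length strings over the 20 amino acids, `-` and `X`), `ids`,
#'   `ncol` and `nseq`.  Input order is preserved; by convention the first
#'   sequence is the query.
#' @export
read_msa <- function(path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (format == "a3m") {
    seqs <- vapply(seqs, function(s) gsub("[a-z.]", "", s), character(1),
                   USE.NAMES = FALSE)
  }
  seqs <- toupper(seqs)
  new_msa(seqs, ids)
}

#' Construct an MSA object from character sequences
#'
#' @param sequences Character vector of equal-length aligned sequences.
#' @param ids Optional sequence identifiers (default `seq1`, `seq2`, ...).
#' @return An `msa` object.
#' @export
new_msa <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) stop("empty alignment: no sequences")
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty-input error: sequence of length 0")
  if (length(unique(lens)) != 1L)
    stop("format error: sequences have unequal lengths after processing (",
         paste(unique(lens), collapse = ", "), ")")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  structure(list(sequences = unname(sequences), ids = ids,
                 ncol = lens[[1L]], nseq = length(sequences)),
            class = "msa")
}

#' Write an MSA as aligned FASTA
#'
#' @param msa An `msa` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  set <- Biostrings::BStringSet(setNames(msa$sequences, msa$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", x$nseq, "sequences x", x$ncol, "columns\n")
  invisible(x)
}

#' Henikoff position-based sequence weights
#'
#' Each column contributes 1/(r * s) to a sequence's weight, where r is the
#' number of distinct symbols in the column and s the count of the sequence's
#' own symbol.  Weights are normalised to sum to the number of sequences, so
#' that pseudocount weights stay on the raw-count scale.
#'
#' @param msa An `msa` object.
#' @return Numeric vector of length `nseq` summing to `nseq`.
#' @export
henikoff_weights <- function(msa) {
  chars <- do.call(rbind, strsplit(msa$sequences, "", fixed = TRUE))
  w <- numeric(msa$nseq)
  for (j in seq_len(msa$ncol)) {
    col <- chars[, j]
    tab <- table(col)
    r <- length(tab)
    w <- w + 1 / (r * as.numeric(tab[col]))
  }
  w * msa$nseq / sum(w)
}

#' Column marginal distributions with pseudocounts
#'
#' Computes, for every MSA column, the probability of the 20 amino acids and
#' the gap symbol: `(weighted count + pc * background) / (weighted nseq + pc)`
#' with a uniform background of 1/21.  Nonstandard residues (`X`) are spread
#' uniformly over the 20 amino acids.
#'
#' @param msa An `msa` object.
#' @param pseudocount_weight Nonnegative pseudocount weight (default 1).
#' @param seq_weighting `"henikoff"` (default) or `"none"`.
#' @return An object of class `column_marginals`: list with `probs` (an
#'   `ncol` x 21 matrix whose rows sum to 1), `neff` (effective sequence
#'   count, from the inverse participation ratio of the weights) and the
#'   weights used.
#' @export
column_marginals <- function(msa, pseudocount_weight = 1,
                             seq_weighting = c("henikoff", "none")) {
  seq_weighting <- match.arg(seq_weighting)
  if (!is.numeric(pseudocount_weight) || pseudocount_weight < 0)
    stop("parameter error: pseudocount_weight must be >= 0")
  w <- if (seq_weighting == "henikoff") henikoff_weights(msa) else
    rep(1, msa$nseq)
  enc <- encode_msa(msa)
  counts <- crossprod(enc, w)   # (21 * ncol) x 1
  counts <- matrix(counts, msa$ncol, N_ALPHA, byrow = TRUE,
                   dimnames = list(NULL, ALPHABET))
  W <- sum(w)
  probs <- (counts + pseudocount_weight / N_ALPHA) / (W + pseudocount_weight)
  probs <- probs / rowSums(probs)
  neff <- sum(w)^2 / sum(w^2)
  structure(list(probs = probs, neff = neff, weights = w,
                 pseudocount_weight = pseudocount_weight),
            class = "column_marginals")
}

#' Write column marginals as TSV
#'
#' @param marg A `column_marginals` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(marg, path) {
  df <- data.frame(column = seq_len(nrow(marg$probs)), marg$probs,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
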