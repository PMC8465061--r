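# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
random_dna <- function(n, len, prob = rep(0.25, 4)) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE, prob = prob),
              nrow = n, ncol = len)
  collapse_rows(m)
}

#' @noRd
collapse_rows <- function(m) {
  # paste rows of a character matrix into strings without a per-row loop
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Character vector of equal-length DNA strings -> integer matrix (A=1..T=4).
#' Non-ACGT characters become NA.
#' @noRd
dna_index_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(integer(0), 0, 0))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length")
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES),
              nrow = length(seqs), ncol = lens[1L], byrow = TRUE)
  m
}

#' Reverse complement of an index matrix (rows = sequences).
#' @noRd
revcomp_index <- function(idx) {
  (5L - idx)[, rev(seq_len(ncol(idx))), drop = FALSE]
}

#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Sum PWM-style per-position scores for windows starting at `offset`.
#' idx: n x L integer matrix; sc: 4 x W matrix. Returns length-n vector.
#' @noRd
window_score_at <- function(idx, sc, offset) {
  w <- ncol(sc)
  s <- numeric(nrow(idx))
  for (j in seq_len(w)) {
    s <- s + sc[cbind(idx[, offset + j - 1L], j)]
  }
  s
}

#' Best score over all offsets and both strands for each row of idx.
#' @noRd
best_window_score <- function(idx, sc) {
  w <- ncol(sc)
  stopifnot(ncol(idx) >= w)
  idxrc <- revcomp_index(idx)
  best <- rep(-Inf, nrow(idx))
  for (o in seq_len(ncol(idx) - w + 1L)) {
    best <- pmax(best, window_score_at(idx, sc, o),
                 window_score_at(idxrc, sc, o))
  }
  best
}

#' @noRd
is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
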