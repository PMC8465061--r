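# PWMotif: position-dependent letter-probability matrix with background.

#' Construct a PWMotif
#'
#' A `pwmotif` is the package's motif container: a position-dependent
#' letter-probability matrix (4 rows, one per base A/C/G/T; one column per
#' motif position), the number of sites that contributed to it, and the
#' background base composition it was estimated against. Every column must
#' sum to 1.
#'
#' @param matrix numeric matrix, 4 x width, rows in A,C,G,T order (rownames
#'   are set if missing). Columns must each sum to 1 (tolerance `1e-9`) and
#'   all entries must be non-negative.
#' @param nsites number of contributing sites (default `NA`).
#' @param background length-4 base probabilities (default uniform).
#' @param score_significance optional log-likelihood-ratio statistic attached
#'   by [discover_motif()]. This is a relative measure for comparing runs on
#'   the same input; it is not calibrated like a MEME E-value.
#' @return An object of class `pwmotif`.
#' @examples
#' m <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
#' pwmotif(m)
#' @export
pwmotif <- function(matrix, nsites = NA_real_,
                    background = rep(0.25, 4),
                    score_significance = NA_real_) {
  if (!is.matrix(matrix) || nrow(matrix) != 4L)
    stop("'matrix' must be a 4-row numeric matrix (rows A, C, G, T)")
  if (is.null(rownames(matrix))) rownames(matrix) <- DNA_BASES
  if (!identical(rownames(matrix), DNA_BASES))
    matrix <- matrix[DNA_BASES, , drop = FALSE]
  if (any(matrix < 0)) stop("letter probabilities must be non-negative")
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9))
    stop("every matrix column must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("'background' must be 4 non-negative probabilities summing to 1")
  names(background) <- DNA_BASES
  structure(
    list(matrix = matrix, nsites = nsites, background = background,
         score_significance = score_significance),
    class = "pwmotif"
  )
}

#' @export
print.pwmotif <- function(x, ...) {
  cat("pwmotif: width", pwm_width(x), "| nsites",
      format(x$nsites), "| IC", round(sum(information_content(x)), 2),
      "bits\n")
  cat("consensus:", consensus_from_pwm(x)$iupac, "\n")
  invisible(x)
}

#' Motif width (number of columns)
#' @param pwm a [pwmotif()].
#' @return integer width.
#' @export
pwm_width <- function(pwm) ncol(pwm$matrix)

#' Reverse complement of a letter-probability matrix
#'
#' Rows are complemented (A<->T, C<->G) and columns reversed.
#'
#' @param m 4 x width matrix in A,C,G,T row order.
#' @return matrix of the same shape.
#' @export
revcomp_matrix <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Reverse complement of a pwmotif
#' @param pwm a [pwmotif()].
#' @return a [pwmotif()] for the opposite strand.
#' @export
revcomp_pwm <- function(pwm) {
  pwmotif(revcomp_matrix(pwm$matrix), nsites = pwm$nsites,
          background = pwm$background,
          score_significance = pwm$score_significance)
}

# IUPAC degenerate code -> allowed base set (subset of ACGT).
iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
}

#' Build a pwmotif from an IUPAC consensus string
#'
#' Each column distributes `1 - mismatch_prob` equally over the bases allowed
#' by the IUPAC code and `mismatch_prob` equally over the disallowed bases
#' (columns allowing all four bases are uniform). Used to define "true"
#' planted motifs for simulations and as a convenient PWM constructor in
#' tests.
#'
#' @param iupac consensus string over IUPAC nucleotide codes.
#' @param mismatch_prob total probability assigned to disallowed bases per
#'   column (default 0.02).
#' @return a [pwmotif()].
#' @examples
#' pwm_from_consensus("AWTGTRANNNNNNTYACAWT")
#' @export
pwm_from_consensus <- function(iupac, mismatch_prob = 0.02) {
  stopifnot(is.character(iupac), length(iupac) == 1L, nchar(iupac) >= 1L)
  if (!is_probability(mismatch_prob) || mismatch_prob >= 1)
    stop("'mismatch_prob' must be in [0, 1)")
  sets <- iupac_sets()
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(sets))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  m <- vapply(chars, function(ch) {
    allowed <- DNA_BASES %in% sets[[ch]]
    k <- sum(allowed)
    p <- numeric(4)
    if (k == 4L) {
      p[] <- 0.25
    } else {
      p[allowed] <- (1 - mismatch_prob) / k
      p[!allowed] <- mismatch_prob / (4 - k)
    }
    p
  }, numeric(4))
  dimnames(m) <- list(DNA_BASES, NULL)
  pwmotif(m)
}
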