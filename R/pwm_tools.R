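# PWM tools: palindromic extension of a matrix block, IUPAC matching with
# spacer variants, and MEME minimal motif format I/O.

#' Palindromically extend a letter-probability matrix block
#'
#' Takes columns `block_start..block_end` (1-based, inclusive; `L` columns)
#' of a motif and returns the width-`2L` matrix `B ++ revcomp(B)`: the block
#' followed by its own reverse complement. The result is exactly
#' self-reverse-complementary, i.e. `M[i][b] = M[2L+1-i][comp(b)]`, the
#' matrix expected for a site bound by a homodimer. This mirrors the
#' construction of an extended dyad matrix from one well-determined half of
#' an asymmetric discovered motif (e.g. an 11-column block extended to 22
#' columns).
#'
#' With `overlap > 0` the mirrored copy is slid back over the block by that
#' many columns and the overlapping columns are averaged with their mirror
#' images (output width `2L - overlap`). This overlay-averaging alternative
#' is provided for completeness; the default (`overlap = 0`, pure
#' concatenation-with-mirror) is the construction consistent with doubling an
#' 11-column block into 22 columns.
#'
#' @param pwm a [pwmotif()].
#' @param block_start,block_end 1-based inclusive column bounds of the block.
#' @param overlap columns shared between the block and its mirrored copy
#'   (default 0).
#' @return a [pwmotif()] of width `2 * (block_end - block_start + 1) -
#'   overlap`.
#' @examples
#' ext <- extend_palindromic(pwm_from_consensus("AWTGTRACACACA"), 1, 10)
#' @export
extend_palindromic <- function(pwm, block_start, block_end, overlap = 0L) {
  stopifnot(inherits(pwm, "pwmotif"))
  w <- pwm_width(pwm)
  if (!(block_start >= 1 && block_start <= block_end && block_end <= w))
    stop("invalid block bounds: need 1 <= block_start <= block_end <= ",
         w)
  B <- pwm$matrix[, block_start:block_end, drop = FALSE]
  L <- ncol(B)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap > L) stop("'overlap' must be in [0, block width]")
  mir <- revcomp_matrix(B)
  if (overlap == 0L) {
    out <- cbind(B, mir)
  } else {
    out <- cbind(B[, seq_len(L - overlap), drop = FALSE],
                 (B[, (L - overlap + 1L):L, drop = FALSE] +
                    mir[, seq_len(overlap), drop = FALSE]) / 2,
                 mir[, (overlap + 1L):L, drop = FALSE])
    # re-symmetrize exactly (averaging the overlap can leave tiny asymmetry)
    out <- (out + revcomp_matrix(out)) / 2
  }
  colnames(out) <- NULL
  pwmotif(out, nsites = pwm$nsites, background = pwm$background)
}

#' Count mismatches of a sequence against an IUPAC pattern
#'
#' The number of positions where the sequence base is not in the allowed set
#' of the pattern's IUPAC code (`N` allows everything). Vectorized over
#' `seq`.
#'
#' @param seq DNA string(s), each the same length as `pattern`.
#' @param pattern IUPAC pattern string.
#' @return integer vector of mismatch counts.
#' @examples
#' iupac_mismatches("ATTGTGACACACATCACAAT", "AWTGTRANNNNNNTYACAWT")  # 0
#' @export
iupac_mismatches <- function(seq, pattern) {
  stopifnot(is.character(seq), is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  pchars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sets <- iupac_sets()
  bad <- setdiff(pchars, names(sets))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  if (any(nchar(seq) != nchar(pattern)))
    stop("sequence and pattern lengths differ")
  vapply(strsplit(toupper(seq), "", fixed = TRUE), function(s) {
    bad_base <- !s %in% DNA_BASES
    if (any(bad_base)) stop("invalid base(s): ",
                            paste(unique(s[bad_base]), collapse = ", "))
    sum(!mapply(function(b, code) b %in% sets[[code]], s, pchars))
  }, integer(1))
}

#' Change the spacer length of a dyad consensus
#'
#' Returns the same half sites with the all-N spacer lengthened (`delta > 0`)
#' or shortened (`delta < 0`) by `|delta|` N's — e.g. the single-deletion
#' (5-bp spacer) and single-insertion (7-bp spacer) variants of a 6-bp-spacer
#' consensus used to probe spacing tolerance.
#'
#' @param pattern a [consensus_pattern()] with a dyad decomposition.
#' @param delta signed change in spacer length; the resulting spacer must be
#'   `>= 0`.
#' @return a [consensus_pattern()].
#' @examples
#' wt <- consensus_pattern("AWTGTRANNNNNNTYACAWT", 7, 6)
#' spacer_variants(wt, -1)  # 19-nt, 5-bp spacer
#' @export
spacer_variants <- function(pattern, delta) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  if (is.na(pattern$spacer_length))
    stop("pattern has no dyad decomposition")
  delta <- as.integer(delta)
  new_spacer <- pattern$spacer_length + delta
  if (new_spacer < 0L) stop("resulting spacer length would be negative")
  h <- pattern$half_site_length
  left <- substr(pattern$iupac, 1L, h)
  right <- substr(pattern$iupac, nchar(pattern$iupac) - h + 1L,
                  nchar(pattern$iupac))
  consensus_pattern(paste0(left, strrep("N", new_spacer), right),
                    half_site_length = h, spacer_length = new_spacer)
}

#' Write a motif in MEME minimal motif format
#'
#' Emits the version line, alphabet, strand information, background letter
#' frequencies and one letter-probability matrix block (`alength= 4 w= W
#' nsites= N`), the plain-text exchange format used by motif scanning tools.
#'
#' @param pwm a [pwmotif()].
#' @param path output file path.
#' @param name motif identifier written after `MOTIF`.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(pwm, path, name = "motif_1") {
  stopifnot(inherits(pwm, "pwmotif"))
  con <- file(path, "w")
  on.exit(close(con))
  nsites <- if (is.na(pwm$nsites)) 20L else as.integer(round(pwm$nsites))
  writeLines(c(
    "MEME version 5", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES, pwm$background), collapse = " "), "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
            pwm_width(pwm), nsites),
    apply(pwm$matrix, 2L, function(p) paste(sprintf("%.8f", p),
                                            collapse = " "))
  ), con)
  invisible(path)
}

#' Read a motif from MEME minimal motif format
#'
#' Parses the first motif block of a MEME minimal file. Malformed files
#' produce an error naming the missing section or the offending line number.
#' `read_meme_minimal(write_meme_minimal(x))` reproduces `x` to within
#' 1e-6 per matrix cell.
#'
#' @param path file path.
#' @return a [pwmotif()] (the parsed motif name is attached as attribute
#'   `"name"`).
#' @export
read_meme_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  if (!any(grepl("^MEME version", trimmed)))
    stop("malformed MEME minimal file: missing 'MEME version' line")
  alpha_i <- grep("^ALPHABET=", trimmed)
  if (!length(alpha_i))
    stop("malformed MEME minimal file: missing 'ALPHABET=' line")
  alphabet <- gsub("\\s", "", sub("^ALPHABET=", "", trimmed[alpha_i[1L]]))
  if (alphabet != "ACGT")
    stop("unsupported alphabet at line ", alpha_i[1L], ": ", alphabet)
  if (!any(grepl("^strands:", trimmed)))
    stop("malformed MEME minimal file: missing 'strands:' line")

  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", trimmed)
  if (length(bg_i)) {
    toks <- strsplit(trimmed[bg_i[1L] + 1L], "\\s+")[[1L]]
    if (length(toks) != 8L)
      stop("malformed background frequencies at line ", bg_i[1L] + 1L)
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
    names(bg) <- toks[c(1, 3, 5, 7)]
    bg <- bg[DNA_BASES]
    bg <- bg / sum(bg)
  }

  mat_i <- grep("^letter-probability matrix:", trimmed)
  if (!length(mat_i))
    stop("malformed MEME minimal file: missing 'letter-probability matrix:' ",
         "section")
  mat_i <- mat_i[1L]
  header <- trimmed[mat_i]
  getfield <- function(key) {
    m <- regmatches(header, regexec(paste0(key, "=\\s*(\\S+)"), header))[[1L]]
    if (length(m) < 2L) return(NA)
    suppressWarnings(as.numeric(m[2L]))
  }
  w <- getfield("w")
  nsites <- getfield("nsites")
  if (is.na(w)) stop("matrix header missing 'w=' at line ", mat_i)
  rows <- matrix(NA_real_, 4L, w)
  for (k in seq_len(w)) {
    line_no <- mat_i + k
    if (line_no > length(trimmed))
      stop("matrix truncated: expected ", w, " rows, file ends at line ",
           length(trimmed))
    toks <- suppressWarnings(as.numeric(strsplit(trimmed[line_no],
                                                 "\\s+")[[1L]]))
    if (length(toks) != 4L || anyNA(toks))
      stop("malformed matrix row at line ", line_no)
    rows[, k] <- toks
  }
  rows <- sweep(rows, 2L, colSums(rows), "/")  # absorb rounding to 1e-6
  rownames(rows) <- DNA_BASES
  name_i <- grep("^MOTIF\\b", trimmed)
  out <- pwmotif(rows, nsites = if (is.na(nsites)) NA_real_ else nsites,
                 background = bg)
  attr(out, "name") <- if (length(name_i))
    sub("^MOTIF\\s+", "", trimmed[name_i[1L]]) else "motif_1"
  out
}
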