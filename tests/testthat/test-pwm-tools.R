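test_that("palindromic extension mirrors the block", {
  # single column A:1 -> [(A:1), (T:1)]
  m <- matrix(c(1, 0, 0, 0), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  ext <- extend_palindromic(pwmotif(m), 1, 1)
  expect_equal(pwm_width(ext), 2)
  expect_equal(ext$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(ext$matrix[, 2], c(A = 0, C = 0, G = 0, T = 1))
})

test_that("an 11-column block of a width-19 motif extends to a width-22 palindrome", {
  set.seed(51)
  m <- matrix(runif(4 * 19), 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  pwm <- pwmotif(m)
  ext <- extend_palindromic(pwm, 6, 16)
  expect_equal(pwm_width(ext), 22)
  # left half is the block verbatim; whole is exactly self-reverse-complementary
  expect_identical(unname(ext$matrix[, 1:11]), unname(m[, 6:16]))
  expect_identical(ext$matrix, revcomp_matrix(ext$matrix))
  # fixed point: extending the output's own left half reproduces it
  again <- extend_palindromic(ext, 1, 11)
  expect_identical(again$matrix, ext$matrix)
  expect_error(extend_palindromic(pwm, 10, 25), "block bounds")
})

test_that("IUPAC mismatch counts reproduce the probe-series design", {
  expect_equal(iupac_mismatches(PROBE_SEQUENCES["wt"], CONSENSUS), 0,
               ignore_attr = TRUE)
  for (p in paste0("wt_p", 1:7)) {
    expect_equal(iupac_mismatches(PROBE_SEQUENCES[p], CONSENSUS), 1,
                 ignore_attr = TRUE)
  }
  # the spacer variants change length, not half-site content
  expect_equal(nchar(PROBE_SEQUENCES["wt_s5"]), 19, ignore_attr = TRUE)
  expect_equal(nchar(PROBE_SEQUENCES["wt_s7"]), 21, ignore_attr = TRUE)
  expect_equal(
    iupac_mismatches(PROBE_SEQUENCES["wt_s5"],
                     spacer_variants(consensus_pattern(CONSENSUS, 7, 6),
                                     -1)$iupac), 0, ignore_attr = TRUE)
  expect_equal(
    iupac_mismatches(PROBE_SEQUENCES["wt_s7"],
                     spacer_variants(consensus_pattern(CONSENSUS, 7, 6),
                                     +1)$iupac), 0, ignore_attr = TRUE)
})

test_that("IUPAC matching handles N, errors, and dyad strand symmetry", {
  expect_equal(iupac_mismatches("GGGG", "NNNN"), 0)
  expect_error(iupac_mismatches("ACG", "NNNN"), "lengths differ")
  expect_error(iupac_mismatches("ACGT", "ACXZ"), "invalid IUPAC")
  # for a dyad-symmetric pattern, mismatches are strand-invariant
  seqs <- random_cores(20, len = 20, seed = 52)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  expect_equal(iupac_mismatches(seqs, CONSENSUS),
               iupac_mismatches(rc, CONSENSUS))
})

test_that("spacer variants adjust only the N run", {
  wt <- consensus_pattern(CONSENSUS, 7, 6)
  expect_identical(spacer_variants(wt, 0)$iupac, CONSENSUS)
  s5 <- spacer_variants(wt, -1)
  expect_identical(s5$iupac, "AWTGTRANNNNNTYACAWT")
  expect_equal(nchar(s5$iupac), 19)
  expect_equal(nchar(spacer_variants(wt, +1)$iupac), 21)
  expect_error(spacer_variants(wt, -7), "negative")
})

test_that("MEME minimal format round-trips and reports malformed files", {
  pwm <- pwm_from_consensus("AWTGTRACAC", mismatch_prob = 0.05)
  pwm$nsites <- 789
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme_minimal(pwm, f, name = "m1")
  back <- read_meme_minimal(f)
  expect_equal(back$matrix, pwm$matrix, tolerance = 1e-6)
  expect_equal(back$nsites, 789)
  expect_identical(attr(back, "name"), "m1")

  lines <- readLines(f)
  f2 <- withr::local_tempfile(fileext = ".meme")
  writeLines(lines[!grepl("^ALPHABET", lines)], f2)
  expect_error(read_meme_minimal(f2), "ALPHABET")

  f3 <- withr::local_tempfile(fileext = ".meme")
  bad <- lines
  bad[grep("^0|^1", bad)[1]] <- "0.2 0.2"
  writeLines(bad, f3)
  expect_error(read_meme_minimal(f3), "line")
})

test_that("a hand-written width-2 file parses to the uniform matrix", {
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 5", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "MOTIF uniform",
               "letter-probability matrix: alength= 4 w= 2 nsites= 10",
               "0.25 0.25 0.25 0.25", "0.25 0.25 0.25 0.25"), f)
  pwm <- read_meme_minimal(f)
  expect_equal(unname(pwm$matrix), matrix(0.25, 4, 2))
  expect_equal(pwm$background, c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
})
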