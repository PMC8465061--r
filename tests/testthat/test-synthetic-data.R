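test_that("generate_library draws uniform cores of the stated shape, reproducibly", {
  lib <- generate_library(4, core_length = 24, seed = 1)
  expect_s3_class(lib, "selection_library")
  expect_equal(library_size(lib), 4)
  expect_true(all(nchar(lib$cores) == 24))
  expect_equal(lib$round_index, 0L)

  expect_identical(generate_library(50, seed = 7),
                   generate_library(50, seed = 7))

  # per-position base frequencies ~ 0.25 (binomial CI: +/-0.01 is ~7 sd)
  big <- generate_library(1e5, core_length = 24, seed = 7)
  ch <- matrix(unlist(strsplit(big$cores, "", fixed = TRUE)),
               ncol = 24, byrow = TRUE)
  for (b in c("A", "C", "G", "T")) {
    freq <- colMeans(ch == b)
    expect_true(all(abs(freq - 0.25) < 0.01))
  }

  expect_error(generate_library(0), ">= 1")
  expect_error(generate_library(10, core_length = 0), ">= 1")
})

test_that("affinity model maps score deficit to KD monotonically", {
  aff <- affinity_model(pwm_from_consensus(CONSENSUS), kd_min = 3, beta = 1)
  cores <- c(paste0("AC", "ATTGTGACACACATCACAAT", "GT"),   # 0 mismatches
             paste0("AC", "CTTGTGACACACATCACAAT", "GT"),   # 1 mismatch
             paste0("AC", "CTGGTGACACACATCACAAT", "GT"))   # 2 mismatches
  ak <- affinity_kd(aff, cores)
  expect_true(all(diff(ak$score) < 0))
  expect_true(all(diff(ak$kd) > 0))
  # a perfect-consensus core sits at the kd_min floor
  expect_equal(ak$kd[1], 3, tolerance = 1e-6)
  expect_error(affinity_model(pwm_from_consensus("ACGT"), kd_min = 0,
                              beta = 1), "> 0")
})

test_that("a selection round with full cleavage and no protein kills the library", {
  lib <- generate_library(200, seed = 3)
  aff <- affinity_model(pwm_from_consensus(CONSENSUS), 3, 1)
  cfg <- repsa_config(protein_conc = 0, cleavage_efficiency = 1,
                      rounds = 1, pcr_resampling_depth = 200, seed = 3)
  out <- simulate_repsa_round(lib, aff, cfg)
  expect_equal(library_size(out), 0)
  expect_equal(out$round_index, 1L)
})

test_that("without cleavage a round is a pure resample of the input", {
  lib <- generate_library(500, seed = 4)
  aff <- affinity_model(pwm_from_consensus(CONSENSUS), 3, 1)
  cfg <- repsa_config(protein_conc = 34, cleavage_efficiency = 0,
                      rounds = 1, pcr_resampling_depth = 500, seed = 4)
  out <- simulate_repsa_round(lib, aff, cfg)
  expect_equal(library_size(out), 500)
  expect_true(all(out$cores %in% lib$cores))
  st <- attr(out, "repsa_stats")
  # no selection pressure: survival is certain, scores essentially unchanged
  expect_equal(st$n_survivors, 500)
  expect_equal(st$mean_score_out, st$mean_score_in, tolerance = 0.05)
})

test_that("survivors before resampling never exceed the input count", {
  lib <- generate_library(300, seed = 5)
  aff <- affinity_model(pwm_from_consensus(CONSENSUS), 3, 1)
  for (seed in 1:5) {
    cfg <- repsa_config(rounds = 1, pcr_resampling_depth = 300, seed = seed)
    st <- attr(simulate_repsa_round(lib, aff, cfg), "repsa_stats")
    expect_lte(st$n_survivors, st$n_input)
  }
})

test_that("selection enriches planted sites: mean score and match fraction rise", {
  set.seed(10)
  cores <- plant_consensus_sites(random_cores(5000, seed = 10), CONSENSUS,
                                 prevalence = 0.01, seed = 11)
  lib <- selection_library(cores)
  aff <- affinity_model(pwm_from_consensus(CONSENSUS), kd_min = 3, beta = 1)
  cfg <- repsa_config(protein_conc = 34, cleavage_efficiency = 0.9,
                      rounds = 4, pcr_resampling_depth = 5000, seed = 12)
  run <- run_repsa(lib, aff, cfg)
  expect_true(all(diff(run$stats$mean_score_out) > -1e-9))
  frac <- vapply(run$libraries, consensus_match_fraction, numeric(1),
                 iupac = CONSENSUS)
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[length(frac)], 0.5)
})

test_that("selection rounds are bit-reproducible under identical seeds", {
  lib <- generate_library(400, seed = 6)
  aff <- affinity_model(pwm_from_consensus(CONSENSUS), 3, 1)
  cfg <- repsa_config(rounds = 2, pcr_resampling_depth = 400, seed = 99)
  expect_identical(run_repsa(lib, aff, cfg)$libraries,
                   run_repsa(lib, aff, cfg)$libraries)
})

test_that("noise-free reads reconstruct their templates exactly", {
  lib <- generate_library(100, seed = 1)
  tpl <- selection_template()
  reads <- reads_from_library(lib, error_rate = 0,
                              flank_corruption_rate = 0, seed = 1)
  expect_identical(unname(as.character(reads)),
                   paste0(tpl$left_flank, expand_cores(lib),
                          tpl$right_flank))
  expect_true(all(Biostrings::width(reads) == 73))
})

test_that("substitution errors appear at the configured rate", {
  lib <- generate_library(1e4, seed = 2)
  tpl <- selection_template()
  truth <- paste0(tpl$left_flank, expand_cores(lib), tpl$right_flank)
  reads <- as.character(reads_from_library(lib, error_rate = 0.01, seed = 2))
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, truth, reads)
  expect_lt(abs(sum(mm) / (length(truth) * 73) - 0.01), 0.002)
})

test_that("FASTQ output round-trips through the package reader", {
  lib <- generate_library(25, seed = 3)
  reads <- reads_from_library(lib, error_rate = 0.01,
                              flank_corruption_rate = 0.1, seed = 3)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_identical(as.character(back), as.character(reads))
  expect_identical(as.character(Biostrings::quality(back)),
                   as.character(Biostrings::quality(reads)))
})

test_that("generate_genome honors GC content and planted sites", {
  g <- generate_genome(1e5, gc = 0.5, seed = 8)
  comp <- Biostrings::alphabetFrequency(g$genome[[1]], as.prob = TRUE)
  expect_true(sum(comp[c("C", "G")]) > 0.49 && sum(comp[c("C", "G")]) < 0.51)

  site <- "ATTGTGACACACATCACAAT"
  g2 <- generate_genome(2e4, seed = 9, planted_sites = data.frame(
    sequence = c(site, site), position = c(5000, 9000),
    strand = c("+", "-")))
  s <- as.character(g2$genome[[1]])
  expect_identical(substr(s, 5000, 5019), site)
  expect_identical(substr(s, 9000, 9019),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(site))))

  expect_error(generate_genome(2e4, seed = 9, planted_sites = data.frame(
    sequence = c(site, site), position = c(5000, 5010),
    strand = c("+", "+"))), "overlap")
})

test_that("generated feature tables are non-overlapping and contain a divergent pair", {
  g <- generate_genome(3e4, seed = 10)
  f <- g$features
  expect_gt(length(f), 2)
  df <- data.frame(start = GenomicRanges::start(f),
                   end = GenomicRanges::end(f),
                   strand = as.character(GenomicRanges::strand(f)))
  df <- df[order(df$start), ]
  expect_true(all(df$start[-1] > df$end[-nrow(df)]))
  expect_true(any(df$strand[-nrow(df)] == "-" & df$strand[-1] == "+"))
  # GFF3 round trip preserves coordinates and ids
  path <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(f, path)
  back <- read_features_gff3(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(f))
  expect_equal(back$gene_id, f$gene_id)
})

test_that("noiseless sensorgrams follow the closed-form kinetics", {
  kon <- 4.6e5; koff <- 1.6e-3; rmax <- 1
  kd_nM <- kd_from_rates(kon, koff)
  # at C = KD the association plateau is rmax / 2
  sg <- simulate_sensorgram(kon, koff, rmax, concs = kd_nM,
                            t_assoc = 50 / koff, t_dissoc = 0, dt = 1000)
  expect_equal(max(sg$response), rmax / 2, tolerance = 1e-6)

  # dissociation is log-linear with slope -koff
  sg2 <- simulate_sensorgram(kon, koff, rmax, concs = 51, t_assoc = 300,
                             t_dissoc = 300, dt = 10)
  diss <- sg2[sg2$time_s > 300, ]
  slope <- coef(lm(log(response) ~ time_s, data = diss))[2]
  expect_equal(unname(slope), -koff, tolerance = 1e-8)

  # traces are ordered by concentration at every association time point
  sg3 <- simulate_sensorgram(kon, koff, rmax, t_assoc = 300, t_dissoc = 0,
                             dt = 5)
  assoc <- sg3[sg3$time_s > 0, ]
  cc <- sort(unique(assoc$concentration_nM))
  wide <- sapply(cc, function(C) assoc$response[assoc$concentration_nM == C])
  expect_true(all(apply(wide, 1, function(r) all(diff(r) > 0))))

  expect_error(simulate_sensorgram(-1, koff, rmax), "> 0")
})

test_that("REPA band simulation follows single-site occupancy", {
  b0 <- simulate_repa_bands(100, concs = 0)
  expect_equal(b0$probe_uncleaved, b0$control_uncleaved)
  bsat <- simulate_repa_bands(1e-3, concs = 1e6, total_intensity = 1)
  expect_equal(bsat$probe_uncleaved, 1, tolerance = 1e-3)
  bt <- simulate_repa_bands(100, concs = c(62.5, 125, 250, 500, 1000))
  expect_true(all(diff(bt$probe_uncleaved) > 0))
  expect_true(all(abs(diff(bt$control_uncleaved)) < 1e-12))
})

test_that("planted consensus realizations always match the consensus", {
  set.seed(1)
  reals <- sample_from_iupac(CONSENSUS, 50)
  expect_true(all(iupac_mismatches(reals, CONSENSUS) == 0))
  cores <- plant_consensus_sites(random_cores(500, seed = 2), CONSENSUS,
                                 prevalence = 0.8, seed = 3)
  lib <- selection_library(cores)
  expect_gt(consensus_match_fraction(lib, CONSENSUS), 0.7)
})
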