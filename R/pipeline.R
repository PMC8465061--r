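# Pipeline orchestration: simulate -> refine -> discover -> extend -> scan
# -> annotate, with on-disk artifacts, derived sub-seeds and a manifest.

required_blocks <- c("library", "selection", "reads", "refine", "discover",
                     "extend", "genome", "scan", "annotate")

validate_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config missing required field: seed")
  if (is.null(config$outdir)) stop("config missing required field: outdir")
  missing <- setdiff(required_blocks, names(config))
  if (length(missing))
    stop("config missing required block(s): ",
         paste(missing, collapse = ", "))
  invisible(config)
}

#' Default demonstration pipeline configuration
#'
#' A small, fast end-to-end configuration: a doped starting library (5% of
#' templates carry a planted consensus site — the desk-scale stand-in for
#' the enormous starting diversity of a real selection, in which consensus
#' sites are present by chance), three selection rounds, read simulation
#' and refinement, palindromic motif discovery, palindromic extension, and
#' a scan of a synthetic genome carrying planted sites near gene starts.
#'
#' @param outdir output directory for stage artifacts.
#' @param seed global pipeline seed.
#' @return a config list accepted by [run_pipeline()].
#' @export
selexscan_demo_config <- function(outdir = tempfile("selexscan_run_"),
                                  seed = 1L) {
  consensus <- "AWTGTRANNNNNNTYACAWT"
  list(
    seed = seed, outdir = outdir,
    library = list(n_templates = 2000, core_length = 24,
                   spike_in = list(consensus = consensus, fraction = 0.05)),
    selection = list(protein_conc = 34, cleavage_efficiency = 0.9,
                     rounds = 3, pcr_resampling_depth = 2000,
                     affinity = list(consensus = consensus, kd_min = 3,
                                     beta = 1)),
    reads = list(error_rate = 0.002, flank_corruption_rate = 0.02,
                 phred = 30),
    refine = list(min_mean_quality = 20),
    discover = list(width = 20, palindromic = TRUE, n_starts = 10,
                    max_sequences = 1000),
    extend = list(block_start = 1, block_end = 10),
    genome = list(length = 50000, gc = 0.5, n_planted = 5),
    scan = list(p_threshold = 1e-4),
    annotate = list(p_max = 5e-6, window_upstream = 200,
                    window_downstream = 20)
  )
}

#' Run the full pipeline
#'
#' Executes simulate -> refine -> discover -> extend -> scan -> annotate
#' with every stage's artifact written to disk (FASTQ, FASTA, MEME minimal,
#' GFF3, TSV, JSON), so each stage is independently re-runnable from files.
#' Every stochastic stage receives a sub-seed derived from the global seed;
#' the manifest records sub-seeds, artifact MD5 hashes and the package
#' version, and reruns with the same config are byte-identical.
#'
#' @param config a config list (see [selexscan_demo_config()]) or the path
#'   to a YAML file holding one.
#' @return the run manifest (a list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @examples
#' \donttest{
#' cfg <- selexscan_demo_config()
#' cfg$library$n_templates <- 300; cfg$selection$pcr_resampling_depth <- 300
#' cfg$genome$length <- 5000; cfg$discover$n_starts <- 2
#' manifest <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  sub_seed <- function(stage_no) seed + 1009L * stage_no
  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate: library, selection, reads, genome ------------------------
  lib <- stage("library", {
    cfgl <- config$library
    l <- generate_library(cfgl$n_templates, cfgl$core_length %||% 24L,
                          seed = sub_seed(1L))
    if (!is.null(cfgl$spike_in)) {
      l <- selection_library(
        plant_consensus_sites(expand_cores(l), cfgl$spike_in$consensus,
                              cfgl$spike_in$fraction, seed = sub_seed(2L)),
        round_index = 0L)
    }
    l
  })

  sel <- stage("selection", {
    cfgs <- config$selection
    aff <- affinity_model(pwm_from_consensus(cfgs$affinity$consensus),
                          kd_min = cfgs$affinity$kd_min,
                          beta = cfgs$affinity$beta)
    cfg <- repsa_config(protein_conc = cfgs$protein_conc,
                        cleavage_efficiency = cfgs$cleavage_efficiency,
                        rounds = cfgs$rounds,
                        pcr_resampling_depth = cfgs$pcr_resampling_depth,
                        seed = sub_seed(3L))
    run_repsa(lib, aff, cfg)
  })
  final_lib <- sel$libraries[[length(sel$libraries)]]
  write.csv(sel$stats, file.path(outdir, "selection_stats.csv"),
            row.names = FALSE)
  note(file.path(outdir, "selection_stats.csv"))

  template <- selection_template(core_length =
                                   nchar(final_lib$cores[1L]))
  reads <- stage("reads", {
    cfgr <- config$reads
    reads_from_library(final_lib, error_rate = cfgr$error_rate %||% 0,
                       flank_corruption_rate =
                         cfgr$flank_corruption_rate %||% 0,
                       seed = sub_seed(4L), template = template,
                       phred = cfgr$phred %||% 30L)
  })
  fastq_path <- file.path(outdir, "reads.fastq")
  write_fastq(reads, fastq_path); note(fastq_path)

  # -- refine -------------------------------------------------------------
  refined <- stage("refine", {
    rc <- refine_reads(fastq_path, template$left_flank,
                       template$right_flank,
                       core_length = template$core_length,
                       min_mean_quality =
                         config$refine$min_mean_quality %||% 20)
    deduplicate(rc)
  })
  cores_path <- file.path(outdir, "cores.fasta")
  write_fasta(setNames(Biostrings::DNAStringSet(refined$cores),
                       sprintf("core_%06d", seq_along(refined$cores))),
              cores_path); note(cores_path)
  jsonlite::write_json(refined$stats,
                       file.path(outdir, "refine_stats.json"),
                       auto_unbox = TRUE)
  note(file.path(outdir, "refine_stats.json"))

  # -- discover + extend --------------------------------------------------
  motif <- stage("discover", {
    cfgd <- config$discover
    discover_motif(refined$cores, width = cfgd$width,
                   palindromic = isTRUE(cfgd$palindromic),
                   n_starts = cfgd$n_starts %||% 10L,
                   seed = sub_seed(5L),
                   max_sequences = cfgd$max_sequences %||% 1000L)
  })
  meme_path <- file.path(outdir, "motif.meme")
  write_meme_minimal(motif, meme_path); note(meme_path)
  cons <- consensus_from_pwm(motif)
  jsonlite::write_json(
    list(consensus = cons$iupac,
         half_site_length = cons$half_site_length,
         spacer_length = cons$spacer_length,
         nsites = motif$nsites,
         information_content_bits = sum(information_content(motif)),
         log_likelihood_ratio = motif$score_significance),
    file.path(outdir, "motif_report.json"), auto_unbox = TRUE, digits = NA)
  note(file.path(outdir, "motif_report.json"))

  extended <- stage("extend", {
    extend_palindromic(motif, config$extend$block_start,
                       config$extend$block_end)
  })
  ext_path <- file.path(outdir, "motif_extended.meme")
  write_meme_minimal(extended, ext_path, name = "motif_1_extended")
  note(ext_path)

  # -- genome + scan + annotate ------------------------------------------
  gen <- stage("genome", {
    cfgg <- config$genome
    n_planted <- cfgg$n_planted %||% 0L
    plants <- NULL
    if (n_planted > 0) {
      set.seed(sub_seed(6L))
      w <- pwm_width(extended)
      # consensus realizations of the *extended* motif at spaced positions
      best_word <- paste(DNA_BASES[apply(extended$matrix, 2L, which.max)],
                         collapse = "")
      gap <- (cfgg$length - 2000L) %/% max(n_planted, 1L)
      plants <- data.frame(
        sequence = rep(best_word, n_planted),
        position = 1000L + gap * (seq_len(n_planted) - 1L) +
          sample.int(max(gap - w - 1L, 1L), n_planted, replace = TRUE),
        strand = sample(c("+", "-"), n_planted, replace = TRUE))
    }
    generate_genome(cfgg$length, gc = cfgg$gc %||% 0.5,
                    planted_sites = plants, seed = sub_seed(7L))
  })
  genome_path <- file.path(outdir, "genome.fasta")
  gff_path <- file.path(outdir, "features.gff3")
  write_fasta(gen$genome, genome_path); note(genome_path)
  write_features_gff3(gen$features, gff_path); note(gff_path)

  hits <- stage("scan", {
    scan_genome(gen$genome, extended,
                p_threshold = config$scan$p_threshold %||% 1e-4)
  })
  hits_path <- file.path(outdir, "hits.tsv")
  utils::write.table(hits, hits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(hits_path)

  calls <- stage("annotate", {
    cfga <- config$annotate
    annotate_hits(hits, gen$features,
                  window_upstream = cfga$window_upstream %||% 200L,
                  window_downstream = cfga$window_downstream %||% 20L,
                  p_max = cfga$p_max %||% 5e-6)
  })
  calls_path <- file.path(outdir, "promoter_calls.tsv")
  utils::write.table(calls, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(calls_path)

  manifest <- list(
    package = "selexscan",
    version = as.character(utils::packageVersion("selexscan")),
    seed = seed,
    sub_seeds = setNames(as.list(vapply(1:7, sub_seed, integer(1))),
                         c("library", "spike_in", "selection", "reads",
                           "discover", "genome_plants", "genome")),
    consensus = cons$iupac,
    n_hits = nrow(hits),
    n_promoter_calls = nrow(calls),
    artifacts = as.list(setNames(unname(tools::md5sum(artifacts)),
                                 basename(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
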