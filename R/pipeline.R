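#' Default pipeline configuration
#'
#' All thresholds default to the standard settings of the analysis: pair
#' filters E-value <= 1e-5, identity >= 40%, alignment >= 150 bp; protein
#' filter >= 50 aa; Ks universe (0, 2); YN00 estimator; mixtures with up to
#' 10 components, 100 random + 10 k-means starts; background-sigma
#' threshold 0.4; clock rate 6.1e-9 substitutions per synonymous site per
#' year.
#'
#' @param fasta Unigene FASTA path.
#' @param protein_hits Path to the transcriptome-vs-protein hit table
#'   guiding CDS extraction.
#' @param allbyall_hits Path to the all-by-all nucleotide hit table.
#' @param protein_fasta Optional protein FASTA (enables the OHR report).
#' @param ... Overrides for any default listed above.
#' @return Named list (class `ksd_run_config`).
#' @export
pipelineConfig <- function(fasta, protein_hits, allbyall_hits,
                           protein_fasta = NULL, ...) {
  cfg <- list(
    fasta = fasta, protein_hits = protein_hits,
    allbyall_hits = allbyall_hits, protein_fasta = protein_fasta,
    evalue_max = 1e-5, pident_min = 40, alnlen_min = 150,
    min_protein_aa = 50L, ks_range = c(0, 2), method = "YN00",
    node_summary = "median", bin_width = 0.05,
    kmax = 10L, n_random_starts = 100L, n_kmeans_starts = 10L,
    seed = 17L, sigma_background_threshold = 0.4, rate = 6.1e-9)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "ksd_run_config"
  cfg
}

.stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 131L) %% .Machine$integer.max
}

#' Run the full Ks-based WGD pipeline
#'
#' Executes qc -> (ohr) -> cds -> pairs -> families -> ks -> node-Ks ->
#' histogram -> mixture -> dating, writing one file per stage plus a
#' `manifest.json` holding the effective configuration, input checksums,
#' package version and per-stage record counts (timestamps live in a
#' separate manifest field so two runs with identical config and seed
#' produce identical stage outputs). When `resume = TRUE` and an existing
#' manifest matches the current configuration and input checksums, existing
#' stage outputs are reused instead of recomputed.
#'
#' @param config A `ksd_run_config` from [pipelineConfig()].
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse matching stage outputs.
#' @param quiet Suppress stage log lines (written to stderr).
#' @return Invisibly, a list with the key results: `qc`, `ohr`, `cds_info`,
#'   `pairs`, `families`, `pair_ks`, `node_ks`, `histogram`, `scan`,
#'   `dates`, `manifest`.
#' @export
runKsPipeline <- function(config, out_dir, resume = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "ksd_run_config"))
  for (f in c("fasta", "protein_hits", "allbyall_hits")) {
    if (!file.exists(config[[f]]))
      stop("input file not found (", f, "): ", config[[f]])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  inputs <- c(config$fasta, config$protein_hits, config$allbyall_hits,
              config$protein_fasta)
  checksums <- as.list(tools::md5sum(inputs))
  fingerprint <- paste(
    paste(unlist(checksums), collapse = ""),
    paste(deparse(config[setdiff(names(config), "protein_fasta")]),
          collapse = ""))
  manifest_path <- file.path(out_dir, "manifest.json")
  old_fp <- NULL
  if (resume && file.exists(manifest_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path),
                    error = function(e) NULL)
    old_fp <- old$fingerprint
  }
  reuse <- isTRUE(resume) && identical(old_fp, fingerprint)
  counts <- list()

  stage_file <- function(name) file.path(out_dir, name)

  ## qc ---------------------------------------------------------------
  unigenes <- readFasta(config$fasta, "nt")
  qc <- lengthStats(unigenes)
  jsonlite::write_json(
    list(n_seqs = qc$n_seqs, total_bases = qc$total_bases,
         mean_len = qc$mean_len, n50 = qc$n50, at_content = qc$at_content,
         histogram = qc$histogram),
    stage_file("qc.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  counts$unigenes <- qc$n_seqs
  log_line("qc", sprintf("%d unigenes, N50 %d", qc$n_seqs, qc$n50))

  ## best protein hits + optional OHR ----------------------------------
  phits <- readHits(config$protein_hits)
  best <- bestHits(phits)
  ohr <- NULL
  if (!is.null(config$protein_fasta)) {
    prots <- readFasta(config$protein_fasta, "aa")
    plen <- stats::setNames(Biostrings::width(prots), names(prots))
    ohr <- orthologHitRatio(best, plen)
    writeTable(ohr$records, stage_file("ohr.tsv"))
    counts$ohr_records <- nrow(ohr$records)
    log_line("ohr", sprintf("%d records, %d full-length",
                            nrow(ohr$records), ohr$classes[["full_length"]]))
  }

  ## cds ----------------------------------------------------------------
  cds_path <- stage_file("cds.fa")
  if (reuse && file.exists(cds_path)) {
    cds <- readFasta(cds_path, "nt")
    rejects <- readTable(stage_file("cds_rejects.tsv"))
    info <- readTable(stage_file("cds_info.tsv"))
    log_line("cds", "reused existing output")
  } else {
    ext <- extractCds(unigenes, best)
    flt <- filterProteins(ext$proteins, min_aa = config$min_protein_aa)
    cds <- ext$cds[names(flt$accepted)]
    rejects <- rbind(ext$rejects, flt$rejects)
    info <- ext$info[ext$info$id %in% names(cds), , drop = FALSE]
    writeFasta(cds, cds_path)
    writeTable(rejects, stage_file("cds_rejects.tsv"))
    writeTable(info, stage_file("cds_info.tsv"))
  }
  counts$cds <- length(cds)
  counts$cds_rejected <- nrow(rejects)
  log_line("cds", sprintf("%d coding regions (%d rejected)",
                          length(cds), nrow(rejects)))

  ## pairs + families ---------------------------------------------------
  ahits <- readHits(config$allbyall_hits)
  pairs <- filterParalogPairs(ahits, evalue_max = config$evalue_max,
                              pident_min = config$pident_min,
                              alnlen_min = config$alnlen_min)
  ## restrict to unigenes with an extracted CDS
  pairs <- pairs[pairs$id_a %in% names(cds) & pairs$id_b %in% names(cds), ,
                 drop = FALSE]
  writeTable(pairs, stage_file("pairs.tsv"))
  families <- singleLinkageFamilies(pairs)
  writeTable(families, stage_file("families.tsv"))
  counts$pairs <- nrow(pairs)
  counts$families <- length(attr(families, "families"))
  log_line("families", sprintf("%d pairs in %d families",
                               nrow(pairs), counts$families))

  ## pairwise Ks ---------------------------------------------------------
  ks_path <- stage_file("ks.tsv")
  if (reuse && file.exists(ks_path)) {
    pair_ks <- readTable(ks_path)
    pair_ks$flags[is.na(pair_ks$flags)] <- ""
    log_line("ks", "reused existing output")
  } else {
    pair_ks <- familyPairKs(families, cds, method = config$method)
    writeTable(pair_ks, ks_path)
  }
  counts$pair_ks <- nrow(pair_ks)
  log_line("ks", sprintf("%d pairwise estimates (%s)",
                         nrow(pair_ks), config$method))

  ## node Ks -------------------------------------------------------------
  node_ks <- allNodeKs(pair_ks, summary = config$node_summary,
                       ks_range = config$ks_range)
  writeTable(node_ks, stage_file("node_ks.tsv"))
  ks_values <- node_ks$ks[node_ks$in_range]
  writeKsList(ks_values, stage_file("node_ks_values.txt"))
  counts$node_ks <- nrow(node_ks)
  counts$node_ks_in_range <- length(ks_values)
  log_line("node_ks", sprintf("%d node values (%d in range)",
                              nrow(node_ks), length(ks_values)))

  ## histogram + mixture -------------------------------------------------
  hist <- ksHistogram(ks_values, bin_width = config$bin_width,
                      range = config$ks_range)
  writeTable(hist$bins, stage_file("hist.tsv"))
  scan <- ksMixtureScan(ks_values, kmax = config$kmax,
                        n_random_starts = config$n_random_starts,
                        n_kmeans_starts = config$n_kmeans_starts,
                        seed = .stage_seed(config$seed, "mixture"))
  best_fit <- scan$fits[[paste0("K", scan$best_bic)]]
  fit_json <- lapply(scan$fits, function(f) {
    list(K = f@K, weights = f@weights, mu = f@mu, sigma = f@sigma,
         loglik = f@loglik, aic = f@aic, bic = f@bic,
         start = f@startLabel, converged = f@converged)
  })
  jsonlite::write_json(
    list(table = scan$table, best_bic = scan$best_bic,
         best_aic = scan$best_aic, fits = fit_json),
    stage_file("mixture.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  counts$best_bic_K <- scan$best_bic
  log_line("mixture", sprintf("BIC selects K = %d (AIC K = %d)",
                              scan$best_bic, scan$best_aic))

  ## dating --------------------------------------------------------------
  dates <- dateWgdEvents(
    best_fit, rate = config$rate,
    sigma_background_threshold = config$sigma_background_threshold)
  writeTable(dates, stage_file("dates.tsv"))
  counts$discrete_events <- sum(dates$label == "discrete-event")
  log_line("date", sprintf("%d discrete-event component(s)",
                           counts$discrete_events))

  manifest <- list(
    tool = "ksdater",
    version = as.character(utils::packageVersion("ksdater")),
    config = config[setdiff(names(config), character(0))],
    input_checksums = checksums,
    counts = counts,
    fingerprint = fingerprint)
  manifest$timestamps <- list(finished = format(Sys.time(), tz = "UTC"))
  class(manifest$config) <- NULL
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(qc = qc, ohr = ohr, cds_info = info, pairs = pairs,
                 families = families, pair_ks = pair_ks, node_ks = node_ks,
                 histogram = hist, scan = scan, dates = dates,
                 manifest = manifest))
}
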