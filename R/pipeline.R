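## End-to-end orchestration: simulate/ingest -> filter -> identity QC ->
## ploidy & heterozygosity -> admixture -> species classification ->
## diversity -> core selection, with a checksummed run manifest.

PIPELINE_STAGES <- c("simulate", "filter", "identity", "ploidy",
                     "admixture", "classify", "diversity", "core")

default_pipeline_config <- function() {
  list(
    sim = NULL,                 # a sim_config(); NULL reads `input` files
    input = list(genotype = NULL, metadata = NULL, pairs = NULL,
                 encoding = "five_cluster"),
    filter = list(sample_max_missing = 0.20, marker_max_missing = 0.10,
                  exclude_file = NULL),
    identity = list(threshold = 0.98, min_overlap = NULL,
                    duplicate_threshold = 0.995),
    ploidy = list(min_het_calls = 50L),
    admixture = list(K = NULL, k_range = NULL, lambda = 0.5433,
                     alpha = 0.2, burn_in = 500L, reps = 500L,
                     n_replicates = 3L),
    classify = list(tolerance = 5, epsilon = 0.5, low_cap = 10,
                    hybrid_margin = 0.1),
    diversity = list(metric = "mismatch", pca_components = 5L),
    core = list(fraction = 0.1168, mini_size = NULL, max_sweeps = 20L),
    last_stage = "core",
    seed = 1L)
}

#' Assemble and validate a pipeline configuration
#'
#' Defaults are overridden by named arguments; unknown keys (top level or
#' within a stage block) are rejected before any stage runs, and the
#' config is echoed verbatim into the run manifest directory.
#'
#' @param ... Named overrides of the default blocks (`sim`, `input`,
#'   `filter`, `identity`, `ploidy`, `admixture`, `classify`,
#'   `diversity`, `core`, `last_stage`, `seed`). Stage blocks are lists
#'   and merge key-wise.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_pipeline_config()
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(names(over) == "")))
    stop("all pipeline_config arguments must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && !inherits(cfg[[nm]], "sim_config") &&
        is.list(over[[nm]]) && !inherits(over[[nm]], "sim_config")) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad) > 0L)
        stop(sprintf("unknown config keys in '%s': %s", nm,
                     paste(bad, collapse = ", ")))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  if (!cfg$last_stage %in% PIPELINE_STAGES)
    stop("last_stage must be one of: ", paste(PIPELINE_STAGES,
                                              collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(log_file, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "", file = log_file, append = TRUE)
  message(msg)
}

#' Run the full genotyping analysis pipeline
#'
#' Executes the stages in dependency order up to
#' `config$last_stage`, one output directory per stage, and writes a
#' manifest of every artifact with its MD5 checksum. Identical config
#' and seed yield identical manifest checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; one sub-directory per
#'   stage).
#' @return Invisibly, a list with the stage summaries and the `manifest`
#'   data.frame (`stage`, `file`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "pipeline.log")
  cat("", file = log_file)
  files <- list()
  note <- function(stage, paths) {
    files[[length(files) + 1L]] <<- data.frame(stage = stage,
                                               file = basename(paths),
                                               path = paths,
                                               stringsAsFactors = FALSE)
  }
  run_upto <- match(config$last_stage, PIPELINE_STAGES)
  stage_on <- function(st) match(st, PIPELINE_STAGES) <= run_upto
  res <- list()

  ## -- simulate or ingest ------------------------------------------------
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- as.integer(config$seed)
    sim <- simulate_collection(sim_cfg, pairs = TRUE)
    sdir <- file.path(out_dir, "01_simulate")
    note("simulate", write_simulation(sim, sdir))
    m <- sim$matrix
    meta <- sim$meta
    pairs <- sim$pairs
    pipeline_log(log_file, "simulate: %d samples x %d markers (seed %d)",
                 nrow(m$calls), ncol(m$calls), config$seed)
    res$sim <- sim
  } else {
    if (is.null(config$input$genotype))
      stop("either a sim config or an input genotype file is required")
    meta <- if (!is.null(config$input$metadata))
      read_metadata(config$input$metadata) else NULL
    pl <- if (!is.null(meta))
      stats::setNames(meta$declared_ploidy, meta$accession_id) else NULL
    m <- read_genotype_table(config$input$genotype,
                             encoding = config$input$encoding, ploidy = pl)
    pairs <- if (!is.null(config$input$pairs))
      utils::read.table(config$input$pairs, header = TRUE, sep = ",",
                        stringsAsFactors = FALSE) else NULL
    pipeline_log(log_file, "ingest: %d samples x %d markers",
                 nrow(m$calls), ncol(m$calls))
  }
  if (!stage_on("filter")) return(invisible(finish_manifest(files, out_dir,
                                                            config, res)))

  ## -- filter ------------------------------------------------------------
  fdir <- file.path(out_dir, "02_filter")
  dir.create(fdir, showWarnings = FALSE)
  if (!is.null(config$filter$exclude_file))
    m <- exclude_markers(m, config$filter$exclude_file)
  fs <- filter_samples(m, config$filter$sample_max_missing)
  fm <- filter_markers(fs$matrix, config$filter$marker_max_missing)
  m <- fm$matrix
  write_genotype_table(m, file.path(fdir, "genotypes_filtered.tsv"))
  write_filter_report(fs$report, file.path(fdir, "removed_samples.csv"))
  write_filter_report(fm$report, file.path(fdir, "removed_markers.csv"))
  note("filter", file.path(fdir, c("genotypes_filtered.tsv",
                                   "removed_samples.csv",
                                   "removed_markers.csv")))
  pipeline_log(log_file,
               "filter: removed %d samples (>=%.0f%% missing), %d markers (>=%.0f%% missing)",
               nrow(fs$report$removed), 100 * config$filter$sample_max_missing,
               nrow(fm$report$removed), 100 * config$filter$marker_max_missing)
  res$filter <- list(samples = fs$report, markers = fm$report)
  if (!stage_on("identity")) return(invisible(finish_manifest(files, out_dir,
                                                              config, res)))

  ## -- identity QC -------------------------------------------------------
  idir <- file.path(out_dir, "03_identity")
  dir.create(idir, showWarnings = FALSE)
  ttt_ids <- rownames(m$calls)
  ttt_ids <- ttt_ids[!grepl("_iv$", ttt_ids)]
  if (!is.null(pairs)) {
    pairs_kept <- pairs[pairs$mother_id %in% rownames(m$calls) &
                        pairs$invitro_id %in% rownames(m$calls), ]
    mo <- config$identity$min_overlap
    if (is.null(mo)) mo <- min(500L, ceiling(ncol(m$calls) / 2))
    pc <- pair_concordance(m, pairs_kept)
    ps <- classify_pairs(pc, config$identity$threshold, mo)
    utils::write.table(ps$pairs, file.path(idir, "pair_report.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    note("identity", file.path(idir, "pair_report.csv"))
    pipeline_log(log_file,
                 "identity: %d pairs, error rate %.1f%% (%d mismatch, %d insufficient)",
                 nrow(ps$pairs), 100 * ps$error_rate, ps$n_mismatch,
                 ps$n_insufficient)
    ttt_ids <- ps$pairs$mother_id[ps$pairs$verdict == "true_to_type"]
    res$identity <- ps
  }
  mothers <- subset_accessions(m, intersect(rownames(m$calls), ttt_ids))
  dup <- duplicate_groups(mothers, config$identity$duplicate_threshold)
  dup_lines <- vapply(dup$groups[lengths(dup$groups) > 1L],
                      paste, "", collapse = ",")
  writeLines(dup_lines, file.path(idir, "duplicate_groups.txt"))
  note("identity", file.path(idir, "duplicate_groups.txt"))
  res$duplicates <- dup
  if (!stage_on("ploidy")) return(invisible(finish_manifest(files, out_dir,
                                                            config, res)))

  ## -- ploidy & heterozygosity -------------------------------------------
  pdir <- file.path(out_dir, "04_ploidy")
  dir.create(pdir, showWarnings = FALSE)
  th <- ploidy_thresholds(min_het_calls = config$ploidy$min_het_calls)
  pp <- predict_ploidy(mothers, th)
  if (!is.null(meta)) {
    rec <- reconcile_ploidy(pp, meta)
    pp$declared_ploidy <- rec$table$declared_ploidy
    pp$status <- rec$table$status
    res$ploidy_reconciliation <- rec
    pipeline_log(log_file, "ploidy: %.1f%% agreement with declared (%d/%d)",
                 rec$summary$pct_agree, rec$summary$n_agree,
                 rec$summary$n_compared)
  }
  utils::write.table(pp, file.path(pdir, "ploidy.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, na = "NA")
  note("ploidy", file.path(pdir, "ploidy.csv"))
  res$ploidy <- pp
  if (!stage_on("admixture")) return(invisible(finish_manifest(files, out_dir,
                                                               config, res)))

  ## -- admixture ---------------------------------------------------------
  adir <- file.path(out_dir, "05_admixture")
  dir.create(adir, showWarnings = FALSE)
  use_ploidy <- stats::setNames(pp$predicted_ploidy, pp$accession_id)
  known <- !is.na(use_ploidy)
  if (!is.null(mothers$ploidy)) {
    # fall back to declared ploidy where prediction was undetermined
    fallback <- mothers$ploidy[pp$accession_id[!known]]
    use_ploidy[!known] <- fallback
    known <- !is.na(use_ploidy)
  }
  amat <- subset_accessions(mothers, pp$accession_id[known])
  acfg <- config$admixture
  if (!is.null(acfg$k_range)) {
    sweep <- run_k_sweep(amat, acfg$k_range, ploidy = use_ploidy,
                         lambda = acfg$lambda, alpha = acfg$alpha,
                         burn_in = acfg$burn_in, reps = acfg$reps,
                         n_replicates = acfg$n_replicates,
                         seed = config$seed + 101L)
    utils::write.table(sweep$diagnostics, file.path(adir, "diagnostics.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    utils::write.table(sweep$evanno$table, file.path(adir, "delta_k.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE, na = "NA")
    K_use <- sweep$selected_k
    if (is.na(K_use)) K_use <- max(acfg$k_range)
    Q <- sweep$Q_by_k[[as.character(K_use)]]
    note("admixture", file.path(adir, c("diagnostics.csv", "delta_k.csv")))
    pipeline_log(log_file, "admixture: delta-K selects K=%d", K_use)
    res$k_sweep <- sweep
  } else {
    K_use <- acfg$K
    if (is.null(K_use))
      K_use <- if (!is.null(config$sim)) config$sim$K_true else
        stop("admixture stage needs K or k_range")
    reps_q <- vector("list", acfg$n_replicates)
    ll <- numeric(acfg$n_replicates)
    for (r in seq_len(acfg$n_replicates)) {
      fit <- fit_admixture(amat, K_use, ploidy = use_ploidy,
                           lambda = acfg$lambda, alpha = acfg$alpha,
                           burn_in = acfg$burn_in, reps = acfg$reps,
                           seed = config$seed + 101L + r)
      reps_q[[r]] <- fit$Q
      ll[r] <- fit$log_lik
    }
    Q <- Reduce(`+`, align_labels(reps_q)) / length(reps_q)
    utils::write.table(data.frame(K = K_use,
                                  replicate = seq_along(ll), log_lik = ll),
                       file.path(adir, "diagnostics.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    note("admixture", file.path(adir, "diagnostics.csv"))
    pipeline_log(log_file, "admixture: K=%d, mean L = %.1f", K_use, mean(ll))
  }
  write_q_matrix(Q, file.path(adir, "q_matrix.csv"))
  note("admixture", file.path(adir, "q_matrix.csv"))
  res$Q <- Q
  res$K <- K_use
  if (!stage_on("classify")) return(invisible(finish_manifest(files, out_dir,
                                                              config, res)))

  ## -- species classification --------------------------------------------
  cdir <- file.path(out_dir, "06_classify")
  dir.create(cdir, showWarnings = FALSE)
  pol <- classification_policy(config$classify$tolerance,
                               config$classify$epsilon,
                               config$classify$low_cap,
                               config$classify$hybrid_margin)
  if (res$K < 6L)
    pipeline_log(log_file,
                 "classify: K=%d < 6, trailing clusters padded with zero ancestry",
                 res$K)
  calls <- classify_accessions(Q, policy = pol)
  utils::write.table(calls, file.path(cdir, "species_calls.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, na = "NA")
  note("classify", file.path(cdir, "species_calls.csv"))
  if (!is.null(meta)) {
    truth <- stats::setNames(meta$species_code, meta$accession_id)
    acc <- evaluate_predictions(calls, truth)
    summ <- utils::capture.output(print(acc))
    writeLines(summ, file.path(cdir, "accuracy.txt"))
    note("classify", file.path(cdir, "accuracy.txt"))
    pipeline_log(log_file, "classify: %.1f%% primary, %.1f%% extended (n=%d)",
                 acc$overall_pct, acc$extended_pct, acc$n_evaluated)
    res$classification_accuracy <- acc
  }
  res$species_calls <- calls
  if (!stage_on("diversity")) return(invisible(finish_manifest(files, out_dir,
                                                               config, res)))

  ## -- diversity ----------------------------------------------------------
  ddir <- file.path(out_dir, "07_diversity")
  dir.create(ddir, showWarnings = FALSE)
  dmat <- pairwise_distance(mothers, metric = config$diversity$metric)
  utils::write.table(data.frame(accession_id = rownames(dmat),
                                round(as.matrix(dmat), 6),
                                check.names = FALSE),
                     file.path(ddir, "distances.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  dfull <- as.matrix(dmat)
  if (any(is.na(dfull))) dfull[is.na(dfull)] <- max(dfull, na.rm = TRUE)
  tree <- upgma(dfull)
  write_newick(tree, file.path(ddir, "upgma.nwk"))
  pca <- pca_dosage(mothers, config$diversity$pca_components)
  utils::write.table(data.frame(accession_id = rownames(pca$scores),
                                round(pca$scores, 6)),
                     file.path(ddir, "pca_scores.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(component = seq_along(pca$var_pct),
                                var_pct = round(pca$var_pct, 4)),
                     file.path(ddir, "pca_variance.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  note("diversity", file.path(ddir, c("distances.csv", "upgma.nwk",
                                      "pca_scores.csv", "pca_variance.csv")))
  pipeline_log(log_file, "diversity: PC1 %.2f%%, PC2 %.2f%%",
               pca$var_pct[1], pca$var_pct[2])
  res$pca <- pca
  res$tree <- tree
  res$distances <- dmat
  if (!stage_on("core")) return(invisible(finish_manifest(files, out_dir,
                                                          config, res)))

  ## -- core / mini core ----------------------------------------------------
  kdir <- file.path(out_dir, "08_core")
  dir.create(kdir, showWarnings = FALSE)
  core <- select_core(dfull, fraction = config$core$fraction,
                      max_sweeps = config$core$max_sweeps)
  mini_size <- config$core$mini_size
  if (is.null(mini_size)) mini_size <- max(2L, round(0.1 * core$size))
  mini <- select_mini_core(core, dfull, mini_size,
                           max_sweeps = config$core$max_sweeps)
  writeLines(core$selected, file.path(kdir, "core.txt"))
  writeLines(mini$selected, file.path(kdir, "minicore.txt"))
  if (!is.null(meta)) {
    utils::write.table(composition_report(core, meta),
                       file.path(kdir, "core_composition.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(composition_report(mini, meta),
                       file.path(kdir, "minicore_composition.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    note("core", file.path(kdir, c("core_composition.csv",
                                   "minicore_composition.csv")))
  }
  note("core", file.path(kdir, c("core.txt", "minicore.txt")))
  pipeline_log(log_file,
               "core: %d entries (ANE %.5f); mini core: %d (ANE %.5f)",
               core$size, core$objective, mini$size, mini$objective)
  res$core <- core
  res$mini_core <- mini

  invisible(finish_manifest(files, out_dir, config, res))
}

finish_manifest <- function(files, out_dir, config, res) {
  tab <- if (length(files) > 0L) do.call(rbind, files) else
    data.frame(stage = character(0), file = character(0),
               path = character(0))
  md5 <- unname(tools::md5sum(tab$path))
  manifest <- data.frame(stage = tab$stage, file = tab$file, md5 = md5,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  res
}
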