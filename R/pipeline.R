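# End-to-end pipeline: simulate -> preprocess -> featurize -> train ->
# predict -> report, driven by a YAML config with full logging and a run
# manifest.

#' Default pipeline configuration
#'
#' Returns the complete configuration list the pipeline validates against.
#' Any subset can be supplied in a YAML file; unspecified entries keep these
#' defaults. Sections: `simulate` (synthetic corpus; set to `NULL` and fill
#' `inputs` to run on existing files), `inputs` (`reference_fasta`,
#' `reads_h5`, optional `checkpoint`), `featurize` (`min_coverage`,
#' `max_reads`), `model` (architecture), `train` (`epochs`, `lr`,
#' `stoich_epochs`), `predict` (`threshold`), plus `outdir` and `seed`.
#'
#' @return nested configuration list.
#' @export
pipeline_defaults <- function() {
  list(
    outdir = "nanodrach_run",
    seed = 1L,
    simulate = list(n_refs = 2L, ref_length = 200L, drach_density = 1 / 50,
                    reads_per_site = 30L, noise_scale = 1,
                    trace_sharpness = 0.85, trace_perturb = 0.2,
                    mod_ratio = 0.5, m6a_offset = 5),
    inputs = list(reference_fasta = NULL, reads_h5 = NULL, checkpoint = NULL),
    featurize = list(min_coverage = 20L, max_reads = 1000L),
    model = list(channels = 12L, skip_channels = 24L, post_channels = 24L,
                 embed_dim = 1024L, q_dim = 64L, v_dim = 64L,
                 stoich_hidden = 32L),
    train = list(epochs = 20L, pretrain_epochs = 3L, lr = 1e-3,
                 stoich_epochs = 30L),
    predict = list(threshold = 0.5)
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

load_pipeline_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    yaml::read_yaml(config)
  } else if (is.list(config)) config else {
    stop("config must be a YAML path or a list", call. = FALSE)
  }
  known <- names(pipeline_defaults())
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- merge_config(pipeline_defaults(), user)
  if (is.null(cfg$simulate) &&
      (is.null(cfg$inputs$reference_fasta) || is.null(cfg$inputs$reads_h5))) {
    stop("config must either enable 'simulate' or provide inputs$reference_fasta",
         " and inputs$reads_h5", call. = FALSE)
  }
  cfg
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Simulate a whole-transcriptome read corpus to disk
#'
#' Generates references with planted DRACH sites, assigns each site a
#' modification ratio, and simulates full-length reads per transcript where
#' every molecule carries m6A at each site independently with that site's
#' ratio. Writes `reference.fasta`, `truth_sites.tsv` (with per-site true
#' ratios) and `reads.h5`.
#'
#' @param scfg a [synth_config()].
#' @param pore a [pore_model()].
#' @param outdir output directory (created).
#' @param ratios optional per-site ratio vector (recycled); default as in
#'   [simulate_site_bags()].
#' @return list: paths (`reference_fasta`, `truth_sites`, `reads_h5`) and the
#'   truth site table.
#' @export
simulate_corpus <- function(scfg, pore = pore_model(), outdir, ratios = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  refs <- make_reference(scfg)
  sites <- refs$sites
  if (is.null(ratios)) {
    ratios <- ifelse(stats::runif(nrow(sites)) < 0.5, 0,
                     sample(c(0.2, 0.4, 0.6, 0.8, 1), nrow(sites), replace = TRUE))
  }
  sites$true_ratio <- rep_len(ratios, nrow(sites))
  reads <- list()
  for (tx in names(refs$sequences)) {
    seq <- refs$sequences[[tx]]
    tx_sites <- sites[sites$transcript == tx, , drop = FALSE]
    for (j in seq_len(scfg$reads_per_site)) {
      mod_here <- tx_sites$pos[stats::runif(nrow(tx_sites)) < tx_sites$true_ratio]
      reads[[length(reads) + 1L]] <-
        simulate_read(seq, modified = length(mod_here) > 0L, pore, scfg,
                      mod_positions = mod_here, ref_name = tx, ref_start = 0L)
    }
  }
  paths <- list(reference_fasta = file.path(outdir, "reference.fasta"),
                truth_sites = file.path(outdir, "truth_sites.tsv"),
                reads_h5 = file.path(outdir, "reads.h5"))
  write_reference_fasta(refs, paths$reference_fasta)
  write_site_table(sites, paths$truth_sites)
  write_reads_h5(reads, paths$reads_h5)
  c(paths, list(sites = sites, n_reads = length(reads)))
}

#' Run the full m6A calling pipeline
#'
#' Executes simulate (or load) -> normalize -> resquiggle -> featurize ->
#' train (or load checkpoint) -> predict -> write, logging counts at every
#' stage and recording a run manifest (config hash, seed, versions, stage
#' statistics). Deterministic under a fixed seed.
#'
#' @param config YAML file path or configuration list
#'   (see [pipeline_defaults()]).
#' @param seed optional override of the config seed.
#' @param threshold optional override of the call threshold.
#' @return invisibly, a list: `calls` (site_calls data.frame), `metrics`
#'   (when ground truth is available), `manifest`, and the output paths.
#' @export
run_pipeline <- function(config, seed = NULL, threshold = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(threshold)) cfg$predict$threshold <- threshold
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  counts <- list()

  # --- stage: input data -----------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    scfg <- synth_config(n_refs = sim$n_refs, ref_length = sim$ref_length,
                         drach_density = sim$drach_density,
                         mod_ratio = sim$mod_ratio,
                         reads_per_site = sim$reads_per_site,
                         noise_scale = sim$noise_scale,
                         trace_sharpness = sim$trace_sharpness,
                         trace_perturb = sim$trace_perturb, seed = cfg$seed)
    pore <- pore_model(m6a_offset = sim$m6a_offset)
    stage_msg("simulate", "generating corpus (%d refs x %d nt, %d reads/ref)",
              sim$n_refs, sim$ref_length, sim$reads_per_site)
    sim_out <- simulate_corpus(scfg, pore, outdir)
    ref_fasta <- sim_out$reference_fasta
    reads_h5 <- sim_out$reads_h5
    truth <- sim_out$sites
    counts$simulated_reads <- sim_out$n_reads
    stage_msg("simulate", "%d reads, %d DRACH sites", sim_out$n_reads,
              nrow(truth))
  } else {
    ref_fasta <- cfg$inputs$reference_fasta
    reads_h5 <- cfg$inputs$reads_h5
    truth <- NULL
    for (f in c(ref_fasta, reads_h5)) {
      if (!file.exists(f)) stop("[inputs] missing file: ", f, call. = FALSE)
    }
  }
  refseqs <- read_reference_fasta(ref_fasta)
  reads <- read_reads_h5(reads_h5)
  counts$reads_in <- length(reads)

  # --- stage: preprocess (normalize + resquiggle) ----------------------
  stage_msg("preprocess", "normalizing and resquiggling %d reads", length(reads))
  prep <- lapply(reads, function(rd) {
    tryCatch({
      nr <- normalize_read(rd)
      ref_seq <- substr(refseqs[[rd$ref_name]], rd$ref_start + 1L, rd$ref_end)
      list(nread = nr, seg = resquiggle_read(nr, ref_seq), read = rd)
    }, error = function(e) NULL)
  })
  failed <- sum(vapply(prep, is.null, logical(1)))
  prep <- prep[!vapply(prep, is.null, logical(1))]
  counts$reads_failed_preprocess <- failed
  counts$reads_preprocessed <- length(prep)
  stage_msg("preprocess", "%d reads resquiggled, %d failed", length(prep), failed)

  # --- stage: featurize ------------------------------------------------
  sites <- do.call(rbind, lapply(names(refseqs), function(nm) {
    find_drach_sites(refseqs[[nm]], transcript = nm)
  }))
  stage_msg("featurize", "extracting windows at %d DRACH sites", nrow(sites))
  feats <- do.call(rbind, lapply(prep, function(pr) {
    ft <- featurize_read(pr$nread, pr$seg, sites)
    if (nrow(ft) > 0L && !is.null(pr$read$mod_positions)) {
      ft$read_label <- as.integer(ft$pos %in% pr$read$mod_positions)
    }
    ft
  }))
  counts$features <- if (is.null(feats)) 0L else nrow(feats)
  bags <- build_bags(feats, min_coverage = cfg$featurize$min_coverage,
                     max_reads = cfg$featurize$max_reads, seed = cfg$seed)
  n_sites_covered <- length(unique(paste(feats$transcript, feats$pos)))
  counts$sites_dropped_coverage <- n_sites_covered - length(bags)
  counts$bags <- length(bags)
  stage_msg("featurize", "%d site bags kept, %d sites dropped for coverage < %d",
            length(bags), counts$sites_dropped_coverage,
            cfg$featurize$min_coverage)
  if (length(bags) == 0L) stop("[featurize] no site reached minimum coverage",
                               call. = FALSE)

  # --- stage: train or load model --------------------------------------
  mc <- cfg$model
  if (!is.null(cfg$inputs$checkpoint)) {
    stage_msg("train", "loading checkpoint %s", cfg$inputs$checkpoint)
    model <- load_checkpoint(cfg$inputs$checkpoint)
  } else {
    if (anyNA(vapply(bags, function(b) b$label, integer(1)))) {
      stop("[train] bags carry no labels and no checkpoint was supplied",
           call. = FALSE)
    }
    enc <- encoder_config(channels = mc$channels,
                          skip_channels = mc$skip_channels,
                          post_channels = mc$post_channels,
                          embed_dim = mc$embed_dim)
    heads <- head_config(q_dim = mc$q_dim, v_dim = mc$v_dim,
                         stoich_hidden = mc$stoich_hidden)
    model <- m6a_model(enc, heads, seed = cfg$seed)
    stage_msg("train", "training on %d bags for %d epochs", length(bags),
              cfg$train$epochs)
    model <- train_m6a_model(model, bags, epochs = cfg$train$epochs,
                             pretrain_epochs = cfg$train$pretrain_epochs,
                             lr = cfg$train$lr, seed = cfg$seed,
                             log_file = file.path(outdir, "training_log.jsonl"))
    has_pure <- any(vapply(bags, function(b)
      isTRUE(b$true_ratio %in% c(0, 1)), logical(1)))
    if (has_pure) {
      model <- train_stoichiometry(model, bags, epochs = cfg$train$stoich_epochs,
                                   lr = cfg$train$lr, seed = cfg$seed)
    } else {
      stage_msg("train", "no pure bags; stoichiometry head left at init")
    }
    save_checkpoint(model, file.path(outdir, "checkpoint.rds"))
  }

  # --- stage: predict ---------------------------------------------------
  stage_msg("predict", "calling %d sites at threshold %.2f", length(bags),
            cfg$predict$threshold)
  calls <- predict_sites(model, bags, threshold = cfg$predict$threshold)
  counts$sites_called <- nrow(calls)
  counts$sites_positive <- sum(calls$call)

  # --- stage: evaluate + write -----------------------------------------
  metrics <- NULL
  if (!is.null(truth)) {
    key <- paste(calls$transcript, calls$pos - 1L)
    tr <- truth[match(key, paste(truth$transcript, truth$pos)), ]
    ok <- !is.na(tr$true_ratio)
    if (any(ok) && length(unique(tr$true_ratio[ok] > 0)) == 2L) {
      cm <- classification_metrics(as.integer(tr$true_ratio[ok] > 0),
                                   calls$p_mod[ok], cfg$predict$threshold)
      metrics <- c(cm, list(
        stoichiometry_pearson = stats::cor(calls$mod_ratio[ok],
                                           tr$true_ratio[ok])))
      jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_msg("evaluate", "accuracy %.3f, ROC-AUC %.3f", cm$accuracy,
                cm$roc_auc)
    }
  }
  paths <- write_sites(calls, file.path(outdir, "sites.tsv"),
                       file.path(outdir, "sites.bed"))
  manifest <- list(
    package = "nanodrach",
    version = as.character(utils::packageVersion("nanodrach")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_msg("done", "wrote %s", paths$tsv)
  invisible(list(calls = calls, metrics = metrics, manifest = manifest,
                 paths = paths, model = model, bags = bags))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write site calls as TSV and BED6
#'
#' The TSV carries all call fields with the 1-based central-A position. The
#' BED6 uses 0-based half-open single-base intervals, `name` = motif,
#' `score` = `round(1000 * p_mod)`, strand `+`.
#'
#' @param calls a `site_calls` data.frame.
#' @param tsv,bed output paths (either may be `NULL` to skip).
#' @return list of written paths.
#' @export
write_sites <- function(calls, tsv = NULL, bed = NULL) {
  stopifnot(is.data.frame(calls))
  if (!is.null(tsv)) {
    utils::write.table(calls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = calls$transcript, start = calls$pos - 1L,
                         end = calls$pos, name = calls$motif,
                         score = as.integer(round(1000 * calls$p_mod)),
                         strand = "+")
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(tsv = tsv, bed = bed)
}

#' Read back a site-call TSV
#' @param tsv path written by [write_sites()].
#' @return `site_calls` data.frame.
#' @export
read_sites <- function(tsv) {
  out <- utils::read.table(tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("site_calls", "data.frame")
  out
}
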