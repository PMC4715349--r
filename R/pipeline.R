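#' Assemble a pipeline run configuration
#'
#' @param datasets List of [dataset_spec()] objects.
#' @param candidates Path to the candidate SV list (BED-like), or an
#'   [sv_calls()] data.frame.
#' @param candidate_dialect Coordinate dialect of the candidate file.
#' @param training Either an [sv_calls()] data.frame / BED path of training
#'   random regions, or an integer: sample that many log-uniform random
#'   regions from the genome implied by the first BAM.
#' @param fasta,repeats,snps Optional reference inputs (paths).
#' @param flank_size Flank width in bp.
#' @param p Per-dataset classification level (SV iff rho > p).
#' @param k Ensemble parameter: SV when at least `k` datasets vote SV;
#'   capped at the number of datasets with a warning.
#' @param max_flank_coverage,min_flank_mapq Pre-filter thresholds applied to
#'   the first paired-end dataset's flank statistics.
#' @param strata Stratum boundaries for [stratify()].
#' @param train_min_size,train_max_size Size bounds when sampling training
#'   regions.
#' @param seed Seed for training-region sampling.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(datasets, candidates, candidate_dialect = "bed0",
                       training = 4000, fasta = NULL, repeats = NULL,
                       snps = NULL, flank_size = 100, p = 0.99, k = 3,
                       max_flank_coverage = 300, min_flank_mapq = 30,
                       strata = DEFAULT_STRATA, train_min_size = 50,
                       train_max_size = 997527, seed = 1, out_dir = NULL) {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, NA, "dataset_spec")))
  if (k > length(datasets)) {
    warning("k = ", k, " exceeds the number of datasets; capping at ",
            length(datasets))
    k <- length(datasets)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]: a `datasets` list (each with `name`,
#' `technology`, `bam`, `mean_coverage`, optional `indel_baseline`), plus any
#' of the scalar settings.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$datasets)) stop("config error: no datasets")
  datasets <- lapply(y$datasets, function(d) {
    args <- list(name = d$name, technology = d$technology, bam_path = d$bam,
                 mean_coverage = d$mean_coverage)
    if (!is.null(d$indel_baseline))
      args$long_read_indel_baseline <- as.numeric(d$indel_baseline)
    do.call(dataset_spec, args)
  })
  args <- y[setdiff(names(y), "datasets")]
  do.call(run_config, c(list(datasets = datasets), args))
}

#' Run the full classification pipeline
#'
#' Per dataset: annotate the training random regions (one-class annotation
#' subset), fit the transform and the L1 one-class model, annotate and score
#' the candidates.  Then: ensemble rho (k-th largest per-dataset rho), votes
#' at level `p`, pre-filter flags from the first paired-end dataset's flank
#' statistics, stratification, and serialized outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `results` (one row per candidate), `models`,
#'   `transforms`, `training_regions`, `paths` (when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (d in config$datasets)
    if (!file.exists(d$bam_path))
      stop("config error: missing BAM ", d$bam_path)
  for (pth in c(config$fasta, config$repeats, config$snps))
    if (!is.null(pth) && !file.exists(pth))
      stop("config error: missing file ", pth)

  candidates <- if (is.character(config$candidates))
    read_sv_calls(config$candidates, dialect = config$candidate_dialect)
  else validate_sv_calls(config$candidates)

  training <- config$training
  if (is.numeric(training) && length(training) == 1L) {
    layout <- genome_layout_from_bam(config$datasets[[1]]$bam_path)
    max_size <- min(config$train_max_size, max(layout$chroms$length) %/% 2)
    training <- sample_random_regions_loguniform(
      layout, n = training, min_size = config$train_min_size,
      max_size = max_size, seed = config$seed)
  } else if (is.character(training)) {
    training <- read_sv_calls(training, dialect = "bed0")
  }

  repeats <- if (!is.null(config$repeats)) read_repeat_track(config$repeats)
  snps <- if (!is.null(config$snps)) read_snp_genotypes(config$snps)

  models <- transforms <- list()
  rho <- matrix(NA_real_, nrow(candidates), length(config$datasets))
  colnames(rho) <- vapply(config$datasets, `[[`, "", "name")
  flank_stats <- NULL
  log_lines <- c(paste("svarbiter", as.character(utils::packageVersion("svarbiter"))),
                 paste("seed:", config$seed),
                 paste("flank:", config$flank_size, "p:", config$p,
                       "k:", config$k),
                 paste("training regions:", nrow(training)),
                 paste("candidates:", nrow(candidates)))

  for (i in seq_along(config$datasets)) {
    ds <- config$datasets[[i]]
    step <- function(what, expr) tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed for dataset ", ds$name, ": ",
           conditionMessage(e)))
    if (ds$technology == "unpaired_long") {
      ds$long_read_indel_baseline <- step("baseline",
        unname(compute_indel_baseline(ds$bam_path, training)))
      log_lines <- c(log_lines, sprintf(
        "%s indel baseline (from training regions): %.4f / %.4f",
        ds$name, ds$long_read_indel_baseline[1], ds$long_read_indel_baseline[2]))
    }
    train_tab <- step("annotate-training",
      annotate_sites(training, ds, flank_size = config$flank_size,
                     subset = "oneclass"))
    tm <- step("fit-transform", fit_transform_model(train_tab))
    model <- step("fit-l1", fit_l1_model(train_tab, tm,
                                         min_train = min(100, nrow(training))))
    cand_tab <- step("annotate-candidates",
      annotate_sites(candidates, ds, flank_size = config$flank_size,
                     subset = "oneclass"))
    rho[, i] <- step("score", score_sites(model, cand_tab))
    transforms[[ds$name]] <- tm
    models[[ds$name]] <- model
    if (is.null(flank_stats) && ds$technology == "paired_short") {
      full <- step("annotate-flanks",
        annotate_sites(candidates, ds, flank_size = config$flank_size,
                       subset = "full"))
      flank_stats <- as.data.frame(
        full$values[, c("L_Cov", "R_Cov", "L_MapQ", "R_MapQ"), drop = FALSE])
    }
  }

  votes <- rowSums(rho > config$p, na.rm = TRUE)
  ens_rho <- apply(rho, 1, ensemble_rho, k = config$k)
  results <- data.frame(chrom = candidates$chrom, start = candidates$start,
                        end = candidates$end, sv_type = candidates$sv_type,
                        source = candidates$source, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(rho))) results[[paste0("rho_", colnames(rho)[j])]] <- rho[, j]
  results$ensemble_rho <- ens_rho
  results$votes <- as.integer(votes)
  results$call <- ifelse(votes >= config$k, "SV", "non-SV")
  if (!is.null(flank_stats)) {
    pf <- prefilter_sites(flank_stats, config$max_flank_coverage,
                          config$min_flank_mapq)
    results$high_flank_coverage <- pf$high_flank_coverage
    results$low_flank_mapq <- pf$low_flank_mapq
    results$filtered <- pf$high_flank_coverage | pf$low_flank_mapq
  } else {
    results$high_flank_coverage <- results$low_flank_mapq <- NA
    results$filtered <- FALSE
  }
  results$stratum <- as.character(stratify(ens_rho, config$strata))
  log_lines <- c(log_lines,
                 paste("pre-filtered sites:", sum(results$filtered)),
                 paste("SV calls at p =", config$p, "k =", config$k, ":",
                       sum(results$call == "SV" & !results$filtered)))

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    write_classified_calls(results, out("classified_calls.tsv"), dialect = "bed0")
    write_sv_calls(training, out("training_regions.bed"), dialect = "bed0")
    for (nm in names(transforms))
      write_transform_model(transforms[[nm]], out(paste0("transform_", nm, ".csv")))
    writeLines(log_lines, out("run_log.txt"))
    paths <- list(calls = out("classified_calls.tsv"),
                  log = out("run_log.txt"))
  }
  invisible(list(results = results, models = models, transforms = transforms,
                 training_regions = training, paths = paths))
}
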