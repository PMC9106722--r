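# Config-driven orchestration of the three analysis tracks, with a
# deterministic output manifest (content hashes) and a plain run log.

#' Validate a pipeline configuration
#'
#' A config is a named list (or a YAML file path) with at least `track`
#' (`"polii"`, `"sc"`, `"stratify"` or `"demo"`), `out_dir` and `seed`;
#' track-specific input paths and parameter overrides are checked before
#' anything runs.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list (with defaults filled in).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      validation_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) validation_error("config must be a list or YAML path")
  track <- config$track
  if (is.null(track) || !track %in% c("polii", "sc", "stratify", "demo"))
    validation_error("field `track` must be one of polii, sc, stratify, demo")
  if (is.null(config$out_dir)) validation_error("field `out_dir` is required")
  config$seed <- as.integer(config$seed %||% 1L)
  config$params <- config$params %||% list()
  required <- switch(track,
    polii = c("genes", "fragments1", "fragments2", "chrom_sizes"),
    sc = c("matrix1_dir", "matrix2_dir", "anchor"),
    stratify = c("expression", "survival"),
    demo = character())
  inputs <- config$inputs %||% list()
  for (f in required)
    if (is.null(inputs[[f]]))
      validation_error(sprintf("track %s: missing input field `%s`", track, f))
  path_fields <- setdiff(required, "anchor")
  for (f in path_fields) {
    p <- inputs[[f]]
    if (is.character(p) && !file.exists(p))
      validation_error(sprintf("input `%s`: path does not exist: %s", f, p))
  }
  config
}

#' Run an analysis track from a config
#'
#' Executes the configured track's stages in order, writing every output
#' file under `out_dir` and a `manifest.tsv` of relative paths with MD5
#' content hashes; an identical config and seed reproduce identical hashes.
#' On a stage failure all partial outputs are removed and the log retained.
#'
#' @param config Named list or YAML path; see [pipeline_config()].
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "log.txt")
  log_con <- file(log_path, "w")
  loginfo <- function(...) writeLines(sprintf(...), log_con)
  loginfo("INFO track=%s seed=%d", config$track, config$seed)
  written <- character()
  emit <- function(path) written <<- c(written, path)
  tryCatch({
    switch(config$track,
      polii = run_track_polii(config, out, loginfo, emit),
      sc = run_track_sc(config, out, loginfo, emit),
      stratify = run_track_stratify(config, out, loginfo, emit),
      demo = run_track_demo(config, out, loginfo, emit))
    TRUE
  }, error = function(e) {
    loginfo("ERROR %s", conditionMessage(e))
    close(log_con)
    unlink(written)
    stop(e)
  })
  loginfo("INFO done: %d output file(s)", length(written))
  close(log_con)
  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}

run_track_polii <- function(config, out, loginfo, emit, sim = NULL) {
  p <- config$params
  if (is.null(sim)) {
    genes <- load_gene_models(config$inputs$genes, dialect = "BED12")
    chrom_sizes <- read_chrom_sizes(config$inputs$chrom_sizes)
    track1 <- coverage_from_fragments(config$inputs$fragments1, chrom_sizes)
    track2 <- coverage_from_fragments(config$inputs$fragments2, chrom_sizes)
  } else {
    genes <- sim$genes; track1 <- sim$track1; track2 <- sim$track2
  }
  loginfo("INFO polii: %d genes, %d + %d fragments", nrow(genes),
          track1$total_fragments, track2$total_fragments)
  tr1 <- compute_tr_table(track1, genes,
                          upstream = p$upstream %||% 30L,
                          downstream = p$downstream %||% 300L)
  tr2 <- compute_tr_table(track2, genes,
                          upstream = p$upstream %||% 30L,
                          downstream = p$downstream %||% 300L)
  emit(write_tr_table(tr1, file.path(out, "tr_condition1.tsv")))
  emit(write_tr_table(tr2, file.path(out, "tr_condition2.tsv")))
  curve <- tr_difference_curve(tr1, tr2)
  cuts <- tangent_cutpoints(curve, smooth_window = p$smooth_window %||% 11L)
  curve_out <- as.data.frame(curve)
  curve_out$slope <- cuts$slope
  emit(write_tsv(curve_out, file.path(out, "curve.tsv")))
  classes <- classify_pause_genes(curve, cuts)
  loginfo("INFO polii: %d pause-release, %d pause genes",
          length(classes$pause_release), length(classes$pause))
  cls <- data.frame(
    gene_id = c(classes$pause_release, classes$pause),
    class = c(rep("pause_release", length(classes$pause_release)),
              rep("pause", length(classes$pause))),
    stringsAsFactors = FALSE)
  emit(write_tsv(cls, file.path(out, "classes.tsv")))
  if (!is.null(config$inputs$gene_set)) {
    gs <- read_gene_set(config$inputs$gene_set)
    cmp <- list(
      KS = unclass(compare_geneset_tr(tr1, tr2, gs, test = "KS")),
      welch_t = unclass(compare_geneset_tr(tr1, tr2, gs, test = "Welch-t")))
    jsonlite::write_json(cmp, file.path(out, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(out, "comparison.json"))
  }
  invisible(classes)
}

run_track_sc <- function(config, out, loginfo, emit, sim = NULL) {
  p <- config$params
  if (is.null(sim)) {
    m1 <- read_cell_matrix(config$inputs$matrix1_dir, condition = "condition1")
    m2 <- read_cell_matrix(config$inputs$matrix2_dir, condition = "condition2")
    anchor <- config$inputs$anchor
  } else {
    m1 <- sim$matrix1; m2 <- sim$matrix2; anchor <- sim$anchor
  }
  q1 <- qc_filter_cells(m1, min_genes = p$min_genes %||% 200L,
                        max_mito_fraction = p$max_mito_fraction %||% 0.80)
  q2 <- qc_filter_cells(m2, min_genes = p$min_genes %||% 200L,
                        max_mito_fraction = p$max_mito_fraction %||% 0.80)
  loginfo("INFO sc: kept %d/%d and %d/%d cells",
          ncol(q1$matrix$counts), ncol(m1$counts),
          ncol(q2$matrix$counts), ncol(m2$counts))
  emit(write_tsv(rbind(q1$report, q2$report), file.path(out, "qc_removed.tsv")))
  shift <- anchor_covariance_shift(q1$matrix, q2$matrix, anchor,
                                   threshold = p$cov_threshold %||% 30,
                                   populations = p$populations)
  loginfo("INFO sc: %d/%d genes flagged", sum(shift$flagged), nrow(shift))
  emit(write_tsv(as.data.frame(shift), file.path(out, "covariance_shift.tsv")))
  if (!is.null(p$transgene)) {
    cen <- rbind(cbind(condition = "condition1",
                       transgene_census(q1$matrix, p$transgene)),
                 cbind(condition = "condition2",
                       transgene_census(q2$matrix, p$transgene)))
    emit(write_tsv(cen, file.path(out, "transgene_census.tsv")))
  }
  invisible(shift)
}

run_track_stratify <- function(config, out, loginfo, emit, sim = NULL) {
  p <- config$params
  if (is.null(sim)) {
    expr <- read_expression_tsv(config$inputs$expression)
    surv <- read_tsv(config$inputs$survival)
    sig_ar <- if (!is.null(config$inputs$sig_ar))
      signature("AR", read_gene_set(config$inputs$sig_ar)) else ar_a_signature()
    sig_myc <- signature("MYC", read_gene_set(config$inputs$sig_myc))
  } else {
    expr <- sim$expression; surv <- sim$survival
    sig_ar <- sim$signatures[[1]]; sig_myc <- sim$signatures[[2]]
  }
  qr <- p$quantile_range %||% c(0.10, 0.90)
  ar_scores <- signature_score(expr, sig_ar)
  myc_scores <- signature_score(expr, sig_myc)
  scores <- merge(ar_scores, myc_scores, by = "sample_id",
                  suffixes = c("_ar", "_myc"))
  emit(write_tsv(scores[order(scores$sample_id), ],
                 file.path(out, "scores.tsv")))
  ar_cut <- maxstat_cutpoint(ar_scores, surv, quantile_range = qr)
  myc_cut <- maxstat_cutpoint(myc_scores, surv, quantile_range = qr)
  jsonlite::write_json(list(ar = unclass(ar_cut), myc = unclass(myc_cut)),
                       file.path(out, "cutpoints.json"),
                       auto_unbox = TRUE, digits = NA)
  emit(file.path(out, "cutpoints.json"))
  groups <- assign_quadrant_groups(ar_scores, myc_scores, ar_cut, myc_cut)
  gtab <- merge(groups, surv, by = "sample_id")
  gtab$group <- as.character(gtab$group)
  emit(write_tsv(gtab[order(gtab$sample_id),
                      c("sample_id", "time", "event", "group")],
                 file.path(out, "groups.tsv")))
  km <- km_logrank(gtab, pairwise = TRUE)
  loginfo("INFO stratify: log-rank chisq=%.3f df=%d", km$chisq, km$df)
  emit(write_tsv(km$curves, file.path(out, "km_curves.tsv")))
  jsonlite::write_json(list(chisq = km$chisq, df = km$df,
                            p_value = km$p_value,
                            pairwise = km$pairwise),
                       file.path(out, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)
  emit(file.path(out, "logrank.json"))
  invisible(km)
}

run_track_demo <- function(config, out, loginfo, emit) {
  seed <- config$seed
  loginfo("INFO demo: synthetic end-to-end run")
  pcfg <- polii_sim_config(n_genes = 400L, reads_per_gene_mean = 300,
                           planted_pause_release =
                             setNames(rep(-0.4, 15), sprintf("g%05d", 1:15)),
                           planted_pause =
                             setNames(rep(0.3, 25), sprintf("g%05d", 16:40)),
                           seed = seed)
  genes <- simulate_gene_models(pcfg)
  sim <- simulate_polii_experiment(genes, pcfg)
  emit(write_gene_models_bed12(genes, file.path(out, "genes.bed")))
  emit(write_tsv(sim$truth, file.path(out, "polii_truth.tsv")))
  run_track_polii(config, out, loginfo, emit,
                  sim = list(genes = genes, track1 = sim$track1,
                             track2 = sim$track2))
  scfg <- sc_sim_config(n_genes = 200L, n_cells_per_condition = 500L,
                        seed = seed)
  ssim <- simulate_sc_experiment(scfg)
  config$params$transgene <- scfg$transgene
  run_track_sc(config, out, loginfo, emit,
               sim = list(matrix1 = ssim$matrix1, matrix2 = ssim$matrix2,
                          anchor = scfg$anchor_gene))
  vcfg <- surv_sim_config(n_samples = 150L, n_genes = 800L, seed = seed)
  vsim <- simulate_survival_cohort(vcfg)
  run_track_stratify(config, out, loginfo, emit, sim = vsim)
  invisible(NULL)
}
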