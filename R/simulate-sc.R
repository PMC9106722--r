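# Two-condition single-cell UMI simulator with a planted covariance
# structure: a latent per-cell activity drives the anchor gene in both
# conditions and a designated covarying gene set in condition 1 only, so the
# anchor covariance of those genes collapses in condition 2.

#' Configuration for the single-cell covariance simulator
#'
#' Counts are negative binomial around `mean = base * exp(loading * a)` where
#' `a ~ N(0,1)` is a per-cell latent activity. Defaults are sized so that
#' planted anchor covariances (order 150 on the per-10k normalized scale)
#' clear the magnitude-30 flagging threshold while null sampling noise stays
#' far below it.
#'
#' @param n_genes Number of background genes (anchor, covarying set and
#'   transgene are added on top).
#' @param n_cells_per_condition Cells per condition.
#' @param populations Named numeric vector of population proportions
#'   (must sum to 1).
#' @param anchor_gene Anchor gene id.
#' @param anchor_loading Latent loading of the anchor (both conditions).
#' @param covarying_set Character vector of covarying gene ids.
#' @param covarying_loading Latent loading of covarying genes, active in
#'   condition 1 only.
#' @param anchor_base,covarying_base Base mean counts for anchor/covarying
#'   genes.
#' @param base_meanlog,base_sdlog Lognormal parameters for background gene
#'   base means.
#' @param transgene Transgene id, or `NULL` to omit.
#' @param transgene_rates Named numeric vector: per-population probability
#'   that a cell expresses the transgene.
#' @param dispersion Negative-binomial size parameter (Poisson as it grows).
#' @param seed Integer seed.
#' @return A list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_genes = 500L, n_cells_per_condition = 2000L,
                          populations = c(luminal = 0.7, basal = 0.2,
                                          hematopoietic = 0.1),
                          anchor_gene = "Ar", anchor_loading = 0.6,
                          covarying_set = paste0("cov", 1:20),
                          covarying_loading = 0.7,
                          anchor_base = 20, covarying_base = 10,
                          base_meanlog = log(15), base_sdlog = 0.25,
                          transgene = "hgMYC",
                          transgene_rates = c(luminal = 0.6, basal = 0.18,
                                              hematopoietic = 0.09),
                          dispersion = 20, seed = 1L) {
  if (abs(sum(populations) - 1) > 1e-8)
    stop_pausekit("population proportions must sum to 1")
  if (any(transgene_rates < 0 | transgene_rates > 1))
    stop_pausekit("transgene rates must be in [0,1]")
  if (!is.null(transgene) && !all(names(populations) %in% names(transgene_rates)))
    stop_pausekit("transgene_rates must name every population")
  if (dispersion <= 0) stop_pausekit("dispersion must be positive")
  if (!all(is.finite(c(anchor_loading, covarying_loading))))
    stop_pausekit("loadings must be finite")
  structure(as.list(environment()), class = "sc_sim_config")
}

#' Simulate a two-condition single-cell experiment
#'
#' @param config An [sc_sim_config].
#' @return A list with `matrix1`, `matrix2` ([cell_matrix]es, condition tags
#'   `"condition1"`/`"condition2"`) and `truth` (per-gene latent loading in
#'   each condition plus the planted covarying flag).
#' @export
simulate_sc_experiment <- function(config) {
  gene_ids <- c(config$anchor_gene, config$covarying_set,
                sprintf("bg%04d", seq_len(config$n_genes)),
                "mt-Nd1", "mt-Co1",
                if (!is.null(config$transgene)) config$transgene)
  if (anyDuplicated(gene_ids))
    stop_pausekit("gene universe contains duplicate ids")
  with_seed(config$seed, {
    base <- c(config$anchor_base,
              rep(config$covarying_base, length(config$covarying_set)),
              rlnorm(config$n_genes, config$base_meanlog, config$base_sdlog),
              8, 8,  # modest mitochondrial baseline
              if (!is.null(config$transgene)) 0)
    ncell <- config$n_cells_per_condition
    sim_cond <- function(cond) {
      w <- numeric(length(gene_ids))
      w[1] <- config$anchor_loading
      if (cond == 1L)
        w[1 + seq_along(config$covarying_set)] <- config$covarying_loading
      a <- rnorm(ncell)
      mu <- outer(base, rep(1, ncell)) * exp(outer(w, a))
      counts <- matrix(rnbinom(length(mu), size = config$dispersion, mu = mu),
                       nrow = length(gene_ids))
      labels <- sample(names(config$populations), ncell, replace = TRUE,
                       prob = config$populations)
      if (!is.null(config$transgene)) {
        ti <- length(gene_ids)
        on <- rbinom(ncell, 1L, unname(config$transgene_rates[labels]))
        counts[ti, ] <- on * rpois(ncell, 3)
      }
      barcodes <- sprintf("c%d_%05d", cond, seq_len(ncell))
      cell_matrix(counts = Matrix::Matrix(counts, sparse = TRUE),
                  genes = gene_ids, cells = barcodes,
                  cell_labels = labels,
                  condition = paste0("condition", cond))
    }
    m1 <- sim_cond(1L)
    m2 <- sim_cond(2L)
    w1 <- numeric(length(gene_ids)); w1[1] <- config$anchor_loading
    w1[1 + seq_along(config$covarying_set)] <- config$covarying_loading
    w2 <- numeric(length(gene_ids)); w2[1] <- config$anchor_loading
    truth <- data.frame(gene_id = gene_ids, loading_1 = w1, loading_2 = w2,
                        covarying = gene_ids %in% config$covarying_set,
                        stringsAsFactors = FALSE)
    list(matrix1 = m1, matrix2 = m2, truth = truth)
  })
}
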