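# Cohort simulator: two latent signature activities per sample drive (i) a
# rank shift of that signature's genes in a TPM table and (ii) membership in
# one of four hazard quadrants with exponential event times and independent
# exponential censoring.

#' Configuration for the survival-cohort simulator
#'
#' @param n_samples Number of samples.
#' @param n_genes Total genes in the expression table.
#' @param signature_sizes Length-2 vector: genes in the first (AR-like) and
#'   second (MYC-like) signature.
#' @param effect_size Multiplicative log-scale strength with which a sample's
#'   latent score lifts its signature genes' expression.
#' @param group_hazards Named vector of event rates per unit time for the
#'   four quadrant labels `AR_high/MYC_high`, `AR_high/MYC_low`,
#'   `AR_low/MYC_high`, `AR_low/MYC_low`.
#' @param censor_rate Exponential censoring rate (> 0).
#' @param seed Integer seed.
#' @return A list of class `surv_sim_config`.
#' @export
surv_sim_config <- function(n_samples = 200L, n_genes = 2000L,
                            signature_sizes = c(9L, 50L),
                            effect_size = 3,
                            group_hazards = c("AR_high/MYC_high" = 0.10,
                                              "AR_high/MYC_low"  = 0.05,
                                              "AR_low/MYC_high"  = 0.30,
                                              "AR_low/MYC_low"   = 0.10),
                            censor_rate = 0.05, seed = 1L) {
  labels <- c("AR_high/MYC_high", "AR_high/MYC_low",
              "AR_low/MYC_high", "AR_low/MYC_low")
  if (!all(labels %in% names(group_hazards)))
    stop_pausekit("group_hazards must name all four quadrant labels")
  if (any(group_hazards <= 0)) stop_pausekit("all hazards must be > 0")
  if (censor_rate <= 0) stop_pausekit("censor_rate must be > 0")
  if (length(signature_sizes) != 2L || any(signature_sizes < 2L))
    stop_pausekit("signature_sizes must be two counts >= 2")
  if (sum(signature_sizes) > n_genes)
    stop_pausekit("signature_sizes exceed n_genes")
  structure(as.list(environment()), class = "surv_sim_config")
}

#' Simulate an expression + survival cohort with quadrant ground truth
#'
#' Latent scores `u_ar`, `u_myc ~ Unif(0,1)` per sample; "high" means
#' `u > 0.5`. Signature genes' TPM is multiplied by
#' `exp(effect_size * (u - 0.5))` so rank-based signature scores increase
#' monotonically with the latent score. Event times are exponential with the
#' quadrant hazard, censoring is exponential with `censor_rate`, and the
#' observed time is the minimum (floored away from zero).
#'
#' @param config A [surv_sim_config].
#' @return A list with `expression` (genes x samples TPM matrix),
#'   `signatures` (list of two [signature]s, `AR_sim` and `MYC_sim`),
#'   `survival` (`sample_id`, `time`, `event`) and `truth` (latent scores
#'   and quadrant label per sample).
#' @export
simulate_survival_cohort <- function(config) {
  with_seed(config$seed, {
    n <- config$n_samples
    ids <- sprintf("s%04d", seq_len(n))
    u_ar <- runif(n); u_myc <- runif(n)
    grp <- paste0(ifelse(u_ar > 0.5, "AR_high", "AR_low"), "/",
                  ifelse(u_myc > 0.5, "MYC_high", "MYC_low"))
    sig1 <- seq_len(config$signature_sizes[1])
    sig2 <- config$signature_sizes[1] + seq_len(config$signature_sizes[2])
    gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
    base <- rlnorm(config$n_genes, meanlog = 2, sdlog = 1)
    noise <- matrix(rlnorm(config$n_genes * n, 0, 0.4), config$n_genes, n)
    expr <- base * noise
    expr[sig1, ] <- expr[sig1, , drop = FALSE] *
      rep(exp(config$effect_size * (u_ar - 0.5)), each = length(sig1))
    expr[sig2, ] <- expr[sig2, , drop = FALSE] *
      rep(exp(config$effect_size * (u_myc - 0.5)), each = length(sig2))
    # TPM: rescale each sample to a million
    expr <- sweep(expr, 2, colSums(expr), "/") * 1e6
    dimnames(expr) <- list(gene_ids, ids)
    haz <- unname(config$group_hazards[grp])
    t_event <- rexp(n, haz)
    t_cens <- rexp(n, config$censor_rate)
    time <- pmax(pmin(t_event, t_cens), 1e-6)
    event <- as.integer(t_event <= t_cens)
    list(expression = expr,
         signatures = list(
           AR_sim = signature("AR_sim", gene_ids[sig1]),
           MYC_sim = signature("MYC_sim", gene_ids[sig2])),
         survival = data.frame(sample_id = ids, time = time, event = event,
                               stringsAsFactors = FALSE),
         truth = data.frame(sample_id = ids, u_ar = u_ar, u_myc = u_myc,
                            group = grp, stringsAsFactors = FALSE))
  })
}
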