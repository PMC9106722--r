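# Rank-based signature scoring, maximally selected log-rank cutpoints,
# quadrant group assignment and Kaplan-Meier / log-rank testing.

#' Construct a gene signature
#'
#' @param name Signature name.
#' @param gene_ids Character vector of (up-regulated) gene ids.
#' @return A list of class `signature`.
#' @export
signature <- function(name, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (!length(gene_ids)) stop_pausekit("signature must be non-empty")
  structure(list(name = name, gene_ids = gene_ids), class = "signature")
}

#' The nine-gene AR-A signature of canonical AR transcriptional targets
#' @return A [signature] with genes KLK3, KLK2, FKBP5, STEAP1, STEAP2,
#'   PPAP2A, RAB3B, ACSL3, NKX3-1.
#' @export
ar_a_signature <- function() {
  signature("AR-A", c("KLK3", "KLK2", "FKBP5", "STEAP1", "STEAP2",
                      "PPAP2A", "RAB3B", "ACSL3", "NKX3-1"))
}

#' Rank-based signature score per sample
#'
#' Within each sample all genes are ranked ascending by expression (mean
#' ranks for ties); the mean rank of the signature genes is rescaled to
#' `[0, 1]` between its theoretical minimum `(n_sig + 1)/2` (signature at
#' the bottom ranks) and maximum `(2N - n_sig + 1)/2` (at the top), making
#' the score invariant to any monotone transform of the expression vector.
#' Signature genes missing from the table are dropped with a warning; fewer
#' than two present is an error.
#'
#' @param expression genes x samples numeric matrix (e.g. TPM) with row and
#'   column names.
#' @param sig A [signature].
#' @return Data frame: `sample_id`, `score` in `[0, 1]`.
#' @examples
#' expr <- matrix(c(5, 1, 4, 2, 3), ncol = 1,
#'                dimnames = list(paste0("g", 1:5), "s1"))
#' signature_score(expr, signature("demo", c("g3", "g5")))
#' @export
signature_score <- function(expression, sig) {
  present <- intersect(sig$gene_ids, rownames(expression))
  missing <- setdiff(sig$gene_ids, rownames(expression))
  if (length(missing))
    warning(sprintf("signature %s: missing gene expression data for %s",
                    sig$name, paste(missing, collapse = ", ")))
  if (length(present) < 2L)
    stop_pausekit(sprintf(
      "signature %s: fewer than 2 genes present in the expression table",
      sig$name))
  N <- nrow(expression)
  k <- length(present)
  lo <- (k + 1) / 2
  hi <- (2 * N - k + 1) / 2
  score <- apply(expression, 2, function(v) {
    r <- rank(v, ties.method = "average")
    (mean(r[present]) - lo) / (hi - lo)
  })
  data.frame(sample_id = colnames(expression), score = unname(score),
             stringsAsFactors = FALSE)
}

# standardized two-group log-rank statistic Z = sum(O-E)/sqrt(sum(V)) for
# group membership `g` (logical); ties handled hypergeometrically
logrank_z <- function(time, event, g) {
  ut <- sort(unique(time))
  idx <- match(time, ut)
  K <- length(ut)
  n_at <- rev(cumsum(rev(tabulate(idx, K))))
  n1_at <- rev(cumsum(rev(tabulate(idx[g], K))))
  d <- tabulate(idx[event == 1], K)
  d1 <- tabulate(idx[event == 1 & g], K)
  keep <- d > 0 & n_at >= 2
  if (!any(keep)) return(NA_real_)
  n <- n_at[keep]; n1 <- n1_at[keep]; dk <- d[keep]; d1k <- d1[keep]
  OE <- sum(d1k - dk * n1 / n)
  V <- sum(dk * (n1 / n) * (1 - n1 / n) * (n - dk) / (n - 1))
  if (V <= 0) return(NA_real_)
  OE / sqrt(V)
}

#' Maximally selected log-rank cutpoint for a score
#'
#' Evaluates every distinct score value whose empirical quantile lies inside
#' `quantile_range` as a candidate low/high split (high: score strictly
#' above the candidate), computes the standardized two-group log-rank
#' statistic at each, and returns the candidate maximizing its absolute
#' value (ties: the smaller cutpoint). No multiple-testing correction is
#' applied to the reported statistic; the cutpoint is used only to form
#' groups.
#'
#' @param scores Data frame (`sample_id`, `score`) from [signature_score()],
#'   or a named numeric vector.
#' @param surv Data frame with `sample_id`, `time`, `event`.
#' @param quantile_range Candidate quantile window (default `c(0.10, 0.90)`).
#' @return A list of class `maxstat_cut`: `value`, `statistic` (absolute
#'   standardized log-rank), `n_candidates`.
#' @export
maxstat_cutpoint <- function(scores, surv, quantile_range = c(0.10, 0.90)) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$sample_id)
  idx <- match(names(scores), surv$sample_id)
  if (anyNA(idx))
    stop_pausekit("samples missing from survival table")
  time <- surv$time[idx]; event <- surv$event[idx]
  if (sum(event) == 0L) stop_pausekit("zero events: cutpoint undefined")
  s <- unname(scores)
  cand <- sort(unique(s))
  q <- vapply(cand, function(v) mean(s <= v), 0)
  cand <- cand[q >= quantile_range[1] & q <= quantile_range[2] & q < 1]
  # a candidate must leave events on both sides
  valid <- vapply(cand, function(v)
    sum(event[s <= v]) > 0 && sum(event[s > v]) > 0, TRUE)
  cand <- cand[valid]
  if (!length(cand))
    stop_pausekit("no valid cutpoint candidate in the quantile range")
  z <- vapply(cand, function(v) abs(logrank_z(time, event, s > v)), 0)
  best <- which(z == max(z, na.rm = TRUE))[1]  # cand sorted: first = smallest
  structure(list(value = cand[best], statistic = z[best],
                 n_candidates = length(cand)),
            class = "maxstat_cut")
}

#' Assign samples to AR x MYC quadrant groups
#'
#' A sample is "high" for a signature when its score is strictly greater
#' than that signature's cutpoint value.
#'
#' @param ar_scores,myc_scores Score data frames from [signature_score()].
#' @param ar_cut,myc_cut [maxstat_cutpoint()] results (or numeric values).
#' @return Data frame: `sample_id`, `group` with levels
#'   `AR_high/MYC_high`, `AR_high/MYC_low`, `AR_low/MYC_high`,
#'   `AR_low/MYC_low`.
#' @export
assign_quadrant_groups <- function(ar_scores, myc_scores, ar_cut, myc_cut) {
  av <- if (is.list(ar_cut)) ar_cut$value else ar_cut
  mv <- if (is.list(myc_cut)) myc_cut$value else myc_cut
  m <- merge(ar_scores, myc_scores, by = "sample_id",
             suffixes = c("_ar", "_myc"), all = TRUE)
  miss <- m$sample_id[!complete.cases(m)]
  if (length(miss))
    stop_pausekit(sprintf("sample(s) missing a score: %s",
                          paste(miss, collapse = ", ")))
  grp <- paste0(ifelse(m$score_ar > av, "AR_high", "AR_low"), "/",
                ifelse(m$score_myc > mv, "MYC_high", "MYC_low"))
  lv <- c("AR_high/MYC_high", "AR_high/MYC_low",
          "AR_low/MYC_high", "AR_low/MYC_low")
  out <- data.frame(sample_id = m$sample_id,
                    group = factor(grp, levels = lv),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id), , drop = FALSE]
}

#' Kaplan-Meier curves and k-group log-rank test
#'
#' Product-limit estimates per group (deaths precede censorings at tied
#' times, the standard convention) and the k-group log-rank chi-square with
#' `k - 1` degrees of freedom, via the survival package. Optional pairwise
#' log-rank tests on group subsets.
#'
#' @param cohort Data frame with `time`, `event`, `group` (and optionally
#'   `sample_id`).
#' @param pairwise Also compute all pairwise log-rank tests.
#' @return A list of class `km_logrank`: `curves` (group, time, n_risk,
#'   n_event, survival), `chisq`, `df`, `p_value`, and `pairwise` (data
#'   frame or `NULL`).
#' @export
km_logrank <- function(cohort, pairwise = FALSE) {
  grp <- droplevels(factor(cohort$group))
  if (nlevels(grp) < 2L) stop_pausekit("need at least 2 groups")
  if (sum(cohort$event) == 0L) stop_pausekit("zero events")
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = data.frame(time = cohort$time,
                                             event = cohort$event,
                                             group = grp))
  sm <- summary(fit, censored = TRUE)
  gname <- if (!is.null(sm$strata)) sub("^group=", "", as.character(sm$strata))
           else rep(levels(grp)[1], length(sm$time))
  curves <- data.frame(group = gname, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = data.frame(time = cohort$time,
                                             event = cohort$event,
                                             group = grp))
  df <- nlevels(grp) - 1L
  p <- pchisq(sd$chisq, df = df, lower.tail = FALSE)
  pw <- NULL
  if (pairwise) {
    cmb <- utils::combn(levels(grp), 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      sel <- grp %in% cmb[, i]
      sdi <- survival::survdiff(survival::Surv(time, event) ~ group,
                                data = data.frame(time = cohort$time[sel],
                                                  event = cohort$event[sel],
                                                  group = droplevels(grp[sel])))
      data.frame(group1 = cmb[1, i], group2 = cmb[2, i], chisq = sdi$chisq,
                 p_value = pchisq(sdi$chisq, 1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(curves = curves, chisq = unname(sd$chisq), df = df,
                 p_value = p, pairwise = pw),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chisq = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Read an expression TSV (genes x samples)
#' @param path TSV with a `gene_id` first column and one column per sample.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an expression matrix as TSV
#' @param expression genes x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
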