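# Traveling-ratio scoring and tangent-based pause-gene classification.
#
# TR = promoter density / gene-body density (per-bp BPM on both sides), so
# TR >> 1 marks promoter-proximal Pol II accumulation. The condition
# difference Delta = TR(condition 1) - TR(condition 2) is ranked ascending;
# on the unit-square rescaling of that curve the points where a slope-1 line
# is tangent mark where the difference "takes off" in each tail, and genes
# beyond them are called pause (lower tail: TR gained in condition 2) or
# pause-release (upper tail: TR lost in condition 2).

#' Per-gene traveling-ratio table
#'
#' Computes promoter and gene-body densities (mean per-base coverage per
#' million mapped fragments) and their ratio for every gene. Genes whose
#' body is empty, whose body density is not above `min_body_density`, or
#' whose promoter density falls below `min_promoter_density` are retained
#' but flagged ineligible with a reason (`empty_body`, `zero_body_density`,
#' `low_promoter`); no pseudocount is used.
#'
#' @param track A [coverage_track].
#' @param genes A [gene_models] data frame.
#' @param min_promoter_density Minimum promoter density for eligibility
#'   (default 0: any signal).
#' @param min_body_density Body density must be strictly greater than this
#'   (default 0).
#' @param upstream,downstream Promoter window around the TSS, in bp.
#' @return A data frame of class `tr_table`: `gene_id`, `promoter_density`,
#'   `body_density`, `tr`, `eligible`, `reason`.
#' @export
compute_tr_table <- function(track, genes, min_promoter_density = 0,
                             min_body_density = 0,
                             upstream = 30L, downstream = 300L) {
  regions <- gene_regions(genes, upstream = upstream, downstream = downstream,
                          chrom_sizes = track$chrom_sizes)
  n <- nrow(regions)
  prom <- rep(NA_real_, n); body <- rep(NA_real_, n)
  ok <- regions$prom_end > regions$prom_start
  prom[ok] <- region_density(track, data.frame(
    chrom = regions$chrom[ok], start = regions$prom_start[ok],
    end = regions$prom_end[ok]))
  hasbody <- regions$eligible
  body[hasbody] <- region_density(track, data.frame(
    chrom = regions$chrom[hasbody], start = regions$body_start[hasbody],
    end = regions$body_end[hasbody]))
  reason <- character(n)
  reason[!hasbody] <- "empty_body"
  zb <- hasbody & body <= min_body_density
  reason[zb] <- "zero_body_density"
  lp <- hasbody & !zb & prom < min_promoter_density
  reason[lp] <- "low_promoter"
  eligible <- reason == ""
  if (!any(eligible))
    stop_pausekit(paste("no eligible genes; consider lowering",
                        "min_promoter_density/min_body_density"))
  tr <- ifelse(eligible, prom / body, NA_real_)
  out <- data.frame(gene_id = regions$gene_id, promoter_density = prom,
                    body_density = body, tr = tr, eligible = eligible,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("tr_table", "data.frame")
  out
}

#' Ranked traveling-ratio difference curve
#'
#' Delta = TR in table 1 minus TR in table 2, over genes eligible in both,
#' sorted ascending (ties broken by gene id for determinism). Both axes are
#' rescaled to the unit interval: `scaled_x = (rank-1)/(n-1)`,
#' `scaled_y = (delta - min) / (max - min)`.
#'
#' @param tr1,tr2 [compute_tr_table()] outputs for the two conditions.
#' @return A data frame of class `ranked_curve` with attribute `degenerate`
#'   set when all deltas are equal (cutpoints unavailable).
#' @export
tr_difference_curve <- function(tr1, tr2) {
  e1 <- tr1[tr1$eligible, c("gene_id", "tr")]
  e2 <- tr2[tr2$eligible, c("gene_id", "tr")]
  m <- merge(e1, e2, by = "gene_id", suffixes = c("_1", "_2"))
  if (nrow(m) < 3L)
    stop_pausekit(sprintf(
      "only %d gene(s) eligible in both conditions; need >= 3", nrow(m)))
  delta <- m$tr_1 - m$tr_2
  o <- order(delta, m$gene_id)
  m <- m[o, ]; delta <- delta[o]
  n <- length(delta)
  rng <- range(delta)
  degenerate <- rng[2] - rng[1] <= 0
  curve <- data.frame(rank = seq_len(n), gene_id = m$gene_id, delta = delta,
                      scaled_x = (seq_len(n) - 1) / (n - 1),
                      scaled_y = if (degenerate) rep(NA_real_, n)
                                 else (delta - rng[1]) / (rng[2] - rng[1]),
                      stringsAsFactors = FALSE)
  rownames(curve) <- NULL
  attr(curve, "degenerate") <- degenerate
  class(curve) <- c("ranked_curve", "data.frame")
  curve
}

# Local slope of the unit-scaled curve by centered finite differences over a
# symmetric window (truncated symmetrically at the edges; one-sided at the
# very ends). Symmetric truncation keeps slopes mirror-invariant, which the
# condition-swap antisymmetry of the classifier relies on.
curve_slopes <- function(x, y, smooth_window) {
  n <- length(x)
  h <- (smooth_window - 1L) %/% 2L
  i <- seq_len(n)
  hi <- pmin(h, i - 1L, n - i)
  lo_i <- pmax(i - hi, 1L); hi_i <- pmin(i + hi, n)
  onesided <- hi == 0L
  lo_i[onesided] <- pmax(i[onesided] - 1L, 1L)
  hi_i[onesided] <- pmin(i[onesided] + 1L, n)
  (y[hi_i] - y[lo_i]) / (x[hi_i] - x[lo_i])
}

#' Tangent-slope-1 cutpoints on a ranked difference curve
#'
#' On the unit-scaled curve the local slope is estimated by centered finite
#' differences over `smooth_window` points. The upper cutpoint is the first
#' index in the upper half of the curve opening a persistent run (length at
#' least `smooth_window`, or reaching the curve end) of slopes above 1 -- the
#' point where a slope-1 line is tangent as the curve takes off; the lower
#' cutpoint is the mirror image: the last index in the lower half closing a
#' persistent slope-above-1 run. A missing crossing yields an `NA` cutpoint.
#'
#' @param curve A `ranked_curve` from [tr_difference_curve()], or any data
#'   frame with `scaled_x` and `scaled_y` columns.
#' @param smooth_window Odd window (>= 3) for slope estimation and the
#'   persistence requirement.
#' @return A list of class `tangent_cuts`: `cut_lo`, `cut_hi` (rank indices
#'   or `NA`), `slope` (per-index estimates) and `smooth_window`.
#' @export
tangent_cutpoints <- function(curve, smooth_window = 11L) {
  if (isTRUE(attr(curve, "degenerate")) || all(is.na(curve$scaled_y)))
    stop_pausekit("degenerate curve (all deltas equal): cutpoints unavailable")
  n <- nrow(curve)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 3L || smooth_window %% 2L == 0L)
    stop_pausekit("smooth_window must be an odd integer >= 3")
  if (n < 2L * smooth_window)
    stop_pausekit("curve too short for the smoothing window")
  slope <- curve_slopes(curve$scaled_x, curve$scaled_y, smooth_window)
  steep <- slope > 1
  half <- n / 2
  w <- smooth_window
  # upper: first index i > half with steep[i], !steep[i-1], and steep
  # persisting over the next w-1 indices (or to the end)
  cut_hi <- NA_integer_
  for (i in seq_len(n)) {
    if (i <= half || !steep[i]) next
    if (i > 1L && steep[i - 1L]) next
    run_end <- min(n, i + w - 1L)
    if (all(steep[i:run_end])) { cut_hi <- i; break }
  }
  # lower: last index i <= half with steep[i], !steep[i+1], persistence
  # over the preceding w-1 indices (or from the start)
  cut_lo <- NA_integer_
  for (i in rev(seq_len(n))) {
    if (i > half || !steep[i]) next
    if (i < n && steep[i + 1L]) next
    run_start <- max(1L, i - w + 1L)
    if (all(steep[run_start:i])) { cut_lo <- i; break }
  }
  if (is.na(cut_lo) && is.na(cut_hi))
    warning("no slope-1 tangent found in either tail; classes will be empty")
  structure(list(cut_lo = cut_lo, cut_hi = cut_hi, slope = slope,
                 smooth_window = w),
            class = "tangent_cuts")
}

#' Classify pause and pause-release genes
#'
#' Pause-release genes lie strictly above the delta value at the upper
#' cutpoint (TR lost in condition 2); pause genes lie strictly below the
#' delta at the lower cutpoint (TR gained in condition 2). An absent
#' cutpoint yields an empty class.
#'
#' @param curve A `ranked_curve`.
#' @param cuts A `tangent_cuts` object from [tangent_cutpoints()].
#' @return A list of class `pause_classes`: `pause_release`, `pause`
#'   (character vectors of gene ids), `cut_lo`, `cut_hi`.
#' @export
classify_pause_genes <- function(curve, cuts) {
  pr <- character(); pa <- character()
  if (!is.na(cuts$cut_hi))
    pr <- curve$gene_id[curve$delta > curve$delta[cuts$cut_hi]]
  if (!is.na(cuts$cut_lo))
    pa <- curve$gene_id[curve$delta < curve$delta[cuts$cut_lo]]
  structure(list(pause_release = pr, pause = pa,
                 cut_lo = cuts$cut_lo, cut_hi = cuts$cut_hi),
            class = "pause_classes")
}

#' @export
print.pause_classes <- function(x, ...) {
  cat(sprintf("<pause_classes> %d pause-release, %d pause gene(s)\n",
              length(x$pause_release), length(x$pause)))
  invisible(x)
}

#' Compare a gene set's TR distributions between conditions
#'
#' Two-sided two-sample test on the TR values of the set's eligible genes in
#' each condition. `KS` uses the exact two-sample Kolmogorov-Smirnov null
#' distribution when `n1 * n2 <= 1e4` (asymptotic otherwise); `Welch-t` is
#' the unequal-variance t test.
#'
#' @param tr1,tr2 [compute_tr_table()] outputs.
#' @param gene_set Character vector of gene ids (`NULL`: all genes).
#' @param test `"KS"` or `"Welch-t"`.
#' @return A list of class `geneset_comparison`: `statistic`, `p_value`,
#'   `n1`, `n2`, `test`, `gene_set_name`.
#' @export
compare_geneset_tr <- function(tr1, tr2, gene_set = NULL,
                               test = c("KS", "Welch-t"),
                               gene_set_name = "gene_set") {
  test <- match.arg(test)
  v1 <- tr1$tr[tr1$eligible]
  names(v1) <- tr1$gene_id[tr1$eligible]
  v2 <- tr2$tr[tr2$eligible]
  names(v2) <- tr2$gene_id[tr2$eligible]
  if (!is.null(gene_set)) {
    v1 <- v1[names(v1) %in% gene_set]
    v2 <- v2[names(v2) %in% gene_set]
  }
  if (length(v1) < 3L || length(v2) < 3L)
    stop_pausekit(sprintf(
      "need >= 3 eligible set genes per condition (have %d and %d)",
      length(v1), length(v2)))
  if (test == "KS") {
    exact <- length(v1) * length(v2) <= 1e4
    ht <- suppressWarnings(ks.test(unname(v1), unname(v2), exact = exact))
  } else {
    ht <- t.test(unname(v1), unname(v2), var.equal = FALSE)
  }
  structure(list(gene_set_name = gene_set_name, test = test,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 n1 = length(v1), n2 = length(v2)),
            class = "geneset_comparison")
}

#' Write a TR table to TSV
#' @param tr A `tr_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tr_table <- function(tr, path) write_tsv(as.data.frame(tr), path)

#' Read a TR table from TSV
#' @param path Path written by [write_tr_table()].
#' @return A `tr_table` data frame.
#' @export
read_tr_table <- function(path) {
  df <- read_tsv(path)
  df$reason[is.na(df$reason)] <- ""
  class(df) <- c("tr_table", "data.frame")
  df
}

#' Read a gene set (GMT or one id per line)
#' @param path File path. GMT lines are `name<TAB>desc<TAB>gene...`.
#' @param name For GMT input, the set to extract (default: first).
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (any(grepl("\t", lines))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- setNames(lapply(parts, function(p) p[-(1:2)]),
                     vapply(parts, `[[`, "", 1L))
    if (is.null(name)) name <- names(sets)[1]
    if (!name %in% names(sets))
      stop_pausekit(sprintf("gene set %s not found in %s", name, path))
    sets[[name]]
  } else lines
}
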