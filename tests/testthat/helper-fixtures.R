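# Shared fixtures built in code.

# A uniform-coverage track over one chromosome.
uniform_track <- function(len = 10000L, value = 2, total = 1e6) {
  coverage_track(list(chr1 = S4Vectors::Rle(value, len)),
                 total_fragments = total)
}

# A tiny deterministic gene set on chr1.
toy_genes <- function() {
  gene_models(c("gp", "gm"), "chr1", c(1000L, 5000L), c(5000L, 8000L),
              c("+", "-"))
}

# A tr_table built directly from TR values (all eligible).
tr_table_from_values <- function(tr, gene_id = NULL) {
  gene_id <- gene_id %||% sprintf("g%03d", seq_along(tr))
  out <- data.frame(gene_id = gene_id, promoter_density = tr,
                    body_density = 1, tr = tr, eligible = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  class(out) <- c("tr_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A ranked_curve-shaped object from explicit x/y grids (already unit scaled).
curve_from_xy <- function(x, y, delta = NULL) {
  n <- length(x)
  curve <- data.frame(rank = seq_len(n),
                      gene_id = sprintf("g%05d", seq_len(n)),
                      delta = delta %||% y, scaled_x = x, scaled_y = y,
                      stringsAsFactors = FALSE)
  attr(curve, "degenerate") <- FALSE
  class(curve) <- c("ranked_curve", "data.frame")
  curve
}

# Small labeled cell_matrix with exact positive counts per population,
# transgene in row "tg" (first n_positive cells of each population positive).
census_matrix <- function(pop_sizes, pop_positive, n_genes = 250L) {
  total <- sum(pop_sizes)
  set.seed(42)
  counts <- matrix(rpois(n_genes * total, 5), nrow = n_genes)
  tg <- unlist(mapply(function(n, k) c(rep(1L, k), rep(0L, n - k)),
                      pop_sizes, pop_positive, SIMPLIFY = FALSE))
  counts <- rbind(counts, tg)
  genes <- c(sprintf("g%04d", seq_len(n_genes)), "tg")
  labels <- rep(names(pop_sizes), pop_sizes)
  cell_matrix(counts, genes, sprintf("c%04d", seq_len(total)), labels)
}

# Brute-force slope-1 crossing oracle: raw adjacent-point slopes, first
# upper-half index whose slope exceeds 1 with all later slopes above 1 too
# (for monotone-convex curves).
brute_force_upper_crossing <- function(x, y) {
  n <- length(x)
  slope <- c(NA, diff(y) / diff(x))
  for (i in seq(ceiling(n / 2) + 1L, n)) {
    if (!is.na(slope[i]) && slope[i] > 1 && all(slope[i:n] > 1, na.rm = TRUE))
      return(i)
  }
  NA_integer_
}
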