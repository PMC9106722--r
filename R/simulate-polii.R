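# Two-condition Pol II coverage simulator with planted pausing shifts.
#
# Per gene, each condition draws Poisson(reads_per_gene_mean) fragments; a
# fragment falls in the promoter window with the gene's condition-specific
# pause fraction, else in the gene body, and is placed uniformly within that
# region (clipped at the region end). The planted pause fraction is therefore
# exactly the expected promoter fragment share, making planted deltas
# directly interpretable as traveling-ratio shifts.

#' Configuration for the Pol II pausing simulator
#'
#' @param n_genes Number of genes.
#' @param chrom_length Chromosome length in bp.
#' @param gene_length_range Length-2 vector of min/max gene length (bp);
#'   minimum must be at least 331 bp so the gene body is non-empty.
#' @param reads_per_gene_mean Poisson mean of fragments per gene per condition.
#' @param pause_fraction_baseline Baseline promoter fragment share in `[0,1]`.
#' @param planted_pause_release Named numeric vector: gene ids whose pause
#'   fraction changes in condition 2 by a negative delta (pause release).
#' @param planted_pause Named numeric vector: gene ids with a positive
#'   condition-2 delta (increased pausing).
#' @param fragment_length Fixed fragment length in bp.
#' @param library_size Number of additional background fragments scattered
#'   uniformly over the chromosome per condition (noise floor; 0 disables).
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return A list of class `polii_sim_config`.
#' @export
polii_sim_config <- function(n_genes = 3000L, chrom_length = NULL,
                             gene_length_range = c(2000L, 4000L),
                             reads_per_gene_mean = 500,
                             pause_fraction_baseline = 0.55,
                             planted_pause_release = numeric(),
                             planted_pause = numeric(),
                             fragment_length = 200L,
                             library_size = 0L, seed = 1L) {
  if (length(gene_length_range) != 2L || gene_length_range[1] > gene_length_range[2])
    stop_pausekit("gene_length_range must be an increasing length-2 vector")
  if (gene_length_range[1] < 331L)
    stop_pausekit("minimum gene length must be >= 331 bp (non-empty body)")
  if (pause_fraction_baseline < 0 || pause_fraction_baseline > 1)
    stop_pausekit("pause_fraction_baseline must be in [0,1]")
  overlap <- intersect(names(planted_pause_release), names(planted_pause))
  if (length(overlap))
    stop_pausekit(sprintf("planted sets must be disjoint; shared: %s",
                          paste(overlap, collapse = ", ")))
  deltas <- c(planted_pause_release, planted_pause)
  if (length(deltas)) {
    shifted <- pause_fraction_baseline + deltas
    if (any(shifted < 0 | shifted > 1))
      stop_pausekit("planted deltas push pause fractions outside [0,1]")
  }
  if (is.null(chrom_length)) {
    # room for all genes plus inter-gene gaps
    chrom_length <- as.integer(ceiling(n_genes * (gene_length_range[2] + 1000) * 1.2)) + 10000L
  }
  structure(list(n_genes = as.integer(n_genes),
                 chrom_length = as.integer(chrom_length),
                 gene_length_range = as.integer(gene_length_range),
                 reads_per_gene_mean = reads_per_gene_mean,
                 pause_fraction_baseline = pause_fraction_baseline,
                 planted_pause_release = planted_pause_release,
                 planted_pause = planted_pause,
                 fragment_length = as.integer(fragment_length),
                 library_size = as.integer(library_size),
                 seed = as.integer(seed)),
            class = "polii_sim_config")
}

#' Simulate non-overlapping gene models
#'
#' Genes are laid left to right on a single chromosome with random uniform
#' lengths and inter-gene gaps, random strands, and at least 500 bp between
#' consecutive genes.
#'
#' @param config A [polii_sim_config].
#' @return A [gene_models] data frame (`g0001`, `g0002`, ... in coordinate
#'   order); deterministic for a fixed seed.
#' @export
simulate_gene_models <- function(config) {
  n <- config$n_genes
  if (n == 0L)
    return(gene_models(character(), character(), integer(), integer(), character()))
  with_seed(config$seed, {
    len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                  n, replace = TRUE)
    min_gap <- 500L
    required <- sum(len) + (n + 1L) * min_gap
    if (required > config$chrom_length)
      stop_pausekit(sprintf(
        "chrom_length %d too small: need >= %d bp for %d genes",
        config$chrom_length, required, n))
    slack <- config$chrom_length - required
    # distribute the slack over the n+1 gaps uniformly at random
    cuts <- sort(sample.int(slack + 1L, n + 1L, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    gaps <- min_gap + extra[seq_len(n + 1L)]
    start <- cumsum(gaps[seq_len(n)]) + cumsum(c(0L, len[-n]))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    width <- max(5L, nchar(as.character(n)))
    ids <- sprintf(paste0("g%0", width, "d"), seq_len(n))
    gene_models(ids, "chrS", start, start + len, strand)
  })
}

#' Simulate a two-condition Pol II coverage experiment
#'
#' @param genes Gene models from [simulate_gene_models()] (or compatible).
#' @param config A [polii_sim_config].
#' @return A list with `track1`, `track2` ([coverage_track]s),
#'   `fragments1`/`fragments2` (BED-style data frames) and `truth`
#'   (per-gene pause fractions, planted class and realized fragment counts).
#' @export
simulate_polii_experiment <- function(genes, config) {
  if (nrow(genes) == 0L) stop_pausekit("empty gene list")
  chrom_sizes <- c(chrS = config$chrom_length)
  regions <- gene_regions(genes, chrom_sizes = chrom_sizes)
  p1 <- rep(config$pause_fraction_baseline, nrow(genes))
  p2 <- p1
  idx <- match(names(config$planted_pause_release), genes$gene_id)
  if (anyNA(idx)) stop_pausekit("planted_pause_release names absent from genes")
  p2[idx] <- p2[idx] + unname(config$planted_pause_release)
  idx <- match(names(config$planted_pause), genes$gene_id)
  if (anyNA(idx)) stop_pausekit("planted_pause names absent from genes")
  p2[idx] <- p2[idx] + unname(config$planted_pause)
  with_seed(config$seed, {
    sim_one <- function(p) {
      nfrag <- rpois(nrow(genes), config$reads_per_gene_mean)
      gene_i <- rep(seq_len(nrow(genes)), nfrag)
      in_prom <- rbinom(length(gene_i), 1L, p[gene_i]) == 1L
      rs <- ifelse(in_prom, regions$prom_start[gene_i], regions$body_start[gene_i])
      re <- ifelse(in_prom, regions$prom_end[gene_i], regions$body_end[gene_i])
      start <- rs + floor(runif(length(gene_i)) * (re - rs))
      end <- pmin(start + config$fragment_length, re)
      if (config$library_size > 0L) {
        bs <- floor(runif(config$library_size) *
                      (config$chrom_length - config$fragment_length))
        gene_i <- c(gene_i, rep(NA_integer_, config$library_size))
        in_prom <- c(in_prom, rep(NA, config$library_size))
        start <- c(start, bs)
        end <- c(end, bs + config$fragment_length)
      }
      list(frags = data.frame(chrom = "chrS", start = as.integer(start),
                              end = as.integer(end), stringsAsFactors = FALSE),
           gene_i = gene_i, in_prom = in_prom, nfrag = nfrag)
    }
    s1 <- sim_one(p1)
    s2 <- sim_one(p2)
    count_prom <- function(s) {
      ok <- !is.na(s$gene_i)
      nprom <- tabulate(s$gene_i[ok & s$in_prom], nbins = nrow(genes))
      list(n = s$nfrag, nprom = nprom)
    }
    c1 <- count_prom(s1); c2 <- count_prom(s2)
    planted <- rep("none", nrow(genes))
    planted[genes$gene_id %in% names(config$planted_pause_release)] <- "pause_release"
    planted[genes$gene_id %in% names(config$planted_pause)] <- "pause"
    truth <- data.frame(gene_id = genes$gene_id,
                        pause_fraction_1 = p1, pause_fraction_2 = p2,
                        planted_class = planted,
                        n_frag_1 = c1$n, n_frag_2 = c2$n,
                        n_promoter_1 = c1$nprom, n_promoter_2 = c2$nprom,
                        stringsAsFactors = FALSE)
    list(track1 = coverage_from_fragments(s1$frags, chrom_sizes),
         track2 = coverage_from_fragments(s2$frags, chrom_sizes),
         fragments1 = s1$frags, fragments2 = s2$frags,
         truth = truth)
  })
}
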