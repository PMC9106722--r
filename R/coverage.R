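# Coverage tracks: per-base fragment coverage per chromosome plus the total
# mapped-fragment count used for per-million (BPM) scaling.

#' Construct a coverage track
#'
#' @param coverage A named list (or `RleList`) of per-chromosome coverage
#'   vectors/Rles, one value per base.
#' @param total_fragments Library size: number of mapped fragments.
#' @param chrom_sizes Optional named chromosome lengths; defaults to the
#'   lengths of the coverage vectors.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(coverage, total_fragments, chrom_sizes = NULL) {
  if (!methods::is(coverage, "RleList"))
    coverage <- do.call(IRanges::RleList,
                        lapply(as.list(coverage), methods::as, "Rle"))
  if (is.null(names(coverage)) || any(!nzchar(names(coverage))))
    stop_pausekit("coverage chromosomes must be named")
  if (total_fragments < 0) stop_pausekit("total_fragments must be >= 0")
  if (is.null(chrom_sizes))
    chrom_sizes <- setNames(lengths(coverage), names(coverage))
  structure(list(coverage = coverage,
                 total_fragments = as.numeric(total_fragments),
                 chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), %.0f fragments\n",
              length(x$coverage), x$total_fragments))
  invisible(x)
}

#' Per-base coverage from fragment intervals
#'
#' Each fragment contributes 1 to every base it overlaps; the library size is
#' the number of input fragments (the denominator of BPM scaling).
#'
#' @param fragments A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) or a path to a BED3(+) file.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A [coverage_track].
#' @examples
#' fr <- data.frame(chrom = "chr1", start = 100L, end = 300L)
#' tr <- coverage_from_fragments(fr, c(chr1 = 1000L))
#' @export
coverage_from_fragments <- function(fragments, chrom_sizes) {
  if (is.character(fragments) && length(fragments) == 1L)
    fragments <- read_fragments_bed(fragments)
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown))
    stop_pausekit(sprintf("fragment(s) on unknown chromosome(s): %s",
                          paste(unknown, collapse = ", ")))
  n <- nrow(fragments)
  cov <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (!nrow(f)) return(S4Vectors::Rle(0L, len))
    s <- pmax(f$start, 0L)
    e <- pmin(f$end, len)
    keep <- e > s
    ir <- IRanges::IRanges(start = s[keep] + 1L, end = e[keep])
    IRanges::coverage(ir, width = len)
  })
  names(cov) <- names(chrom_sizes)
  coverage_track(methods::as(cov, "RleList"), total_fragments = n,
                 chrom_sizes = chrom_sizes)
}

read_fragments_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
}

#' Write fragments as BED3
#' @param fragments Data frame with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  f <- fragments[order(fragments$chrom, fragments$start, fragments$end), ,
                 drop = FALSE]
  write.table(f[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#' @param track A [coverage_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$coverage)) {
    r <- track$coverage[[ch]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    e <- cumsum(as.numeric(l))
    s <- e - l
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, as.integer(s[keep]),
                         as.integer(e[keep]), v[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph path.
#' @param chrom_sizes Named chromosome lengths.
#' @param total_fragments Library size to attach (bedGraph does not carry it).
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path, chrom_sizes, total_fragments) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    v <- numeric(len)
    if (length(sub)) {
      s <- BiocGenerics::start(sub); e <- BiocGenerics::end(sub)
      sc <- S4Vectors::mcols(sub)$score
      for (k in seq_along(sub)) v[s[k]:e[k]] <- sc[k]
    }
    methods::as(v, "Rle")
  })
  names(cov) <- names(chrom_sizes)
  coverage_track(methods::as(cov, "RleList"), total_fragments, chrom_sizes)
}

#' Read a chrom.sizes file
#' @param path Two-column (name, length) tab-separated file.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  cs <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  setNames(as.integer(cs[[2]]), as.character(cs[[1]]))
}

# sum of coverage over [start, end) on one chromosome
region_sum <- function(track, chrom, start, end) {
  r <- track$coverage[[chrom]]
  if (is.null(r)) stop_pausekit(sprintf("unknown chromosome: %s", chrom))
  v <- IRanges::Views(r, start = start + 1L, end = end)
  sum(v)[1]
}

#' Mean per-base coverage density per million mapped fragments
#'
#' Density = (sum of coverage over the region / region length) x 1e6 /
#' library size -- per-base BPM, the unit in which promoter and gene-body
#' occupancy are comparable.
#'
#' @param track A [coverage_track] with `total_fragments > 0`.
#' @param regions Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return Numeric vector of densities, one per region.
#' @export
region_density <- function(track, regions) {
  if (track$total_fragments <= 0)
    stop_pausekit("library size is zero: densities undefined")
  if (any(regions$end <= regions$start))
    stop_pausekit("empty region(s): end must exceed start")
  unknown <- setdiff(unique(regions$chrom), names(track$coverage))
  if (length(unknown))
    stop_pausekit(sprintf("unknown chromosome(s): %s",
                          paste(unknown, collapse = ", ")))
  dens <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    v <- IRanges::Views(track$coverage[[ch]],
                        start = regions$start[i] + 1L, end = regions$end[i])
    dens[i] <- sum(v) / (regions$end[i] - regions$start[i])
  }
  dens * 1e6 / track$total_fragments
}

#' Metagene occupancy profile
#'
#' Bins each gene into fixed-width flank bins (default +/- 3 kb around TSS
#' and TES) and a fixed number of length-rescaled body bins; minus-strand
#' genes are reversed so every row reads TSS to TES left to right. Values
#' are mean per-base BPM per bin; bases beyond chromosome ends are `NA`.
#'
#' @param track A [coverage_track].
#' @param genes A [gene_models] data frame.
#' @param flank Flank extent in bp (default 3000).
#' @param body_bins Number of bins the gene body is rescaled to.
#' @param flank_bin Flank bin width in bp.
#' @return A list with `matrix` (genes x bins) and `profile` (column means,
#'   `NA` removed).
#' @export
metagene_profile <- function(track, genes, flank = 3000L, body_bins = 100L,
                             flank_bin = 50L) {
  if (flank <= 0 || body_bins <= 0 || flank_bin <= 0)
    stop_pausekit("flank, body_bins and flank_bin must be positive")
  nf <- as.integer(flank / flank_bin)
  ncol_total <- nf + body_bins + nf
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = ncol_total,
              dimnames = list(genes$gene_id, NULL))
  scale <- 1e6 / track$total_fragments
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    r <- track$coverage[[ch]]
    if (is.null(r)) stop_pausekit(sprintf("unknown chromosome: %s", ch))
    len <- length(r)
    from <- genes$start[i] - flank
    to <- genes$end[i] + flank
    v <- rep(NA_real_, to - from)
    lo <- max(from, 0L); hi <- min(to, len)
    if (hi > lo)
      v[(lo - from + 1L):(hi - from)] <- as.numeric(r[(lo + 1L):hi])
    up <- binned_means(v[seq_len(flank)], nf)
    body <- binned_means(v[(flank + 1L):(flank + genes$end[i] - genes$start[i])],
                         body_bins)
    down <- binned_means(v[(length(v) - flank + 1L):length(v)], nf)
    row <- c(up, body, down)
    if (genes$strand[i] == "-") row <- rev(row)
    m[i, ] <- row * scale
  }
  list(matrix = m, profile = colMeans(m, na.rm = TRUE))
}

binned_means <- function(v, nbins) {
  idx <- floor((seq_along(v) - 1L) * nbins / length(v)) + 1L
  out <- rep(NA_real_, nbins)
  agg <- tapply(v, idx, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Select genes within a window of peaks
#'
#' A gene is selected when the minimum distance between its interval and any
#' peak is at most `window` bp (0 when overlapping; the bound is closed).
#'
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes A [gene_models] data frame.
#' @param window Maximum distance in bp (default 100000).
#' @return Data frame of selected genes with their nearest-peak `distance`,
#'   sorted by chrom, start, gene_id.
#' @export
genes_near_peaks <- function(peaks, genes, window = 100000L) {
  if (is.null(peaks) || nrow(peaks) == 0L)
    return(data.frame(gene_id = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hit <- GenomicRanges::distanceToNearest(gn, pk, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hit)
  d <- S4Vectors::mcols(hit)$distance
  keep <- d <= window
  out <- data.frame(gene_id = genes$gene_id[qi][keep],
                    chrom = genes$chrom[qi][keep],
                    start = genes$start[qi][keep],
                    distance = as.integer(d[keep]), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene_id), c("gene_id", "distance")]
  rownames(out) <- NULL
  out
}
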