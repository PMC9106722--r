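# Gene models: strand-aware gene coordinates (0-based half-open) from which
# promoter/body regions derive.

#' Construct a gene-model table
#'
#' Gene models are plain data frames with columns `gene_id`, `chrom`,
#' `start`, `end` (0-based half-open) and `strand` (`"+"`/`"-"`). The TSS is
#' `start` on the plus strand and `end - 1` on the minus strand.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome names.
#' @param start,end Integer coordinates, 0-based half-open (`start < end`).
#' @param strand `"+"` or `"-"` per gene.
#' @return A `data.frame` of class `gene_models`.
#' @examples
#' gene_models("g1", "chr1", 1000L, 5000L, "+")
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    stop_pausekit(sprintf("invalid strand for gene(s): %s",
                          paste(df$gene_id[bad], collapse = ", ")))
  if (any(df$start >= df$end))
    stop_pausekit(sprintf("start >= end for gene(s): %s",
                          paste(df$gene_id[df$start >= df$end], collapse = ", ")))
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop_pausekit(sprintf("duplicate gene_id(s): %s", paste(dup, collapse = ", ")))
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Load gene models from GTF or BED12
#'
#' GTF coordinates (1-based inclusive) are converted to the package's
#' internal 0-based half-open convention; BED is used as-is. For GTF the
#' `gene` feature is taken when present, otherwise genes are assembled as
#' the min-start/max-end union of their transcripts.
#'
#' @param path Path to the annotation file.
#' @param dialect `"GTF"` or `"BED12"`; default guessed from the extension.
#' @return A [gene_models] data frame sorted by chrom, start, gene_id.
#' @export
load_gene_models <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_pausekit(sprintf("annotation file not found: %s", path))
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "GTF" else "BED12"
  }
  dialect <- match.arg(toupper(dialect), c("GTF", "BED12"))
  if (dialect == "GTF") {
    check_gtf_lines(path)
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md) && any(md$type == "gene")) {
      gr <- gr[md$type == "gene"]
    } else if ("type" %in% names(md) && any(md$type == "transcript")) {
      gr <- gr[md$type == "transcript"]
    }
    gid <- as.character(S4Vectors::mcols(gr)$gene_id)
    if (anyNA(gid) || any(gid == ""))
      stop_pausekit("GTF records missing gene_id attribute")
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*"))
      stop_pausekit(sprintf("unknown strand for gene(s): %s",
                            paste(unique(gid[strand == "*"]), collapse = ", ")))
    df <- data.frame(gene_id = gid,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     strand = strand, stringsAsFactors = FALSE)
    if (anyDuplicated(df$gene_id)) {
      # union of transcripts per gene
      chrom1 <- tapply(df$chrom, df$gene_id, function(x) x[1])
      st1 <- tapply(df$strand, df$gene_id, function(x) x[1])
      consistent <- tapply(seq_len(nrow(df)), df$gene_id, function(i)
        length(unique(df$chrom[i])) == 1L && length(unique(df$strand[i])) == 1L)
      if (!all(unlist(consistent)))
        stop_pausekit("gene_id spans multiple chromosomes or strands")
      df <- data.frame(gene_id = names(chrom1), chrom = as.character(chrom1),
                       start = as.integer(tapply(df$start, df$gene_id, min)),
                       end = as.integer(tapply(df$end, df$gene_id, max)),
                       strand = as.character(st1), stringsAsFactors = FALSE)
    }
  } else {
    bed <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(bed) < 6)
      stop_pausekit("BED input needs >= 6 columns (strand required)")
    bad <- which(!bed[[6]] %in% c("+", "-"))
    if (length(bad))
      stop_pausekit(sprintf("unknown strand %s for gene(s): %s",
                            dQuote(bed[[6]][bad[1]]),
                            paste(bed[[4]][bad], collapse = ", ")))
    df <- data.frame(gene_id = as.character(bed[[4]]),
                     chrom = as.character(bed[[1]]),
                     start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
                     strand = as.character(bed[[6]]), stringsAsFactors = FALSE)
  }
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  gene_models(df$gene_id, df$chrom, df$start, df$end, df$strand)
}

# fast structural scan so malformed lines are reported with their number
check_gtf_lines <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8)) {
    ln <- which(body)[which(nfield < 8)[1]]
    stop_pausekit(sprintf("malformed GTF line %d: expected >= 8 tab-separated fields", ln))
  }
  invisible(TRUE)
}

#' Write gene models as BED12
#'
#' @param genes A [gene_models] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  g <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  len <- g$end - g$start
  bed <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
                    g$start, g$end, "0,0,0", 1L, paste0(len, ","), "0,")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' TSS positions of gene models
#'
#' @param genes A [gene_models] data frame.
#' @return Integer vector: `start` for plus-strand genes, `end - 1` for minus.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Derive promoter and gene-body regions
#'
#' The promoter window spans `-upstream` to `+downstream` around the TSS in
#' the direction of transcription (default \eqn{-30}/\eqn{+300} bp, a 330 bp
#' window); the gene body is the remaining gene length downstream of the
#' promoter. Genes too short to have a non-empty body are flagged ineligible
#' rather than erroring.
#'
#' @param genes A [gene_models] data frame.
#' @param upstream,downstream Promoter extent around the TSS, in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   clip promoters at chromosome edges.
#' @return A data frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   promoter and body intervals (0-based half-open) and an `eligible` flag
#'   with `reason` `"empty_body"` where the body is empty.
#' @examples
#' g <- gene_models(c("a", "b"), "chr1", c(1000L, 5000L), c(5000L, 8000L),
#'                  c("+", "-"))
#' gene_regions(g)
#' @export
gene_regions <- function(genes, upstream = 30L, downstream = 300L,
                         chrom_sizes = NULL) {
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  prom_end   <- ifelse(plus, tss + downstream, tss + upstream + 1L)
  body_start <- ifelse(plus, tss + downstream, genes$start)
  body_end   <- ifelse(plus, genes$end, tss - downstream + 1L)
  prom_start <- pmax(prom_start, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[genes$chrom])
    if (anyNA(lim))
      stop_pausekit(sprintf("chromosome(s) missing from chrom_sizes: %s",
                            paste(unique(genes$chrom[is.na(lim)]), collapse = ", ")))
    prom_end <- pmin(prom_end, lim)
  }
  eligible <- body_end > body_start
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand,
             prom_start = as.integer(prom_start), prom_end = as.integer(prom_end),
             body_start = as.integer(body_start), body_end = as.integer(body_end),
             eligible = eligible,
             reason = ifelse(eligible, "", "empty_body"),
             stringsAsFactors = FALSE)
}
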