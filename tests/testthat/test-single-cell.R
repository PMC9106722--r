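# QC filtering, normalization, covariance shift, census, concordance.

test_that("QC keeps boundary cells and reports removal reasons", {
  # 4 cells: ok, low genes, high mito, exactly-at-boundary
  n_genes <- 300L
  counts <- matrix(0L, nrow = n_genes + 1L, ncol = 4L)
  genes <- c(sprintf("g%03d", seq_len(n_genes)), "mt-Nd1")
  counts[1:250, 1] <- 1L                     # 250 genes, no mito
  counts[1:150, 2] <- 1L                     # 150 genes -> low_genes
  counts[1:210, 3] <- 1L; counts[n_genes + 1L, 3] <- 5000L  # ~96% mito
  counts[1:199, 4] <- 1L; counts[n_genes + 1L, 4] <- 796L   # 200 genes, exactly 80% mito
  mat <- cell_matrix(counts, genes, paste0("c", 1:4), rep("pop", 4))
  qc <- qc_filter_cells(mat, min_genes = 200L, max_mito_fraction = 0.80)
  expect_setequal(qc$matrix$cells, c("c1", "c4"))
  expect_equal(qc$report$reason[qc$report$barcode == "c2"], "low_genes")
  expect_equal(qc$report$reason[qc$report$barcode == "c3"], "high_mito")

  # idempotence
  qc2 <- qc_filter_cells(qc$matrix, min_genes = 200L, max_mito_fraction = 0.80)
  expect_identical(qc2$matrix$cells, qc$matrix$cells)
  expect_equal(nrow(qc2$report), 0L)
})

test_that("normalization is per-cell scale-invariant and log is optional", {
  counts <- matrix(c(10, 990, 20, 1980), nrow = 2)
  mat <- cell_matrix(counts, c("a", "b"), c("c1", "c2"), rep("p", 2))
  x <- normalize_cells(mat, scale_total = 10000)
  expect_equal(as.numeric(x["a", "c1"]), 100)
  # doubling a cell's counts leaves its normalized vector unchanged
  expect_equal(as.numeric(x[, "c1"]), as.numeric(x[, "c2"]))
  xl <- normalize_cells(mat, scale_total = 10000, log_transform = TRUE)
  expect_equal(as.numeric(xl["a", "c1"]), log1p(100))
  expect_true(attr(xl, "logged"))

  z <- cell_matrix(matrix(c(1, 0), 2, 1), c("a", "b"), "c1", "p")
  z$counts[1, 1] <- 0
  expect_error(normalize_cells(z), "zero-total")
})

test_that("anchor covariance matches cov() and var() identities", {
  set.seed(13)
  n <- 200L
  a <- rpois(n, 20)
  other <- matrix(rpois(3 * n, 5), nrow = 3)
  counts <- rbind(a, a, other)  # gene 2 identical to the anchor
  genes <- c("anchor", "twin", "x1", "x2", "x3")
  m1 <- cell_matrix(counts, genes, sprintf("c%03d", 1:n), rep("p", n),
                    condition = "condition1")
  counts2 <- rbind(rpois(n, 20), rpois(n, 20), matrix(rpois(3 * n, 5), 3))
  m2 <- cell_matrix(counts2, genes, sprintf("d%03d", 1:n), rep("p", n),
                    condition = "condition2")
  # raw-count scale for a direct cov() comparison
  shift <- anchor_covariance_shift(m1, m2, "anchor", threshold = 30,
                                   normalize = FALSE)
  x1 <- m1$counts
  expect_equal(shift$cov_condition1[shift$gene_id == "twin"],
               cov(as.numeric(x1["twin", ]), as.numeric(x1["anchor", ])))
  expect_equal(shift$cov_condition1[shift$gene_id == "anchor"],
               var(as.numeric(x1["anchor", ])))
  expect_equal(shift$delta_cov, shift$cov_condition1 - shift$cov_condition2)

  # constant gene: zero covariance in both conditions, not flagged
  cm <- rbind(counts, const = 7)
  mm1 <- cell_matrix(cm, c(genes, "const"), m1$cells, m1$cell_labels)
  cm2 <- rbind(counts2, const = 7)
  mm2 <- cell_matrix(cm2, c(genes, "const"), m2$cells, m2$cell_labels)
  s2 <- anchor_covariance_shift(mm1, mm2, "anchor", normalize = FALSE)
  expect_equal(s2$delta_cov[s2$gene_id == "const"], 0)
  expect_false(s2$flagged[s2$gene_id == "const"])

  expect_error(anchor_covariance_shift(m1, m2, "nope"), "anchor")
})

test_that("covariance shift is antisymmetric under condition swap", {
  cfg <- sc_sim_config(n_genes = 40L, n_cells_per_condition = 300L, seed = 17L)
  sim <- simulate_sc_experiment(cfg)
  fwd <- anchor_covariance_shift(sim$matrix1, sim$matrix2, cfg$anchor_gene)
  rev_ <- anchor_covariance_shift(sim$matrix2, sim$matrix1, cfg$anchor_gene)
  expect_equal(rev_$delta_cov, -fwd$delta_cov)
  expect_identical(rev_$flagged, fwd$flagged)
})

test_that("planted covarying genes are recovered at the default threshold", {
  res <- lapply(1:2, function(s) {
    cfg <- sc_sim_config(seed = s)  # defaults: 2000 cells, 20 planted genes
    sim <- simulate_sc_experiment(cfg)
    shift <- anchor_covariance_shift(sim$matrix1, sim$matrix2,
                                     cfg$anchor_gene, threshold = 30)
    # the anchor row is its own variance shift, not a candidate discovery
    flagged <- setdiff(shift$gene_id[shift$flagged], cfg$anchor_gene)
    planted <- cfg$covarying_set
    c(precision = mean(flagged %in% planted),
      recall = mean(planted %in% flagged))
  })
  for (r in res) {
    expect_gte(r[["precision"]], 0.9)
    expect_gte(r[["recall"]], 0.9)
  }
})

test_that("census reproduces printed worked examples and sums consistently", {
  mat <- census_matrix(
    pop_sizes = c(basal = 93L, hematopoietic = 35L, vascular = 8L),
    pop_positive = c(basal = 17L, hematopoietic = 3L, vascular = 1L))
  cen <- transgene_census(mat, "tg")
  expect_equal(cen$percent_positive[cen$population == "basal"], 18.3)
  expect_equal(cen$percent_positive[cen$population == "hematopoietic"], 8.6)
  expect_equal(cen$percent_positive[cen$population == "vascular"], 12.5)
  expect_equal(sum(cen$n_positive),
               sum(as.numeric(mat$counts["tg", ]) > 0))
  expect_error(transgene_census(mat, "absent"), "absent")
})

test_that("pseudobulk concordance has the right identities and oracle value", {
  set.seed(19)
  counts <- matrix(rpois(50 * 20, 3), nrow = 50)
  genes <- sprintf("g%02d", 1:50)
  mat <- cell_matrix(counts, genes, sprintf("c%02d", 1:20), rep("p", 20))
  sc_sum <- Matrix::rowSums(mat$counts)
  # bulk equal to sc sums: r = 1; doubling bulk is an (almost exact, up to
  # the +1 pseudocount) log shift
  expect_equal(pseudobulk_concordance(mat, setNames(sc_sum, genes))$r, 1.0)
  expect_equal(pseudobulk_concordance(mat, setNames(2 * sc_sum, genes))$r, 1.0,
               tolerance = 1e-4)

  # 3-gene closed-form Pearson oracle
  m3 <- cell_matrix(matrix(c(1, 2, 4), 3, 1), c("a", "b", "c"), "c1", "p")
  bulk <- c(a = 2, b = 3, c = 9)
  got <- suppressWarnings(tryCatch(pseudobulk_concordance(m3, bulk),
                                   error = function(e) NULL))
  # n < 10 shared genes is rejected; use the padded version
  expect_null(got)
  pad_counts <- matrix(c(1, 2, 4, rep(5, 9)), ncol = 1)
  mp <- cell_matrix(pad_counts, c("a", "b", "c", sprintf("p%d", 1:9)),
                    "c1", "p")
  bulkp <- c(bulk, setNames(rep(5, 9), sprintf("p%d", 1:9)))
  r <- pseudobulk_concordance(mp, bulkp)$r
  lx <- log(c(1, 2, 4, rep(5, 9)) + 1); ly <- log(c(2, 3, 9, rep(5, 9)) + 1)
  oracle <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
})

test_that("MTX round-trip preserves counts and labels", {
  cfg <- sc_sim_config(n_genes = 15L, n_cells_per_condition = 40L, seed = 23L)
  sim <- simulate_sc_experiment(cfg)
  dir <- tempfile()
  write_cell_matrix(sim$matrix1, dir)
  back <- read_cell_matrix(dir, condition = "condition1")
  expect_identical(as.matrix(back$counts), as.matrix(sim$matrix1$counts))
  expect_identical(back$cell_labels, sim$matrix1$cell_labels)
})
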