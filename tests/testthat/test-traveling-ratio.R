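# Traveling-ratio scoring, difference curves, tangent cutpoints and
# gene-set distribution tests.

test_that("TR is the promoter/body density ratio with eligibility policy", {
  # promoter density 10, body density 2: piecewise-constant coverage
  g <- gene_models("g1", "chr1", 1000L, 5000L, "+")
  v <- numeric(10000L)
  v[971:1300] <- 10   # promoter [970, 1300)
  v[1301:5000] <- 2   # body [1300, 5000)
  tr <- compute_tr_table(coverage_track(list(chr1 = S4Vectors::Rle(v)),
                                        total_fragments = 1e6), g)
  expect_equal(tr$tr, 5.0)

  # uniform coverage: TR = 1 for every gene
  trt <- compute_tr_table(uniform_track(len = 10000L), toy_genes())
  expect_equal(trt$tr, c(1, 1))

  # zero body coverage: ineligible with the right reason
  v2 <- numeric(10000L); v2[971:1300] <- 4
  g2 <- rbind(g, gene_models("g2", "chr1", 6000L, 9000L, "+"))
  class(g2) <- c("gene_models", "data.frame")
  v2[5671:9000] <- 1  # keep one gene eligible
  tr2 <- compute_tr_table(coverage_track(list(chr1 = S4Vectors::Rle(v2)),
                                         total_fragments = 1e6), g2)
  expect_false(tr2$eligible[tr2$gene_id == "g1"])
  expect_equal(tr2$reason[tr2$gene_id == "g1"], "zero_body_density")
  expect_true(is.na(tr2$tr[tr2$gene_id == "g1"]))
})

test_that("TR is invariant to rescaling coverage and library size together", {
  cfg <- polii_sim_config(n_genes = 40L, reads_per_gene_mean = 200, seed = 4L)
  genes <- simulate_gene_models(cfg)
  sim <- simulate_polii_experiment(genes, cfg)
  t1 <- sim$track1
  tr_a <- compute_tr_table(t1, genes)
  scaled <- coverage_track(t1$coverage * 7, t1$total_fragments * 7,
                           chrom_sizes = t1$chrom_sizes)
  tr_b <- compute_tr_table(scaled, genes)
  expect_equal(tr_a$tr, tr_b$tr)
  expect_equal(tr_a$promoter_density, tr_b$promoter_density)
})

test_that("difference curve ranks WT-minus-MYC deltas with deterministic ties", {
  tr1 <- tr_table_from_values(c(5, 2, 4, 4), c("a", "b", "c", "d"))
  tr2 <- tr_table_from_values(c(2, 2, 1, 1), c("a", "b", "c", "d"))
  cur <- tr_difference_curve(tr1, tr2)
  expect_equal(cur$delta, c(0, 3, 3, 3))
  expect_equal(cur$gene_id, c("b", "a", "c", "d"))  # ties by gene_id
  expect_equal(cur$scaled_x, c(0, 1, 2, 3) / 3)
  expect_equal(cur$scaled_y, c(0, 1, 1, 1))

  expect_error(tr_difference_curve(tr_table_from_values(1:3, c("x", "y", "z")),
                                   tr2), ">= 3")
  flat <- tr_difference_curve(tr_table_from_values(rep(2, 5)),
                              tr_table_from_values(rep(1, 5)))
  expect_true(attr(flat, "degenerate"))
  expect_error(tangent_cutpoints(flat), "degenerate")
})

test_that("tangent detector finds the analytic slope-1 point of y = x^3", {
  x <- seq(0, 1, length.out = 10000L)
  cur <- curve_from_xy(x, x^3)
  cuts <- tangent_cutpoints(cur, smooth_window = 11L)
  expect_true(is.na(cuts$cut_lo))
  x_star <- 3^(-1/2)
  grid <- x[2] - x[1]
  expect_lte(abs(cur$scaled_x[cuts$cut_hi] - x_star), 2 * grid)
})

test_that("a slope-1 line has no tangent crossings", {
  x <- seq(0, 1, length.out = 500L)
  cur <- curve_from_xy(x, x)
  expect_warning(cuts <- tangent_cutpoints(cur), "no slope-1 tangent")
  expect_true(is.na(cuts$cut_lo) && is.na(cuts$cut_hi))
  cls <- classify_pause_genes(cur, cuts)
  expect_length(cls$pause_release, 0)
  expect_length(cls$pause, 0)
})

test_that("flat-then-steep curves put the cut near the junction", {
  n <- 1000L
  x <- seq(0, 1, length.out = n)
  # flat (slope 0) for 90%, then linear to 1 (scaled slope 10)
  y <- ifelse(x <= 0.9, 0, (x - 0.9) / 0.1)
  cuts <- tangent_cutpoints(curve_from_xy(x, y), smooth_window = 11L)
  junction <- which(x > 0.9)[1]
  expect_false(is.na(cuts$cut_hi))
  expect_lte(abs(cuts$cut_hi - junction), 11L)
})

test_that("smoothed detector tracks the brute-force slope scan on monotone curves", {
  set.seed(21)
  for (rep in 1:20) {
    # exponent > 2 keeps the slope-1 point in the upper half, where the
    # detector looks for the pause-release takeoff
    p <- runif(1, 2.5, 6)
    n <- 2000L
    x <- seq(0, 1, length.out = n)
    cur <- curve_from_xy(x, x^p)
    cuts <- tangent_cutpoints(cur, smooth_window = 11L)
    oracle <- brute_force_upper_crossing(x, x^p)
    expect_false(is.na(cuts$cut_hi))
    expect_lte(abs(cuts$cut_hi - oracle), 11L)
  }
})

test_that("classification counts genes strictly beyond the cut deltas", {
  x <- seq(0, 1, length.out = 200L)
  cur <- curve_from_xy(x, x^4, delta = x^4 * 10)
  cuts <- tangent_cutpoints(cur, smooth_window = 11L)
  cls <- classify_pause_genes(cur, cuts)
  expect_equal(cls$pause_release,
               cur$gene_id[cur$delta > cur$delta[cuts$cut_hi]])
  expect_length(cls$pause, 0)
})

test_that("condition swap negates deltas and exactly swaps the classes", {
  cfg <- polii_sim_config(
    n_genes = 600L, reads_per_gene_mean = 300,
    planted_pause_release = setNames(rep(-0.4, 10), sprintf("g%05d", 1:10)),
    planted_pause = setNames(rep(0.4, 20), sprintf("g%05d", 11:30)),
    seed = 8L)
  genes <- simulate_gene_models(cfg)
  sim <- simulate_polii_experiment(genes, cfg)
  tr1 <- compute_tr_table(sim$track1, genes)
  tr2 <- compute_tr_table(sim$track2, genes)
  fwd <- tr_difference_curve(tr1, tr2)
  rev_ <- tr_difference_curve(tr2, tr1)
  expect_equal(sort(rev_$delta), sort(-fwd$delta))
  cls_f <- classify_pause_genes(fwd, tangent_cutpoints(fwd))
  cls_r <- classify_pause_genes(rev_, tangent_cutpoints(rev_))
  expect_setequal(cls_f$pause_release, cls_r$pause)
  expect_setequal(cls_f$pause, cls_r$pause_release)
})

test_that("gene-set TR comparison: KS identities and the exact enumeration case", {
  t1 <- tr_table_from_values(c(1, 2, 3), c("a", "b", "c"))
  t2 <- tr_table_from_values(c(4, 5, 6), c("a", "b", "c"))
  ks <- compare_geneset_tr(t1, t2, test = "KS")
  expect_equal(ks$statistic, 1)
  expect_equal(ks$p_value, 0.1)  # exact: 2 / choose(6, 3)

  same <- compare_geneset_tr(t1, t1, test = "KS")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  wt <- compare_geneset_tr(t1, t2, test = "Welch-t")
  expect_lt(wt$statistic, 0)
  expect_true(wt$p_value > 0 && wt$p_value < 1)

  expect_error(compare_geneset_tr(t1, t2, gene_set = c("a", "b")), ">= 3")
})

test_that("planted pause shifts in a gene set are detected with high power", {
  hits <- vapply(1:40, function(s) {
    set_genes <- sprintf("g%05d", 1:50)
    cfg <- polii_sim_config(
      n_genes = 120L, reads_per_gene_mean = 300,
      planted_pause = setNames(rep(0.3, 50), set_genes), seed = s)
    genes <- simulate_gene_models(cfg)
    sim <- simulate_polii_experiment(genes, cfg)
    tr1 <- compute_tr_table(sim$track1, genes)
    tr2 <- compute_tr_table(sim$track2, genes)
    compare_geneset_tr(tr1, tr2, gene_set = set_genes, test = "KS")$p_value < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
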