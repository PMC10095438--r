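# A tiny hand-built universe for matching tests.
match_fixture <- function() {
  dmrs <- data.frame(
    region_id = c("d1", "d2", "d3", "d4"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 5000L, 100L, 9000L),
    end = c(300L, 5200L, 300L, 9100L),
    n_cpgs = 2L,
    member_cpgs = c("cg1,cg2", "cg3,cg4", "cg5,cg6", "cg7,cg8"),
    mean_delta_beta = 0.1, direction = "hyper",
    stringsAsFactors = FALSE)
  ann <- data.frame(
    cpg_id = paste0("cg", 1:8),
    chrom = rep(c("chr1", "chr2"), each = 4),
    pos = c(100, 300, 5000, 5200, 100, 300, 9000, 9100),
    gene = c("gA", "gA", "gB", "gC", "", "", "", ""),
    feature = c("TSS1500", "TSS1500", "Body", "Body", "IGR", "IGR", "IGR", "IGR"),
    stringsAsFactors = FALSE)
  genes <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = 1L, end = 20000L,
                      gene_id = c("gA", "gB", "gC", "gD"),
                      strand = "+", tss = c(1800L, 6000L, 6500L, 2000L),
                      first_exon_start = 0L, first_exon_end = 0L,
                      stringsAsFactors = FALSE)
  list(dmrs = dmrs, ann = ann, genes = genes)
}

test_that("cis matching fans out, drops unexpressed genes, logs intergenic", {
  fx <- match_fixture()
  m <- match_cis(fx$dmrs, fx$ann, fx$genes,
                 expressed = c("gA", "gB", "gC", "gD"), cis_window = 1e5)
  # d1 -> gA; d2 -> gB and gC (fan-out); d3 intergenic -> nearest TSS gD
  expect_equal(m$pairs$gene_id[m$pairs$region_id == "d1"], "gA")
  expect_setequal(m$pairs$gene_id[m$pairs$region_id == "d2"], c("gB", "gC"))
  d3 <- m$pairs[m$pairs$region_id == "d3", ]
  expect_equal(d3$gene_id, "gD")
  expect_true(d3$intergenic_match)
  # d4 is 7000 bp from the only chr2 TSS: matched within 1e5 window,
  # dropped when the window shrinks
  expect_true("d4" %in% m$pairs$region_id)
  m2 <- match_cis(fx$dmrs, fx$ann, fx$genes,
                  expressed = c("gA", "gB", "gC", "gD"), cis_window = 1000)
  expect_false("d4" %in% m2$pairs$region_id)
  expect_true("d4" %in% m2$dropped$region_id)
  # unexpressed gene lands in the drop log
  m3 <- match_cis(fx$dmrs, fx$ann, fx$genes,
                  expressed = c("gB", "gC", "gD"), cis_window = 1e5)
  expect_false("gA" %in% m3$pairs$gene_id)
  drop <- m3$dropped[m3$dropped$region_id == "d1", ]
  expect_equal(drop$gene_id, "gA")
  expect_match(drop$reason, "not expressed")
})

test_that("region median methylation uses the midpoint rule", {
  beta <- matrix(c(0.2, 0.4, 0.9,
                   0.1, 0.5, 0.7), 3, 2,
                 dimnames = list(c("cg1", "cg2", "cg3"), c("S1", "S2")))
  expect_equal(unname(dmr_median_methylation(beta, c("cg1", "cg2", "cg3"))),
               c(0.4, 0.5))
  expect_equal(unname(dmr_median_methylation(beta, c("cg1", "cg2"))),
               c(0.3, 0.3))
  expect_equal(unname(dmr_median_methylation(beta, "cg3")), c(0.9, 0.7))
  expect_error(dmr_median_methylation(beta, c("cg1", "cgX")), "cgX")
})

test_that("the correlation kernel matches the sum-formula oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(eqtm_correlation(x, 2 * x + 1), 1)
  expect_equal(eqtm_correlation(x, -x), -1)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    num <- n * sum(a * b) - sum(a) * sum(b)
    den <- sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
    expect_equal(eqtm_correlation(a, b), num / den, tolerance = 1e-12)
  }
  expect_error(eqtm_correlation(c(1, 1, 1), rnorm(3)), "constant")
  expect_error(eqtm_correlation(1:2, 1:2), "3 samples")
})

test_that("bootstrap CI collapses on collinear data and is seeded", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 3 * x - 2
  ci <- bootstrap_ci(x, y, n_boot = 500, seed = 4)
  expect_equal(unname(ci), c(1, 1))
  set.seed(99)
  a <- rnorm(30); b <- a + rnorm(30)
  ci1 <- bootstrap_ci(a, b, n_boot = 2000, seed = 7)
  ci2 <- bootstrap_ci(a, b, n_boot = 2000, seed = 7)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(a, b, n_boot = 2000, seed = 8)
  expect_false(identical(ci1, ci3))
  r <- cor(a, b)
  expect_lte(ci1[1], r); expect_gte(ci1[2], r)
  expect_true(ci1[1] >= -1 && ci1[2] <= 1)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(123)
  width <- vapply(c(20, 63, 200), function(n) {
    mean(vapply(1:30, function(i) {
      x <- rnorm(n); y <- 0.5 / sqrt(0.75) * x + rnorm(n)
      ci <- bootstrap_ci(x, y, n_boot = 1000, seed = i)
      ci[2] - ci[1]
    }, 0))
  }, 0)
  expect_true(all(diff(width) < 0))
})

test_that("permutation p-values are exact, floored and seeded", {
  set.seed(31)
  # exhaustive-permutation oracle at n = 5 (120 permutations)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    p_exact <- perm_p_oracle(x, y)
    p_est <- resampling_pvalue(x, y, n_perm = 40000, seed = i)
    expect_lt(abs(p_est - p_exact), 0.01)
  }
  # add-one floor: p can never be 0 and never below 1/(n_perm+1)
  x <- 1:10
  y <- c(1:9, 20)  # extremely strong monotone association
  p <- resampling_pvalue(x, y, n_perm = 999, seed = 3)
  expect_gte(p, 1 / 1000)
  expect_lte(p, 5 / 1000)
  expect_identical(resampling_pvalue(x, y, n_perm = 999, seed = 3), p)
})

test_that("group-specific correlations decompose a planted uncoupling", {
  set.seed(41)
  groups <- rep(c("case", "control"), c(12, 51))
  x <- rnorm(63)
  y <- rnorm(63, sd = 0.4)
  y[groups == "case"] <- y[groups == "case"] + 1.5 * x[groups == "case"]
  gc <- group_correlations(x, y, groups)
  expect_gt(abs(gc$r_case), 0.7)
  expect_lt(abs(gc$r_control), 0.45)
  expect_false(gc$flagged)
  # same linear law in both groups -> both r = combined r = 1
  y2 <- 2 * x + 1
  gc2 <- group_correlations(x, y2, groups)
  expect_equal(gc2$r_case, 1)
  expect_equal(gc2$r_control, 1)
  # undersized group -> sentinel + flag
  gc3 <- group_correlations(x[1:5], y[1:5], c("case", "case", rep("control", 3)))
  expect_true(is.na(gc3$r_case))
  expect_true(gc3$flagged)
})

test_that("feature and direction labels follow the classification rules", {
  # hypomethylated promoter region, case expression up
  cls <- eqtmr:::classify_pair(-0.12, group_effect = 0.8, raw_diff = 0.7)
  expect_equal(cls$dmr_direction, "Hypo-methylated")
  expect_equal(cls$expression_direction, "Overexpression")
  # hypermethylated with expression up (direction labels are independent)
  cls2 <- eqtmr:::classify_pair(0.12, group_effect = 0.8, raw_diff = 0.7)
  expect_equal(cls2$dmr_direction, "Hyper-methylated")
  expect_equal(cls2$expression_direction, "Overexpression")
  # zero adjusted effect falls back to the raw mean difference
  cls3 <- eqtmr:::classify_pair(-0.1, group_effect = 0, raw_diff = -0.4)
  expect_equal(cls3$expression_direction, "Underexpression")
  # exact tie is labelled none, never asserted as a direction
  cls4 <- eqtmr:::classify_pair(-0.1, group_effect = 0, raw_diff = 0)
  expect_equal(cls4$expression_direction, "none")

  feat <- eqtmr:::region_feature
  gm <- data.frame(strand = "+", tss = 10000)
  expect_equal(feat(c("Body"), 9200, gm), "Promoter")       # in TSS window
  expect_equal(feat(c("1stExon", "Body"), 20000, gm), "1st exon")
  expect_equal(feat(c("Body", "3UTR"), 20000, gm), "Gene body")
  expect_equal(feat(c("IGR"), 20000, gm), "Intergenic")
})

test_that("the full eQTM pipeline recovers planted pairs end to end", {
  cfg <- sim_config(
    n_cpgs = 2000, n_genes = 200, n_chromosomes = 4, seed = 5,
    planted_dmr_specs = list(list(n_cpgs = 4, delta_beta = -0.15),
                             list(n_cpgs = 3, delta_beta = 0.15)),
    planted_eqtm_specs = list(list(rho = -0.5), list(rho = 0.5)))
  ds <- generate_cohort(cfg)
  dmps <- fit_dmps(ds$beta, ds$samples)
  dmrs <- call_dmrs(dmps, ds$cpg_annotation, fdr_threshold = 0.1)
  res <- run_eqtm_analysis(ds$beta, ds$counts, ds$samples, dmrs,
                           ds$cpg_annotation, ds$gene_models,
                           n_boot = 2000, n_perm = 999, seed = 11)
  planted_genes <- vapply(ds$truth$eqtm_pairs, `[[`, "", "gene_id")
  hits <- res$eqtms[res$eqtms$gene_id %in% planted_genes, ]
  expect_equal(nrow(hits), 2)
  expect_true(all(hits$significant))
  expect_equal(sort(sign(hits$r)), c(-1, 1))
  # planted promoters annotated as such, direction labels consistent
  expect_true(all(hits$dmr_feature == "Promoter"))
  expect_setequal(hits$dmr_direction, c("Hypo-methylated", "Hyper-methylated"))
  # CI bracket contract and self-consistency of the reported r
  for (i in seq_len(nrow(res$eqtms))) {
    row <- res$eqtms[i, ]
    expect_lte(row$ci_low, row$r + 0.02)
    expect_gte(row$ci_high, row$r - 0.02)
    dmr <- dmrs[dmrs$region_id == row$region_id, ]
    med <- dmr_median_methylation(ds$beta,
                                  strsplit(dmr$member_cpgs, ",")[[1]])
    le <- log_transform(normalize_counts(filter_expressed(ds$counts))$normalized)
    expect_equal(row$r, eqtm_correlation(med, le[row$gene_id, ]),
                 tolerance = 1e-12)
  }
  # determinism and ordering
  res2 <- run_eqtm_analysis(ds$beta, ds$counts, ds$samples, dmrs,
                            ds$cpg_annotation, ds$gene_models,
                            n_boot = 2000, n_perm = 999, seed = 11)
  expect_identical(res$eqtms, res2$eqtms)
  expect_true(!is.unsorted(res$eqtms$p_value))
})

test_that("empty region tables give an empty, well-formed result", {
  ds <- generate_cohort(sim_config(n_cases = 3, n_controls = 4, n_cpgs = 50,
                                   n_genes = 10, seed = 2))
  dmps <- fit_dmps(ds$beta, ds$samples,
                   design_spec(covariates = character(0)))
  empty_dmrs <- call_dmrs(dmps, ds$cpg_annotation, fdr_threshold = 1e-9)
  res <- run_eqtm_analysis(ds$beta, ds$counts, ds$samples, empty_dmrs,
                           ds$cpg_annotation, ds$gene_models,
                           n_boot = 100, n_perm = 99, seed = 1)
  expect_equal(nrow(res$eqtms), 0)
  expect_true(all(c("r", "ci_low", "ci_high", "p_value") %in% names(res$eqtms)))
})

test_that("scatter export carries one row per sample and pair", {
  cfg <- sim_config(n_cpgs = 500, n_genes = 50, seed = 13,
                    planted_dmr_specs = list(list(n_cpgs = 3, delta_beta = -0.2)),
                    planted_eqtm_specs = list(list(rho = -0.5)))
  ds <- generate_cohort(cfg)
  dmps <- fit_dmps(ds$beta, ds$samples)
  dmrs <- call_dmrs(dmps, ds$cpg_annotation, fdr_threshold = 0.1)
  res <- run_eqtm_analysis(ds$beta, ds$counts, ds$samples, dmrs,
                           ds$cpg_annotation, ds$gene_models,
                           n_boot = 200, n_perm = 199, seed = 3)
  le <- log_transform(normalize_counts(filter_expressed(ds$counts))$normalized)
  sc <- eqtm_scatter_data(ds$beta, le, ds$samples, dmrs, res$eqtms)
  expect_equal(nrow(sc), nrow(res$eqtms) * nrow(ds$samples))
  expect_true(all(sc$group %in% c("case", "control")))
})
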