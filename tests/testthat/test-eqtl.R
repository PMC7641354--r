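# cis/trans eQTL mapping, the rank transform, permutation calibration, LD.

test_that("inverse normal transform maps ranks to normal quantiles", {
  # frozen quantiles: [3,1,2] -> qnorm(5/6), qnorm(1/6), 0
  got <- inverse_normal_transform(c(3, 1, 2))
  expect_equal(got, c(0.9674216, -0.9674216, 0), tolerance = 1e-6)
  expect_equal(got[3], 0)
  # ties share the average-rank quantile: ranks (2.5, 2.5, 1)
  tied <- inverse_normal_transform(c(5, 5, 1))
  expect_equal(tied, qnorm(c(2/3, 2/3, 1/6)))
  # the median element of an odd-length tie-free vector maps to 0
  x <- c(10, 2, 7, 30, 4)
  expect_equal(inverse_normal_transform(x)[x == median(x)], 0)
})

test_that("the transform is idempotent on ranks and rejects bad input", {
  set.seed(1)
  x <- rnorm(51)
  once <- inverse_normal_transform(x)
  expect_equal(inverse_normal_transform(once), once, tolerance = 1e-12)
  expect_error(inverse_normal_transform(c(2, 2, 2)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), "3 finite values")
})

test_that("fit_snp_gene matches lm() and the t distribution", {
  set.seed(2)
  for (rep in 1:20) {
    n <- 60
    g <- rbinom(n, 2, 0.3)
    pop <- rep(0:1, each = n / 2)
    y <- 0.3 * g + 0.2 * pop + rnorm(n)
    got <- fit_snp_gene(g, y, pop)
    ref <- summary(lm(y ~ g + pop))$coefficients["g", ]
    expect_equal(got$beta, unname(ref["Estimate"]), tolerance = 1e-10)
    expect_equal(got$se, unname(ref["Std. Error"]), tolerance = 1e-10)
    expect_equal(got$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
    # two-sided p equals the t survival function at the reported statistic
    expect_equal(got$p, 2 * pt(abs(got$beta / got$se), df = got$df,
                               lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("exact linear expression gives p ~ 0 and r2 = 1; monomorphic is flagged", {
  g <- rep(c(0, 1, 2), 10)
  y <- 2 * g + 1
  got <- fit_snp_gene(g, y, covariates = NULL)
  expect_lt(got$p, 1e-300)
  expect_equal(got$r2, 1)
  mono <- fit_snp_gene(rep(1, 30), rnorm(30), covariates = NULL)
  expect_true(mono$monomorphic)
  expect_equal(mono$p, 1)
  expect_true(is.na(mono$beta))
})

test_that("null fits cover zero at the nominal rate", {
  set.seed(3)
  n <- 200
  inside <- vapply(1:1000, function(i) {
    g <- rbinom(n, 2, 0.3)
    y <- rnorm(n)
    f <- fit_snp_gene(g, y, covariates = NULL)
    abs(f$beta) < 2 * f$se
  }, TRUE)
  expect_gte(mean(inside), 0.93)
})

test_that("map_cis_eqtl scans SNP x condition and respects the window", {
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 50, seed = 10))
  cis <- map_cis_eqtl(sim$genotypes, sim$expression, sim$truth$target_gene)
  expect_equal(nrow(cis), 50 * 2)
  expect_setequal(unique(cis$condition), c("NS", "LPS"))
  expect_true(all(cis$p >= 0 & cis$p <= 1))
  expect_true(all(cis$r2 >= 0 & cis$r2 <= 1))
  # windowing: center on the causal SNP with a tight window
  center <- sim$genotypes$variants$pos[sim$truth$causal_index]
  cis_w <- map_cis_eqtl(sim$genotypes, sim$expression,
                        sim$truth$target_gene, window = 2e4,
                        center = center)
  in_win <- abs(sim$genotypes$variants$pos - center) <= 1e4
  expect_equal(sort(unique(cis_w$snp)),
               sort(sim$genotypes$variants$id[in_win]))
  # no SNPs in window -> empty result
  empty <- map_cis_eqtl(sim$genotypes, sim$expression,
                        sim$truth$target_gene, window = 2,
                        center = -5000)
  expect_equal(nrow(empty), 0L)
})

test_that("duplicated SNP columns give identical results", {
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 10, seed = 12))
  g <- sim$genotypes
  v2 <- g$variants
  v2$id[2] <- "dup_of_1"
  v2$pos[2] <- v2$pos[1] + 1L
  d2 <- g$dosages
  d2[2, ] <- d2[1, ]
  g2 <- genotype_matrix(v2, d2, g$individuals, g$population)
  cis <- map_cis_eqtl(g2, sim$expression, sim$truth$target_gene)
  a <- cis[cis$snp == v2$id[1], c("beta", "se", "p", "r2")]
  b <- cis[cis$snp == "dup_of_1", c("beta", "se", "p", "r2")]
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = 1e-12)
})

test_that("the planted causal SNP attains the minimum p-value", {
  hits <- vapply(1:40, function(s) {
    sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 100, beta_cis = 0.8,
                                               seed = 60000 + s))
    cis <- map_cis_eqtl(sim$genotypes, sim$expression,
                        sim$truth$target_gene)
    cis$snp[which.min(cis$p)] == sim$truth$causal_snp
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("permutation thresholds follow the empirical quantile contract", {
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 30, beta_cis = 0,
                                             seed = 14))
  cal <- permutation_fwer_threshold(sim$genotypes, sim$expression,
                                    sim$truth$target_gene,
                                    n_permutations = 100,
                                    target_fwer = 0.01, seed = 1)
  # quantile edge: 100 permutations at 1% -> the smallest recorded minimum
  expect_equal(cal$threshold, min(cal$min_p_distribution))
  expect_length(cal$min_p_distribution, 100)
  expect_error(permutation_fwer_threshold(sim$genotypes, sim$expression,
                                          sim$truth$target_gene,
                                          n_permutations = 100,
                                          target_fwer = 0.005),
               "quantile unsupported")
  expect_error(permutation_fwer_threshold(sim$genotypes, sim$expression,
                                          sim$truth$target_gene,
                                          n_permutations = 50),
               "at least 100")
})

test_that("independent SNPs give a Sidak-like threshold", {
  # 50 independent SNPs, one condition: threshold ~ 1 - 0.99^(1/50)
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 50, beta_cis = 0,
                                             ld_decay = 0, n_conditions = 1,
                                             seed = 15))
  cal <- permutation_fwer_threshold(sim$genotypes, sim$expression,
                                    sim$truth$target_gene,
                                    n_permutations = 2000, seed = 2)
  sidak <- 1 - (1 - 0.01)^(1 / 50)
  # the 1% quantile of 2000 permutation minima carries Monte-Carlo noise
  expect_gt(cal$threshold, sidak / 2.5)
  expect_lt(cal$threshold, sidak * 2.5)
})

test_that("permutation thresholds tighten as more SNPs are scanned", {
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 120, beta_cis = 0,
                                             ld_decay = 0.3, seed = 16))
  sub <- function(k) subset_genotypes(sim$genotypes, seq_len(k))
  th <- vapply(c(15, 60, 120), function(k)
    permutation_fwer_threshold(sub(k), sim$expression,
                               sim$truth$target_gene,
                               n_permutations = 400, seed = 3)$threshold, 0)
  expect_true(th[1] >= th[2] && th[2] >= th[3])
})

test_that("conditioning on the causal SNP removes its proxy's signal", {
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 40, beta_cis = 0.8,
                                             seed = 18))
  g <- sim$genotypes
  ci <- sim$truth$causal_index
  # append a perfect-LD proxy of the causal SNP
  v2 <- rbind(g$variants, g$variants[ci, ])
  v2$id[41] <- "rs_proxy"
  v2$pos[41] <- v2$pos[ci] + 1L
  g2 <- genotype_matrix(v2, rbind(g$dosages, g$dosages[ci, ]),
                        g$individuals, g$population)
  expect_equal(ld_r2(g2$dosages[41, ], g2$dosages[ci, ]), 1.0)
  cal <- permutation_fwer_threshold(g2, sim$expression,
                                    sim$truth$target_gene,
                                    n_permutations = 200, seed = 4)
  plain <- map_cis_eqtl(g2, sim$expression, sim$truth$target_gene)
  expect_true(any(plain$p[plain$snp == "rs_proxy"] < cal$threshold))
  cond <- conditional_scan(g2, sim$expression, sim$truth$target_gene,
                           condition_on = sim$truth$causal_snp)
  expect_false(sim$truth$causal_snp %in% cond$snp)
  expect_true(all(cond$p[cond$snp == "rs_proxy"] > cal$threshold))
  # conditioning on an independent SNP leaves the causal signal intact
  far <- which.min(abs(seq_len(40) - (ci + 20) %% 40))
  cond2 <- conditional_scan(g2, sim$expression, sim$truth$target_gene,
                            condition_on = g$variants$id[far])
  expect_true(any(cond2$p[cond2$snp == sim$truth$causal_snp] <
                    cal$threshold))
})

test_that("conditioning on the only SNP yields an empty result", {
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 2, seed = 19))
  g1 <- subset_genotypes(sim$genotypes, 1)
  cond <- conditional_scan(g1, sim$expression, sim$truth$target_gene,
                           condition_on = g1$variants$id[1])
  expect_equal(nrow(cond), 0L)
})

test_that("trans scan applies BH FDR and the effect-size filter", {
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 10, n_genes = 300,
                                             seed = 20))
  g <- as.numeric(sim$genotypes$dosages[sim$truth$causal_index, ])
  gz <- (g - mean(g)) / sd(g)
  lps <- which(sim$expression$condition == "LPS")
  planted <- 2:21
  sim$expression$values[planted, lps] <-
    -0.5 * matrix(rep(gz, 20), nrow = 20, byrow = TRUE) +
    matrix(rnorm(20 * length(lps), sd = sqrt(0.75)), nrow = 20)
  tr <- map_trans_eqtl(sim$genotypes, sim$truth$causal_snp,
                       sim$expression, "LPS")
  planted_ids <- sim$expression$genes[planted]
  expect_gte(mean(planted_ids %in% tr$hits$gene), 0.9)
  expect_true(all(tr$hits$direction[tr$hits$gene %in% planted_ids] ==
                    "down"))
  expect_true(all(tr$hits$q <= 0.01 & abs(tr$hits$beta) >= 0.2))
})

test_that("sub-threshold effect sizes are excluded whatever their q-value", {
  # the effect-size filter acts after (and independently of) the FDR filter:
  # a gene whose q passes but whose |beta| < 0.2 must be dropped
  sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 10, n_genes = 50,
                                             seed = 22))
  tr <- map_trans_eqtl(sim$genotypes, sim$truth$causal_snp,
                       sim$expression, "LPS", fdr = 0.9)
  weak <- tr$all$gene[tr$all$q <= 0.9 & abs(tr$all$beta) < 0.2]
  expect_gt(length(weak), 0)
  expect_false(any(weak %in% tr$hits$gene))
  # dropping the effect-size filter re-admits exactly those genes
  tr2 <- map_trans_eqtl(sim$genotypes, sim$truth$causal_snp,
                        sim$expression, "LPS", fdr = 0.9, min_abs_beta = 0)
  expect_true(all(weak %in% tr2$hits$gene))
  expect_setequal(tr$hits$gene,
                  tr2$hits$gene[abs(tr2$hits$beta) >= 0.2])
})

test_that("an all-null trans scan returns (almost always) nothing", {
  empty <- vapply(1:30, function(s) {
    sim <- simulate_eqtl_dataset(eqtl_sim_spec(n_snps = 5, n_genes = 400,
                                               beta_cis = 0,
                                               seed = 70000 + s))
    tr <- map_trans_eqtl(sim$genotypes, sim$truth$causal_snp,
                         sim$expression, "LPS")
    nrow(tr$hits) == 0
  }, TRUE)
  expect_gte(mean(empty), 0.9)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(5:80, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("ld_r2 behaves as squared correlation with pairwise deletion", {
  set.seed(6)
  a <- rbinom(500, 2, 0.4)
  expect_equal(ld_r2(a, a), 1.0)
  b <- rbinom(10000, 2, 0.4)
  c2 <- rbinom(10000, 2, 0.4)
  expect_lt(ld_r2(b, c2), 0.01)
  am <- a; am[1:20] <- NA
  bm <- rbinom(500, 2, 0.3)
  expect_equal(ld_r2(am, bm), cor(am[-(1:20)], bm[-(1:20)])^2)
  expect_warning(r <- ld_r2(rep(1, 500), a), "monomorphic")
  expect_true(is.na(r))
})
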