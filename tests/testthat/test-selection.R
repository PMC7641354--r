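# Tajima's D, EHH/iHS, Weir-Cockerham F_ST, empirical p-values.

test_that("Tajima's D matches a hand-checkable four-haplotype fixture", {
  hs <- toy_haps(c("0000", "0011", "1100", "1111"), c(10, 20, 30, 40))
  got <- tajimas_d(hs)
  expect_equal(got$S, 4L)
  expect_equal(got$a1, 1 + 1/2 + 1/3)
  # mean pairwise difference over the 6 pairs: (2+2+4+4+2+2)/6
  expect_equal(got$pi, 16 / 6)
  expect_equal(got$D, oracle_tajima_d(hs$haplotypes), tolerance = 1e-12)
})

test_that("Tajima's D is NaN without segregating sites and windows subset", {
  hs <- toy_haps(c("0101", "0101", "0101", "0101"), c(10, 20, 30, 40))
  expect_true(is.nan(tajimas_d(hs)$D))
  hs2 <- toy_haps(c("0000", "0011", "1100", "1111"), c(10, 20, 30, 40))
  sub <- tajimas_d(hs2, window = c(15, 35))  # sites at 20 and 30 only
  expect_equal(sub$S, 2L)
  expect_true(is.nan(tajimas_d(hs2, window = c(100, 200))$D))
})

test_that("Tajima's D equals the pairwise oracle on random small fixtures", {
  for (i in 1:50) {
    hs <- random_haps(n = sample(4:10, 1), S = sample(2:20, 1),
                      seed = 300 + i)
    expect_equal(tajimas_d(hs)$D, oracle_tajima_d(hs$haplotypes),
                 tolerance = 1e-10)
  }
})

test_that("EHH starts at 1, is non-increasing, and matches the pairwise oracle", {
  hs <- toy_haps(c("101100", "101100", "100111", "000101", "001100",
                   "101110"), c(5, 12, 20, 31, 45, 60))
  for (al in c(0L, 1L)) {
    for (dir in c("left", "right")) {
      got <- ehh(hs, 3, al, dir)
      expect_equal(got$ehh[1], 1)
      expect_true(all(diff(got$ehh) <= 1e-12))
      ref <- oracle_ehh(hs$haplotypes, hs$positions, 3, al, dir)
      k <- nrow(got)
      expect_equal(got$ehh, ref$ehh[seq_len(k)], tolerance = 1e-12)
      expect_equal(got$distance, ref$distance[seq_len(k)])
      if (k < nrow(ref)) expect_true(all(ref$ehh[-seq_len(k)] == 0))
    }
  }
  expect_error(ehh(toy_haps(c("10", "00", "00"), c(1, 2)), 1, 1L), "carriers")
})

test_that("identical carrier haplotypes keep EHH at 1 to the region edge", {
  hs <- toy_haps(c("110101", "110101", "110101", "001010", "011010"),
                 c(2, 9, 17, 33, 41, 55))
  curve <- ehh(hs, 3, 1L, "right")
  expect_equal(curve$ehh, rep(1, 4))
})

test_that("EHH equals the oracle on random fixtures (oracle sweep)", {
  for (i in 1:50) {
    hs <- random_haps(n = sample(6:12, 1), S = sample(4:12, 1),
                      seed = 400 + i)
    core <- sample(ncol(hs$haplotypes), 1)
    cnt <- sum(hs$haplotypes[, core])
    al <- if (cnt >= 2 && cnt <= nrow(hs$haplotypes) - 2)
      sample(0:1, 1) else if (cnt >= 2) 1L else 0L
    dir <- sample(c("left", "right"), 1)
    got <- ehh(hs, core, al, dir)
    ref <- oracle_ehh(hs$haplotypes, hs$positions, core, al, dir)
    k <- nrow(got)
    expect_equal(got$ehh, ref$ehh[seq_len(k)], tolerance = 1e-10)
  }
})

test_that("iHS integrals match trapezoid arithmetic on a hand fixture", {
  rows <- c("11011011", "11011011", "11011001", "10011010",
            "00100110", "00100101", "00101110", "00100110")
  hs <- toy_haps(rows, c(100, 900, 2500, 4000, 5200, 7900, 8800, 9900))
  core <- 4
  got <- ihs_unstandardized(hs, core, truncation_ehh = 0.05,
                            max_extension = 1e5)
  for (al in c(0L, 1L)) {
    ref <- oracle_ihh(oracle_ehh(hs$haplotypes, hs$positions, core, al,
                                 "left"), 0.05, 1e5) +
      oracle_ihh(oracle_ehh(hs$haplotypes, hs$positions, core, al,
                            "right"), 0.05, 1e5)
    want <- if (al == 0L) got$ihh_ancestral else got$ihh_derived
    expect_equal(want, ref, tolerance = 1e-6)
  }
  expect_equal(got$uihs, log(got$ihh_ancestral / got$ihh_derived),
               tolerance = 1e-12)
  expect_equal(got$daf, mean(hs$haplotypes[, core]))
})

test_that("iHS oracle equivalence holds across random fixtures", {
  checked <- 0
  i <- 0
  while (checked < 50) {
    i <- i + 1
    hs <- random_haps(n = 10, S = sample(6:14, 1), seed = 500 + i)
    core <- sample(ncol(hs$haplotypes), 1)
    cnt <- sum(hs$haplotypes[, core])
    if (cnt < 2 || cnt > 8) next
    got <- ihs_unstandardized(hs, core, truncation_ehh = 0.05,
                              max_extension = 5000)
    ref_a <- oracle_ihh(oracle_ehh(hs$haplotypes, hs$positions, core, 0L,
                                   "left"), 0.05, 5000) +
      oracle_ihh(oracle_ehh(hs$haplotypes, hs$positions, core, 0L,
                            "right"), 0.05, 5000)
    expect_equal(got$ihh_ancestral, ref_a, tolerance = 1e-6)
    checked <- checked + 1
  }
})

test_that("mirror-image allele structures give uihs = 0", {
  # derived carriers are an exact copy of the ancestral carriers' flanks
  rows <- c("101010", "110001", "100011",
            "101110", "110101", "100111")
  hs <- toy_haps(rows, c(10, 20, 30, 40, 50, 60))
  got <- ihs_unstandardized(hs, 4, truncation_ehh = 0, max_extension = 1e5)
  expect_equal(got$ihh_ancestral, got$ihh_derived, tolerance = 1e-12)
  expect_equal(got$uihs, 0, tolerance = 1e-12)
})

test_that("iHH grows monotonically with the allowed extension", {
  hs <- random_haps(n = 12, S = 12, seed = 77)
  core <- 6
  exts <- c(500, 2000, 5000, 10000)
  vals <- vapply(exts, function(e)
    ihs_unstandardized(hs, core, truncation_ehh = 0,
                       max_extension = e)$ihh_derived, 0)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("standardized iHS has mean 0 and sd 1 within occupied bins", {
  set.seed(12)
  tab <- data.frame(site = 1:2000, position = 1:2000,
                    daf = runif(2000, 0.05, 0.95),
                    uihs = rnorm(2000, 1, 2))
  std <- ihs_standardize(tab)
  for (b in unique(std$bin)) {
    v <- std$ihs[std$bin == b]
    v <- v[!is.na(v)]
    if (length(v) >= 2) {
      expect_lt(abs(mean(v)), 1e-9)
      expect_lt(abs(sd(v) - 1), 1e-9)
    }
  }
})

test_that("DAF range filtering and two-bin hand arithmetic are exact", {
  tab <- data.frame(site = 1:7, position = 1:7,
                    daf = c(0.10, 0.12, 0.11, 0.80, 0.82, 0.96, 0.02),
                    uihs = c(1, 2, 3, 10, 14, 99, -99))
  std <- ihs_standardize(tab, n_bins = 2, daf_range = c(0.05, 0.95))
  expect_equal(nrow(std), 5L)           # 0.96 and 0.02 dropped
  expect_false(any(std$daf > 0.95 | std$daf < 0.05))
  lo <- std$ihs[std$bin == 1]
  expect_equal(lo, (c(1, 2, 3) - 2) / 1, tolerance = 1e-12)
  hi <- std$ihs[std$bin == 2]
  expect_equal(hi, (c(10, 14) - 12) / sd(c(10, 14)), tolerance = 1e-12)
})

test_that("standardization is invariant to within-bin affine rescaling", {
  set.seed(13)
  tab <- data.frame(site = 1:300, position = 1:300,
                    daf = runif(300, 0.05, 0.95), uihs = rnorm(300))
  s1 <- ihs_standardize(tab)
  tab2 <- tab
  tab2$uihs <- 3 * tab$uihs + 7   # affine map applied to every bin alike
  s2 <- ihs_standardize(tab2)
  expect_equal(s1$ihs, s2$ihs, tolerance = 1e-9)
})

test_that("precomputed bin statistics can standardize new sites", {
  set.seed(14)
  ref <- data.frame(site = 1:4000, position = 1:4000,
                    daf = runif(4000, 0.05, 0.95), uihs = rnorm(4000, 2, 3))
  bs <- attr(ihs_standardize(ref), "bin_stats")
  new <- data.frame(site = 1, position = 1, daf = 0.5, uihs = 2)
  std <- ihs_standardize(new, bin_stats = bs)
  b <- std$bin[1]
  expect_equal(std$ihs[1],
               (2 - bs$mean[bs$bin == b]) / bs$sd[bs$bin == b],
               tolerance = 1e-12)
})

test_that("F_ST separates fixed populations and is null for identical ones", {
  v <- variant_table("chr1", 1, "s1", "A", "G")
  d <- matrix(c(rep(0L, 50), rep(2L, 50)), nrow = 1)
  g <- genotype_matrix(v, d, paste0("i", 1:100),
                       rep(c("P1", "P2"), each = 50))
  expect_gte(fst_amova(g)$per_site$fst, 0.97)
  set.seed(15)
  m <- 200
  d2 <- matrix(rbinom(m * 200, 2, 0.4), nrow = m)
  g2 <- genotype_matrix(variant_table("chr1", 1:m, paste0("s", 1:m),
                                      "A", "G"),
                        d2, paste0("i", 1:200),
                        rep(c("P1", "P2"), each = 100))
  expect_lte(abs(fst_amova(g2)$global), 0.02)
})

test_that("F_ST equals the ANOVA oracle on toy and random tables", {
  # 3 populations x 6 individuals
  v <- variant_table("chr1", 1, "s1", "A", "G")
  d <- matrix(c(0L, 1L, 0L, 1L, 2L, 1L, 2L, 2L, 1L, 0L, 0L, 1L, 2L, 1L,
                2L, 2L, 1L, 2L), nrow = 1)
  pops <- rep(c("P1", "P2", "P3"), each = 6)
  g <- genotype_matrix(v, d, paste0("i", 1:18), pops)
  expect_equal(fst_amova(g)$per_site$fst,
               oracle_wc_fst_diploid(as.numeric(d), pops),
               tolerance = 1e-10)
  set.seed(16)
  for (i in 1:50) {
    r <- sample(2:4, 1)
    n_i <- sample(4:12, r, replace = TRUE)
    pops <- rep(paste0("P", seq_len(r)), times = n_i)
    repeat {
      dos <- rbinom(sum(n_i), 2, runif(1, 0.15, 0.85))
      if (var(dos) > 0 && mean(dos) / 2 > 0 && mean(dos) / 2 < 1) break
    }
    gg <- genotype_matrix(variant_table("chr1", 1, "s", "A", "G"),
                          matrix(dos, 1), paste0("i", seq_along(dos)), pops)
    expect_equal(fst_amova(gg)$per_site$fst,
                 oracle_wc_fst_diploid(dos, pops), tolerance = 1e-10)
  }
})

test_that("haploid F_ST from haplotypes matches its one-way ANOVA oracle", {
  set.seed(17)
  for (i in 1:20) {
    n <- 24
    H <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
    pops <- rep(c("P1", "P2"), each = n / 2)
    hs <- haplotype_set(H, positions = 1:5 * 10, population = pops)
    got <- fst_amova(hs)$per_site$fst
    ref <- vapply(1:5, function(j) oracle_wc_fst_haploid(H[, j], pops), 0)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("F_ST is invariant to label permutation and sample duplication", {
  set.seed(18)
  dos <- rbinom(150, 2, 0.4)
  pops <- rep(c("P1", "P2", "P3"), each = 50)
  g <- genotype_matrix(variant_table("chr1", 1, "s", "A", "G"),
                       matrix(dos, 1), paste0("i", 1:150), pops)
  base <- fst_amova(g)$per_site$fst
  relab <- c(P1 = "X", P2 = "Y", P3 = "Z")[pops]
  g2 <- genotype_matrix(g$variants, matrix(dos, 1), paste0("i", 1:150),
                        unname(relab))
  expect_equal(fst_amova(g2)$per_site$fst, base, tolerance = 1e-12)
  gd <- genotype_matrix(g$variants, matrix(rep(dos, 2), 1),
                        paste0("i", 1:300), c(pops, pops))
  expect_lt(abs(fst_amova(gd)$per_site$fst - base), 0.01)
})

test_that("monomorphic sites are flagged and missing data handled pairwise", {
  v <- variant_table("chr1", 1:2, c("s1", "s2"), "A", "G")
  d <- rbind(rep(1L, 20), rep(0L, 20))
  g <- genotype_matrix(v, d, paste0("i", 1:20),
                       rep(c("P1", "P2"), each = 10))
  # site 2 fixed overall -> NA; site 1 is all-het (polymorphic)
  fst <- fst_amova(g)
  expect_true(is.na(fst$per_site$fst[2]))
  expect_false(is.na(fst$per_site$fst[1]))
  set.seed(19)
  dos <- rbinom(40, 2, 0.5)
  dos[c(3, 17)] <- NA
  pops <- rep(c("P1", "P2"), each = 20)
  gm <- genotype_matrix(variant_table("chr1", 1, "s", "A", "G"),
                        matrix(dos, 1), paste0("i", 1:40), pops)
  expect_equal(fst_amova(gm)$per_site$fst,
               oracle_wc_fst_diploid(dos, pops), tolerance = 1e-10)
})

test_that("empirical p-values follow the add-one rank rule", {
  ref <- seq_len(999)
  top <- empirical_pvalue(1000, ref)
  expect_equal(top$p_emp, 1 / 1000)
  mid <- empirical_pvalue(500, ref)
  expect_equal(mid$p_emp, (500 + 1) / 1000)
  set.seed(20)
  r <- rnorm(100)
  for (obs in c(-2, 0, 1.3)) {
    expect_equal(empirical_pvalue(obs, r)$p_emp, oracle_empirical_p(obs, r),
                 tolerance = 1e-12)
    expect_equal(empirical_pvalue(obs, r, tail = "abs")$p_emp,
                 oracle_empirical_p(abs(obs), abs(r)), tolerance = 1e-12)
  }
  expect_error(empirical_pvalue(1, rnorm(10)), "too small")
})
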