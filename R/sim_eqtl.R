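# Synthetic genotype/expression panels with one planted cis effect, emulating
# a two-population monocyte eQTL cohort (default 100 + 100 individuals, two
# stimulation conditions).

#' Specification for a synthetic eQTL panel
#'
#' @param n_individuals individuals per population (length-2 vector; default
#'   `c(100, 100)`, African- and European-ancestry panels).
#' @param n_snps number of SNPs in the cis window (default 500).
#' @param maf_range range of simulated minor allele frequencies (default
#'   `c(0.05, 0.5)`, matching a >5% MAF genotyping filter).
#' @param beta_cis planted per-allele effect of the causal SNP on the
#'   inverse-normal-transformed expression scale, in units of total
#'   within-population phenotypic SD (default 0.5). 0 gives a fully null
#'   panel.
#' @param pop_shift mean expression offset of the second population (default
#'   0.3 SD; removed by the population covariate in the model).
#' @param n_conditions number of stimulation conditions, 1-4 (default 2:
#'   non-stimulated and LPS).
#' @param noise_sd residual SD of the target gene. The default `NULL`
#'   completes the target gene to unit total variance
#'   (`sqrt(1 - beta_cis^2 * var(dosage))`, resolved at simulation time), so
#'   that the rank-based inverse-normal transform leaves the planted
#'   per-allele-copy slope unchanged and `beta_cis` is directly recoverable
#'   by the eQTL fit.
#' @param ld_decay probability that an allele copies its state from the
#'   previous SNP in the latent copy process (first-order Markov LD along the
#'   panel; default 0.9). 0 gives independent SNPs.
#' @param n_genes total genes in the expression matrix (default 50); all but
#'   the target are pure noise.
#' @param causal_maf the causal SNP is chosen as the simulated SNP with
#'   overall MAF closest to this value (default 0.3, the worldwide frequency
#'   scale of the motivating variant).
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return a list of class `eqtl_sim_spec`.
#' @export
eqtl_sim_spec <- function(n_individuals = c(100, 100), n_snps = 500,
                          maf_range = c(0.05, 0.5), beta_cis = 0.5,
                          pop_shift = 0.3, n_conditions = 2, noise_sd = NULL,
                          ld_decay = 0.9, n_genes = 50, causal_maf = 0.3,
                          seed = 1) {
  stopifnot(length(n_individuals) == 2, n_snps >= 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            ld_decay >= 0, ld_decay < 1,
            n_conditions >= 1, n_conditions <= 4)
  if (!is.null(noise_sd) && noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 maf_range = maf_range, beta_cis = beta_cis,
                 pop_shift = pop_shift, n_conditions = n_conditions,
                 noise_sd = noise_sd, ld_decay = ld_decay, n_genes = n_genes,
                 causal_maf = causal_maf, seed = seed),
            class = "eqtl_sim_spec")
}

#' Simulate a genotype/expression panel with a planted cis-eQTL
#'
#' Genotypes for two populations are drawn with per-SNP allele frequencies
#' uniform in `maf_range` and local LD from a first-order Markov copy process
#' on allele copies (a latent uniform is re-used from the previous SNP with
#' probability `ld_decay`, which preserves the marginal frequencies). One SNP
#' (overall MAF closest to `causal_maf`) is designated causal: in every
#' condition the target gene is
#' `beta_cis * centered dosage + pop_shift * I(pop2) + N(0, noise_sd)`;
#' all other genes are standard-normal noise. Raw FPKM are derived as
#' `2^(baseline + log2-signal)` with per-gene baselines, for expression
#' filters.
#'
#' @param spec an [eqtl_sim_spec()].
#' @return list with `genotypes` (`GenotypeMatrix`), `expression`
#'   (`ExpressionMatrix`; samples = individuals x conditions), and `truth`
#'   (causal SNP id and index, target gene, `beta_cis`).
#' @export
simulate_eqtl_dataset <- function(spec) {
  stopifnot(inherits(spec, "eqtl_sim_spec"))
  set.seed(spec$seed)
  n1 <- spec$n_individuals[1]; n2 <- spec$n_individuals[2]
  n <- n1 + n2
  m <- spec$n_snps
  pops <- c(rep("AFB", n1), rep("EUB", n2))
  p <- runif(m, spec$maf_range[1], spec$maf_range[2])

  nh <- 2L * n
  Z <- matrix(NA_real_, nh, m)
  Z[, 1] <- runif(nh)
  if (m > 1) {
    for (j in 2:m) {
      fresh <- runif(nh)
      copy <- runif(nh) < spec$ld_decay
      Z[, j] <- ifelse(copy, Z[, j - 1], fresh)
    }
  }
  A <- sweep(Z, 2, p, "<") * 1L
  dos <- t(A[seq(1, nh, 2), , drop = FALSE] + A[seq(2, nh, 2), , drop = FALSE])
  storage.mode(dos) <- "integer"

  pos <- sort(sample.int(1e6, m)) + 20500000L
  ids <- sprintf("rs_sim%04d", seq_len(m))
  # ref is ancestral by construction; alt (= allele "1") is derived
  variants <- variant_table(chrom = "chr9", pos = pos, id = ids,
                            ref = "A", alt = "G", ancestral = "A")
  geno <- genotype_matrix(variants, dos, sprintf("ind%03d", seq_len(n)), pops)

  causal <- which.min(abs(geno$maf$maf_overall - spec$causal_maf))
  g <- as.numeric(dos[causal, ])
  gc <- g - mean(g)
  noise_sd <- spec$noise_sd
  if (is.null(noise_sd)) {
    resid_var <- 1 - spec$beta_cis^2 * var(g)
    if (resid_var <= 0)
      stop("planted effect explains the full unit variance; give noise_sd")
    noise_sd <- sqrt(resid_var)
  }

  conds <- c("NS", "LPS", "PAM3", "R848")[seq_len(spec$n_conditions)]
  samples <- as.vector(outer(sprintf("ind%03d", seq_len(n)), conds, paste,
                             sep = "_"))
  cond_lab <- rep(conds, each = n)
  pop_lab <- rep(pops, times = spec$n_conditions)
  ind_lab <- rep(sprintf("ind%03d", seq_len(n)), times = spec$n_conditions)

  genes <- sprintf("gene_%03d", seq_len(spec$n_genes))
  vals <- matrix(rnorm(spec$n_genes * length(samples)), spec$n_genes,
                 dimnames = list(genes, samples))
  target <- genes[1]
  for (k in seq_along(conds)) {
    cols <- seq_len(n) + (k - 1) * n
    vals[1, cols] <- spec$beta_cis * gc +
      spec$pop_shift * (pops == "EUB") +
      rnorm(n, sd = noise_sd)
  }
  baseline <- runif(spec$n_genes, 0, 10)
  expr <- expression_matrix(genes, vals, cond_lab, pop_lab, ind_lab,
                            fpkm_raw = 2^(vals + baseline))
  list(genotypes = geno,
       expression = expr,
       truth = list(causal_snp = ids[causal], causal_index = causal,
                    target_gene = target, beta_cis = spec$beta_cis,
                    causal_maf = geno$maf$maf_overall[causal]))
}
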