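# cis/trans eQTL mapping on inverse-normal-transformed expression with a
# population covariate, permutation-based family-wise error calibration,
# conditional analysis, and LD computation.
#
# All fits are ordinary least squares. For speed the scan residualizes
# phenotype and genotypes on the covariates once (QR projection) and obtains
# the dosage coefficient from the partial regression; this is numerically
# identical to refitting the full model per SNP.

#' Inverse normal rank transformation
#'
#' Maps values to normal quantiles `qnorm((rank - 0.5) / n)`, with average
#' ranks for ties. Applied to expression per condition before every eQTL fit,
#' making the phenotype scale-free and the planted effects comparable across
#' genes.
#'
#' @param x numeric vector with at least 3 finite values.
#' @return transformed vector (mean approximately 0).
#' @export
inverse_normal_transform <- function(x) {
  if (sum(is.finite(x)) < 3) stop("need at least 3 finite values")
  if (length(unique(x[is.finite(x)])) == 1L)
    stop("rank transform undefined for a constant vector")
  r <- rank(x, ties.method = "average", na.last = "keep")
  qnorm((r - 0.5) / sum(!is.na(r)))
}

# Residualize columns of M on covariates X (with intercept) via QR.
.residualize <- function(M, X) {
  Q <- qr.Q(qr(cbind(1, X)))
  M - Q %*% crossprod(Q, M)
}

# Core vectorized association: y (n) against each column of G (n x m),
# adjusting for covariates X. Returns beta/se/p/r2 per SNP.
.assoc_scan <- function(G, y, X) {
  n <- length(y)
  k <- 1L + if (is.null(dim(X))) as.integer(length(X) > 0) else ncol(X)
  if (is.null(dim(X)) && length(X)) X <- matrix(X, ncol = 1)
  df <- n - k - 1L
  yr <- .residualize(matrix(y, ncol = 1), X)
  Gr <- .residualize(G, X)
  gss <- colSums(Gr^2)
  yss <- sum(yr^2)
  mono <- gss < 1e-12 * n
  gss[mono] <- NA_real_
  beta <- as.vector(crossprod(Gr, yr)) / gss
  rss <- pmax(yss - beta^2 * gss, 0)
  se <- sqrt(rss / df / gss)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  p[rss == 0] <- 0
  r2 <- tstat^2 / (tstat^2 + df)
  r2[rss == 0] <- 1
  p[mono] <- 1
  r2[mono] <- NA_real_
  data.frame(beta = beta, se = se, p = p, r2 = r2, df = df,
             monomorphic = mono)
}

#' Single SNP-gene ordinary least squares fit
#'
#' Regresses (already transformed) expression on the dosage plus covariates;
#' the two-sided p-value for the dosage coefficient comes from the t
#' distribution, and `r2` is the partial variance explained by genotype after
#' the covariates (`t^2 / (t^2 + df)`).
#'
#' A monomorphic genotype yields `beta = NA`, `p = 1` and
#' `monomorphic = TRUE` rather than an error, so that set operations
#' downstream never crash.
#'
#' @param dosage numeric dosage vector.
#' @param expression transformed expression vector (same length).
#' @param covariates numeric vector/matrix of covariates (typically the
#'   population indicator); may be `NULL`.
#' @return one-row data.frame: `beta`, `se`, `p`, `r2`, `df`, `monomorphic`.
#' @export
fit_snp_gene <- function(dosage, expression, covariates = NULL) {
  stopifnot(length(dosage) == length(expression))
  if (length(dosage) < 10) stop("need at least 10 samples")
  X <- if (is.null(covariates)) matrix(nrow = length(dosage), ncol = 0)
       else as.matrix(covariates)
  .assoc_scan(matrix(as.numeric(dosage), ncol = 1), expression, X)
}

# Shared setup: transformed phenotype per condition, matched genotype matrix
# (individuals ordered as in the genotype object), population indicator.
.cis_setup <- function(geno, expr, target_gene, window = NULL, center = NULL,
                       extra_covar = NULL) {
  if (!target_gene %in% expr$genes) stop("gene not found: ", target_gene)
  snp_keep <- rep(TRUE, nrow(geno$variants))
  if (!is.null(window) && !is.null(center))
    snp_keep <- abs(geno$variants$pos - center) <= window / 2
  G_all <- t(impute_dosages(geno))  # individuals x variants
  G <- G_all[, snp_keep, drop = FALSE]
  pop_num <- as.numeric(factor(geno$population))
  conds <- unique(expr$condition)
  per_cond <- lapply(conds, function(cc) {
    cols <- which(expr$condition == cc)
    idx <- match(geno$individuals, expr$individual[cols])
    if (anyNA(idx)) stop("individuals missing from condition ", cc)
    y <- inverse_normal_transform(expr$values[match(target_gene, expr$genes),
                                              cols[idx]])
    y
  })
  names(per_cond) <- conds
  list(G = G, snp_ids = geno$variants$id[snp_keep], y = per_cond,
       X = cbind(pop = pop_num,
                 if (!is.null(extra_covar)) as.matrix(extra_covar)),
       population = geno$population)
}

#' Map cis-eQTLs of one gene
#'
#' Fits every SNP x condition pair in a window around the gene: the gene's
#' expression is inverse-normal transformed within each condition, then
#' regressed on the dosage with the population of origin as covariate.
#'
#' @param geno a `GenotypeMatrix`.
#' @param expr an `ExpressionMatrix` containing `target_gene` in every
#'   condition.
#' @param target_gene gene id to map.
#' @param window window size in bp (SNPs within `window / 2` of `center` are
#'   tested); `NULL` (default) tests all SNPs in `geno`.
#' @param center window midpoint (bp, 0-based), e.g. the gene's TSS.
#' @param covariate_snp optional SNP id whose dosage is added as a covariate
#'   (used by [conditional_scan()]).
#' @return data.frame with one row per SNP x condition: `snp`, `gene`,
#'   `condition`, `beta`, `se`, `p`, `r2`, `monomorphic`.
#' @export
map_cis_eqtl <- function(geno, expr, target_gene, window = NULL,
                         center = NULL, covariate_snp = NULL) {
  extra <- NULL
  if (!is.null(covariate_snp)) {
    j <- match(covariate_snp, geno$variants$id)
    if (is.na(j)) stop("covariate SNP not found: ", covariate_snp)
    cv <- impute_dosages(geno)[j, ]
    if (var(cv) == 0) stop("conditioning SNP is monomorphic")
    extra <- cv
  }
  st <- .cis_setup(geno, expr, target_gene, window, center, extra)
  if (ncol(st$G) == 0)
    return(data.frame(snp = character(), gene = character(),
                      condition = character(), beta = numeric(),
                      se = numeric(), p = numeric(), r2 = numeric(),
                      monomorphic = logical()))
  out <- do.call(rbind, lapply(names(st$y), function(cc) {
    res <- .assoc_scan(st$G, st$y[[cc]], st$X)
    data.frame(snp = st$snp_ids, gene = target_gene, condition = cc,
               res[c("beta", "se", "p", "r2", "monomorphic")])
  }))
  rownames(out) <- NULL
  if (!is.null(covariate_snp)) out <- out[out$snp != covariate_snp, ]
  out
}

#' Permutation calibration of the family-wise error rate
#'
#' Permutes the transformed phenotype across individuals *within each
#' population stratum* (the same permutation applied to every condition, so
#' the covariate structure and the cross-condition dependence are preserved
#' under the null), re-runs the scan, and records per permutation the lowest
#' p-value across all SNPs and conditions. The significance threshold is the
#' `target_fwer` empirical quantile of these minima, i.e. the k-th smallest
#' minimum with `k = floor(target_fwer * n_permutations)`.
#'
#' @inheritParams map_cis_eqtl
#' @param n_permutations number of permutations (>= 100; default 1000).
#' @param target_fwer target family-wise error rate (default 0.01).
#' @param seed RNG seed for the permutations.
#' @return list of class `FwerCalibration`: `threshold`, `min_p_distribution`,
#'   `n_permutations`, `target_fwer`, `seed`.
#' @export
permutation_fwer_threshold <- function(geno, expr, target_gene,
                                       n_permutations = 1000,
                                       target_fwer = 0.01, seed = 1,
                                       window = NULL, center = NULL) {
  if (n_permutations < 100) stop("need at least 100 permutations")
  k <- floor(target_fwer * n_permutations)
  if (k < 1)
    stop("target_fwer * n_permutations < 1: quantile unsupported")
  set.seed(seed)
  st <- .cis_setup(geno, expr, target_gene, window, center)
  n <- nrow(st$G)
  strata <- split(seq_len(n), st$population)
  perms <- replicate(n_permutations, {
    ix <- integer(n)
    for (s in strata) ix[s] <- s[sample.int(length(s))]
    ix
  })
  X <- st$X
  Q <- qr.Q(qr(cbind(1, X)))
  Gr <- st$G - Q %*% crossprod(Q, st$G)
  gss <- colSums(Gr^2)
  poly <- gss > 1e-12 * n
  df <- n - ncol(X) - 2L
  min_p <- rep(1, n_permutations)
  for (cc in names(st$y)) {
    Y <- matrix(st$y[[cc]][perms], nrow = n)
    Yr <- Y - Q %*% crossprod(Q, Y)
    B <- crossprod(Gr[, poly, drop = FALSE], Yr) / gss[poly]
    yss <- colSums(Yr^2)
    T2 <- B^2 * gss[poly] / (sweep(-(B^2 * gss[poly]), 2, yss, "+") / df)
    pmin_cond <- 2 * pt(-sqrt(apply(T2, 2, max)), df)
    min_p <- pmin(min_p, pmin_cond)
  }
  structure(list(threshold = sort(min_p)[k],
                 min_p_distribution = min_p,
                 n_permutations = n_permutations,
                 target_fwer = target_fwer, seed = seed),
            class = "FwerCalibration")
}

#' @export
print.FwerCalibration <- function(x, ...) {
  cat(sprintf("FwerCalibration: threshold p = %.3g at FWER %.2g (%d permutations)\n",
              x$threshold, x$target_fwer, x$n_permutations))
  invisible(x)
}

#' Conditional cis scan
#'
#' Re-runs [map_cis_eqtl()] with the dosage of `condition_on` added as a
#' covariate; the conditioned SNP itself is excluded from the results. Used
#' to ask whether any association remains once the lead variant is accounted
#' for.
#'
#' @inheritParams map_cis_eqtl
#' @param condition_on SNP id to condition on (must be polymorphic).
#' @return as [map_cis_eqtl()], without the conditioned SNP.
#' @export
conditional_scan <- function(geno, expr, target_gene, condition_on,
                             window = NULL, center = NULL) {
  map_cis_eqtl(geno, expr, target_gene, window = window, center = center,
               covariate_snp = condition_on)
}

#' Trans-eQTL scan of one SNP against all genes
#'
#' In one condition, tests the SNP against every gene (each gene
#' inverse-normal transformed within the condition), corrects p-values with
#' the Benjamini-Hochberg step-up procedure, and returns the associations
#' with `q <= fdr` and `|beta| >= min_abs_beta`, labelled up/down by the sign
#' of the effect.
#'
#' @param geno a `GenotypeMatrix`.
#' @param snp SNP id to test.
#' @param expr an `ExpressionMatrix`.
#' @param condition condition label to use (e.g. `"LPS"`).
#' @param fdr false discovery rate threshold (default 0.01).
#' @param min_abs_beta minimum absolute effect size (default 0.2).
#' @return list with `hits` (significant associations: `gene`, `beta`, `se`,
#'   `p`, `q`, `direction`) and `all` (the full per-gene table).
#' @export
map_trans_eqtl <- function(geno, snp, expr, condition, fdr = 0.01,
                           min_abs_beta = 0.2) {
  j <- match(snp, geno$variants$id)
  if (is.na(j)) stop("SNP not found: ", snp)
  if (length(unique(expr$genes)) < 2) stop("need at least 2 genes")
  cols <- which(expr$condition == condition)
  if (!length(cols)) stop("no samples in condition ", condition)
  idx <- match(geno$individuals, expr$individual[cols])
  if (anyNA(idx)) stop("individuals missing from condition ", condition)
  g <- impute_dosages(geno)[j, ]
  pop_num <- as.numeric(factor(geno$population))
  Y <- t(apply(expr$values[, cols[idx], drop = FALSE], 1,
               inverse_normal_transform))
  n <- length(g)
  X <- matrix(pop_num, ncol = 1)
  Q <- qr.Q(qr(cbind(1, X)))
  gr <- as.vector(g - Q %*% crossprod(Q, g))
  gss <- sum(gr^2)
  if (gss < 1e-12 * n) stop("SNP is monomorphic")
  Yr <- t(Y) - Q %*% crossprod(Q, t(Y))   # n x genes
  beta <- as.vector(crossprod(Yr, gr)) / gss
  df <- n - 3L
  rss <- pmax(colSums(Yr^2) - beta^2 * gss, 0)
  se <- sqrt(rss / df / gss)
  p <- 2 * pt(-abs(beta / se), df)
  q <- p.adjust(p, method = "BH")
  all <- data.frame(gene = expr$genes, beta = beta, se = se, p = p, q = q,
                    direction = ifelse(beta >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  hits <- all[all$q <= fdr & abs(all$beta) >= min_abs_beta, ]
  rownames(hits) <- NULL
  list(hits = hits, all = all, snp = snp, condition = condition,
       fdr = fdr, min_abs_beta = min_abs_beta)
}

#' Linkage disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of dosages across individuals, excluding
#' missing genotypes pairwise.
#'
#' @param a,b dosage vectors over the same individuals.
#' @return r^2 in `[0, 1]`; `NA` with a warning if either vector is
#'   monomorphic after missing-data removal.
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (var(a[ok]) == 0 || var(b[ok]) == 0) {
    warning("monomorphic input; r2 undefined")
    return(NA_real_)
  }
  cor(a[ok], b[ok])^2
}
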