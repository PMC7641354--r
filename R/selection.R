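# Population-genetic statistics around a focal SNP: Tajima's D, extended
# haplotype homozygosity (EHH) and the integrated haplotype score (iHS) with
# DAF-bin standardization, the Weir-Cockerham variance-components F_ST, and
# chromosome-wide empirical p-values.

#' Tajima's D over a window of a haplotype set
#'
#' Computes the mean pairwise difference pi, the number of segregating sites
#' S, the standard normalizing constants derived from the haplotype count n,
#' and `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`. With `S = 0`, `D` is
#' `NaN`.
#'
#' @param haps a `HaplotypeSet`.
#' @param window optional `c(start, end)` in bp (half-open) restricting the
#'   sites used; default uses all sites.
#' @return list of class `TajimaComponents`: `n`, `S`, `pi`, the constants
#'   `a1, a2, b1, b2, c1, c2, e1, e2`, and `D`.
#' @export
tajimas_d <- function(haps, window = NULL) {
  H <- haps$haplotypes
  if (!is.null(window)) {
    sel <- haps$positions >= window[1] & haps$positions < window[2]
    H <- H[, sel, drop = FALSE]
  }
  n <- nrow(H)
  if (n < 4) stop("need at least 4 haplotypes")
  cnt <- colSums(H)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  # pi as the average pairwise Hamming distance
  pi <- sum(cnt[seg] * (n - cnt[seg])) / choose(n, 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0) NaN else (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(list(n = n, S = S, pi = pi, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 c1 = c1, c2 = c2, e1 = e1, e2 = e2, D = D),
            class = "TajimaComponents")
}

#' @export
print.TajimaComponents <- function(x, ...) {
  cat(sprintf("Tajima's D = %.4f (n=%d, S=%d, pi=%.3f)\n", x$D, x$n, x$S,
              x$pi))
  invisible(x)
}

#' Extended haplotype homozygosity decay from a core site
#'
#' Among the haplotypes carrying `core_allele` at the core site, EHH at each
#' successive site outward is the probability that two randomly drawn
#' carriers are identical over all sites from the core to that site:
#' `EHH = sum_k C(n_k, 2) / C(n_core, 2)` over extended-haplotype classes k.
#' `EHH(0) = 1` and the curve is non-increasing.
#'
#' @param haps a `HaplotypeSet`.
#' @param core_site column index of the core site.
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @param direction `"left"` or `"right"` of the core.
#' @return data.frame `distance` (bp from the core, starting at 0) and `ehh`.
#' @export
ehh <- function(haps, core_site, core_allele, direction = c("right", "left")) {
  direction <- match.arg(direction)
  H <- haps$haplotypes
  carriers <- which(H[, core_site] == core_allele)
  nc <- length(carriers)
  if (nc < 2) stop("fewer than 2 carriers of the core allele")
  denom <- choose(nc, 2)
  S <- ncol(H)
  idx <- if (direction == "right") {
    if (core_site < S) (core_site + 1L):S else integer(0)
  } else {
    if (core_site > 1L) (core_site - 1L):1L else integer(0)
  }
  dist <- c(0, abs(haps$positions[idx] - haps$positions[core_site]))
  vals <- numeric(length(idx) + 1L)
  vals[1] <- 1
  grp <- rep(1L, nc)
  for (k in seq_along(idx)) {
    key <- grp * 2L + H[carriers, idx[k]]
    grp <- match(key, unique(key))
    sizes <- tabulate(grp)
    vals[k + 1L] <- sum(choose(sizes, 2)) / denom
    if (vals[k + 1L] == 0) {
      vals <- vals[seq_len(k + 1L)]
      dist <- dist[seq_len(k + 1L)]
      break
    }
  }
  data.frame(distance = dist, ehh = vals)
}

# Trapezoidal integral of an EHH curve, truncated where EHH first falls
# below `trunc` (the segment down to that point is included) or at
# `max_extension` bp. Returns the integral and whether it hit the cap.
.ihh_one_side <- function(curve, trunc, max_extension) {
  d <- curve$distance
  e <- curve$ehh
  below <- which(e < trunc)
  stop_k <- if (length(below)) below[1] else length(e)
  d <- d[seq_len(stop_k)]
  e <- e[seq_len(stop_k)]
  truncated <- length(below) == 0
  if (d[length(d)] > max_extension) {
    inside <- d <= max_extension
    k <- sum(inside)
    # interpolate EHH at the cap
    if (k < length(d)) {
      frac <- (max_extension - d[k]) / (d[k + 1] - d[k])
      d <- c(d[seq_len(k)], max_extension)
      e <- c(e[seq_len(k)], e[k] + frac * (e[k + 1] - e[k]))
      truncated <- e[length(e)] >= trunc
    }
  }
  if (length(d) < 2) return(list(ihh = 0, truncated = truncated))
  list(ihh = sum(diff(d) * (head(e, -1) + tail(e, -1)) / 2),
       truncated = truncated)
}

#' Unstandardized integrated haplotype score at a core site
#'
#' Integrates the EHH decay curve over physical distance (trapezoid rule) for
#' each allele, in both directions from the core, truncating where EHH falls
#' below `truncation_ehh` or at `max_extension` bp per side. The
#' unstandardized score is `uihs = ln(iHH_ancestral / iHH_derived)`; a sweep
#' on the derived allele (long derived haplotypes) therefore gives negative
#' values.
#'
#' @param haps a `HaplotypeSet`.
#' @param core_site column index of the (polarized) core site.
#' @param truncation_ehh EHH truncation threshold (default 0.05).
#' @param max_extension maximum integration distance per side in bp
#'   (default 50000, i.e. a 100 kb window around the site).
#' @return list of class `IhsResult`: `site`, `position`, `daf`,
#'   `ihh_ancestral`, `ihh_derived`, `uihs`, `truncated` (TRUE when EHH never
#'   fell below the threshold within the window on some side), and `ihs = NA`
#'   until standardized by [ihs_standardize()].
#' @export
ihs_unstandardized <- function(haps, core_site, truncation_ehh = 0.05,
                               max_extension = 50000) {
  cnt <- sum(haps$haplotypes[, core_site])
  n <- nrow(haps$haplotypes)
  if (cnt < 2 || n - cnt < 2)
    stop("both alleles need at least 2 carriers at the core site")
  parts <- lapply(c(0L, 1L), function(al) {
    l <- .ihh_one_side(ehh(haps, core_site, al, "left"),
                       truncation_ehh, max_extension)
    r <- .ihh_one_side(ehh(haps, core_site, al, "right"),
                       truncation_ehh, max_extension)
    list(ihh = l$ihh + r$ihh, truncated = l$truncated || r$truncated)
  })
  ihh_anc <- parts[[1]]$ihh
  ihh_der <- parts[[2]]$ihh
  structure(list(site = core_site,
                 position = haps$positions[core_site],
                 daf = cnt / n,
                 ihh_ancestral = ihh_anc, ihh_derived = ihh_der,
                 uihs = log(ihh_anc / ihh_der),
                 truncated = parts[[1]]$truncated || parts[[2]]$truncated,
                 ihs = NA_real_, bin = NA_integer_),
            class = "IhsResult")
}

#' Standardize iHS in derived-allele-frequency bins
#'
#' Within each of `n_bins` equal-width DAF bins over `daf_range`, the
#' unstandardized scores are centred and scaled
#' (`ihs = (uihs - bin mean) / bin sd`), so that standardized scores are
#' comparable across frequencies. Sites outside `daf_range` are dropped;
#' bins with fewer than 2 sites are flagged and left unstandardized.
#'
#' @param results list of `IhsResult` (or data.frame with `uihs`, `daf`).
#' @param n_bins number of DAF bins (default 40).
#' @param daf_range analysed DAF interval (default `c(0.05, 0.95)`).
#' @param bin_stats optional precomputed data.frame (`bin`, `mean`, `sd`),
#'   e.g. from a genome-wide neutral reference, used instead of the bin
#'   statistics of `results` itself.
#' @return data.frame with one row per retained site: `site`, `position`,
#'   `daf`, `uihs`, `bin`, `ihs` (`NA` in sparse bins), plus the bin table as
#'   attribute `"bin_stats"`.
#' @export
ihs_standardize <- function(results, n_bins = 40, daf_range = c(0.05, 0.95),
                            bin_stats = NULL) {
  tab <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r)
      data.frame(site = r$site, position = r$position, daf = r$daf,
                 uihs = r$uihs)))
  tab <- tab[tab$daf >= daf_range[1] & tab$daf <= daf_range[2] &
               is.finite(tab$uihs), , drop = FALSE]
  breaks <- seq(daf_range[1], daf_range[2], length.out = n_bins + 1)
  tab$bin <- findInterval(tab$daf, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  if (is.null(bin_stats)) {
    bs <- do.call(rbind, lapply(split(tab$uihs, tab$bin), function(u)
      data.frame(n = length(u), mean = mean(u), sd = sd(u))))
    bs$bin <- as.integer(rownames(bs))
    if (all(bs$n >= 2) && nrow(bs) == 1 && bs$sd == 0)
      stop("all sites in one bin with zero variance; cannot standardize")
    bin_stats <- bs
  }
  m <- bin_stats$mean[match(tab$bin, bin_stats$bin)]
  s <- bin_stats$sd[match(tab$bin, bin_stats$bin)]
  ok_bins <- if (is.null(bin_stats$n)) bin_stats$bin
             else bin_stats$bin[bin_stats$n >= 2]
  usable <- !is.na(s) & s > 0 & tab$bin %in% ok_bins
  tab$ihs <- ifelse(usable, (tab$uihs - m) / s, NA_real_)
  rownames(tab) <- NULL
  attr(tab, "bin_stats") <- bin_stats
  tab
}

#' Weir-Cockerham F_ST across populations
#'
#' Per-SNP variance-components estimator (theta of Weir & Cockerham 1984)
#' across all populations at once, from diploid dosages: components `a`
#' (among populations), `b` (among individuals within populations) and `c`
#' (within individuals), with `fst = a / (a + b + c)`. Missing genotypes are
#' excluded pairwise; negative estimates are retained (not clipped). The
#' global value over a set of SNPs is the ratio of summed components, and a
#' per-SNP "global" estimate is the multi-population estimate at that SNP.
#'
#' @param geno a `GenotypeMatrix` (populations from its labels), or a
#'   `HaplotypeSet` (haploid variant of the estimator: `c = 0` and allele
#'   counts play the role of individuals).
#' @param sites optional variant index restriction.
#' @return list of class `FstResult`: `per_site` data.frame (`id`, `a`, `b`,
#'   `c`, `fst`; `NA` where the site is monomorphic overall) and `global`
#'   (ratio of sums over usable sites).
#' @export
fst_amova <- function(geno, sites = NULL) {
  if (inherits(geno, "HaplotypeSet")) {
    A <- t(geno$haplotypes)  # sites x haplotypes, 0/1 alleles
    pops <- geno$population
    ids <- geno$site_id
    haploid <- TRUE
  } else {
    A <- geno$dosages
    pops <- geno$population
    ids <- geno$variants$id
    haploid <- FALSE
  }
  if (!is.null(sites)) {
    A <- A[sites, , drop = FALSE]
    ids <- ids[sites]
  }
  upops <- unique(pops)
  r <- length(upops)
  if (r < 2) stop("need at least 2 populations")
  ns <- sapply(upops, function(p) sum(pops == p))
  if (any(ns < 2)) stop("each population needs at least 2 samples")
  per <- t(apply(A, 1, function(row) .wc_site(row, pops, upops, haploid)))
  per_site <- data.frame(id = ids, a = per[, 1], b = per[, 2], c = per[, 3],
                         fst = per[, 4])
  ok <- !is.na(per_site$fst)
  global <- if (any(ok))
    sum(per_site$a[ok]) / sum(per_site$a[ok] + per_site$b[ok] +
                                per_site$c[ok]) else NA_real_
  structure(list(per_site = per_site, global = global,
                 populations = upops), class = "FstResult")
}

# Weir & Cockerham (1984) components at one site. For diploid input `row`
# holds dosages 0/1/2 (NA allowed); for haploid input 0/1 alleles, where the
# heterozygosity terms vanish and individuals are haplotypes.
.wc_site <- function(row, pops, upops, haploid) {
  n_i <- p_i <- h_i <- numeric(length(upops))
  for (k in seq_along(upops)) {
    x <- row[pops == upops[k]]
    x <- x[!is.na(x)]
    n_i[k] <- length(x)
    if (haploid) {
      p_i[k] <- mean(x)
      h_i[k] <- 0
    } else {
      p_i[k] <- mean(x) / 2
      h_i[k] <- mean(x == 1)
    }
  }
  if (any(n_i < 1)) return(c(NA, NA, NA, NA))
  r <- length(upops)
  nbar <- mean(n_i)
  p_all <- sum(n_i * p_i) / (r * nbar)
  if (p_all <= 0 || p_all >= 1) return(c(NA, NA, NA, NA))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  s2 <- sum(n_i * (p_i - p_all)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (p_all * (1 - p_all) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (p_all * (1 - p_all) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (haploid) {
    # haploid theta: no within-individual component; b reduces accordingly
    a <- (nbar / nc) *
      (s2 - (p_all * (1 - p_all) - (r - 1) / r * s2) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (p_all * (1 - p_all) - (r - 1) / r * s2)
    cc <- 0
  }
  c(a, b, cc, a / (a + b + cc))
}

#' @export
print.FstResult <- function(x, ...) {
  cat(sprintf("FstResult: global F_ST = %.4f over %d sites, %d populations\n",
              x$global, nrow(x$per_site), length(x$populations)))
  invisible(x)
}

#' Empirical p-value of an observed statistic
#'
#' Rank-based p-value against a chromosome-wide reference distribution with
#' the add-one rule: `p = (#(reference >= observed) + 1) / (N + 1)`, so p is
#' never zero; ties count as greater-or-equal. `tail = "abs"` applies the
#' absolute value to both sides first (used for iHS).
#'
#' @param observed observed statistic.
#' @param reference numeric vector of reference values (N >= 20).
#' @param tail `"upper"` or `"abs"`.
#' @return list of class `EmpiricalP`: `observed`, `N`, `rank` (number of
#'   reference values >= observed), `p_emp`.
#' @export
empirical_pvalue <- function(observed, reference, tail = c("upper", "abs")) {
  tail <- match.arg(tail)
  reference <- reference[is.finite(reference)]
  if (length(reference) < 20) stop("reference distribution too small (< 20)")
  if (tail == "abs") {
    observed <- abs(observed)
    reference <- abs(reference)
  }
  cnt <- sum(reference >= observed)
  structure(list(observed = observed, N = length(reference), rank = cnt,
                 p_emp = (cnt + 1) / (length(reference) + 1)),
            class = "EmpiricalP")
}

#' @export
print.EmpiricalP <- function(x, ...) {
  cat(sprintf("Empirical p = %.4g (observed %.4g, N = %d)\n", x$p_emp,
              x$observed, x$N))
  invisible(x)
}
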