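# Independent brute-force oracles, coded separately from the package
# implementations they check (explicit pairwise loops, ANOVA sums of squares,
# direct step-up recursions).

# Tajima's D by explicit pairwise Hamming distances over all haplotype pairs.
oracle_tajima_d <- function(H) {
  n <- nrow(H)
  prs <- utils::combn(n, 2)
  pi_hat <- mean(apply(prs, 2, function(ix) sum(H[ix[1], ] != H[ix[2], ])))
  S <- sum(apply(H, 2, function(col) length(unique(col)) == 2L))
  if (S == 0) return(NaN)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_hat - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Weir-Cockerham theta via the nested random-effects ANOVA route
# (alleles within individuals within populations), algebraically equivalent
# to the 1984 moment estimator but computed from sums of squares.
oracle_wc_fst_diploid <- function(dosage, pops) {
  ok <- !is.na(dosage)
  dosage <- dosage[ok]; pops <- pops[ok]
  upops <- unique(pops)
  r <- length(upops)
  n_i <- sapply(upops, function(p) sum(pops == p))
  ntot <- sum(n_i)
  p_i <- sapply(upops, function(p) mean(dosage[pops == p]) / 2)
  pbar <- sum(n_i * p_i) / ntot
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  # sums of squares on the allele indicator y in {0,1}
  SSG <- sum(dosage == 1) * 0.5
  ybar_ind <- dosage / 2
  SSI <- 2 * sum((ybar_ind - p_i[match(pops, upops)])^2)
  SSP <- 2 * sum(n_i * (p_i - pbar)^2)
  MSG <- SSG / ntot
  MSI <- SSI / (ntot - r)
  MSP <- SSP / (r - 1)
  nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  sG <- MSG
  sI <- (MSI - MSG) / 2
  sP <- (MSP - MSI) / (2 * nc)
  sP / (sP + sI + sG)
}

# Haploid analogue: one-way ANOVA on allele indicators.
oracle_wc_fst_haploid <- function(allele, pops) {
  upops <- unique(pops)
  r <- length(upops)
  n_i <- sapply(upops, function(p) sum(pops == p))
  ntot <- sum(n_i)
  p_i <- sapply(upops, function(p) mean(allele[pops == p]))
  pbar <- sum(n_i * p_i) / ntot
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  SSW <- sum((allele - p_i[match(pops, upops)])^2)
  SSP <- sum(n_i * (p_i - pbar)^2)
  MSW <- SSW / (ntot - r)
  MSP <- SSP / (r - 1)
  nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  sP <- (MSP - MSW) / nc
  sP / (sP + MSW)
}

# EHH by explicit pairwise identity over the spanned interval.
oracle_ehh <- function(H, pos, core, allele, direction) {
  carriers <- which(H[, core] == allele)
  prs <- utils::combn(length(carriers), 2)
  idx <- if (direction == "right") {
    if (core < ncol(H)) (core + 1L):ncol(H) else integer(0)
  } else {
    if (core > 1L) (core - 1L):1L else integer(0)
  }
  dist <- 0
  vals <- 1
  span <- integer(0)
  for (j in idx) {
    span <- c(span, j)
    same <- apply(prs, 2, function(px)
      all(H[carriers[px[1]], span] == H[carriers[px[2]], span]))
    dist <- c(dist, abs(pos[j] - pos[core]))
    vals <- c(vals, mean(same))
  }
  data.frame(distance = dist, ehh = vals)
}

# Trapezoid integral of an EHH curve with the same truncation contract as
# the implementation: stop at the first point below `trunc` (inclusive),
# cap at `max_ext` with linear interpolation.
oracle_ihh <- function(curve, trunc = 0.05, max_ext = 50000) {
  d <- curve$distance; e <- curve$ehh
  stop_k <- length(e)
  for (k in seq_along(e)) if (e[k] < trunc) { stop_k <- k; break }
  d <- d[1:stop_k]; e <- e[1:stop_k]
  if (max(d) > max_ext) {
    k <- max(which(d <= max_ext))
    f <- (max_ext - d[k]) / (d[k + 1] - d[k])
    d <- c(d[1:k], max_ext)
    e <- c(e[1:k], e[k] + f * (e[k + 1] - e[k]))
  }
  if (length(d) < 2) return(0)
  tot <- 0
  for (k in 2:length(d)) tot <- tot + (d[k] - d[k - 1]) * (e[k] + e[k - 1]) / 2
  tot
}

# Benjamini-Hochberg adjusted values by the textbook step-up recursion.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, m * p[o[k]] / k)
    q[o[k]] <- running
  }
  q
}

# PWM hits by an explicit double loop over start positions and strands.
oracle_pwm_hits <- function(pwm, seqstr, min_rel = 0.85) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqstr, "")[[1]]
  L <- pwm$length
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- NULL
  for (start in 0:(length(chars) - L)) {
    win <- chars[(start + 1):(start + L)]
    if (!all(win %in% bases)) next
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rev(unname(comp[win]))
      raw <- 0
      for (k in seq_len(L)) raw <- raw + pwm$weights[match(w[k], bases), k]
      rel <- (raw - pwm$min_score) / (pwm$max_score - pwm$min_score)
      if (rel >= min_rel)
        out <- rbind(out, data.frame(start = start, strand = strand,
                                     raw_score = raw, relative_score = rel))
    }
  }
  out
}

# Empirical p by sort-and-count.
oracle_empirical_p <- function(obs, ref) {
  (length(ref[ref >= obs]) + 1) / (length(ref) + 1)
}
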