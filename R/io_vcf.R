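# VCF input/output. Parsing is delegated to vcfR; this layer filters to
# biallelic SNPs, converts 1-based positions to the internal 0-based
# convention, decodes dosages and (for phased files) polarized haplotypes.

#' Read genotypes (and haplotypes) from a VCF
#'
#' Reads a VCF 4.x file, keeps biallelic SNPs above a minor-allele-frequency
#' cutoff, and returns dosage-coded genotypes. When every genotype is phased
#' (`|` separator) a [haplotype_set()] polarized to ancestral/derived is also
#' returned; sites whose ancestral allele (INFO `AA` tag, or `ancestral`
#' side table) is missing or matches neither allele are dropped from the
#' haplotypes and counted.
#'
#' @param path path to a plain or bgzipped VCF.
#' @param region optional `list(chrom=, start=, end=)`, 0-based half-open,
#'   restricting the variants read.
#' @param min_maf minimum overall minor allele frequency; sites strictly below
#'   are removed (default 0, keep all).
#' @param population per-sample population labels; defaults to a single
#'   `"POP1"` stratum.
#' @param ancestral optional named character vector (variant id -> ancestral
#'   base) overriding the `AA` INFO tag.
#' @return a list with elements `genotypes` (a `GenotypeMatrix`),
#'   `haplotypes` (a `HaplotypeSet` or `NULL` if unphased), and
#'   `n_unpolarized` (sites dropped from the haplotypes for lack of a usable
#'   ancestral allele).
#' @export
read_vcf <- function(path, region = NULL, min_maf = 0, population = NULL,
                     ancestral = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  bases <- c("A", "C", "G", "T")
  keep <- fix$REF %in% bases & fix$ALT %in% bases
  if (!is.null(region)) {
    pos0 <- as.integer(fix$POS) - 1L
    keep <- keep & fix$CHROM == region$chrom &
      pos0 >= region$start & pos0 < region$end
  }
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]
  n_sites <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(population)) population <- rep("POP1", length(samples))
  if (n_sites == 0) {
    warning("no variants survive filtering in ", path)
    empty <- genotype_matrix(
      variant_table(character(0), integer(0), character(0), character(0),
                    character(0)),
      matrix(integer(0), 0, length(samples)), samples, population)
    return(list(genotypes = empty, haplotypes = NULL, n_unpolarized = 0L))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (n_sites == 1 && is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  bad <- !grepl("^(\\.|[01])([|/]([.]|[01]))?$", gt) & !is.na(gt)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype '%s' at %s:%s sample %s",
                 gt[bad][1], fix$CHROM[w[1]], fix$POS[w[1]], samples[w[2]]))
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  a2[a2 == ""] <- a1[a2 == ""]  # haploid records
  to_int <- function(x) ifelse(x == ".", NA_integer_, as.integer(x))
  h1 <- matrix(to_int(a1), nrow = n_sites)
  h2 <- matrix(to_int(a2), nrow = n_sites)
  dos <- h1 + h2

  id <- fix$ID
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  aa <- toupper(vcfR::extract.info(vcf, element = "AA"))
  if (!is.null(ancestral)) {
    override <- match(id, names(ancestral))
    aa[!is.na(override)] <- ancestral[override[!is.na(override)]]
  }
  aa[!aa %in% bases] <- NA_character_
  usable_aa <- !is.na(aa) & (aa == fix$REF | aa == fix$ALT)
  aa[!usable_aa] <- NA_character_

  variants <- variant_table(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
                            id = id, ref = fix$REF, alt = fix$ALT,
                            ancestral = aa)
  geno <- genotype_matrix(variants, dos, samples, population)
  pass_maf <- geno$maf$maf_overall >= min_maf & !is.na(geno$maf$maf_overall)
  geno <- subset_genotypes(geno, pass_maf)
  if (nrow(geno$variants) == 0)
    warning("no variants survive filtering in ", path)

  haps <- NULL
  n_unpolarized <- 0L
  phased <- all(grepl("\\|", gt) | is.na(gt))
  if (phased && nrow(geno$variants) > 0) {
    keep2 <- which(pass_maf)
    pol <- !is.na(variants$ancestral[keep2])
    n_unpolarized <- sum(!pol)
    sel <- keep2[pol]
    # sites with any missing call cannot enter the haplotype matrix
    complete <- rowSums(is.na(h1[sel, , drop = FALSE])) +
      rowSums(is.na(h2[sel, , drop = FALSE])) == 0
    sel <- sel[complete]
    if (length(sel) > 0) {
      H <- matrix(0L, nrow = 2 * length(samples), ncol = length(sel))
      H[seq(1, nrow(H), by = 2), ] <- t(h1[sel, , drop = FALSE])
      H[seq(2, nrow(H), by = 2), ] <- t(h2[sel, , drop = FALSE])
      # polarize: 1 must mean "derived"; flip sites whose ancestral is ALT
      flip <- variants$ancestral[sel] == fix$ALT[sel]
      H[, flip] <- 1L - H[, flip]
      haps <- haplotype_set(H, positions = variants$pos[sel],
                            population = rep(population, each = 2),
                            site_id = variants$id[sel],
                            chrom = variants$chrom[sel][1])
    }
  }
  list(genotypes = geno, haplotypes = haps, n_unpolarized = n_unpolarized)
}

#' Subset a GenotypeMatrix by variant
#'
#' @param geno a `GenotypeMatrix`.
#' @param which logical or integer index over variants.
#' @return the subsetted `GenotypeMatrix` (MAF recomputed).
#' @export
subset_genotypes <- function(geno, which) {
  genotype_matrix(geno$variants[which, , drop = FALSE],
                  geno$dosages[which, , drop = FALSE],
                  geno$individuals, geno$population)
}

#' Mean-impute missing dosages
#'
#' Missing genotypes are replaced by the per-variant, per-population mean
#' dosage (the convention used by the eQTL regressions; allele-frequency and
#' F_ST computations instead exclude missing calls pairwise).
#'
#' @param geno a `GenotypeMatrix`.
#' @return numeric dosage matrix with no missing values.
#' @export
impute_dosages <- function(geno) {
  d <- geno$dosages
  storage.mode(d) <- "double"
  if (!anyNA(d)) return(d)
  for (p in unique(geno$population)) {
    cols <- geno$population == p
    sub <- d[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) sub[idx] <- mu[idx[, 1]]
    d[, cols] <- sub
  }
  d[is.na(d)] <- 0
  d
}

#' Write a GenotypeMatrix or HaplotypeSet to a VCF file
#'
#' Emits a minimal VCF 4.2 with `GT` genotypes and the ancestral allele in the
#' `AA` INFO tag; internal 0-based positions are converted back to 1-based.
#' A `HaplotypeSet` is written phased, pairing consecutive haplotypes into
#' individuals (ref = ancestral, alt = derived).
#'
#' @param x a `GenotypeMatrix` or `HaplotypeSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "HaplotypeSet")) {
    n_ind <- nrow(x$haplotypes) / 2
    if (n_ind != floor(n_ind)) stop("odd number of haplotypes")
    h1 <- x$haplotypes[seq(1, by = 2, length.out = n_ind), , drop = FALSE]
    h2 <- x$haplotypes[seq(2, by = 2, length.out = n_ind), , drop = FALSE]
    gts <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(x$haplotypes))
    fix <- data.frame(chrom = x$chrom, pos1 = x$positions + 1, id = x$site_id,
                      ref = "A", alt = "G", info = "AA=A")
    samples <- paste0("ind", seq_len(n_ind))
  } else {
    v <- x$variants
    gts <- x$dosages
    gts[] <- c("0/0", "0/1", "1/1")[x$dosages + 1L]
    gts[is.na(x$dosages)] <- "./."
    info <- ifelse(is.na(v$ancestral), ".", paste0("AA=", v$ancestral))
    fix <- data.frame(chrom = v$chrom, pos1 = v$pos + 1, id = v$id,
                      ref = v$ref, alt = v$alt, info = info)
    samples <- x$individuals
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  body <- cbind(fix$chrom, fix$pos1, fix$id, fix$ref, fix$alt, ".", "PASS",
                fix$info, "GT", gts)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
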