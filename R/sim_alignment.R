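# Synthetic ortholog alignment blocks: a root sequence independently mutated
# per species (star phylogeny), with a motif consensus planted in a
# controllable number of species at a fixed offset from the focal column.

#' Specification for a synthetic ortholog alignment
#'
#' @param n_species number of species, reference included (default 46,
#'   emulating a 46-way vertebrate alignment).
#' @param seq_length alignment length in bp (default 201; the focal column is
#'   the central one).
#' @param substitution_prob per-base probability that a species differs from
#'   the root (default 0.1).
#' @param motif consensus motif string over `{A,C,G,T}` planted around the
#'   focal column (default `"TTTGTCAAC"`, a C/EBP-like site).
#' @param n_species_with_motif number of species (taken in order, reference
#'   first) that receive the exact motif (default `n_species`).
#' @param motif_offset start of the motif relative to the focal column
#'   (default centers the motif on it).
#' @param seed RNG seed.
#' @return list of class `aln_sim_spec`.
#' @export
aln_sim_spec <- function(n_species = 46, seq_length = 201,
                         substitution_prob = 0.1, motif = "TTTGTCAAC",
                         n_species_with_motif = n_species,
                         motif_offset = -(nchar(motif) %/% 2), seed = 1) {
  stopifnot(n_species >= 1, n_species <= 46,
            n_species_with_motif <= n_species, n_species_with_motif >= 0,
            grepl("^[ACGT]+$", motif))
  if (nchar(motif) > seq_length)
    stop("motif longer than the simulated sequence")
  structure(list(n_species = n_species, seq_length = seq_length,
                 substitution_prob = substitution_prob, motif = motif,
                 n_species_with_motif = n_species_with_motif,
                 motif_offset = motif_offset, seed = seed),
            class = "aln_sim_spec")
}

#' Simulate an ortholog alignment block with a planted motif
#'
#' The root sequence is uniform random; each species' row is the root with
#' independent substitutions at rate `substitution_prob`. The motif consensus
#' is then written into the first `n_species_with_motif` species at
#' `motif_offset` relative to the focal (central) column; the remaining
#' species keep their background sequence there. The block is ungapped, so
#' the reference column map is the identity.
#'
#' @param spec an [aln_sim_spec()].
#' @return an [alignment_block()] with attribute fields `focal_column`
#'   (1-based) and `motif_species`.
#' @export
simulate_ortholog_alignment <- function(spec) {
  stopifnot(inherits(spec, "aln_sim_spec"))
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  L <- spec$seq_length
  root <- sample(bases, L, replace = TRUE)
  focal <- L %/% 2 + 1L
  mstart <- focal + spec$motif_offset
  if (mstart < 1 || mstart + nchar(spec$motif) - 1L > L)
    stop("motif does not fit in the sequence at the requested offset")
  species <- c("hg_sim", sprintf("sp_sim%02d", seq_len(spec$n_species - 1)))
  motif_chars <- strsplit(spec$motif, "")[[1]]
  rows <- character(spec$n_species)
  for (i in seq_len(spec$n_species)) {
    s <- root
    mut <- runif(L) < spec$substitution_prob
    if (any(mut))
      s[mut] <- vapply(s[mut], function(b)
        sample(setdiff(bases, b), 1), "")
    if (i <= spec$n_species_with_motif)
      s[mstart:(mstart + length(motif_chars) - 1L)] <- motif_chars
    rows[i] <- paste(s, collapse = "")
  }
  blk <- alignment_block(species, rows, ref_species = species[1],
                        ref_chrom = "chrSim", ref_start = 0L)
  blk$focal_column <- focal
  blk$motif_species <- species[seq_len(spec$n_species_with_motif)]
  blk
}
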