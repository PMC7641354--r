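# Forward Wright-Fisher haplotype simulation (compiled core in src/wf_sim.cpp)
# under neutrality or a partial selective sweep, producing a polarized
# HaplotypeSet for the selection-scan statistics.

#' Specification for a Wright-Fisher haplotype simulation
#'
#' The simulator evolves `pop_size` haploid haplotypes forward in time under
#' infinite-sites mutation and uniform recombination, then samples
#' `n_haplotypes` of them. Default rates are scaled down from human values so
#' that a 100 kb region at population size 400 carries on the order of a
#' hundred segregating sites (theta = 2 * pop_size * mutation_density *
#' region_length = 20, and rho = theta).
#'
#' @param n_haplotypes haplotypes sampled from the final population
#'   (default 200).
#' @param region_length region length in bp (default 1e5).
#' @param mutation_density per-bp per-haplotype per-generation mutation rate
#'   (default 2.5e-7).
#' @param recomb_prob per-bp per-generation recombination probability
#'   (default 2.5e-7).
#' @param pop_size haploid population size (default 400).
#' @param n_generations neutral burn-in generations (default
#'   `10 * pop_size`, comfortably past the coalescent time scale).
#' @param sweep `NULL` for neutrality, else
#'   `list(site_position=, selection_coefficient=, final_frequency=)`: after
#'   the burn-in a single derived copy is injected at `site_position` and
#'   evolved under selection until it reaches `final_frequency` (restarting
#'   on loss, up to `max_restarts`).
#' @param max_restarts maximum sweep restarts before erroring (default 100).
#' @param seed RNG seed.
#' @return list of class `hap_sim_spec`.
#' @export
hap_sim_spec <- function(n_haplotypes = 200, region_length = 1e5,
                         mutation_density = 2.5e-7, recomb_prob = 2.5e-7,
                         pop_size = 400, n_generations = 10 * pop_size,
                         sweep = NULL, max_restarts = 100, seed = 1) {
  stopifnot(mutation_density >= 0, recomb_prob >= 0, region_length > 0,
            n_haplotypes >= 2, n_haplotypes <= pop_size)
  if (!is.null(sweep)) {
    stopifnot(sweep$final_frequency > 0, sweep$final_frequency < 1,
              sweep$selection_coefficient >= 0,
              sweep$site_position >= 0,
              sweep$site_position < region_length)
  }
  structure(list(n_haplotypes = n_haplotypes, region_length = region_length,
                 mutation_density = mutation_density,
                 recomb_prob = recomb_prob, pop_size = pop_size,
                 n_generations = n_generations, sweep = sweep,
                 max_restarts = max_restarts, seed = seed),
            class = "hap_sim_spec")
}

#' Simulate phased haplotypes under neutrality or a partial sweep
#'
#' Runs the forward Wright-Fisher core and samples a [haplotype_set()]. The
#' returned set keeps only sites segregating in the sample; alleles are coded
#' 0 = ancestral, 1 = derived by construction (every mutation creates a new
#' derived allele). Under a sweep the focal site is guaranteed present and its
#' sample index is reported in the `focal_site` element, together with the
#' number of restarts the sweep needed.
#'
#' @param spec a [hap_sim_spec()].
#' @return a `HaplotypeSet`; under a sweep it carries `focal_site` (column
#'   index), `focal_position` (bp) and `sweep_restarts` elements.
#' @export
simulate_haplotypes <- function(spec) {
  stopifnot(inherits(spec, "hap_sim_spec"))
  set.seed(spec$seed)
  mu_region <- spec$mutation_density * spec$region_length
  rec_region <- spec$recomb_prob * spec$region_length
  sw <- spec$sweep
  res <- wf_sim_cpp(n_pop = spec$pop_size, n_gen = spec$n_generations,
                    mu_region = mu_region, rec_region = rec_region,
                    region_length = spec$region_length,
                    sweep_pos = if (is.null(sw)) -1 else sw$site_position,
                    sel_coef = if (is.null(sw)) 0 else sw$selection_coefficient,
                    target_freq = if (is.null(sw)) 0 else sw$final_frequency,
                    max_sweep_gen = 100000L,
                    max_restarts = spec$max_restarts)
  H <- res$haplotypes
  take <- sample.int(nrow(H), spec$n_haplotypes)
  H <- H[take, , drop = FALSE]
  counts <- colSums(H)
  keep <- counts > 0 & counts < nrow(H)
  focal <- res$sweep_index
  if (!is.null(sw)) {
    if (focal < 0 || !keep[focal])
      stop("sweep site monomorphic in the sample; increase n_haplotypes")
  }
  H <- H[, keep, drop = FALSE]
  pos <- floor(res$positions[keep])
  if (!is.null(sw)) focal <- sum(keep[seq_len(focal)])
  # infinite-sites positions are continuous; resolve rare bp collisions by
  # dropping the later site (never the focal one)
  dup <- duplicated(pos)
  if (!is.null(sw) && dup[focal]) {
    dup[focal] <- FALSE
    dup[match(pos[focal], pos)] <- TRUE
  }
  H <- H[, !dup, drop = FALSE]
  if (!is.null(sw)) focal <- sum(!dup[seq_len(focal)])
  pos <- pos[!dup]
  hs <- haplotype_set(H, positions = pos,
                      population = rep("POP1", nrow(H)),
                      chrom = "chrSim")
  if (!is.null(sw)) {
    hs$focal_site <- focal
    hs$focal_position <- pos[focal]
    hs$sweep_restarts <- res$restarts
  }
  hs
}
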