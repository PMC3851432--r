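# Simulation configuration for the synthetic genome pair and panel.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults describe
#' a desk-scale study: two 500 kb chromosomes diverged at roughly one SNP
#' per kilobase with a 2:1 transition:transversion target, one 1-6 bp InDel
#' per 10 kb, 50 seeded SSR arrays of which 60% differ in repeat count
#' between the cultivars, and ~20-fold simulated coverage with phred-like
#' qualities centred at 40.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_lengths integer vector of chromosome lengths in bp
#'   (each >= 10 kb); recycled to `n_chromosomes`.
#' @param gc_fraction target GC content of the random background.
#' @param n_genes total number of gene models across the genome.
#' @param snp_rate per-bp probability of a planted SNP.
#' @param titv_target transition:transversion odds for planted SNPs.
#' @param indel_rate per-bp probability of a planted 1-6 bp InDel.
#' @param indel_len_probs probability over InDel lengths 1..6 bp.
#' @param n_ssr_seeds number of SSR arrays seeded into the reference.
#' @param ssr_motif_len_probs probability over SSR motif lengths 1..6.
#' @param ssr_mutation_prob probability a seeded SSR differs in repeat
#'   count between the two cultivars.
#' @param depth_mean mean simulated read depth (Poisson).
#' @param qual_mean mean simulated call quality (clipped Gaussian, sd 5).
#' @param seed integer master seed; fixes all randomness.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_lengths = 500000L,
                       gc_fraction = 0.38,
                       n_genes = 40L,
                       snp_rate = 0.001,
                       titv_target = 2.0,
                       indel_rate = 1e-4,
                       indel_len_probs = c(0.514, 0.218, 0.099, 0.08, 0.05, 0.039),
                       n_ssr_seeds = 50L,
                       ssr_motif_len_probs = c(0.437, 0.401, 0.118, 0.029, 0.009, 0.006),
                       ssr_mutation_prob = 0.6,
                       depth_mean = 20,
                       qual_mean = 40,
                       seed = 1L) {
  chrom_lengths <- as.integer(rep_len(chrom_lengths, n_chromosomes))
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths = chrom_lengths,
    gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes),
    snp_rate = snp_rate,
    titv_target = titv_target,
    indel_rate = indel_rate,
    indel_len_probs = indel_len_probs,
    n_ssr_seeds = as.integer(n_ssr_seeds),
    ssr_motif_len_probs = ssr_motif_len_probs,
    ssr_mutation_prob = ssr_mutation_prob,
    depth_mean = depth_mean,
    qual_mean = qual_mean,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$gc_fraction, cfg$snp_rate, cfg$indel_rate, cfg$ssr_mutation_prob)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  for (nm in c("indel_len_probs", "ssr_motif_len_probs")) {
    p <- cfg[[nm]]
    if (length(p) != 6 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("%s must be 6 non-negative values summing to 1", nm))
    }
  }
  if (cfg$n_chromosomes < 1) abort("need at least one chromosome")
  if (any(cfg$chrom_lengths < 10000L)) {
    abort("every chromosome must be at least 10 kb")
  }
  if (cfg$titv_target <= 0) abort("titv_target must be positive")
  if (cfg$depth_mean <= 0 || cfg$qual_mean <= 0) {
    abort("depth_mean and qual_mean must be positive")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d chromosome(s): %s bp\n", x$n_chromosomes,
              paste(format(x$chrom_lengths, big.mark = ","), collapse = ", ")))
  cat(sprintf("  genes: %d  GC: %.2f  seed: %d\n", x$n_genes, x$gc_fraction, x$seed))
  cat(sprintf("  snp_rate: %g (ti/tv %.1f)  indel_rate: %g  ssr seeds: %d (P[mut] %.2f)\n",
              x$snp_rate, x$titv_target, x$indel_rate, x$n_ssr_seeds,
              x$ssr_mutation_prob))
  cat(sprintf("  depth ~ Poisson(%g), quality ~ N(%g, 5) clipped\n",
              x$depth_mean, x$qual_mean))
  invisible(x)
}
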