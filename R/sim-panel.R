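# Multi-genotype biallelic SNP panel simulation.
#
# Samples belong to subpopulations, each with its own alt-allele frequency
# per locus; genotypes are drawn under Hardy-Weinberg within subpopulation
# and every call carries simulated depth/quality/per-allele read support so
# the panel filter has something to chew on.

#' Simulate a multi-sample biallelic SNP genotype panel
#'
#' @param n_samples number of samples (>= 2); default 24, the size of a
#'   typical cultivar diversity panel.
#' @param n_loci number of biallelic loci (>= 1).
#' @param subpops subpopulation assignment: either a single integer k
#'   (samples split as evenly as possible into k groups) or a character
#'   vector of length `n_samples` of group labels.
#' @param freq optional matrix of alt-allele frequencies, one row per
#'   subpopulation (rownames = labels) and one column per locus, all in
#'   \[0, 1\]; when `NULL`, frequencies are drawn Uniform(0.1, 0.9)
#'   independently per subpopulation and locus.
#' @param depth_mean,qual_mean confidence-field parameters as in
#'   [sim_config()]; depth defaults to 20 (capture-style coverage).
#' @param seed integer seed.
#' @return a `genotype_panel` list: `calls` (long tibble with `locus_id`,
#'   `chrom`, `pos`, `sample`, `allele1`, `allele2`, `depth`, `quality`,
#'   `reads1`, `reads2`), `loci` (locus table with ref/alt alleles) and
#'   `truth` (subpopulation labels and the frequency matrix).
#' @export
simulate_genotype_panel <- function(n_samples = 24L, n_loci = 100L,
                                    subpops = 1L, freq = NULL,
                                    depth_mean = 20, qual_mean = 40,
                                    seed = 1L) {
  if (n_samples < 2) abort("need at least 2 samples")
  if (n_loci < 1) abort("need at least 1 locus")
  set.seed(stage_seed(seed, "panel"))

  samples <- sprintf("S%02d", seq_len(n_samples))
  if (is.numeric(subpops) && length(subpops) == 1) {
    labels <- paste0("pop", rep_len(seq_len(subpops), n_samples))
    labels <- sort(labels)
  } else {
    if (length(subpops) != n_samples) {
      abort("subpops must be a count or one label per sample")
    }
    labels <- as.character(subpops)
  }
  pops <- unique(labels)

  if (is.null(freq)) {
    freq <- matrix(runif(length(pops) * n_loci, 0.1, 0.9),
                   nrow = length(pops), dimnames = list(pops, NULL))
  }
  freq <- as.matrix(freq)
  if (is.null(rownames(freq))) rownames(freq) <- pops
  if (nrow(freq) != length(pops) || ncol(freq) != n_loci) {
    abort(sprintf("freq must be %d x %d (subpopulations x loci)",
                  length(pops), n_loci))
  }
  if (any(freq < 0 | freq > 1)) abort("allele frequencies must lie in [0, 1]")

  # biallelic loci with distinct ref/alt bases on a nominal map
  ref_allele <- sample(DNA_BASES, n_loci, replace = TRUE)
  alt_allele <- vapply(ref_allele, function(r) sample(setdiff(DNA_BASES, r), 1),
                       character(1), USE.NAMES = FALSE)
  loci <- tibble(
    locus_id = sprintf("L%04d", seq_len(n_loci)),
    chrom = paste0("chr", 1L + (seq_len(n_loci) - 1L) %% 8L),
    pos = as.integer(seq_len(n_loci) * 1000L),
    ref = ref_allele, alt = alt_allele
  )

  grid <- tidyr::expand_grid(locus_idx = seq_len(n_loci),
                             sample_idx = seq_len(n_samples))
  p_alt <- freq[cbind(match(labels[grid$sample_idx], pops), grid$locus_idx)]
  n_alt <- rbinom(nrow(grid), 2L, p_alt)     # Hardy-Weinberg within subpop

  depth <- pmax(rpois(nrow(grid), depth_mean), 1L)
  quality <- round_half_up(pmin(pmax(rnorm(nrow(grid), qual_mean, 5), 2), 99), 1)
  # read support: hets split depth ~binomially, homs give all reads to one allele
  r1 <- ifelse(n_alt == 1L, rbinom(nrow(grid), depth, 0.5), depth)
  calls <- tibble(
    locus_id = loci$locus_id[grid$locus_idx],
    chrom = loci$chrom[grid$locus_idx],
    pos = loci$pos[grid$locus_idx],
    sample = samples[grid$sample_idx],
    allele1 = ifelse(n_alt == 2L, alt_allele[grid$locus_idx],
                     ref_allele[grid$locus_idx]),
    allele2 = ifelse(n_alt >= 1L, alt_allele[grid$locus_idx],
                     ref_allele[grid$locus_idx]),
    depth = as.integer(depth),
    quality = quality,
    reads1 = as.integer(r1),
    reads2 = as.integer(ifelse(n_alt == 1L, depth - r1, 0L))
  ) %>%
    arrange(.data$locus_id, .data$sample)

  structure(
    list(
      calls = calls,
      loci = loci,
      samples = tibble(sample = samples, subpop = labels),
      truth = list(subpops = tibble(sample = samples, subpop = labels),
                   freq = freq)
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d loci x %d samples (%d subpopulation(s))\n",
              nrow(x$loci), nrow(x$samples), length(unique(x$samples$subpop))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.genotype_panel <- function(x, ...) x$calls

#' @exportS3Method generics::glance
glance.genotype_panel <- function(x, ...) {
  tibble(n_loci = nrow(x$loci), n_samples = nrow(x$samples),
         n_subpops = length(unique(x$samples$subpop)),
         missing_rate = mean(is.na(x$calls$allele1)))
}
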