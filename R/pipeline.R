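# End-to-end orchestration: simulate -> scan -> classify -> annotate ->
# summarize -> diversity, with one config, one seed, and a content-hashed
# run manifest so reruns are verifiably byte-identical.

#' Pipeline run configuration
#'
#' Collects every stage threshold (defaulted to the standard analysis
#' values: SSR minima 12/12/12/16/20/24 bp with class I at >= 20 bp, SSR
#' polymorphism at >= 2 bp length difference, InDels of 1-6 bp at >= 1 bp
#' difference, SNP filter depth > 8 / quality > 30 / >= 4 reads per
#' allele, panel filter depth > 15, 100 kb windows), the simulation
#' config, panel dimensions and the master seed.  Unknown arguments are
#' rejected.
#'
#' @param sim a [sim_config()]; its seed is re-keyed from `seed`.
#' @param seed master seed for the whole run.
#' @param outdir optional output directory; when set, every stage product
#'   is written there along with `manifest.json`.
#' @param panel_samples,panel_loci,panel_subpops genotype-panel dimensions.
#' @param go_map optional gene-to-GO mapping tibble (`gene_id`, `go_id`,
#'   `category`) for the annotation tallies.
#' @param ... threshold overrides: `snp_min_depth` (8), `snp_min_quality`
#'   (30), `snp_min_allele_reads` (4), `indel_max_len` (6),
#'   `indel_min_diff` (1), `indel_flank_len` (195), `ssr_min_diff` (2),
#'   `ssr_flank_len` (180), `panel_min_depth` (15), `panel_min_quality`
#'   (30), `panel_min_allele_reads` (4), `window` (1e5).
#' @return a validated `run_config` list.
#' @export
run_config <- function(sim = NULL, seed = 1L, outdir = NULL,
                       panel_samples = 24L, panel_loci = 100L,
                       panel_subpops = 3L, go_map = NULL, ...) {
  thresholds <- list(
    snp_min_depth = 8, snp_min_quality = 30, snp_min_allele_reads = 4,
    indel_max_len = 6L, indel_min_diff = 1L, indel_flank_len = 195L,
    ssr_min_diff = 2L, ssr_flank_len = 180L,
    panel_min_depth = 15, panel_min_quality = 30, panel_min_allele_reads = 4,
    window = 1e5
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(thresholds))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  thresholds[names(overrides)] <- overrides
  sim <- sim %||% sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  structure(
    list(sim = sim, seed = as.integer(seed), outdir = outdir,
         panel_samples = as.integer(panel_samples),
         panel_loci = as.integer(panel_loci),
         panel_subpops = panel_subpops,
         go_map = go_map,
         thresholds = thresholds),
    class = "run_config")
}

write_tsv_commented <- function(x, path, header_lines) {
  writeLines(paste0("# ", header_lines), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the whole marker-discovery pipeline
#'
#' Executes simulate, SSR scan (both cultivars), polymorphism
#' classification (SNP/InDel/SSR), annotation, genome summaries and panel
#' diversity in order, all driven by one seed.  With `outdir` set, every
#' product is written (FASTA, GFF3, call-table/marker/panel TSVs, a
#' VCF-flavored SNP file, a BED-like window track, PHYLIP distances,
#' Newick tree) together with a `manifest.json` recording the seed, all
#' thresholds and an md5 of every file; rerunning with the same config
#' reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @return a `marker_study` object: `genome`, `panel`, `ssr_scans`,
#'   `markers` (annotated combined tibble), `summaries`, `diversity`,
#'   `config`, and `manifest` when written.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds

  # --- simulate ------------------------------------------------------------
  genome <- simulate_reference(config$sim)
  genome <- seed_ssr_loci(genome)
  genome <- derive_cultivar_pair(genome)
  panel <- simulate_genotype_panel(
    n_samples = config$panel_samples, n_loci = config$panel_loci,
    subpops = config$panel_subpops, seed = config$seed)

  # --- ssr scan ------------------------------------------------------------
  ssr_scans <- list(A = scan_ssrs(genome$cultivars$A),
                    B = scan_ssrs(genome$cultivars$B))

  # --- classify ------------------------------------------------------------
  snps <- call_snp_polymorphisms(
    genome$calls$A, genome$calls$B,
    min_depth = th$snp_min_depth, min_quality = th$snp_min_quality,
    min_allele_reads = th$snp_min_allele_reads)
  indels <- call_indel_polymorphisms(
    genome$calls$A, genome$calls$B, genome$sequences,
    max_len = th$indel_max_len, min_diff = th$indel_min_diff,
    flank_len = th$indel_flank_len)
  ssrs <- call_ssr_polymorphisms(
    ssr_scans$A, ssr_scans$B, genome$sequences,
    genome$cultivars$A, genome$cultivars$B, min_diff = th$ssr_min_diff)

  # --- annotate ------------------------------------------------------------
  index <- build_feature_index(genome$genes)
  markers <- bind_rows(snps, indels, ssrs) %>%
    annotate_markers(index)
  markers <- classify_coding_snps(markers, index, genome$sequences)
  go <- if (!is.null(config$go_map)) attach_go(markers, config$go_map) else NULL

  # --- summarize -----------------------------------------------------------
  chrom_sizes <- tibble(chrom = names(genome$sequences),
                        size_mb = nchar(genome$sequences) / 1e6)
  summaries <- list(
    per_chromosome = per_chromosome_table(markers, chrom_sizes),
    windows = window_density(markers, genome$sequences, genome$genes,
                             window = th$window),
    titv = titv_ratio(markers %>% filter(.data$marker_type == "SNP")),
    syn_nonsyn = syn_nonsyn_ratio(markers),
    motif_spectrum = motif_spectrum(ssrs),
    motif_groups = if (nrow(ssrs) > 0) motif_group_table(ssrs) else NULL,
    indel_spectrum = indel_spectrum(
      markers %>% filter(.data$marker_type == "InDel")),
    pct_snps_cds = fraction_in_region(
      markers %>% filter(.data$marker_type == "SNP"), "CDS")
  )

  # --- diversity -----------------------------------------------------------
  fpanel <- filter_panel_calls(panel, min_depth = th$panel_min_depth,
                               min_quality = th$panel_min_quality,
                               min_allele_reads = th$panel_min_allele_reads)
  stats <- locus_stats(fpanel)
  bm <- binary_matrix(fpanel)
  sim_mat <- similarity_matrix(bm)
  tree <- if (nrow(sim_mat$distance) >= 3) neighbor_joining(sim_mat$distance) else NULL
  diversity <- list(panel = fpanel, locus_stats = stats,
                    binary = bm, similarity = sim_mat, tree = tree)

  study <- structure(
    list(genome = genome, panel = panel, ssr_scans = ssr_scans,
         markers = markers, go = go, summaries = summaries,
         diversity = diversity, config = config, manifest = NULL),
    class = "marker_study")

  if (!is.null(config$outdir)) {
    study$manifest <- write_study(study, config$outdir)
  }
  study
}

write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  g <- study$genome
  th_lines <- sprintf("%s = %s", names(study$config$thresholds),
                      vapply(study$config$thresholds, format, character(1)))

  write_fasta(g$sequences, p("reference.fa"))
  write_fasta(g$cultivars$A, p("cultivarA.fa"))
  write_fasta(g$cultivars$B, p("cultivarB.fa"))
  write_gff3(g$genes, p("genes.gff3"))
  write_call_table(g$calls$A, p("calls_A.tsv"))
  write_call_table(g$calls$B, p("calls_B.tsv"))
  readr::write_tsv(g$truth$planted_snps, p("truth_snps.tsv"))
  readr::write_tsv(g$truth$planted_indels, p("truth_indels.tsv"))
  readr::write_tsv(g$truth$planted_ssr_variants, p("truth_ssrs.tsv"))
  readr::write_tsv(study$ssr_scans$A, p("ssr_A.tsv"))
  readr::write_tsv(study$ssr_scans$B, p("ssr_B.tsv"))
  write_tsv_commented(study$markers, p("markers.tsv"), th_lines)
  write_snp_vcf(study$markers %>% filter(.data$marker_type == "SNP"),
                p("snps.vcf"))
  readr::write_tsv(study$summaries$per_chromosome, p("per_chromosome.tsv"))
  readr::write_tsv(tibble::as_tibble(study$summaries$windows), p("windows.tsv"))
  readr::write_tsv(study$summaries$motif_spectrum, p("motif_spectrum.tsv"))
  write_panel_tsv(study$panel, p("panel.tsv"))
  readr::write_tsv(study$diversity$locus_stats %>% select(-"freqs"),
                   p("locus_stats.tsv"))
  write_phylip_dist(study$diversity$similarity$distance, p("distance.phy"))
  if (!is.null(study$diversity$tree)) {
    write_newick(study$diversity$tree, p("tree.nwk"))
  }

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "dualmark",
    version = as.character(utils::packageVersion("dualmark")),
    seed = study$config$seed,
    thresholds = study$config$thresholds,
    sim = unclass(study$config$sim),
    hashes = setNames(
      as.list(vapply(file.path(outdir, files), digest::digest,
                     character(1), file = TRUE, algo = "md5")),
      files)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.marker_study <- function(x, ...) {
  s <- x$summaries$per_chromosome
  tot <- s[s$chrom == "Total", ]
  cat("<marker_study>\n")
  cat(sprintf("  markers: %d SNPs (%d/Mb), %d InDels (%d/Mb), %d SSRs (%d/Mb) on %.1f Mb\n",
              tot$n_snps, tot$density_snps, tot$n_indels, tot$density_indels,
              tot$n_ssrs, tot$density_ssrs, tot$size_mb))
  cat(sprintf("  ti/tv: %.2f   nonsyn/syn: %s   SNPs in CDS: %.1f%%\n",
              x$summaries$titv$ratio,
              format(x$summaries$syn_nonsyn$ratio),
              x$summaries$pct_snps_cds))
  cat(sprintf("  panel: %d loci x %d samples, mean PIC %.2f\n",
              nrow(x$panel$loci), nrow(x$panel$samples),
              mean(x$diversity$locus_stats$PIC)))
  invisible(x)
}

#' Broom-style accessors for a pipeline run
#'
#' `tidy()` returns the annotated marker table; `glance()` a one-row
#' study-level summary.
#'
#' @param x a `marker_study` from [run_pipeline()].
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.marker_study <- function(x, ...) as_tibble(x$markers)

#' @rdname tidy.marker_study
#' @exportS3Method generics::glance
glance.marker_study <- function(x, ...) {
  tot <- x$summaries$per_chromosome %>% filter(.data$chrom == "Total")
  tibble(
    n_snps = tot$n_snps, n_indels = tot$n_indels, n_ssrs = tot$n_ssrs,
    snp_density = tot$density_snps,
    titv_ratio = x$summaries$titv$ratio,
    nonsyn_syn_ratio = x$summaries$syn_nonsyn$ratio,
    pct_snps_cds = x$summaries$pct_snps_cds,
    n_panel_loci = nrow(x$diversity$locus_stats),
    mean_PIC = round_half_up(mean(x$diversity$locus_stats$PIC), 2),
    mean_He = round_half_up(mean(x$diversity$locus_stats$He), 2),
    mean_Ho = round_half_up(mean(x$diversity$locus_stats$Ho), 2)
  )
}

#' Build a run configuration from a YAML file
#'
#' The YAML mirrors [run_config()]: top-level `seed`, `outdir`,
#' `panel_samples`, `panel_loci`, `panel_subpops`, a `sim` block with
#' [sim_config()] fields, and a `thresholds` block with threshold
#' overrides.  Unknown keys anywhere are rejected.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known_top <- c("seed", "outdir", "panel_samples", "panel_loci",
                 "panel_subpops", "sim", "thresholds")
  unknown <- setdiff(names(y), known_top)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  sim_args <- y$sim %||% list()
  bad_sim <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad_sim) > 0) {
    abort(sprintf("unknown config key(s) in sim block: %s",
                  paste(bad_sim, collapse = ", ")))
  }
  sim_args$seed <- y$seed %||% 1L
  args <- c(
    list(sim = do.call(sim_config, sim_args),
         seed = y$seed %||% 1L, outdir = y$outdir),
    y[intersect(names(y), c("panel_samples", "panel_loci", "panel_subpops"))],
    y$thresholds %||% list()
  )
  do.call(run_config, args)
}
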