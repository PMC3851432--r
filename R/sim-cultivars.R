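# Derivation of the two cultivar consensus genomes from the reference.
#
# SNPs and 1-6 bp InDels are planted at the configured per-bp rates, each
# assigned to one cultivar (the other keeps the reference allele), with
# transition:transversion odds matching the target.  Seeded SSR arrays
# change repeat count in one cultivar with the configured probability.
# Planted events never overlap each other and stay 40 bp clear of SSR
# arrays so that truth-based recovery is exact.

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

draw_alt_base <- function(ref, titv) {
  ti <- runif(length(ref)) < titv / (1 + titv)
  tv_choice <- purrr::map2_chr(ref, ti, function(r, is_ti) {
    if (is_ti) TRANSITION_OF[[r]] else sample(setdiff(DNA_BASES, c(r, TRANSITION_OF[[r]])), 1)
  })
  tv_choice
}

simulate_confidence <- function(n, depth_mean, qual_mean, error_rate = 0.01) {
  depth <- pmax(rpois(n, depth_mean), 1L)
  quality <- round_half_up(pmin(pmax(rnorm(n, qual_mean, 5), 2), 99), 1)
  reads_ref <- rbinom(n, depth, error_rate)
  tibble(depth = as.integer(depth), quality = quality,
         reads_ref = as.integer(reads_ref),
         reads_alt = as.integer(depth - reads_ref))
}

#' Derive two diverged cultivar genomes with call tables
#'
#' Plants SNPs, InDels and SSR repeat-count changes onto the reference to
#' produce cultivar A and B consensus sequences, simulated per-call
#' confidence fields (Poisson depth, clipped-Gaussian quality, per-allele
#' read counts) and the completed truth ledger.  Each planted SNP/InDel
#' belongs to exactly one cultivar; each seeded SSR mutates its repeat
#' count by at least one unit in one cultivar with probability
#' `ssr_mutation_prob`.  InDels and SNPs are placed outside SSR arrays
#' (40 bp buffer) and never overlap one another.
#'
#' @param genome a `sim_genome`, normally after [seed_ssr_loci()].
#' @param config a [sim_config()]; defaults to the genome's own.
#' @return the genome extended with `cultivars` (named lists `A`/`B` of
#'   sequences), `calls` (per-cultivar tibbles with columns `cultivar`,
#'   `chrom`, `pos`, `type`, `ref`, `alt`, `length`, `depth`, `quality`,
#'   `reads_ref`, `reads_alt`) and filled-in `truth`.
#' @export
derive_cultivar_pair <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(stage_seed(config$seed, "cultivars"))
  minima <- ssr_min_lengths()

  chrom_names <- names(genome$sequences)
  snp_rows <- list()
  indel_rows <- list()

  # per-chromosome event placement in reference coordinates
  events <- purrr::map(chrom_names, function(cn) {
    L <- nchar(genome$sequences[[cn]])
    chars <- strsplit(genome$sequences[[cn]], "")[[1]]
    blocked <- rep(FALSE, L)
    sp <- genome$ssr_spans %>% filter(.data$chrom == cn)
    for (i in seq_len(nrow(sp))) {
      blocked[max(1L, sp$start[i] - 40L):min(L, sp$end[i] + 40L)] <- TRUE
    }
    blocked[c(1:10, (L - 10):L)] <- TRUE     # keep clear of contig ends

    n_snp <- rbinom(1, L, config$snp_rate)
    free <- which(!blocked)
    if (n_snp > length(free)) {
      abort(sprintf("snp_rate too high for %s: %d events, %d free bp",
                    cn, n_snp, length(free)))
    }
    snp_pos <- sort(sample(free, n_snp))
    blocked[pmin(pmax(rep(snp_pos, each = 17) + (-8:8), 1), L)] <- TRUE

    n_ind <- rbinom(1, L, config$indel_rate)
    free <- which(!blocked)
    if (n_ind > length(free)) {
      abort(sprintf("indel_rate too high for %s: %d events after SNPs, %d free bp",
                    cn, n_ind, length(free)))
    }
    ind_pos <- sort(sample(free, n_ind))
    # enforce >= 15 bp separation between indels
    if (length(ind_pos) > 1) {
      keep <- c(TRUE, diff(ind_pos) >= 15L)
      while (!all(keep)) {
        ind_pos <- ind_pos[keep]
        keep <- c(TRUE, diff(ind_pos) >= 15L)
      }
    }

    snps <- tibble(
      chrom = cn, pos = snp_pos,
      ref_base = chars[snp_pos],
      alt_base = if (n_snp > 0) draw_alt_base(chars[snp_pos], config$titv_target) else character(),
      cultivar = sample(c("A", "B"), length(snp_pos), replace = TRUE)
    )
    indels <- tibble(
      chrom = cn, pos = ind_pos,
      type = sample(c("ins", "del"), length(ind_pos), replace = TRUE),
      length = if (length(ind_pos) > 0) {
        as.integer(sample(1:6, length(ind_pos), replace = TRUE,
                          prob = config$indel_len_probs))
      } else integer(),
      cultivar = sample(c("A", "B"), length(ind_pos), replace = TRUE)
    ) %>%
      mutate(motif = purrr::pmap_chr(list(.data$pos, .data$type, .data$length),
        function(p, ty, len) {
          if (ty == "del") paste(chars[p:(p + len - 1L)], collapse = "")
          else paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
        }))
    list(snps = snps, indels = indels)
  })
  names(events) <- chrom_names

  snps <- bind_rows(purrr::map(events, "snps"))
  indels <- bind_rows(purrr::map(events, "indels"))

  # SSR repeat-count mutations
  ssr_truth <- genome$truth$planted_ssr_variants
  if (nrow(ssr_truth) > 0) {
    period <- nchar(ssr_truth$motif)
    min_count <- ceiling(minima[as.character(period)] / period)
    mutate_it <- runif(nrow(ssr_truth)) < config$ssr_mutation_prob
    which_cv <- sample(c("A", "B"), nrow(ssr_truth), replace = TRUE)
    delta <- sample(1:3, nrow(ssr_truth), replace = TRUE, prob = c(0.6, 0.3, 0.1)) *
      sample(c(-1L, 1L), nrow(ssr_truth), replace = TRUE)
    new_count <- pmax(ssr_truth$repeat_count_ref + delta, min_count)
    # a clamp may land back on the reference count; push away instead
    same <- new_count == ssr_truth$repeat_count_ref
    new_count[same] <- ssr_truth$repeat_count_ref[same] + abs(delta[same])
    ssr_truth$repeat_count_A <- ifelse(mutate_it & which_cv == "A",
                                       new_count, ssr_truth$repeat_count_ref)
    ssr_truth$repeat_count_B <- ifelse(mutate_it & which_cv == "B",
                                       new_count, ssr_truth$repeat_count_ref)
  }

  # build each cultivar consensus chromosome by chromosome
  build_cultivar <- function(cv) {
    out <- purrr::map_chr(chrom_names, function(cn) {
      chars <- strsplit(genome$sequences[[cn]], "")[[1]]
      L <- length(chars)
      keep <- rep(TRUE, L)
      ins_after <- rep("", L)

      s <- snps %>% filter(.data$chrom == cn, .data$cultivar == cv)
      chars[s$pos] <- s$alt_base

      d <- indels %>% filter(.data$chrom == cn, .data$cultivar == cv)
      for (i in seq_len(nrow(d))) {
        if (d$type[i] == "del") {
          keep[d$pos[i]:(d$pos[i] + d$length[i] - 1L)] <- FALSE
        } else {
          ins_after[d$pos[i]] <- d$motif[i]
        }
      }

      ss <- ssr_truth %>% filter(.data$chrom == cn)
      for (i in seq_len(nrow(ss))) {
        cnt <- if (cv == "A") ss$repeat_count_A[i] else ss$repeat_count_B[i]
        ref_cnt <- ss$repeat_count_ref[i]
        if (is.na(cnt) || cnt == ref_cnt) next
        p <- nchar(ss$motif[i])
        arr_end <- ss$anchor[i] + ref_cnt * p - 1L
        if (cnt < ref_cnt) {
          keep[(ss$anchor[i] + cnt * p):arr_end] <- FALSE
        } else {
          ins_after[arr_end] <- strrep(ss$motif[i], cnt - ref_cnt)
        }
      }
      paste(paste0(ifelse(keep, chars, ""), ins_after), collapse = "")
    })
    setNames(out, chrom_names)
  }

  cultivars <- list(A = build_cultivar("A"), B = build_cultivar("B"))

  # call tables with simulated confidence fields
  set.seed(stage_seed(config$seed, "calls"))
  make_calls <- function(cv) {
    s <- snps %>% filter(.data$cultivar == cv) %>%
      transmute(cultivar = cv, chrom = .data$chrom, pos = .data$pos,
                type = "snp", ref = .data$ref_base, alt = .data$alt_base,
                length = 0L)
    # deletions remove, and insertions add, bases starting AT/after pos;
    # "-" marks the empty allele
    d <- indels %>% filter(.data$cultivar == cv) %>%
      transmute(
        cultivar = cv, chrom = .data$chrom, pos = .data$pos, type = .data$type,
        ref = as.character(ifelse(.data$type == "del", .data$motif, "-")),
        alt = as.character(ifelse(.data$type == "ins", .data$motif, "-")),
        length = .data$length
      )
    calls <- bind_rows(s, d) %>% arrange(.data$chrom, .data$pos)
    bind_cols(calls, simulate_confidence(nrow(calls), config$depth_mean,
                                         config$qual_mean))
  }
  calls <- list(A = make_calls("A"), B = make_calls("B"))

  genome$truth$planted_snps <- snps %>%
    transmute(chrom = .data$chrom, pos = .data$pos, ref_base = .data$ref_base,
              cultivarA_base = ifelse(.data$cultivar == "A", .data$alt_base, .data$ref_base),
              cultivarB_base = ifelse(.data$cultivar == "B", .data$alt_base, .data$ref_base))
  genome$truth$planted_indels <- indels %>%
    select("chrom", "pos", "type", "motif", "length", "cultivar")
  genome$truth$planted_ssr_variants <- ssr_truth
  genome$cultivars <- cultivars
  genome$calls <- calls
  genome
}
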