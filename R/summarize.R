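# Genome-scale report tables: per-chromosome counts and densities, 100 kb
# window tracks, ti/tv, syn/nonsyn ratios, motif and InDel spectra, and
# fraction-in-region percentages.  Printed precision is centralized:
# densities are whole markers/Mb, percentages one decimal, ratios two
# decimals, fold differences one decimal (see round_half_up()).

#' Per-chromosome marker table
#'
#' Counts SNP/InDel/SSR markers per chromosome with integer-rounded
#' densities per Mb, plus a totals row whose density uses summed counts
#' over summed sizes.
#'
#' @param markers tibble with `marker_type` ("SNP"/"InDel"/"SSR") and
#'   `chrom` columns.
#' @param chrom_sizes tibble with `chrom` and `size_mb` columns.
#' @return tibble with one row per chromosome plus a "Total" row; columns
#'   `chrom`, `n_snps`, `density_snps`, `n_indels`, `density_indels`,
#'   `n_ssrs`, `density_ssrs`, `size_mb`.
#' @export
per_chromosome_table <- function(markers, chrom_sizes) {
  unknown <- setdiff(unique(markers$chrom), chrom_sizes$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("marker(s) on chromosome(s) absent from the size table: %s",
                  paste(unknown, collapse = ", ")))
  }
  counts <- markers %>%
    count(.data$chrom, .data$marker_type) %>%
    tidyr::pivot_wider(names_from = "marker_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("SNP", "InDel", "SSR")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  per_chrom <- chrom_sizes %>%
    left_join(counts, by = "chrom") %>%
    mutate(across(c("SNP", "InDel", "SSR"), ~ dplyr::coalesce(.x, 0L)))
  totals <- tibble(
    chrom = "Total",
    SNP = sum(per_chrom$SNP), InDel = sum(per_chrom$InDel),
    SSR = sum(per_chrom$SSR), size_mb = sum(per_chrom$size_mb)
  )
  bind_rows(per_chrom, totals) %>%
    transmute(
      chrom = .data$chrom,
      n_snps = .data$SNP, density_snps = marker_density(.data$SNP, .data$size_mb),
      n_indels = .data$InDel, density_indels = marker_density(.data$InDel, .data$size_mb),
      n_ssrs = .data$SSR, density_ssrs = marker_density(.data$SSR, .data$size_mb),
      size_mb = .data$size_mb
    )
}

#' Marker density in fixed windows
#'
#' Tiles each chromosome with non-overlapping windows (default 100 kb; the
#' last window may be short), counts markers of each type per window, and
#' adds GC-content and gene-coverage channels.  Windows are flagged
#' high-density above `high_per_mb` SNPs/Mb and low-density below
#' `low_per_mb` SNPs/Mb.
#'
#' @param markers tibble with `marker_type`, `chrom`, `pos`.
#' @param sequences named character vector of the underlying sequences.
#' @param genes optional gene-model tibble for the gene-coverage channel.
#' @param window window width in bp (default 1e5).
#' @param high_per_mb,low_per_mb SNP density flags (defaults 1000 and 500
#'   SNPs/Mb).
#' @return a `window_track` tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `n_indels`, `n_ssrs`, `snps_per_mb`, `gc`, `gene_frac`,
#'   `high_density`, `low_density`.
#' @export
window_density <- function(markers, sequences, genes = NULL, window = 1e5,
                           high_per_mb = 1000, low_per_mb = 500) {
  window <- as.integer(window)
  tracks <- purrr::imap(sequences, function(s, cn) {
    L <- nchar(s)
    starts <- seq(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    m <- markers %>% filter(.data$chrom == cn)
    if (nrow(m) > 0 && (any(m$pos < 1L) || any(m$pos > L))) {
      abort(sprintf("marker coordinates out of bounds on %s", cn))
    }
    win_of <- function(pos) findInterval(pos, starts)
    tally <- function(type) {
      tabulate(win_of(m$pos[m$marker_type == type]), nbins = length(starts))
    }
    gc <- purrr::map2_dbl(starts, ends, function(a, b) {
      sub <- substring(s, a, b)
      counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(sub))
      acgt <- sum(counts[c("A", "C", "G", "T")])
      if (acgt == 0) return(NA_real_)
      sum(counts[c("G", "C")]) / acgt
    })
    gene_frac <- rep(0, length(starts))
    if (!is.null(genes)) {
      g <- genes %>% filter(.data$type == "gene", .data$seq_id == cn)
      if (nrow(g) > 0) {
        gr <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
        covered <- pmin(as.integer(IRanges::coverage(gr, width = L)), 1L)
        cum <- cumsum(covered)
        gene_frac <- (cum[ends] - c(0, cum[utils::head(ends, -1)])) /
          (ends - starts + 1)
      }
    }
    tibble(
      chrom = cn, start = starts, end = ends,
      n_snps = tally("SNP"), n_indels = tally("InDel"), n_ssrs = tally("SSR"),
      gc = gc, gene_frac = gene_frac
    )
  })
  out <- bind_rows(tracks) %>%
    mutate(
      snps_per_mb = .data$n_snps / ((.data$end - .data$start + 1) / 1e6),
      high_density = .data$snps_per_mb > high_per_mb,
      low_density = .data$snps_per_mb < low_per_mb
    )
  class(out) <- c("window_track", class(out))
  out
}

#' Transition/transversion summary
#'
#' @param snps SNP marker tibble with a `substitution` column
#'   ("transition"/"transversion"; `NA` rows, e.g. multiallelic sites, are
#'   ignored), or use [titv_from_counts()] with raw counts.
#' @return one-row tibble: `n_transitions`, `n_transversions`, `pct_ti`,
#'   `pct_tv` (1 d.p.), `ratio` (2 d.p.; `NA` when there are no
#'   transversions).
#' @export
titv_ratio <- function(snps) {
  titv_from_counts(sum(snps$substitution == "transition", na.rm = TRUE),
                   sum(snps$substitution == "transversion", na.rm = TRUE))
}

#' @rdname titv_ratio
#' @param n_ti,n_tv transition and transversion counts.
#' @export
titv_from_counts <- function(n_ti, n_tv) {
  total <- n_ti + n_tv
  tibble(
    n_transitions = n_ti, n_transversions = n_tv,
    pct_ti = pct_1dp(n_ti, total), pct_tv = pct_1dp(n_tv, total),
    ratio = ratio_2dp(n_ti, n_tv)
  )
}

#' Nonsynonymous/synonymous summary
#'
#' @param markers annotated SNP markers with a `coding_effect` column, or
#'   use [syn_nonsyn_from_counts()].
#' @return one-row tibble: `n_synonymous`, `n_nonsynonymous`, `ratio`
#'   (nonsynonymous / synonymous, 2 d.p.; `NA` when there are no
#'   synonymous SNPs).
#' @export
syn_nonsyn_ratio <- function(markers) {
  syn_nonsyn_from_counts(
    sum(markers$coding_effect == "synonymous", na.rm = TRUE),
    sum(markers$coding_effect == "nonsynonymous", na.rm = TRUE))
}

#' @rdname syn_nonsyn_ratio
#' @param n_syn,n_nonsyn synonymous and nonsynonymous counts.
#' @export
syn_nonsyn_from_counts <- function(n_syn, n_nonsyn) {
  tibble(n_synonymous = n_syn, n_nonsynonymous = n_nonsyn,
         ratio = ratio_2dp(n_nonsyn, n_syn))
}

MOTIF_CLASS_NAMES <- c("Mononucleotide", "Dinucleotide", "Trinucleotide",
                       "Tetranucleotide", "Pentanucleotide", "Hexanucleotide")

#' SSR motif spectrum
#'
#' Tabulates SSR markers by motif length class: counts, percentage of the
#' total (1 d.p.), average tract length (rounded to integer), a
#' repeat-count histogram (4, 5, ..., 10, >10) and class I / class II
#' splits, plus a totals row.  Pass loci from [find_ssrs()]/[scan_ssrs()]
#' or SSR polymorphism markers carrying `motif`, a repeat count and a
#' tract length.
#'
#' @param ssrs tibble with `motif`, `repeat_count` and `total_length`
#'   columns (for polymorphic markers, `repeat_count_a`/`len_a` are
#'   accepted as the representative allele).
#' @return a `motif_spectrum` tibble.
#' @export
motif_spectrum <- function(ssrs) {
  if (!"repeat_count" %in% names(ssrs) && "repeat_count_a" %in% names(ssrs)) {
    ssrs <- ssrs %>% mutate(repeat_count = dplyr::coalesce(
      .data$repeat_count_a, .data$repeat_count_b))
  }
  if (!"total_length" %in% names(ssrs) && "len_a" %in% names(ssrs)) {
    ssrs <- ssrs %>% mutate(total_length = .data$len_a)
  }
  empty_row <- function(cls) {
    tibble(motif_class = cls, n = 0L, pct = 0,
           avg_length = NA_real_,
           !!!setNames(as.list(rep(0L, 8)), c(paste0("r", 4:10), "r_gt10")),
           class_I = 0L, class_II = 0L)
  }
  total_n <- nrow(ssrs)
  rows <- purrr::map(1:6, function(p) {
    sub <- ssrs %>% filter(nchar(.data$motif) == p)
    if (nrow(sub) == 0) return(empty_row(MOTIF_CLASS_NAMES[p]))
    reps <- pmin(pmax(sub$repeat_count, 4L), 11L)   # 11 == ">10" bucket
    hist <- tabulate(reps - 3L, nbins = 8L)
    tibble(
      motif_class = MOTIF_CLASS_NAMES[p], n = nrow(sub),
      pct = pct_1dp(nrow(sub), total_n),
      avg_length = round_half_up(mean(sub$total_length), 0),
      !!!setNames(as.list(as.integer(hist)), c(paste0("r", 4:10), "r_gt10")),
      class_I = sum(sub$total_length >= 20L),
      class_II = sum(sub$total_length >= 12L & sub$total_length < 20L)
    )
  })
  out <- bind_rows(rows)
  totals <- out %>%
    summarise(motif_class = "Total", n = sum(.data$n), pct = ifelse(total_n > 0, 100, 0),
              avg_length = if (total_n > 0)
                round_half_up(mean(ssrs$total_length), 0) else NA_real_,
              across(c(paste0("r", 4:10), "r_gt10", "class_I", "class_II"),
                     ~ sum(.x)))
  out <- bind_rows(out, totals)
  class(out) <- c("motif_spectrum", class(out))
  out
}

#' Canonical-motif group table
#'
#' Counts SSR loci per canonical motif group ("AG/CT"-style) within each
#' motif length class, with percentages within the class.
#'
#' @param ssrs tibble with a `canonical_motif` column (or `motif`).
#' @return tibble: `motif_length`, `group`, `n`, `pct` (share within the
#'   motif length class, 1 d.p.).
#' @export
motif_group_table <- function(ssrs) {
  if (!"canonical_motif" %in% names(ssrs)) {
    ssrs <- ssrs %>%
      mutate(canonical_motif = vapply(.data$motif, canonical_motif, character(1), USE.NAMES = FALSE))
  }
  ssrs %>%
    mutate(motif_length = nchar(.data$canonical_motif),
           group = vapply(.data$canonical_motif, motif_group, character(1), USE.NAMES = FALSE)) %>%
    count(.data$motif_length, .data$group) %>%
    group_by(.data$motif_length) %>%
    mutate(pct = pct_1dp(.data$n, sum(.data$n))) %>%
    ungroup() %>%
    arrange(.data$motif_length, dplyr::desc(.data$n))
}

#' InDel length-by-region spectrum
#'
#' Cross-tabulates annotated InDel markers by signed length (+1..+6
#' insertions, -1..-6 deletions) and genomic feature, with
#' insertion/deletion totals, per-region totals and the share of InDels in
#' CDS+UTR.
#'
#' @param indels annotated InDel markers with `type` ("ins"/"del"),
#'   `length` (1-6) and `feature` columns.
#' @return an `indel_spectrum` list: `table` (signed_length x feature
#'   counts, long tibble), `by_type` (insertion/deletion totals),
#'   `by_region` (per-feature totals), `pct_cds_utr` (1 d.p.), `total`.
#' @export
indel_spectrum <- function(indels) {
  feature <- if ("feature" %in% names(indels)) indels$feature else "intergenic"
  tab <- indels %>%
    mutate(
      signed_length = ifelse(.data$type == "ins", .data$length, -.data$length),
      feature = factor(feature, levels = FEATURE_LEVELS)
    ) %>%
    count(.data$signed_length, .data$feature, .drop = FALSE) %>%
    tidyr::complete(signed_length = c(-6:-1, 1:6),
                    feature = factor(FEATURE_LEVELS, levels = FEATURE_LEVELS),
                    fill = list(n = 0L)) %>%
    filter(.data$signed_length != 0)
  by_type <- tibble(
    type = c("insertion", "deletion"),
    n = c(sum(tab$n[tab$signed_length > 0]), sum(tab$n[tab$signed_length < 0]))
  )
  by_region <- tab %>% group_by(feature = .data$feature) %>%
    summarise(n = sum(.data$n), .groups = "drop")
  total <- sum(tab$n)
  in_cds_utr <- sum(by_region$n[by_region$feature %in% c("CDS", "UTR5", "UTR3")])
  structure(
    list(table = tab, by_type = by_type, by_region = by_region,
         pct_cds_utr = pct_1dp(in_cds_utr, total), total = total),
    class = "indel_spectrum"
  )
}

#' Fraction of markers in a region set
#'
#' @param markers annotated marker tibble with a `feature` column.
#' @param regions character vector of feature labels (subset of CDS, UTR5,
#'   UTR3, intron, intergenic).
#' @return percentage (1 d.p.) of markers whose feature is in `regions`.
#' @export
fraction_in_region <- function(markers, regions) {
  pct_1dp(sum(markers$feature %in% regions), nrow(markers))
}
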