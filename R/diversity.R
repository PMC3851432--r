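# Panel diversity statistics.
#
# Per-locus allele number (Na), observed heterozygosity (Ho), expected
# heterozygosity with Nei's small-sample correction
# He = (2n / (2n - 1)) * (1 - sum p_i^2), and polymorphism information
# content by the uncorrected formula PIC = 1 - sum p_i^2.  The unbiased
# He explains how a biallelic panel can print He up to 0.51 while PIC
# caps at exactly 0.50.

#' Filter panel genotype calls on confidence fields
#'
#' Sets to missing every call failing depth strictly above `min_depth`,
#' quality strictly above `min_quality`, or any observed allele supported
#' by fewer than `min_allele_reads` reads.  Loci left with fewer than two
#' called samples, or monomorphic after filtering, are flagged (not
#' removed).
#'
#' @param panel a `genotype_panel` (or its `calls` tibble).
#' @param min_depth exclusive depth threshold (default 15, the capture-
#'   panel rule; the resequencing rule uses 8).
#' @param min_quality exclusive quality threshold (default 30).
#' @param min_allele_reads inclusive per-allele read minimum (default 4).
#' @return the panel with failing calls' alleles set to `NA` and a
#'   `locus_flags` tibble attached (locus_id, n_called, monomorphic,
#'   usable).
#' @export
filter_panel_calls <- function(panel, min_depth = 15, min_quality = 30,
                               min_allele_reads = 4) {
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else panel
  het <- !is.na(calls$allele1) & calls$allele1 != calls$allele2
  allele_ok <- ifelse(het,
                      calls$reads1 >= min_allele_reads & calls$reads2 >= min_allele_reads,
                      calls$reads1 + calls$reads2 >= min_allele_reads)
  ok <- !is.na(calls$allele1) &
    calls$depth > min_depth & calls$quality > min_quality & allele_ok
  calls$allele1[!ok] <- NA_character_
  calls$allele2[!ok] <- NA_character_

  flags <- calls %>%
    group_by(locus_id = .data$locus_id) %>%
    summarise(
      n_called = sum(!is.na(.data$allele1)),
      monomorphic = dplyr::n_distinct(
        c(.data$allele1[!is.na(.data$allele1)],
          .data$allele2[!is.na(.data$allele2)])) <= 1L,
      .groups = "drop") %>%
    mutate(usable = .data$n_called >= 2L)

  if (inherits(panel, "genotype_panel")) {
    panel$calls <- calls
    panel$locus_flags <- flags
    panel
  } else {
    attr(calls, "locus_flags") <- flags
    calls
  }
}

#' Polymorphism information content from allele frequencies
#'
#' The study formula PIC = 1 - sum(p_i^2).  For a biallelic locus the
#' maximum is 0.5, attained at equal frequencies.
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @return PIC value in \[0, 1).
#' @export
pic_from_freqs <- function(p) {
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-6) {
    abort("allele frequencies must be in [0, 1] and sum to 1")
  }
  1 - sum(p^2)
}

#' Per-locus diversity statistics
#'
#' Computes, for every locus with at least two non-missing diploid calls:
#' allele number Na, observed heterozygosity Ho (heterozygote fraction),
#' unbiased expected heterozygosity He = (2n/(2n-1)) (1 - sum p_i^2) with
#' n the number of called individuals, and PIC = 1 - sum p_i^2.
#' Monomorphic loci are valid (Na = 1, Ho = He = PIC = 0).
#'
#' @param panel a (filtered) `genotype_panel` or its `calls` tibble.
#' @return a `locus_diversity` tibble: `locus_id`, `n_called`, `Na`, `Ho`,
#'   `He`, `PIC` and a list-column `freqs` of named allele frequencies.
#' @export
locus_stats <- function(panel) {
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else panel
  out <- calls %>%
    filter(!is.na(.data$allele1)) %>%
    group_by(locus_id = .data$locus_id) %>%
    summarise(
      n_called = n(),
      Ho = mean(.data$allele1 != .data$allele2),
      freqs = list(table(c(.data$allele1, .data$allele2)) /
                     (2 * n())),
      .groups = "drop") %>%
    filter(.data$n_called >= 2L) %>%
    mutate(
      Na = purrr::map_int(.data$freqs, length),
      PIC = purrr::map_dbl(.data$freqs, ~ pic_from_freqs(as.numeric(.x))),
      He = (2 * .data$n_called) / (2 * .data$n_called - 1) * .data$PIC,
      freqs = purrr::map(.data$freqs, ~ setNames(as.numeric(.x), names(.x)))
    ) %>%
    select("locus_id", "n_called", "Na", "Ho", "He", "PIC", "freqs")
  class(out) <- c("locus_diversity", class(out))
  out
}

#' @exportS3Method generics::glance
glance.locus_diversity <- function(x, ...) {
  tibble(
    n_loci = nrow(x),
    mean_Na = mean(x$Na), mean_Ho = round_half_up(mean(x$Ho), 2),
    mean_He = round_half_up(mean(x$He), 2),
    mean_PIC = round_half_up(mean(x$PIC), 2),
    min_PIC = round_half_up(min(x$PIC), 2),
    max_PIC = round_half_up(max(x$PIC), 2)
  )
}

#' Binary allele-presence matrix
#'
#' Scores each (locus, allele) for presence (1) or absence (0) of the
#' allele in each sample; missing calls give `NA` across that locus's
#' columns and are excluded pairwise from similarity.
#'
#' @param panel a (filtered) `genotype_panel` or its `calls` tibble.
#' @return numeric matrix, samples x (locus:allele) columns.
#' @export
binary_matrix <- function(panel) {
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else panel
  alleles <- calls %>%
    filter(!is.na(.data$allele1)) %>%
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") %>%
    distinct(.data$locus_id, .data$allele) %>%
    arrange(.data$locus_id, .data$allele) %>%
    mutate(column = paste0(.data$locus_id, ":", .data$allele))
  samples <- sort(unique(calls$sample))
  mat <- matrix(NA_real_, nrow = length(samples), ncol = nrow(alleles),
                dimnames = list(samples, alleles$column))
  for (i in seq_len(nrow(alleles))) {
    lc <- calls[calls$locus_id == alleles$locus_id[i], ]
    carried <- ifelse(is.na(lc$allele1), NA_real_,
                      as.numeric(lc$allele1 == alleles$allele[i] |
                                   lc$allele2 == alleles$allele[i]))
    mat[lc$sample, i] <- carried
  }
  mat
}

#' Similarity and distance matrices from a binary matrix
#'
#' Pairwise similarity between samples with pairwise deletion of masked
#' (NA) cells.  Coefficients: simple matching (matches / comparable
#' cells), Jaccard (1-1 matches / cells with any 1) or Dice.  Distance is
#' 1 - similarity.
#'
#' @param bin binary matrix from [binary_matrix()].
#' @param coefficient "sm" (default), "jaccard" or "dice".
#' @return list with `similarity` and `distance` matrices (class
#'   `dm_similarity`).
#' @export
similarity_matrix <- function(bin, coefficient = c("sm", "jaccard", "dice")) {
  coefficient <- match.arg(coefficient)
  n <- nrow(bin)
  if (n < 2) abort("need at least 2 samples")
  s <- matrix(1, n, n, dimnames = list(rownames(bin), rownames(bin)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- bin[i, ]; y <- bin[j, ]
      ok <- !is.na(x) & !is.na(y)
      if (!any(ok)) {
        abort(sprintf("samples %s and %s share no comparable cells",
                      rownames(bin)[i], rownames(bin)[j]))
      }
      x <- x[ok]; y <- y[ok]
      a <- sum(x == 1 & y == 1)
      b <- sum(x == 1 & y == 0)
      cc <- sum(x == 0 & y == 1)
      d <- sum(x == 0 & y == 0)
      s[i, j] <- s[j, i] <- switch(coefficient,
        sm = (a + d) / (a + b + cc + d),
        jaccard = if (a + b + cc == 0) 1 else a / (a + b + cc),
        dice = if (2 * a + b + cc == 0) 1 else 2 * a / (2 * a + b + cc))
    }
  }
  structure(list(similarity = s, distance = 1 - s,
                 coefficient = coefficient),
            class = "dm_similarity")
}

#' @export
print.dm_similarity <- function(x, ...) {
  cat(sprintf("<dm_similarity> %d samples, %s coefficient\n",
              nrow(x$similarity), x$coefficient))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dm_similarity <- function(x, ...) {
  s <- x$similarity
  pairs <- which(upper.tri(s), arr.ind = TRUE)
  tibble(
    sample1 = rownames(s)[pairs[, 1]],
    sample2 = colnames(s)[pairs[, 2]],
    similarity = s[pairs],
    distance = 1 - s[pairs]
  )
}
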