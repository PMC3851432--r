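# ggplot2 views of the result tables.  Cosmetic layers only; every number
# plotted comes straight from the corresponding summary function.

#' Plot a window density track
#'
#' Marker counts per window along each chromosome, one facet per
#' chromosome, one colour per marker type.
#'
#' @param object a `window_track` from [window_density()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.window_track <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("n_snps", "n_indels", "n_ssrs"),
                              names_to = "type", values_to = "n") %>%
    mutate(type = dplyr::recode(.data$type, n_snps = "SNP",
                                n_indels = "InDel", n_ssrs = "SSR"))
  ggplot2::ggplot(long, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                     y = .data$n, colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$type),
                        cols = ggplot2::vars(.data$chrom), scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = "markers per window",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an SSR motif spectrum
#'
#' Class I / class II counts per motif length class.
#'
#' @param object a `motif_spectrum` from [motif_spectrum()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.motif_spectrum <- function(object, ...) {
  long <- as_tibble(object) %>%
    filter(.data$motif_class != "Total") %>%
    select("motif_class", "class_I", "class_II") %>%
    tidyr::pivot_longer(c("class_I", "class_II"),
                        names_to = "class", values_to = "count") %>%
    mutate(motif_class = factor(.data$motif_class, levels = MOTIF_CLASS_NAMES),
           class = sub("class_", "class ", .data$class))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$motif_class, y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "polymorphic SSRs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an InDel length spectrum
#'
#' Counts by signed InDel length (+ insertions, - deletions), stacked by
#' genomic feature.
#'
#' @param object an `indel_spectrum` from [indel_spectrum()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.indel_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$signed_length,
                                          levels = c(-6:-1, 1:6)),
                               y = .data$n, fill = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "InDel length (bp; + insertion, - deletion)",
                  y = "InDels", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-locus diversity distributions
#'
#' Histograms of Ho, He and PIC across panel loci.
#'
#' @param object a `locus_diversity` tibble from [locus_stats()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.locus_diversity <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("Ho", "He", "PIC"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), nrow = 1) +
    ggplot2::labs(x = NULL, y = "loci") +
    ggplot2::theme_minimal()
}
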