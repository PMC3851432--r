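# Marker annotation against gene models.
#
# Every genomic position gets exactly one label under the precedence
# CDS > UTR > intron > intergenic.  Coding SNPs are classified synonymous
# or nonsynonymous by rebuilding the affected codon from the spliced CDS
# on the annotated strand and translating with the standard nuclear code.

FEATURE_LEVELS <- c("CDS", "UTR5", "UTR3", "intron", "intergenic")

#' Build a feature index from gene models
#'
#' Compiles GFF3-shaped gene models into per-label interval structures
#' answering point queries under the precedence CDS > 5'UTR = 3'UTR >
#' intron > intergenic.  Introns are derived as the gaps between a gene's
#' exons.  Genes whose CDS pieces do not sum to a multiple of 3 are
#' flagged; coding-effect calls for flagged genes are refused.
#'
#' @param genes tibble with `seq_id`, `type` (gene/mRNA/exon/CDS/
#'   five_prime_UTR/three_prime_UTR), `start`, `end`, `strand`, `gene_id`
#'   columns, e.g. `sim_genome$genes` or [read_gff3()] output.
#' @return a `feature_index` object.
#' @export
build_feature_index <- function(genes) {
  stopifnot(all(c("seq_id", "type", "start", "end", "strand", "gene_id")
                %in% names(genes)))
  gr_of <- function(tbl) {
    GenomicRanges::GRanges(
      seqnames = tbl$seq_id,
      ranges = IRanges::IRanges(tbl$start, tbl$end),
      strand = tbl$strand, gene_id = tbl$gene_id)
  }
  cds <- genes %>% filter(.data$type == "CDS")
  utr5 <- genes %>% filter(.data$type == "five_prime_UTR")
  utr3 <- genes %>% filter(.data$type == "three_prime_UTR")
  exons <- genes %>% filter(.data$type == "exon")
  gene_tbl <- genes %>% filter(.data$type == "gene")

  # introns = gene span minus exons, per gene
  introns <- exons %>%
    group_by(.data$seq_id, .data$gene_id, .data$strand) %>%
    summarise(intron = list({
      ex <- IRanges::reduce(IRanges::IRanges(.data$start, .data$end))
      span <- range(ex)
      BiocGenerics::setdiff(span, ex)
    }), .groups = "drop") %>%
    mutate(n = purrr::map_int(.data$intron, length)) %>%
    filter(.data$n > 0)
  intron_tbl <- if (nrow(introns) > 0) {
    introns %>%
      mutate(start = purrr::map(.data$intron, IRanges::start),
             end = purrr::map(.data$intron, IRanges::end)) %>%
      select("seq_id", "gene_id", "strand", "start", "end") %>%
      tidyr::unnest(c("start", "end"))
  } else {
    tibble(seq_id = character(), gene_id = character(), strand = character(),
           start = integer(), end = integer())
  }

  # CDS length check, transcript-ordered CDS pieces per gene
  cds_by_gene <- cds %>%
    group_by(.data$gene_id) %>%
    summarise(
      seq_id = .data$seq_id[1], strand = .data$strand[1],
      pieces = list({
        o <- order(.data$start)
        s <- .data$start[o]; e <- .data$end[o]
        tibble(start = s, end = e)
      }),
      cds_len = sum(.data$end - .data$start + 1L), .groups = "drop")
  flagged <- cds_by_gene$gene_id[cds_by_gene$cds_len %% 3L != 0L]
  if (length(flagged) > 0) {
    warn(sprintf("%d gene(s) flagged: CDS length not a multiple of 3 (%s...)",
                 length(flagged), flagged[1]))
  }

  structure(
    list(
      granges = list(
        CDS = gr_of(cds), UTR5 = gr_of(utr5), UTR3 = gr_of(utr3),
        intron = gr_of(intron_tbl), gene = gr_of(gene_tbl)),
      cds_by_gene = cds_by_gene,
      genes = genes,
      flagged_genes = flagged
    ),
    class = "feature_index"
  )
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf("<feature_index> %d gene(s), %d flagged\n",
              length(x$granges$gene), length(x$flagged_genes)))
  invisible(x)
}

#' Label markers by genomic feature
#'
#' Assigns each marker (by its reference anchor position - spans are not
#' split) a single `feature` label under the precedence CDS > UTR >
#' intron > intergenic, plus the `gene_id` of the containing feature where
#' applicable.
#'
#' @param markers tibble with `chrom` and `pos` columns.
#' @param index a [build_feature_index()] result.
#' @return `markers` with `feature` and `gene_id` columns appended.
#' @export
annotate_markers <- function(markers, index) {
  stopifnot(inherits(index, "feature_index"))
  n <- nrow(markers)
  feature <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0) return(mutate(markers, feature = character(), gene_id = character()))
  q <- GenomicRanges::GRanges(markers$chrom, IRanges::IRanges(markers$pos, markers$pos))
  for (lab in c("intron", "UTR3", "UTR5", "CDS")) {   # ascending precedence
    gr <- index$granges[[lab]]
    if (length(gr) == 0) next
    hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    feature[qh] <- lab
    gene_id[qh] <- gr$gene_id[S4Vectors::subjectHits(hits)]
  }
  mutate(markers, feature = feature, gene_id = gene_id)
}

# spliced CDS sequence and a genomic-position -> CDS-index map for one gene
spliced_cds <- function(gene_row, sequences) {
  pieces <- gene_row$pieces[[1]]
  chrom_seq <- sequences[[gene_row$seq_id]]
  piece_seqs <- purrr::map2_chr(pieces$start, pieces$end,
                                ~ substring(chrom_seq, .x, .y))
  if (gene_row$strand == "+") {
    cds_seq <- paste(piece_seqs, collapse = "")
    pos_map <- unlist(purrr::map2(pieces$start, pieces$end, base::seq))
  } else {
    cds_seq <- paste(rev(revcomp(piece_seqs)), collapse = "")
    pos_map <- rev(unlist(purrr::map2(pieces$start, pieces$end, base::seq)))
  }
  list(seq = cds_seq, pos_map = pos_map)   # pos_map[i] = genomic pos of CDS base i
}

#' Classify coding SNPs as synonymous or nonsynonymous
#'
#' For each SNP marker labelled `CDS`, rebuilds the affected codon from
#' the spliced CDS sequence on the annotated strand (the alternate allele
#' is complemented for minus-strand genes), translates reference and
#' alternate codons with the standard nuclear genetic code, and compares
#' the amino acids.  SNPs in genes flagged by [build_feature_index()] get
#' `NA`.  A mismatch between the marker's stated reference base and the
#' reference sequence is a data-integrity error.
#'
#' @param markers annotated marker tibble (needs `chrom`, `pos`, `ref`,
#'   `feature`, `gene_id`, and the cultivar alleles `allele_a`/`allele_b`
#'   or an `alt` column).
#' @param index a [build_feature_index()] result.
#' @param sequences named character vector of reference sequences.
#' @return `markers` with a `coding_effect` column ("synonymous",
#'   "nonsynonymous", or `NA` for non-CDS/flagged/multiallelic rows).
#' @export
classify_coding_snps <- function(markers, index, sequences) {
  stopifnot(inherits(index, "feature_index"))
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  alt_of <- if ("alt" %in% names(markers)) {
    markers$alt
  } else {
    ifelse(markers$allele_a != markers$ref, markers$allele_a, markers$allele_b)
  }
  is_multi <- if ("multiallelic" %in% names(markers)) markers$multiallelic else FALSE
  target <- which(markers$feature == "CDS" &
                    !markers$gene_id %in% index$flagged_genes &
                    !is_multi)
  effect <- rep(NA_character_, nrow(markers))
  code <- Biostrings::GENETIC_CODE

  cache <- new.env(parent = emptyenv())
  for (i in target) {
    gid <- markers$gene_id[i]
    if (!exists(gid, envir = cache)) {
      row <- index$cds_by_gene[index$cds_by_gene$gene_id == gid, ]
      if (nrow(row) == 0) next
      assign(gid, spliced_cds(row, sequences), envir = cache)
    }
    sc <- get(gid, envir = cache)
    idx <- match(markers$pos[i], sc$pos_map)
    if (is.na(idx)) next                     # anchor outside this gene's CDS
    strand <- index$cds_by_gene$strand[index$cds_by_gene$gene_id == gid]
    ref_genomic <- substring(sequences[[markers$chrom[i]]], markers$pos[i], markers$pos[i])
    if (ref_genomic != markers$ref[i]) {
      abort(sprintf("reference base at %s:%d is %s but the marker says %s",
                    markers$chrom[i], markers$pos[i], ref_genomic, markers$ref[i]))
    }
    alt_tx <- if (strand == "+") alt_of[i] else unname(COMPLEMENT[alt_of[i]])
    codon_i <- (idx - 1L) %/% 3L
    codon <- substring(sc$seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    within <- idx - codon_i * 3L
    alt_codon <- codon
    substring(alt_codon, within, within) <- alt_tx
    effect[i] <- if (code[[codon]] == code[[alt_codon]]) "synonymous" else "nonsynonymous"
  }
  mutate(markers, coding_effect = effect)
}

#' Join GO terms onto marker-containing genes
#'
#' Given annotated markers and a gene-to-GO mapping, reports the set of
#' marker-containing genes, which of them carry at least one GO term
#' ("assigned"), and term counts per top-level ontology (term-gene pairs).
#' Records with an unknown category are skipped with a warning.
#'
#' @param markers annotated marker tibble (needs `gene_id`).
#' @param go_map tibble with `gene_id`, `go_id`, `category` columns;
#'   categories must be "biological process", "cellular component" or
#'   "molecular function".
#' @return list with `genes` (tibble gene_id/n_terms/annotated),
#'   `categories` (per-ontology term-gene pair counts and percentages) and
#'   `annotated_fraction` (1-decimal percentage of marker-containing genes
#'   with >= 1 term).
#' @export
attach_go <- function(markers, go_map) {
  valid <- c("biological process", "cellular component", "molecular function")
  bad <- !go_map$category %in% valid
  if (any(bad)) {
    warn(sprintf("%d GO record(s) skipped: unknown category", sum(bad)))
    go_map <- go_map[!bad, , drop = FALSE]
  }
  marker_genes <- markers %>%
    filter(!is.na(.data$gene_id)) %>%
    distinct(gene_id = .data$gene_id)
  gene_terms <- go_map %>%
    dplyr::semi_join(marker_genes, by = "gene_id") %>%
    distinct(.data$gene_id, .data$go_id, .data$category)
  genes <- marker_genes %>%
    left_join(gene_terms %>% count(.data$gene_id, name = "n_terms"),
              by = "gene_id") %>%
    mutate(n_terms = dplyr::coalesce(.data$n_terms, 0L),
           annotated = .data$n_terms > 0L)
  categories <- gene_terms %>%
    count(category = .data$category, name = "n_term_gene_pairs") %>%
    mutate(pct = pct_1dp(.data$n_term_gene_pairs, sum(.data$n_term_gene_pairs)))
  list(
    genes = genes,
    categories = categories,
    annotated_fraction = pct_1dp(sum(genes$annotated), nrow(genes))
  )
}
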