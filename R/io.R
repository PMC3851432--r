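# File formats: FASTA via Biostrings, GFF3 via rtracklayer, TSV tables via
# readr, PHYLIP square distance matrices and a minimal VCF-flavored SNP
# emitter.

#' FASTA input/output
#'
#' @param sequences named character vector of sequences.
#' @param path file path.
#' @return `read_fasta()`: named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unlist(sequences))
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' GFF3 input/output for gene models
#'
#' Writes the gene-model tibble used throughout the package (gene, mRNA,
#' exon, CDS, five_prime_UTR, three_prime_UTR rows with 1-based inclusive
#' coordinates) as GFF3, carrying an explicit `gene_id` attribute on every
#' feature, and reads it back.
#'
#' @param genes gene-model tibble (see [simulate_reference()]).
#' @param path file path.
#' @return `read_gff3()`: gene-model tibble.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seq_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  gr$source <- genes$source %||% "dualmark"
  gr$type <- genes$type
  gr$phase <- genes$phase
  gr$ID <- ifelse(genes$type == "gene", genes$gene_id,
                  ifelse(genes$type == "mRNA", genes$parent, NA_character_))
  # mRNA rows store their own id in `parent` slot convention used here:
  # gene rows have no parent; mRNA rows have parent = gene_id
  gr$ID <- ifelse(genes$type == "mRNA", paste0(genes$gene_id, ".t1"), gr$ID)
  gr$Parent <- ifelse(genes$type == "gene", NA_character_,
                      ifelse(genes$type == "mRNA", genes$gene_id,
                             paste0(genes$gene_id, ".t1")))
  gr$gene_id <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- gr$Parent
  if (!is.null(parent) && !is.character(parent)) {
    parent <- vapply(as.list(parent), function(p) {
      if (length(p) == 0) NA_character_ else p[[1]]
    }, character(1))
  }
  gene_id <- gr$gene_id
  if (is.null(gene_id)) {
    # fall back to walking Parent/ID links for third-party GFF3
    id <- gr$ID
    tx_gene <- setNames(parent[gr$type == "mRNA"], id[gr$type == "mRNA"])
    gene_id <- ifelse(as.character(gr$type) == "gene", id,
                      ifelse(as.character(gr$type) == "mRNA", parent,
                             unname(tx_gene[parent])))
  }
  tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(gr$source %||% NA_character_),
    type = as.character(gr$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    phase = as.integer(gr$phase %||% NA_integer_),
    gene_id = as.character(gene_id),
    parent = parent %||% NA_character_
  ) %>%
    filter(.data$type %in% c("gene", "mRNA", "exon", "CDS",
                             "five_prime_UTR", "three_prime_UTR"))
}

#' Variant call tables
#'
#' TSV with columns `cultivar`, `chrom`, `pos`, `type`, `ref`, `alt`,
#' `length`, `depth`, `quality`, `reads_ref`, `reads_alt`.
#'
#' @param calls call tibble.
#' @param path file path.
#' @return `read_call_table()`: call tibble.
#' @export
write_call_table <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cultivar = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), type = readr::col_character(),
    ref = readr::col_character(), alt = readr::col_character(),
    length = readr::col_integer(), depth = readr::col_integer(),
    quality = readr::col_double(), reads_ref = readr::col_integer(),
    reads_alt = readr::col_integer()))
}

#' Genotype panel TSV
#'
#' Wide format: one row per locus (`locus_id`, `chrom`, `pos`), then per
#' sample a genotype column ("A/G", "./." when missing) and `<sample>.DP`,
#' `<sample>.GQ`, `<sample>.AD` companion columns (AD as "r1,r2").
#'
#' @param panel a `genotype_panel`.
#' @param path file path.
#' @return `read_panel_tsv()`: a `genotype_panel` (without truth).
#' @export
write_panel_tsv <- function(panel, path) {
  calls <- panel$calls %>%
    mutate(
      gt = ifelse(is.na(.data$allele1), "./.",
                  paste0(.data$allele1, "/", .data$allele2)),
      ad = paste0(.data$reads1, ",", .data$reads2)
    )
  wide <- calls %>%
    select("locus_id", "chrom", "pos", "sample", "gt",
           dp = "depth", gq = "quality", "ad") %>%
    tidyr::pivot_wider(
      names_from = "sample",
      values_from = c("gt", "dp", "gq", "ad"),
      names_glue = "{sample}{ifelse(.value == 'gt', '', paste0('.', toupper(.value)))}")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  # everything as character first: AD fields like "17,0" must not be
  # parsed as grouped numbers
  wide <- readr::read_tsv(path,
                          col_types = readr::cols(.default = readr::col_character()))
  wide$pos <- as.integer(wide$pos)
  samples <- setdiff(names(wide), c("locus_id", "chrom", "pos"))
  samples <- unique(sub("\\.(DP|GQ|AD)$", "", samples))
  calls <- purrr::map(samples, function(sm) {
    gt <- wide[[sm]]
    ad <- strsplit(wide[[paste0(sm, ".AD")]], ",")
    tibble(
      locus_id = wide$locus_id, chrom = wide$chrom, pos = wide$pos,
      sample = sm,
      allele1 = ifelse(gt == "./.", NA_character_, sub("/.*$", "", gt)),
      allele2 = ifelse(gt == "./.", NA_character_, sub("^.*/", "", gt)),
      depth = as.integer(wide[[paste0(sm, ".DP")]]),
      quality = as.numeric(wide[[paste0(sm, ".GQ")]]),
      reads1 = as.integer(purrr::map_chr(ad, 1)),
      reads2 = as.integer(purrr::map_chr(ad, 2))
    )
  }) %>% bind_rows() %>% arrange(.data$locus_id, .data$sample)
  loci <- wide %>% select("locus_id", "chrom", "pos")
  structure(list(calls = calls, loci = loci,
                 samples = tibble(sample = samples, subpop = NA_character_),
                 truth = NULL),
            class = "genotype_panel")
}

#' PHYLIP square distance matrix
#'
#' @param d symmetric numeric matrix with row names.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' VCF-flavored SNP marker output
#'
#' Writes SNP polymorphisms as a minimal VCF 4.2 body (CHROM POS ID REF
#' ALT QUAL FILTER INFO) with the differing cultivar in INFO.  This is an
#' export convenience; the TSV marker tables are the primary interface.
#'
#' @param snps SNP marker tibble from [call_snp_polymorphisms()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CV,Number=1,Type=String,Description=\"Cultivar differing from the reference\">",
    "##INFO=<ID=SUB,Number=1,Type=String,Description=\"transition or transversion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  alt <- ifelse(snps$allele_a != snps$ref & snps$allele_b != snps$ref,
                paste0(snps$allele_a, ",", snps$allele_b),
                ifelse(snps$allele_a != snps$ref, snps$allele_a, snps$allele_b))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCV=%s%s",
                  snps$chrom, snps$pos, snps$ref, alt, snps$cultivar,
                  ifelse(is.na(snps$substitution), "",
                         paste0(";SUB=", snps$substitution)))
  writeLines(c(header, body), path)
  invisible(path)
}
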