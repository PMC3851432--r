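test_that("point queries honour the CDS > UTR > intron > intergenic precedence", {
  fx <- toy_gene_fixture()
  idx <- build_feature_index(fx$genes)
  q <- tibble::tibble(
    chrom = "chrT",
    pos = c(50L,                       # intergenic
            120L,                      # plus-strand 5'UTR
            150L,                      # plus-strand CDS
            250L,                      # plus-strand intron
            350L,                      # plus-strand 3'UTR
            430L,                      # minus-strand 3'UTR (left end of gene)
            470L,                      # minus-strand CDS
            520L,                      # minus-strand intron
            640L))                     # minus-strand 5'UTR (right end of gene)
  ann <- annotate_markers(q, idx)
  expect_equal(ann$feature, c("intergenic", "UTR5", "CDS", "intron", "UTR3",
                              "UTR3", "CDS", "intron", "UTR5"))
  expect_equal(ann$gene_id, c(NA, "gP", "gP", "gP", "gP",
                              "gM", "gM", "gM", "gM"))
})

test_that("feature labels partition each chromosome completely", {
  fx <- toy_gene_fixture()
  idx <- build_feature_index(fx$genes)
  L <- nchar(fx$sequences[["chrT"]])
  every <- annotate_markers(tibble::tibble(chrom = "chrT", pos = seq_len(L)), idx)
  counts <- table(every$feature)
  expect_equal(sum(counts), L)
  co <- fx$coords
  expect_equal(unname(counts[["CDS"]]), 126L + 120L)
  expect_equal(unname(counts[["intron"]]), 80L + 60L)
  expect_equal(unname(counts[["UTR5"]]), 60L)
  expect_equal(unname(counts[["UTR3"]]), 60L)
  expect_equal(unname(counts[["intergenic"]]), L - (126 + 120 + 80 + 60 + 120))
})

# whole-protein oracle: an exhaustive re-translation of the mutated spliced
# CDS decides synonymous vs nonsynonymous, independent of codon arithmetic
protein_oracle <- function(fx, gene, genomic_pos, alt) {
  co <- fx$coords[[gene]]
  seqs <- fx$sequences
  chars <- strsplit(seqs[["chrT"]], "")[[1]]
  chars[genomic_pos] <- alt
  mutated <- paste(chars, collapse = "")
  splice <- function(s) {
    p1 <- substring(s, co$cds1[1], co$cds1[2])
    p2 <- substring(s, co$cds2[1], co$cds2[2])
    if (gene == "plus") paste0(p1, p2) else revcomp(paste0(p2, p1))
  }
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X", no.init.codon = TRUE))
  if (tr(splice(seqs[["chrT"]])) == tr(splice(mutated))) "synonymous" else "nonsynonymous"
}

test_that("coding SNP calls agree with whole-protein re-translation on both strands", {
  fx <- toy_gene_fixture()
  idx <- build_feature_index(fx$genes)
  set.seed(20)
  cases <- dplyr::bind_rows(
    tibble::tibble(gene = "plus",
                   pos = sample(c(131:230, 311:336), 25)),
    tibble::tibble(gene = "minus",
                   pos = sample(c(447:496, 557:626), 25)))
  ref <- substring(fx$sequences[["chrT"]], cases$pos, cases$pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  markers <- tibble::tibble(marker_type = "SNP", chrom = "chrT",
                            pos = cases$pos, ref = ref, alt = alt)
  ann <- annotate_markers(markers, idx)
  expect_true(all(ann$feature == "CDS"))
  out <- classify_coding_snps(ann, idx, fx$sequences)
  want <- purrr::pmap_chr(list(cases$gene, cases$pos, alt),
                          function(g, p, a) protein_oracle(fx, g, p, a))
  expect_equal(out$coding_effect, want)
})

test_that("reverse-complementing the chromosome and flipping annotations preserves calls", {
  fx <- toy_gene_fixture()
  idx <- build_feature_index(fx$genes)
  L <- nchar(fx$sequences[["chrT"]])
  flipped_seq <- c(chrT = revcomp(fx$sequences[["chrT"]]))
  flipped_genes <- fx$genes %>%
    dplyr::mutate(
      s = L - .data$end + 1L, e = L - .data$start + 1L,
      start = .data$s, end = .data$e,
      strand = ifelse(.data$strand == "+", "-", "+")
    ) %>%
    dplyr::select(-"s", -"e")
  idx2 <- build_feature_index(flipped_genes)

  set.seed(21)
  pos <- sample(c(131:230, 311:336, 447:496, 557:626), 30)
  ref <- substring(fx$sequences[["chrT"]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  m1 <- annotate_markers(tibble::tibble(marker_type = "SNP", chrom = "chrT",
                                        pos = pos, ref = ref, alt = alt), idx)
  r1 <- classify_coding_snps(m1, idx, fx$sequences)
  m2 <- annotate_markers(
    tibble::tibble(marker_type = "SNP", chrom = "chrT", pos = L - pos + 1L,
                   ref = revcomp(ref), alt = revcomp(alt)), idx2)
  r2 <- classify_coding_snps(m2, idx2, flipped_seq)
  expect_equal(r1$coding_effect, r2$coding_effect)
})

test_that("a marker's stated reference base must match the sequence", {
  fx <- toy_gene_fixture()
  idx <- build_feature_index(fx$genes)
  pos <- 150L
  truth <- substring(fx$sequences[["chrT"]], pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(truth, wrong))[1]
  m <- annotate_markers(tibble::tibble(marker_type = "SNP", chrom = "chrT",
                                       pos = pos, ref = wrong, alt = alt), idx)
  expect_error(classify_coding_snps(m, idx, fx$sequences), "data|reference base")
})

test_that("genes with a broken CDS frame are flagged and their calls refused", {
  fx <- toy_gene_fixture()
  broken <- fx$genes
  i <- which(broken$type == "CDS" & broken$gene_id == "gP")[1]
  broken$end[i] <- broken$end[i] + 1L            # CDS length now 127, not %% 3
  expect_warning(idx <- build_feature_index(broken), "flagged")
  expect_equal(idx$flagged_genes, "gP")
  m <- annotate_markers(tibble::tibble(marker_type = "SNP", chrom = "chrT",
                                       pos = 150L, ref = "A", alt = "G"), idx)
  out <- classify_coding_snps(m, idx, fx$sequences)
  expect_true(is.na(out$coding_effect))
})

test_that("classifiable CDS SNPs split exactly into synonymous + nonsynonymous", {
  st <- tiny_study()
  snps <- st$markers %>% dplyr::filter(.data$marker_type == "SNP")
  cds <- snps %>% dplyr::filter(.data$feature == "CDS", !.data$multiallelic,
                                !.data$gene_id %in% character())
  expect_equal(sum(!is.na(cds$coding_effect)), nrow(cds))
  s <- syn_nonsyn_ratio(snps)
  expect_equal(s$n_synonymous + s$n_nonsynonymous,
               sum(snps$coding_effect %in% c("synonymous", "nonsynonymous")))
})

test_that("GO attachment tallies genes and term-gene pairs per ontology", {
  markers <- tibble::tibble(gene_id = c(sprintf("g%02d", 1:10), NA, "g01"))
  go_map <- tibble::tibble(
    gene_id = c("g01", "g01", "g02", "g03", "g04", "g05", "g06", "zz"),
    go_id = sprintf("GO:%07d", 1:8),
    category = c("biological process", "molecular function",
                 "biological process", "cellular component",
                 "molecular function", "biological process",
                 "biological process", "molecular function"))
  res <- attach_go(markers, go_map)
  expect_equal(nrow(res$genes), 10)
  expect_equal(res$annotated_fraction, 60.0)     # 6 of 10 marker genes
  # g01 has terms in two ontologies: once per category tally, once as a gene
  expect_equal(sum(res$genes$annotated), 6)
  bp <- res$categories$n_term_gene_pairs[res$categories$category == "biological process"]
  expect_equal(bp, 4L)
  expect_warning(attach_go(markers, dplyr::mutate(go_map, category = "nope")),
                 "unknown category")
  empty <- attach_go(markers, go_map[0, ])
  expect_equal(empty$annotated_fraction, 0)
  expect_equal(nrow(empty$categories), 0)
})
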