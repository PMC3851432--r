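fake_markers <- function(n_snp, n_indel, n_ssr, chrom = "chr1", max_pos = 1e6) {
  set.seed(1)
  tibble::tibble(
    marker_type = rep(c("SNP", "InDel", "SSR"), c(n_snp, n_indel, n_ssr)),
    chrom = chrom,
    pos = sample(max_pos, n_snp + n_indel + n_ssr, replace = TRUE))
}

test_that("per-chromosome table rounds densities and totals self-consistently", {
  m <- dplyr::bind_rows(fake_markers(500, 40, 20, "chr1"),
                        fake_markers(300, 10, 5, "chr2"))
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), size_mb = c(1.0, 0.5))
  tab <- per_chromosome_table(m, sizes)
  expect_equal(tab$chrom, c("chr1", "chr2", "Total"))
  expect_equal(tab$n_snps, c(500L, 300L, 800L))
  expect_equal(tab$density_snps, c(500, 600, 533))   # totals over summed size
  expect_equal(tab$n_indels[3], 50L)
  # totals row equals column sums
  expect_equal(tab$n_ssrs[3], sum(tab$n_ssrs[1:2]))
  expect_error(per_chromosome_table(fake_markers(1, 0, 0, "chrZ"), sizes),
               "absent from the size table")
  empty <- per_chromosome_table(m[0, ], sizes)
  expect_true(all(empty$density_snps == 0))
})

test_that("window counts conserve totals and flag density extremes", {
  set.seed(2)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3e5, replace = TRUE),
                         collapse = ""))
  m <- tibble::tibble(
    marker_type = "SNP", chrom = "chr1",
    pos = c(sample(1:1e5, 120), sample(100001:200000, 30),
            sample(200001:300000, 70)))
  wt <- window_density(m, seqs)
  expect_equal(nrow(wt), 3)
  expect_equal(sum(wt$n_snps), nrow(m))                 # conservation
  expect_equal(wt$high_density, c(TRUE, FALSE, FALSE))  # 120 > 100 per window
  expect_equal(wt$low_density, c(FALSE, TRUE, FALSE))   # 30 < 50 per window
  expect_true(all(wt$gc > 0.4 & wt$gc < 0.6))
  # a short trailing window keeps conservation
  wt2 <- window_density(m, c(chr1 = substring(seqs, 1, 250000)),
                        window = 1e5)
  expect_equal(nrow(wt2), 3)
  expect_equal(wt2$end[3], 250000L)
  expect_error(window_density(tibble::tibble(marker_type = "SNP",
                                             chrom = "chr1", pos = 4e5),
                              seqs), "out of bounds")
})

test_that("ti/tv and syn/nonsyn summaries handle boundary inputs", {
  expect_equal(titv_from_counts(50, 50)$ratio, 1.00)
  expect_true(is.na(titv_from_counts(10, 0)$ratio))
  expect_equal(titv_from_counts(611, 389)$ratio, 1.57)
  expect_equal(syn_nonsyn_from_counts(100, 0)$ratio, 0.00)
  expect_true(is.na(syn_nonsyn_from_counts(0, 5)$ratio))
  snps <- tibble::tibble(substitution = c("transition", "transition",
                                          "transversion", NA))
  tt <- titv_ratio(snps)
  expect_equal(tt$n_transitions, 2)
  expect_equal(tt$ratio, 2.00)
})

test_that("third-position SNPs in fourfold-degenerate codons are all synonymous", {
  # a CDS of fourfold-degenerate codons (GCx, Ala) with planted third-position
  # changes: the nonsyn/syn ratio must be exactly 0
  k <- 40                                            # codons; CDS = 120 bp
  cds <- paste0("ATG", strrep("GCT", k - 2), "TAA")  # 51..170 on the chrom
  chrom <- paste0(strrep("T", 50), cds, strrep("T", 50))
  genes <- tibble::tibble(
    seq_id = "c", source = "t",
    type = c("gene", "mRNA", "exon", "five_prime_UTR", "CDS",
             "three_prime_UTR"),
    start = c(41L, 41L, 41L, 41L, 51L, 171L),
    end = c(180L, 180L, 180L, 50L, 170L, 180L),
    strand = "+", phase = NA_integer_, gene_id = "g1",
    parent = c(NA, "g1", rep("g1.t1", 4)))
  idx <- build_feature_index(genes)
  third_pos <- seq(56, 167, by = 3)                  # third base of each GCT
  m <- tibble::tibble(marker_type = "SNP", chrom = "c", pos = third_pos,
                      ref = "T", alt = "C")
  ann <- annotate_markers(m, idx)
  out <- classify_coding_snps(ann, idx, c(c = chrom))
  expect_true(all(out$coding_effect == "synonymous"))
  expect_equal(syn_nonsyn_ratio(out)$ratio, 0.00)
})

test_that("motif spectrum reproduces counts, percents, histogram and class split", {
  ssrs <- dplyr::bind_rows(
    tibble::tibble(motif = "A", repeat_count = c(12L, 25L),
                   total_length = c(12L, 25L)),
    tibble::tibble(motif = "AG", repeat_count = c(6L, 10L),
                   total_length = c(12L, 20L)),
    tibble::tibble(motif = "AAT", repeat_count = 4L, total_length = 12L),
    tibble::tibble(motif = "ACGTA", repeat_count = 4L, total_length = 20L))
  sp <- motif_spectrum(ssrs)
  expect_equal(sp$n[sp$motif_class == "Mononucleotide"], 2L)
  expect_equal(sp$pct[sp$motif_class == "Dinucleotide"], pct_1dp(2, 6))
  expect_equal(sp$r4[sp$motif_class == "Trinucleotide"], 1L)
  expect_equal(sp$r_gt10[sp$motif_class == "Mononucleotide"], 2L)
  expect_equal(sp$class_I[sp$motif_class == "Dinucleotide"], 1L)
  expect_equal(sp$class_II[sp$motif_class == "Dinucleotide"], 1L)
  tot <- sp[sp$motif_class == "Total", ]
  expect_equal(tot$n, 6L)
  expect_equal(tot$class_I + tot$class_II, 6L)
  # class I + class II = count on every row
  body <- sp[sp$motif_class != "Total", ]
  expect_equal(body$class_I + body$class_II, body$n)
  # penta/hexa can never be class II (their minima exceed 20 bp)
  expect_equal(sp$class_II[sp$motif_class %in% c("Pentanucleotide",
                                                 "Hexanucleotide")], c(0L, 0L))
  empty <- motif_spectrum(ssrs[0, ])
  expect_equal(empty$n[empty$motif_class == "Total"], 0L)
})

test_that("motif groups pool rotations and strands within a length class", {
  ssrs <- tibble::tibble(canonical_motif = c("AG", "AG", "AT", "AAT"))
  g <- motif_group_table(ssrs)
  expect_equal(g$group[g$motif_length == 2], c("AG/CT", "AT/AT"))
  expect_equal(g$pct[g$group == "AG/CT"], pct_1dp(2, 3))
  expect_equal(g$pct[g$group == "AAT/ATT"], 100)
})

test_that("the InDel spectrum cross-tabulates signed length by region", {
  one <- tibble::tibble(marker_type = "InDel", type = "ins", length = 3L,
                        feature = "CDS")
  sp <- indel_spectrum(one)
  expect_equal(sum(sp$table$n), 1L)
  expect_equal(sp$table$n[sp$table$signed_length == 3 &
                            sp$table$feature == "CDS"], 1L)
  expect_equal(sp$by_type$n, c(1L, 0L))
  expect_equal(sp$by_region$n[sp$by_region$feature == "CDS"], 1L)
  expect_equal(sp$pct_cds_utr, 100)

  several <- tibble::tibble(
    marker_type = "InDel",
    type = c("ins", "del", "del", "ins"),
    length = c(1L, 1L, 6L, 2L),
    feature = c("intergenic", "intron", "UTR5", "CDS"))
  sp2 <- indel_spectrum(several)
  expect_equal(sp2$total, 4L)
  expect_equal(sp2$by_type$n, c(2L, 2L))
  expect_equal(sp2$pct_cds_utr, 50)
})

test_that("fraction-in-region percentages use annotated features", {
  m <- tibble::tibble(feature = c("CDS", "CDS", "intron", "intergenic",
                                  "UTR5"))
  expect_equal(fraction_in_region(m, "CDS"), 40.0)
  expect_equal(fraction_in_region(m, c("CDS", "UTR5", "UTR3")), 60.0)
  expect_equal(fraction_in_region(m, character(0)), 0.0)
})

test_that("pipeline summaries equal the same statistics taken from truth", {
  st <- tiny_study()
  g <- st$genome
  # SNP count: truth SNPs whose call passed the filter
  passA <- filter_snp_calls(g$calls$A)
  passB <- filter_snp_calls(g$calls$B)
  expect_equal(sum(st$markers$marker_type == "SNP"),
               nrow(passA) + nrow(passB))
  # InDel count equals all planted InDels (each in exactly one cultivar)
  expect_equal(sum(st$markers$marker_type == "InDel"),
               nrow(g$truth$planted_indels))
  # SSR polymorphisms: planted pairs differing by >= 2 bp
  ss <- g$truth$planted_ssr_variants
  expect_equal(sum(st$markers$marker_type == "SSR"),
               sum(abs(ss$repeat_count_A - ss$repeat_count_B) *
                     nchar(ss$motif) >= 2))
  # window conservation
  wt <- st$summaries$windows
  expect_equal(sum(wt$n_snps), sum(st$markers$marker_type == "SNP"))
})
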