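snp_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                     depth = 20L, quality = 40, reads_ref = 0L,
                     reads_alt = NULL, cultivar = "A") {
  tibble::tibble(cultivar = cultivar, chrom = chrom, pos = pos, type = "snp",
                 ref = ref, alt = alt, length = 0L, depth = depth,
                 quality = quality, reads_ref = reads_ref,
                 reads_alt = reads_alt %||% (depth - reads_ref))
}

indel_call <- function(chrom = "chr1", pos = 100L, type = "ins", motif = "TAG",
                       cultivar = "A") {
  tibble::tibble(cultivar = cultivar, chrom = chrom, pos = pos, type = type,
                 ref = if (type == "del") motif else "-",
                 alt = if (type == "ins") motif else "-",
                 length = nchar(motif), depth = 25L, quality = 45,
                 reads_ref = 0L, reads_alt = 25L)
}

test_that("the SNP confidence filter reads its thresholds literally", {
  # depth > 8 and quality > 30 strict; >= 4 reads per observed allele
  keep <- snp_call(depth = 9L, quality = 31, reads_ref = 4L, reads_alt = 4L)
  expect_equal(nrow(filter_snp_calls(keep)), 1)
  expect_equal(nrow(filter_snp_calls(snp_call(depth = 8L))), 0)
  expect_equal(nrow(filter_snp_calls(snp_call(quality = 30))), 0)
  expect_equal(nrow(filter_snp_calls(
    snp_call(depth = 13L, reads_ref = 10L, reads_alt = 3L))), 0)
  # an unobserved reference allele (0 reads) does not trip the per-allele rule
  expect_equal(nrow(filter_snp_calls(
    snp_call(depth = 20L, reads_ref = 0L, reads_alt = 20L))), 1)
  expect_warning(out <- filter_snp_calls(snp_call(depth = NA_integer_)),
                 "missing confidence")
  expect_equal(nrow(out), 0)
})

test_that("raising any filter threshold never enlarges the retained set", {
  set.seed(8)
  calls <- dplyr::bind_rows(purrr::map(1:200, ~ snp_call(
    pos = .x, depth = sample(5:30, 1), quality = runif(1, 20, 60),
    reads_ref = sample(0:10, 1), reads_alt = sample(0:25, 1))))
  base_ids <- filter_snp_calls(calls)$pos
  for (arg in list(list(min_depth = 12), list(min_quality = 40),
                   list(min_allele_reads = 6))) {
    stricter <- do.call(filter_snp_calls, c(list(calls), arg))$pos
    expect_true(all(stricter %in% base_ids))
  }
})

test_that("substitution typing is the purine/pyrimidine partition", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("A", "C"), "transversion")
  pairs <- expand.grid(r = c("A", "C", "G", "T"), a = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  cls <- classify_substitution(pairs$r, pairs$a)
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "unambiguous")
})

test_that("SNP polymorphisms join across cultivars with multiallelic flagging", {
  a <- dplyr::bind_rows(snp_call(pos = 10L, ref = "A", alt = "G"),
                        snp_call(pos = 20L, ref = "C", alt = "T"),
                        snp_call(pos = 30L, ref = "G", alt = "A"))
  b <- dplyr::bind_rows(snp_call(pos = 20L, ref = "C", alt = "T", cultivar = "B"),
                        snp_call(pos = 30L, ref = "G", alt = "C", cultivar = "B"))
  m <- call_snp_polymorphisms(a, b)
  # pos 10: only A differs; pos 20: same alt in both -> not polymorphic;
  # pos 30: two different non-reference alleles -> multiallelic
  expect_equal(m$pos, c(10L, 30L))
  expect_equal(m$cultivar, c("A", "both"))
  expect_equal(m$multiallelic, c(FALSE, TRUE))
  expect_equal(m$substitution, c("transition", NA))
})

test_that("InDel polymorphism classification follows the length-difference rule", {
  set.seed(12)
  ref <- c(chr1 = random_dna(2000))
  a <- indel_call(pos = 500L, type = "ins", motif = "TAG")
  b_empty <- indel_call(pos = 900L, type = "del", motif = "AT", cultivar = "B")
  m <- call_indel_polymorphisms(a, b_empty, ref)
  expect_equal(nrow(m), 2)                       # both loci unmatched -> polymorphic
  expect_equal(m$length[m$pos == 500], 3L)
  expect_equal(m$type[m$pos == 900], "del")

  # identical call in both cultivars: zero difference, not polymorphic
  same_b <- dplyr::mutate(a, cultivar = "B")
  expect_equal(nrow(call_indel_polymorphisms(a, same_b, ref)), 0)

  # opposite events at one locus differ by the sum of their lengths
  opp <- call_indel_polymorphisms(
    indel_call(pos = 700L, type = "ins", motif = "AAA"),
    indel_call(pos = 700L, type = "del", motif = "AAA", cultivar = "B"), ref)
  expect_equal(opp$length, 6L)
  expect_equal(opp$cultivar, "both")

  # a 7 bp event is outside the 1-6 bp class
  long <- indel_call(pos = 600L, type = "ins", motif = "TTTTTTT")
  expect_equal(nrow(call_indel_polymorphisms(long, b_empty[0, ], ref)), 0)

  expect_error(call_indel_polymorphisms(
    dplyr::mutate(a, chrom = "chrX"), b_empty[0, ], ref), "unknown chromosome")
})

test_that("InDel flanks are checked for uniqueness in the reference", {
  set.seed(3)
  core <- random_dna(1200)
  ref_dup <- c(chr1 = paste0(core, core))       # every flank occurs twice
  m <- call_indel_polymorphisms(indel_call(pos = 600L), indel_call(pos = 900L, cultivar = "B")[0, ],
                                ref_dup, flank_len = 195)
  expect_false(m$flank_ok)
  ref_uni <- c(chr1 = random_dna(2400))
  m2 <- call_indel_polymorphisms(indel_call(pos = 600L), indel_call(pos = 900L, cultivar = "B")[0, ],
                                 ref_uni, flank_len = 195)
  expect_true(m2$flank_ok)
})

make_ssr_pair <- function(core_a, core_b, seed = 44) {
  set.seed(seed)
  left <- random_dna(400); right <- random_dna(400)
  list(ref = c(chr1 = paste0(left, core_a, right)),
       a = c(chr1 = paste0(left, core_a, right)),
       b = c(chr1 = paste0(left, core_b, right)))
}

test_that("SSR polymorphism needs a tract-length difference of at least 2 bp", {
  # (AG)8 vs (AG)9: delta 2 -> polymorphic
  x <- make_ssr_pair(strrep("AG", 8), strrep("AG", 9))
  m <- call_ssr_polymorphisms(scan_ssrs(x$a), scan_ssrs(x$b), x$ref, x$a, x$b)
  expect_equal(nrow(m), 1)
  expect_equal(m$length, 2L)
  expect_equal(m$motif, "AG")
  expect_equal(m$pos, 401L)

  # (A)12 vs (A)13: delta 1 -> below the rule
  y <- make_ssr_pair(strrep("A", 12), strrep("A", 13), seed = 45)
  expect_equal(nrow(call_ssr_polymorphisms(
    scan_ssrs(y$a), scan_ssrs(y$b), y$ref, y$a, y$b)), 0)

  # (AAT)5 vs (AAT)7: delta 6
  z <- make_ssr_pair(strrep("AAT", 5), strrep("AAT", 7), seed = 46)
  m3 <- call_ssr_polymorphisms(scan_ssrs(z$a), scan_ssrs(z$b), z$ref, z$a, z$b)
  expect_equal(m3$length, 6L)
})

test_that("an SSR below detection in one cultivar is compared to the reference run", {
  # A carries (AAT)6 (18 bp); B has the tract eroded to (AAT)3 (undetectable);
  # the reference itself carries (AAT)3 -> delta vs reference run = 9 bp
  set.seed(47)
  left <- random_dna(400); right <- random_dna(400)
  ref <- c(chr1 = paste0(left, strrep("AAT", 3), right))
  a <- c(chr1 = paste0(left, strrep("AAT", 6), right))
  b <- ref
  expect_message(
    m <- call_ssr_polymorphisms(scan_ssrs(a), scan_ssrs(b), ref, a, b),
    "only in cultivar")
  expect_equal(nrow(m), 1)
  expect_equal(m$matched, "A")
  expect_equal(m$len_a, 18L)
  expect_equal(m$len_b, 9L)
})

test_that("swapping the cultivars permutes labels but keeps the marker set", {
  g <- tiny_genome()
  scans <- list(A = scan_ssrs(g$cultivars$A), B = scan_ssrs(g$cultivars$B))
  fwd <- call_ssr_polymorphisms(scans$A, scans$B, g$sequences,
                                g$cultivars$A, g$cultivars$B)
  rev <- call_ssr_polymorphisms(scans$B, scans$A, g$sequences,
                                g$cultivars$B, g$cultivars$A)
  expect_equal(fwd$pos, rev$pos)
  expect_equal(fwd$len_a, rev$len_b)
  expect_equal(fwd$length, rev$length)

  snp_fwd <- call_snp_polymorphisms(g$calls$A, g$calls$B)
  snp_rev <- call_snp_polymorphisms(g$calls$B, g$calls$A)
  expect_equal(snp_fwd$pos, snp_rev$pos)
  expect_equal(snp_fwd$allele_a, snp_rev$allele_b)

  ind_fwd <- call_indel_polymorphisms(g$calls$A, g$calls$B, g$sequences)
  ind_rev <- call_indel_polymorphisms(g$calls$B, g$calls$A, g$sequences)
  expect_equal(ind_fwd$pos, ind_rev$pos)
  expect_equal(ind_fwd$len_a, ind_rev$len_b)
})
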