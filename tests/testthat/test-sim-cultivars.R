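test_that("zero rates give two cultivars identical to the reference", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths = 20000, n_genes = 0,
                    snp_rate = 0, indel_rate = 0, ssr_mutation_prob = 0,
                    n_ssr_seeds = 3, seed = 4)
  g <- derive_cultivar_pair(seed_ssr_loci(simulate_reference(cfg)))
  expect_identical(g$cultivars$A, g$sequences)
  expect_identical(g$cultivars$B, g$sequences)
  expect_equal(nrow(g$calls$A), 0)
  expect_equal(nrow(g$calls$B), 0)
})

test_that("planted ti/tv matches the target within the binomial bound", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths = 500000, n_genes = 0,
                    snp_rate = 0.02, indel_rate = 0, ssr_mutation_prob = 0,
                    n_ssr_seeds = 1, titv_target = 2.0, seed = 6)
  g <- derive_cultivar_pair(seed_ssr_loci(simulate_reference(cfg)))
  snps <- g$truth$planted_snps
  expect_gt(nrow(snps), 9000)
  alt <- ifelse(snps$cultivarA_base != snps$ref_base,
                snps$cultivarA_base, snps$cultivarB_base)
  sub <- classify_substitution(snps$ref_base, alt)
  ratio <- sum(sub == "transition") / sum(sub == "transversion")
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("chromosome lengths balance the net planted indel and SSR deltas", {
  g <- tiny_genome()
  truth <- g$truth
  for (cn in names(g$sequences)) {
    for (cv in c("A", "B")) {
      ind <- truth$planted_indels[truth$planted_indels$chrom == cn &
                                    truth$planted_indels$cultivar == cv, ]
      net_indel <- sum(ifelse(ind$type == "ins", ind$length, -ind$length))
      ssr <- truth$planted_ssr_variants[truth$planted_ssr_variants$chrom == cn, ]
      cnt <- if (cv == "A") ssr$repeat_count_A else ssr$repeat_count_B
      net_ssr <- sum((cnt - ssr$repeat_count_ref) * nchar(ssr$motif))
      expect_equal(nchar(g$cultivars[[cv]][[cn]]),
                   nchar(g$sequences[[cn]]) + net_indel + net_ssr)
    }
  }
})

# independent reconstruction: applying the truth ledger to the reference
# must reproduce each cultivar consensus exactly (whole-sequence diff)
test_that("every cultivar/reference difference is attributable to a truth entry", {
  g <- tiny_genome()
  rebuild <- function(cn, cv) {
    chars <- strsplit(g$sequences[[cn]], "")[[1]]
    sn <- g$truth$planted_snps
    sn <- sn[sn$chrom == cn, ]
    alt <- if (cv == "A") sn$cultivarA_base else sn$cultivarB_base
    chars[sn$pos] <- alt
    drop <- rep(FALSE, length(chars))
    add <- rep("", length(chars))
    ind <- g$truth$planted_indels
    ind <- ind[ind$chrom == cn & ind$cultivar == cv, ]
    for (i in seq_len(nrow(ind))) {
      if (ind$type[i] == "del") {
        drop[ind$pos[i]:(ind$pos[i] + ind$length[i] - 1)] <- TRUE
      } else {
        add[ind$pos[i]] <- ind$motif[i]
      }
    }
    ss <- g$truth$planted_ssr_variants
    ss <- ss[ss$chrom == cn, ]
    for (i in seq_len(nrow(ss))) {
      cnt <- if (cv == "A") ss$repeat_count_A[i] else ss$repeat_count_B[i]
      p <- nchar(ss$motif[i])
      arr_end <- ss$anchor[i] + ss$repeat_count_ref[i] * p - 1
      if (cnt < ss$repeat_count_ref[i]) {
        drop[(ss$anchor[i] + cnt * p):arr_end] <- TRUE
      } else if (cnt > ss$repeat_count_ref[i]) {
        add[arr_end] <- strrep(ss$motif[i], cnt - ss$repeat_count_ref[i])
      }
    }
    paste(paste0(ifelse(drop, "", chars), add), collapse = "")
  }
  for (cn in names(g$sequences)) {
    expect_identical(rebuild(cn, "A"), g$cultivars$A[[cn]])
    expect_identical(rebuild(cn, "B"), g$cultivars$B[[cn]])
  }
})

test_that("call tables mirror the planted events with plausible confidence fields", {
  g <- tiny_genome()
  calls <- dplyr::bind_rows(g$calls$A, g$calls$B)
  n_truth <- nrow(g$truth$planted_snps) + nrow(g$truth$planted_indels)
  expect_equal(nrow(calls), n_truth)
  expect_true(all(calls$type %in% c("snp", "ins", "del")))
  expect_true(all(calls$length[calls$type != "snp"] %in% 1:6))
  expect_true(all(calls$depth >= 1))
  expect_true(all(calls$reads_ref + calls$reads_alt == calls$depth))
  expect_true(all(calls$quality > 0 & calls$quality < 100))
  # a planted deletion shortens the carrying cultivar by its length
  del <- g$truth$planted_indels[g$truth$planted_indels$type == "del", ]
  expect_gt(nrow(del), 0)
  d1 <- del[1, ]
  ref_seg <- substring(g$sequences[[d1$chrom]], d1$pos, d1$pos + d1$length - 1)
  expect_equal(ref_seg, d1$motif)
  cv_seq <- g$cultivars[[d1$cultivar]][[d1$chrom]]
  expect_false(nchar(cv_seq) == nchar(g$sequences[[d1$chrom]]) &&
                 identical(cv_seq, g$sequences[[d1$chrom]]))
})

test_that("mutated SSRs change repeat count by at least one unit in one cultivar", {
  g <- tiny_genome()
  ss <- g$truth$planted_ssr_variants
  mutated <- ss[ss$repeat_count_A != ss$repeat_count_B, ]
  expect_gt(nrow(mutated), 0)
  expect_true(all(mutated$repeat_count_A == mutated$repeat_count_ref |
                    mutated$repeat_count_B == mutated$repeat_count_ref))
  expect_true(all(abs(mutated$repeat_count_A - mutated$repeat_count_B) >= 1))
})
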