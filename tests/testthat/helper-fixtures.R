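# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small end-to-end study used by polymorphism/pipeline tests
tiny_sim_config <- function(seed = 11) {
  sim_config(n_chromosomes = 1, chrom_lengths = 120000, n_genes = 8,
             n_ssr_seeds = 12, seed = seed)
}

tiny_study <- function() {
  cached("tiny_study", {
    cfg <- run_config(sim = tiny_sim_config(), seed = 11, panel_loci = 40)
    suppressMessages(run_pipeline(cfg))
  })
}

tiny_genome <- function() {
  cached("tiny_genome", {
    g <- simulate_reference(tiny_sim_config())
    g <- seed_ssr_loci(g)
    derive_cultivar_pair(g)
  })
}

# hand-built two-gene chromosome with known coordinates: one plus-strand
# and one minus-strand gene, each with 5'UTR / CDS split by an intron /
# 3'UTR.  Returns exact coordinates so annotation tests can assert labels
# at chosen positions.
toy_gene_fixture <- function(seed = 42) {
  set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"), paste0),
                                c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  mk_cds <- function(k) {
    paste0("ATG", paste(sample(sense, k - 2, replace = TRUE), collapse = ""), "TAA")
  }

  u5p <- rand(30); cds_plus <- mk_cds(42)            # 126 bp CDS
  cds1p <- substr(cds_plus, 1, 100)
  cds2p <- substr(cds_plus, 101, 126)
  int_p <- rand(80); u3p <- rand(30)

  u5m <- rand(30); cds_minus <- mk_cds(40)           # 120 bp CDS
  cds_m1 <- substr(cds_minus, 1, 70)                 # transcript-first piece
  cds_m2 <- substr(cds_minus, 71, 120)
  int_m <- rand(60); u3m <- rand(30)

  gene_plus <- paste0(u5p, cds1p, int_p, cds2p, u3p)
  # minus-strand gene: genomic left-to-right = 3'UTR, CDS piece 2, intron,
  # CDS piece 1, 5'UTR, each reverse-complemented
  gene_minus <- paste0(revcomp(u3m), revcomp(cds_m2), int_m,
                       revcomp(cds_m1), revcomp(u5m))
  chrom <- paste0(rand(100), gene_plus, rand(50), gene_minus, rand(100))

  co <- list(
    plus = list(gene = c(101, 366), utr5 = c(101, 130), cds1 = c(131, 230),
                intron = c(231, 310), cds2 = c(311, 336), utr3 = c(337, 366)),
    minus = list(gene = c(417, 656), utr3 = c(417, 446), cds2 = c(447, 496),
                 intron = c(497, 556), cds1 = c(557, 626), utr5 = c(627, 656))
  )
  row <- function(type, iv, strand, phase, gid) {
    tibble::tibble(seq_id = "chrT", source = "test", type = type,
                   start = iv[1], end = iv[2], strand = strand,
                   phase = phase, gene_id = gid,
                   parent = if (type == "gene") NA_character_
                            else if (type == "mRNA") gid else paste0(gid, ".t1"))
  }
  genes <- dplyr::bind_rows(
    row("gene", co$plus$gene, "+", NA, "gP"),
    row("mRNA", co$plus$gene, "+", NA, "gP"),
    row("exon", c(co$plus$gene[1], co$plus$cds1[2]), "+", NA, "gP"),
    row("exon", c(co$plus$cds2[1], co$plus$gene[2]), "+", NA, "gP"),
    row("five_prime_UTR", co$plus$utr5, "+", NA, "gP"),
    row("CDS", co$plus$cds1, "+", 0L, "gP"),
    row("CDS", co$plus$cds2, "+", 2L, "gP"),
    row("three_prime_UTR", co$plus$utr3, "+", NA, "gP"),
    row("gene", co$minus$gene, "-", NA, "gM"),
    row("mRNA", co$minus$gene, "-", NA, "gM"),
    row("exon", c(co$minus$gene[1], co$minus$cds2[2]), "-", NA, "gM"),
    row("exon", c(co$minus$cds1[1], co$minus$gene[2]), "-", NA, "gM"),
    row("three_prime_UTR", co$minus$utr3, "-", NA, "gM"),
    row("CDS", co$minus$cds2, "-", 2L, "gM"),
    row("CDS", co$minus$cds1, "-", 0L, "gM"),
    row("five_prime_UTR", co$minus$utr5, "-", NA, "gM")
  )
  list(sequences = c(chrT = chrom), genes = genes, coords = co,
       cds_plus = cds_plus, cds_minus = cds_minus)
}
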