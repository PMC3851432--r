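# Reference genome and gene-model simulation.
#
# The generator produces a random-background genome at a target GC, writes
# clean gene models onto it (two exons, one intron, both UTRs, CDS a
# multiple of 3 that translates without internal stops), and later seeds
# perfect SSR arrays into intergenic space.  All randomness derives from
# the config seed via per-stage sub-seeds, so identical configs give
# byte-identical outputs.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

sense_codons <- function() {
  all_codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all_codons, STOP_CODONS)
}

#' Generate a reference genome with gene models
#'
#' Simulates `n_chromosomes` random sequences at the requested lengths and
#' GC fraction, then lays `n_genes` non-overlapping gene models onto them
#' (allocated to chromosomes proportionally to length).  Each gene has two
#' exons separated by one intron, a 5' and a 3' UTR, and a CDS whose total
#' length is a multiple of 3, starts with ATG, ends with a stop codon and
#' contains no internal stop on its annotated strand.  Strands are assigned
#' at random and the exon/intron split point need not fall on a codon
#' boundary, so CDS pieces carry non-trivial phases.
#'
#' @param config a [sim_config()].
#' @return a `sim_genome` list with elements `sequences` (named character
#'   vector), `genes` (GFF3-shaped tibble of gene/mRNA/exon/CDS/UTR rows),
#'   `truth` (empty planted-marker ledgers), `ssr_spans` and `config`.
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "reference"))

  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  sequences <- setNames(
    vapply(config$chrom_lengths,
           function(L) paste(random_bases(L, config$gc_fraction), collapse = ""),
           character(1)),
    chrom_names
  )

  genes <- tibble(
    seq_id = character(), source = character(), type = character(),
    start = integer(), end = integer(), strand = character(),
    phase = integer(), gene_id = character(), parent = character()
  )

  if (config$n_genes > 0) {
    # allocate genes to chromosomes proportionally to length
    share <- config$chrom_lengths / sum(config$chrom_lengths)
    n_per <- floor(share * config$n_genes)
    rem <- config$n_genes - sum(n_per)
    if (rem > 0) {
      extra <- order(share * config$n_genes - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1L
    }

    codon_pool <- sense_codons()
    gene_rows <- list()
    gid <- 0L

    for (ci in seq_along(chrom_names)) {
      n_i <- n_per[ci]
      if (n_i == 0) next
      L <- config$chrom_lengths[ci]
      chars <- strsplit(sequences[[ci]], "")[[1]]

      specs <- purrr::map(seq_len(n_i), function(j) {
        u5 <- sample(30:80, 1)
        u3 <- sample(30:80, 1)
        k <- sample(40:160, 1)                 # codons incl. start and stop
        cds_len <- 3L * k
        split_at <- sample(3:(cds_len - 3L), 1)  # any phase allowed
        intron <- sample(60:200, 1)
        list(u5 = u5, u3 = u3, cds_len = cds_len, split = split_at,
             intron = intron, strand = sample(c("+", "-"), 1),
             len = u5 + cds_len + intron + u3)
      })
      total_gene <- sum(purrr::map_int(specs, ~ as.integer(.x$len)))
      min_gap <- 300L
      slack <- L - total_gene - min_gap * (n_i + 1L)
      if (slack < 0) {
        abort(sprintf(
          "cannot fit %d gene(s) (%d bp + gaps) on %s (%d bp)",
          n_i, total_gene, chrom_names[ci], L))
      }
      cuts <- sort(runif(n_i))
      extra <- floor(diff(c(0, cuts, 1)) * slack)
      gaps <- min_gap + extra

      pos <- 0L
      for (j in seq_len(n_i)) {
        gid <- gid + 1L
        sp <- specs[[j]]
        g_start <- pos + gaps[j] + 1L
        g_end <- g_start + sp$len - 1L
        pos <- g_end

        # genomic layout: [utr_left][cds piece 1][intron][cds piece 2][utr_right]
        utr_left <- if (sp$strand == "+") sp$u5 else sp$u3
        utr_right <- if (sp$strand == "+") sp$u3 else sp$u5
        cds1_len <- sp$split
        cds2_len <- sp$cds_len - sp$split
        cds1 <- c(g_start + utr_left, g_start + utr_left + cds1_len - 1L)
        intron <- c(cds1[2] + 1L, cds1[2] + sp$intron)
        cds2 <- c(intron[2] + 1L, intron[2] + cds2_len)
        exon1 <- c(g_start, cds1[2])
        exon2 <- c(cds2[1], g_end)

        # spliced CDS on the coding strand: ATG ... sense codons ... stop
        k <- sp$cds_len / 3L
        spliced <- paste0("ATG",
                          paste(sample(codon_pool, k - 2L, replace = TRUE),
                                collapse = ""),
                          sample(STOP_CODONS, 1))
        if (sp$strand == "+") {
          chars[cds1[1]:cds1[2]] <- strsplit(substring(spliced, 1L, cds1_len), "")[[1]]
          chars[cds2[1]:cds2[2]] <- strsplit(substring(spliced, cds1_len + 1L), "")[[1]]
          phases <- c(0L, (3L - cds1_len %% 3L) %% 3L)  # cds1 first in transcript
        } else {
          # transcript runs right-to-left: cds2 holds the 5' piece
          chars[cds2[1]:cds2[2]] <- strsplit(revcomp(substring(spliced, 1L, cds2_len)), "")[[1]]
          chars[cds1[1]:cds1[2]] <- strsplit(revcomp(substring(spliced, cds2_len + 1L)), "")[[1]]
          phases <- c((3L - cds2_len %% 3L) %% 3L, 0L)  # phase of cds1, cds2
        }

        id <- sprintf("gene%04d", gid)
        mk <- function(type, s, e, phase = NA_integer_, parent = paste0(id, ".t1")) {
          tibble(seq_id = chrom_names[ci], source = "dualmark", type = type,
                 start = as.integer(s), end = as.integer(e), strand = sp$strand,
                 phase = phase, gene_id = id, parent = parent)
        }
        utr_l_type <- if (sp$strand == "+") "five_prime_UTR" else "three_prime_UTR"
        utr_r_type <- if (sp$strand == "+") "three_prime_UTR" else "five_prime_UTR"
        gene_rows[[gid]] <- bind_rows(
          mk("gene", g_start, g_end, parent = NA_character_),
          mk("mRNA", g_start, g_end, parent = id),
          mk("exon", exon1[1], exon1[2]),
          mk("exon", exon2[1], exon2[2]),
          mk(utr_l_type, g_start, g_start + utr_left - 1L),
          mk("CDS", cds1[1], cds1[2], phase = phases[1]),
          mk("CDS", cds2[1], cds2[2], phase = phases[2]),
          mk(utr_r_type, g_end - utr_right + 1L, g_end)
        )
      }
      sequences[[ci]] <- paste(chars, collapse = "")
    }
    genes <- bind_rows(gene_rows)
  }

  structure(
    list(
      sequences = sequences,
      genes = genes,
      truth = list(
        planted_snps = tibble(chrom = character(), pos = integer(),
                              ref_base = character(), cultivarA_base = character(),
                              cultivarB_base = character()),
        planted_indels = tibble(chrom = character(), pos = integer(),
                                type = character(), motif = character(),
                                length = integer(), cultivar = character()),
        planted_ssr_variants = tibble(chrom = character(), anchor = integer(),
                                      motif = character(),
                                      canonical_motif = character(),
                                      repeat_count_ref = integer(),
                                      repeat_count_A = integer(),
                                      repeat_count_B = integer())
      ),
      ssr_spans = tibble(chrom = character(), start = integer(), end = integer()),
      config = config
    ),
    class = "sim_genome"
  )
}

#' Seed perfect SSR arrays into a simulated reference
#'
#' Overwrites `n_ssr_seeds` intergenic segments of the reference with
#' perfect tandem arrays of random non-periodic 1-6 bp motifs.  Every
#' seeded array meets the detection minimum for its motif class, seeds sit
#' at least 400 bp apart and at least 200 bp from chromosome ends (so
#' 180 bp flanks always exist), and the bases immediately flanking each
#' array are forced to break the repeat so the planted span is exactly the
#' maximal run a detector should report.  Arrays replace reference bases in
#' place, so no coordinates shift.
#'
#' @param genome a `sim_genome` from [simulate_reference()].
#' @param config a [sim_config()]; defaults to the genome's own.
#' @return the genome with arrays written into `sequences`, the
#'   planted-SSR truth ledger filled in, and `ssr_spans` recorded.
#' @export
seed_ssr_loci <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "sim_genome"))
  if (config$n_ssr_seeds <= 0) abort("n_ssr_seeds must be positive")
  set.seed(stage_seed(config$seed, "ssr"))

  minima <- ssr_min_lengths()
  chrom_names <- names(genome$sequences)
  lens <- nchar(genome$sequences)

  # intergenic intervals, 50 bp clear of genes, 200 bp clear of contig ends
  allowed <- purrr::map(chrom_names, function(cn) {
    L <- nchar(genome$sequences[[cn]])
    g <- genome$genes %>% filter(.data$seq_id == cn, .data$type == "gene")
    free <- tibble(start = 201L, end = L - 200L)
    if (nrow(g) > 0) {
      occ <- IRanges::reduce(IRanges::IRanges(pmax(g$start - 50L, 1L), g$end + 50L))
      gap <- BiocGenerics::setdiff(IRanges::IRanges(201L, L - 200L), occ)
      free <- tibble(start = IRanges::start(gap), end = IRanges::end(gap))
    }
    free %>% filter(.data$end - .data$start + 1L >= 120L)
  })
  names(allowed) <- chrom_names

  # draw motif + repeat count for each seed
  seeds <- purrr::map(seq_len(config$n_ssr_seeds), function(i) {
    p <- sample(1:6, 1, prob = config$ssr_motif_len_probs)
    repeat {
      motif <- paste(sample(DNA_BASES, p, replace = TRUE), collapse = "")
      if (!is_periodic_motif(motif)) break
    }
    min_count <- ceiling(minima[[as.character(p)]] / p)
    count <- min_count + sample(0:8, 1)
    list(motif = motif, period = p, count = count, len = p * count)
  })

  # greedy placement: uniform draws, >= 400 bp apart, inside allowed space
  placed <- tibble(chrom = character(), pos = integer(), len = integer(),
                   motif = character(), period = integer(), count = integer())
  weights <- purrr::map_dbl(allowed, ~ sum(.x$end - .x$start + 1))
  if (sum(weights) <= 0) abort("no intergenic room to seed SSR arrays")
  attempts <- 0L
  max_attempts <- 400L * config$n_ssr_seeds
  for (s in seeds) {
    ok <- FALSE
    while (!ok) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf(
          "could not place %d SSR seeds with 400 bp separation (placed %d); reduce n_ssr_seeds",
          config$n_ssr_seeds, nrow(placed)))
      }
      cn <- sample(chrom_names, 1, prob = weights)
      iv <- allowed[[cn]]
      row <- iv[sample.int(nrow(iv), 1, prob = iv$end - iv$start + 1), ]
      hi <- row$end - s$len - 1L
      if (hi < row$start + 1L) next
      pos <- as.integer(sample(row$start:hi, 1))
      near <- placed$chrom == cn & abs(placed$pos - pos) < 400L + s$len
      if (any(near)) next
      placed <- bind_rows(placed, tibble(
        chrom = cn, pos = pos, len = as.integer(s$len), motif = s$motif,
        period = as.integer(s$period), count = as.integer(s$count)))
      ok <- TRUE
    }
  }

  # write arrays in place, breaking the repeat at both boundaries
  chars_by <- purrr::map(genome$sequences, ~ strsplit(.x, "")[[1]])
  for (i in seq_len(nrow(placed))) {
    pl <- placed[i, ]
    chars <- chars_by[[pl$chrom]]
    array <- strsplit(strrep(pl$motif, pl$count), "")[[1]]
    span <- pl$pos:(pl$pos + pl$len - 1L)
    chars[span] <- array
    m <- strsplit(pl$motif, "")[[1]]
    if (chars[pl$pos - 1L] == m[pl$period]) {
      chars[pl$pos - 1L] <- sample(setdiff(DNA_BASES, m[pl$period]), 1)
    }
    right <- pl$pos + pl$len
    if (chars[right] == m[1]) {
      chars[right] <- sample(setdiff(DNA_BASES, m[1]), 1)
    }
    chars_by[[pl$chrom]] <- chars
  }
  genome$sequences <- setNames(
    vapply(chars_by, paste, character(1), collapse = ""), chrom_names)

  genome$truth$planted_ssr_variants <- placed %>%
    mutate(canonical = vapply(.data$motif, canonical_motif, character(1), USE.NAMES = FALSE)) %>%
    transmute(
      chrom = .data$chrom, anchor = .data$pos, motif = .data$motif,
      canonical_motif = .data$canonical,
      repeat_count_ref = .data$count,
      repeat_count_A = NA_integer_, repeat_count_B = NA_integer_
    )
  genome$ssr_spans <- placed %>%
    transmute(chrom = .data$chrom, start = .data$pos,
              end = .data$pos + .data$len - 1L)
  genome
}
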