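# Independent oracles used across the suite.  The brute-force SSR
# enumerator deliberately shares no code with find_ssrs(): it scans
# character by character, checks motif primitivity by explicit division,
# and applies the same reporting rules (maximal runs, whole repeat units,
# per-motif-length minima, shortest-period suppression by containment).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# is `motif` a repetition of a shorter unit?  (divisor check, independent
# of dualmark's recursive implementation)
bf_is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(TRUE)
  for (q in seq_len(k - 1)) {
    if (k %% q == 0 && strrep(substr(motif, 1, q), k / q) == motif) return(FALSE)
  }
  TRUE
}

brute_force_ssrs <- function(sequence, thresholds = c(`1` = 12L, `2` = 12L,
                                                      `3` = 12L, `4` = 16L,
                                                      `5` = 20L, `6` = 24L)) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  rows <- list()
  for (p in 1:6) {
    if (n < p + 1) next
    eq <- function(j) {
      j >= 1 && j + p <= n && chars[j] != "N" && chars[j + p] != "N" &&
        chars[j] == chars[j + p]
    }
    j <- 1
    while (j <= n - p) {
      if (eq(j) && !eq(j - 1)) {
        k <- j
        while (eq(k + 1)) k <- k + 1
        run_len <- k - j + 1 + p                    # span j .. k+p
        total <- (run_len %/% p) * p                # whole units
        motif <- paste(chars[j:(j + p - 1)], collapse = "")
        if (total >= thresholds[[as.character(p)]] && bf_is_primitive(motif)) {
          rows[[length(rows) + 1]] <- data.frame(
            start = j, end = j + total - 1, motif = motif, period = p,
            repeat_count = total %/% p, total_length = total,
            stringsAsFactors = FALSE)
        }
        j <- k + 1
      } else {
        j <- j + 1
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      period = integer(), repeat_count = integer(),
                      total_length = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  # suppress loci contained within a shorter-period locus
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(df$period < df$period[i] & df$start <= df$start[i] &
           df$end >= df$end[i])
  }, logical(1))
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$period), c("start", "end", "motif", "repeat_count",
                                   "total_length")]
}

# random unrooted tree with positive branch lengths and its additive
# distance matrix (tip-to-tip path lengths)
random_additive_matrix <- function(n_taxa) {
  tree <- ape::unroot(ape::rtree(n_taxa, br = function(k) runif(k, 0.2, 2)))
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

expect_same_topology <- function(t1, t2) {
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
}
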