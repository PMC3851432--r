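# Perfect microsatellite (SSR) mining.
#
# A locus is a maximal perfect tandem run of a 1-6 bp motif whose total
# length reaches the per-motif-class minimum (12 bp for mono/di/tri, 16 for
# tetra, 20 for penta, 24 for hexa).  Runs are reported under their shortest
# period only, never contain N, and are truncated to whole repeat units.
# Tracts of >= 20 bp are "class I" (hypervariable), 12-19 bp "class II".

#' Default per-motif-length SSR minima
#'
#' Minimum total tract length (bp) required to report an SSR, indexed by
#' motif length 1..6: 12 bp for mono-, di- and trinucleotides, 16 bp for
#' tetranucleotides, 20 bp for pentanucleotides and 24 bp for
#' hexanucleotides.
#'
#' @return named integer vector of length 6.
#' @export
ssr_min_lengths <- function() {
  c(`1` = 12L, `2` = 12L, `3` = 12L, `4` = 16L, `5` = 20L, `6` = 24L)
}

#' Class I / class II boundary
#'
#' Tracts of total length >= 20 bp are hypervariable class I; tracts of
#' >= 12 and < 20 bp are potentially variable class II.
#'
#' @param total_length integer vector of tract lengths in bp.
#' @return character vector "I" / "II".
#' @export
ssr_class <- function(total_length) {
  ifelse(total_length >= 20L, "I", "II")
}

#' Find perfect SSRs in a sequence
#'
#' Scans one nucleotide sequence for maximal perfect tandem repeats of
#' 1-6 bp motifs.  Each maximal run is truncated to a whole number of
#' repeat units, reported under its shortest period (a poly-A tract is a
#' mononucleotide locus, never a dinucleotide "AA" locus), broken at any N,
#' and kept only if its truncated length reaches the minimum for its motif
#' length.  A locus whose span lies inside the span of a shorter-period
#' locus is suppressed.
#'
#' @param sequence a single character string over A/C/G/T/N.
#' @param seq_id name recorded in the `seq_id` column.
#' @param thresholds named vector of per-motif-length minima (bp), indexed
#'   "1".."6"; defaults to [ssr_min_lengths()].
#' @return a tibble with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `motif`, `canonical_motif`, `repeat_count`, `total_length`
#'   and `ssr_class`, sorted by `start` then motif length.
#' @examples
#' find_ssrs(paste0("TTCG", strrep("AG", 10), "CCGT"))
#' @export
find_ssrs <- function(sequence, seq_id = "seq", thresholds = ssr_min_lengths()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  assert_bases(sequence, what = sprintf("sequence '%s'", seq_id))
  n <- nchar(sequence)
  empty <- tibble(
    seq_id = character(), start = integer(), end = integer(),
    motif = character(), canonical_motif = character(),
    repeat_count = integer(), total_length = integer(),
    ssr_class = character()
  )
  if (n < min(thresholds)) return(empty)

  chars <- strsplit(sequence, "")[[1]]
  is_n <- chars == "N"
  out <- vector("list", 6L)

  for (p in 1:6) {
    if (n < p + 1L) break
    min_len <- thresholds[[as.character(p)]]
    eq <- chars[seq_len(n - p)] == chars[seq_len(n - p) + p]
    # runs containing N are broken at the N
    eq <- eq & !is_n[seq_len(n - p)] & !is_n[seq_len(n - p) + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths + p >= min_len
    if (!any(keep)) next
    run_start <- starts[keep]
    run_len <- r$lengths[keep]
    total <- ((run_len + p) %/% p) * p          # whole repeat units only
    ok <- total >= min_len
    if (!any(ok)) next
    run_start <- run_start[ok]
    total <- total[ok]
    motif <- substring(sequence, run_start, run_start + p - 1L)
    prim <- !vapply(motif, is_periodic_motif, logical(1))  # shortest period
    if (!any(prim)) next
    out[[p]] <- tibble(
      seq_id = seq_id,
      start = run_start[prim],
      end = run_start[prim] + total[prim] - 1L,
      motif = motif[prim],
      period = p,
      repeat_count = as.integer(total[prim] %/% p),
      total_length = as.integer(total[prim])
    )
  }

  loci <- bind_rows(out)
  if (nrow(loci) == 0) return(empty)
  loci <- arrange(loci, .data$start, .data$period)

  # suppress a locus contained in the span of a shorter-period locus
  contained <- vapply(seq_len(nrow(loci)), function(i) {
    any(loci$period < loci$period[i] &
          loci$start <= loci$start[i] & loci$end >= loci$end[i])
  }, logical(1))
  loci <- loci[!contained, , drop = FALSE]

  loci %>%
    mutate(
      canonical_motif = vapply(.data$motif, canonical_motif, character(1), USE.NAMES = FALSE),
      ssr_class = ssr_class(.data$total_length)
    ) %>%
    select("seq_id", "start", "end", "motif", "canonical_motif",
           "repeat_count", "total_length", "ssr_class")
}

#' Scan a set of sequences for SSRs
#'
#' @param sequences named character vector of sequences (names are used as
#'   `seq_id`), or a [Biostrings::DNAStringSet].
#' @inheritParams find_ssrs
#' @return row-bound tibble of [find_ssrs()] results.
#' @export
scan_ssrs <- function(sequences, thresholds = ssr_min_lengths()) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  purrr::imap(sequences, function(s, id) find_ssrs(s, id, thresholds)) %>%
    bind_rows()
}

#' Canonical motif and strand/rotation group
#'
#' Equivalent SSR motifs differ only by rotation (phase of the repeat) or
#' by strand; the canonical representative is the lexicographically smallest
#' string among all rotations of the motif and all rotations of its reverse
#' complement.  `motif_group()` renders the usual "X/Y" group label with
#' Y the reverse complement of X (e.g. "GA" -> canonical "AG", group
#' "AG/CT").
#'
#' @param motif base string of length 1-6 that is not a repetition of a
#'   shorter motif.
#' @return `canonical_motif()`: the canonical base string; `motif_group()`:
#'   the "X/Y" group label.
#' @examples
#' canonical_motif("GA")   # "AG"
#' motif_group("TTA")      # "AAT/ATT"
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1)
  motif <- toupper(motif)
  assert_bases(motif, what = "motif", allow_n = FALSE)
  k <- nchar(motif)
  if (k < 1 || k > 6) abort("motif length must be 1-6 bp")
  if (is_periodic_motif(motif)) {
    abort(sprintf("motif '%s' is a repetition of a shorter motif", motif))
  }
  rotations <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n) - 1L, function(i) {
      paste0(substring(s, i + 1L, n), substring(s, 1L, i))
    }, character(1))
  }
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' @rdname canonical_motif
#' @export
motif_group <- function(motif) {
  canon <- canonical_motif(motif)
  paste0(canon, "/", revcomp(canon))
}

#' Extract SSR flanking sequences
#'
#' Pulls `flank_len` bases either side of each locus and flags whether each
#' flank occurs exactly once as an exact substring of the whole reference
#' (across both strands of nothing - matching is on the given strand only,
#' which is how locus identity is established for primer design context).
#' Loci closer than `flank_len` to a contig end are flagged unextractable.
#'
#' @param loci tibble with `seq_id`, `start`, `end` columns (1-based
#'   inclusive), e.g. from [find_ssrs()].
#' @param sequences named character vector (or DNAStringSet) holding the
#'   sequences the loci refer to, used both for extraction and for the
#'   uniqueness check.
#' @param flank_len flank length in bp (default 180).
#' @return the input tibble with `left_flank`, `right_flank`, `extractable`
#'   and `flank_unique` columns appended (`NA` flanks when unextractable).
#' @export
extract_flanks <- function(loci, sequences, flank_len = 180L) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(all(loci$seq_id %in% names(sequences)))
  subject <- Biostrings::DNAStringSet(unlist(sequences))
  seq_len_of <- setNames(nchar(sequences), names(sequences))

  res <- purrr::pmap(list(loci$seq_id, loci$start, loci$end), function(id, s, e) {
    L <- seq_len_of[[id]]
    if (s - flank_len < 1L || e + flank_len > L) {
      return(list(left = NA_character_, right = NA_character_,
                  extractable = FALSE, unique = NA))
    }
    left <- substring(sequences[[id]], s - flank_len, s - 1L)
    right <- substring(sequences[[id]], e + 1L, e + flank_len)
    n_left <- sum(Biostrings::vcountPattern(left, subject))
    n_right <- sum(Biostrings::vcountPattern(right, subject))
    list(left = left, right = right, extractable = TRUE,
         unique = n_left == 1L && n_right == 1L)
  })

  loci %>%
    mutate(
      left_flank = purrr::map_chr(res, "left"),
      right_flank = purrr::map_chr(res, "right"),
      extractable = purrr::map_lgl(res, "extractable"),
      flank_unique = purrr::map_lgl(res, "unique")
    )
}
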