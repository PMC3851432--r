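# Cross-cultivar polymorphism classification.
#
# SNP calls pass a depth/quality/per-allele-read filter (depth strictly
# greater than 8, quality strictly greater than 30, every observed allele
# supported by at least 4 reads).  InDel loci are polymorphic when the
# signed motif lengths in the two cultivars differ by at least 1 bp
# (a missing call counts as length 0); SSR loci when their total tract
# lengths differ by at least 2 bp.

#' Filter SNP calls on confidence fields
#'
#' Retains calls with depth strictly above `min_depth`, quality strictly
#' above `min_quality`, and every observed allele (read count > 0)
#' supported by at least `min_allele_reads` reads.  Records with missing
#' confidence fields are rejected with a per-record warning, never an
#' error.  Input order is preserved.
#'
#' @param calls tibble with `depth`, `quality`, `reads_ref`, `reads_alt`
#'   columns; rows with a `type` column are restricted to `type == "snp"`.
#' @param min_depth exclusive depth threshold (default 8).
#' @param min_quality exclusive quality threshold (default 30).
#' @param min_allele_reads inclusive per-allele read minimum (default 4).
#' @return the retained rows.
#' @export
filter_snp_calls <- function(calls, min_depth = 8, min_quality = 30,
                             min_allele_reads = 4) {
  if ("type" %in% names(calls)) calls <- filter(calls, .data$type == "snp")
  needed <- c("depth", "quality", "reads_ref", "reads_alt")
  missing_field <- Reduce(`|`, lapply(calls[needed], is.na))
  if (any(missing_field)) {
    warn(sprintf("%d call(s) dropped: missing confidence fields", sum(missing_field)))
  }
  ok <- !missing_field &
    calls$depth > min_depth &
    calls$quality > min_quality &
    (calls$reads_ref == 0 | calls$reads_ref >= min_allele_reads) &
    (calls$reads_alt == 0 | calls$reads_alt >= min_allele_reads) &
    (calls$reads_ref + calls$reads_alt > 0)
  calls[which(ok), , drop = FALSE]
}

#' Transition or transversion
#'
#' A&#8596;G and C&#8596;T substitutions are transitions (purine-purine /
#' pyrimidine-pyrimidine); the other eight ordered pairs are transversions.
#'
#' @param ref_base,alt_base character vectors of single distinct bases in
#'   A/C/G/T.
#' @return character vector "transition" / "transversion".
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  bad <- !(ref_base %in% DNA_BASES) | !(alt_base %in% DNA_BASES)
  if (any(bad)) abort("substitution bases must be unambiguous A/C/G/T")
  if (any(ref_base == alt_base)) abort("ref and alt bases must differ")
  purine <- c("A", "G")
  ifelse((ref_base %in% purine) == (alt_base %in% purine),
         "transition", "transversion")
}

#' Assemble SNP polymorphisms between two cultivars
#'
#' Filters each cultivar's SNP calls with [filter_snp_calls()], then joins
#' them on (chrom, pos).  A site is polymorphic between the cultivars when
#' their alleles differ (a missing call means the reference allele).
#' Sites where both cultivars carry the same alternate allele are not
#' polymorphic between them and are dropped; sites with two different
#' non-reference alleles are kept and flagged `multiallelic`.
#'
#' @param calls_a,calls_b per-cultivar call tibbles (see
#'   [derive_cultivar_pair()] for the column contract).
#' @inheritParams filter_snp_calls
#' @return marker tibble: `marker_type`, `chrom`, `pos`, `ref`, `allele_a`,
#'   `allele_b`, `cultivar` (which cultivar differs from the reference, or
#'   "both"), `substitution` (transition/transversion, `NA` for
#'   multiallelic sites), `multiallelic`.
#' @export
call_snp_polymorphisms <- function(calls_a, calls_b, min_depth = 8,
                                   min_quality = 30, min_allele_reads = 4) {
  fa <- filter_snp_calls(calls_a, min_depth, min_quality, min_allele_reads) %>%
    select("chrom", "pos", "ref", alt_a = "alt")
  fb <- filter_snp_calls(calls_b, min_depth, min_quality, min_allele_reads) %>%
    select("chrom", "pos", "ref", alt_b = "alt")
  joined <- dplyr::full_join(fa, fb, by = c("chrom", "pos"),
                             suffix = c("_a", "_b")) %>%
    mutate(
      ref = dplyr::coalesce(.data$ref_a, .data$ref_b),
      allele_a = dplyr::coalesce(.data$alt_a, .data$ref),
      allele_b = dplyr::coalesce(.data$alt_b, .data$ref)
    ) %>%
    filter(.data$allele_a != .data$allele_b)
  joined %>%
    mutate(
      marker_type = "SNP",
      cultivar = dplyr::case_when(
        .data$allele_a != .data$ref & .data$allele_b != .data$ref ~ "both",
        .data$allele_a != .data$ref ~ "A",
        TRUE ~ "B"
      ),
      multiallelic = .data$cultivar == "both",
      substitution = ifelse(.data$multiallelic, NA_character_,
                            classify_substitution(
                              .data$ref,
                              ifelse(.data$allele_a != .data$ref,
                                     .data$allele_a, .data$allele_b)))
    ) %>%
    select("marker_type", "chrom", "pos", "ref", "allele_a", "allele_b",
           "cultivar", "substitution", "multiallelic") %>%
    arrange(.data$chrom, .data$pos)
}

# flank extraction + uniqueness on the reference around an anchor position
reference_flanks <- function(chrom, pos, sequences, flank_len) {
  subject <- Biostrings::DNAStringSet(unlist(sequences))
  purrr::map2(chrom, pos, function(cn, p) {
    s <- sequences[[cn]]
    left <- substring(s, max(1L, p - flank_len), p - 1L)
    right <- substring(s, p + 1L, min(nchar(s), p + flank_len))
    uni <- function(fl) {
      nzchar(fl) && sum(Biostrings::vcountPattern(fl, subject)) == 1L
    }
    list(left = left, right = right, flank_ok = uni(left) && uni(right))
  })
}

#' Call InDel polymorphisms between two cultivars
#'
#' Matches 1-6 bp InDel calls across cultivars by (chrom, pos) and
#' classifies a locus as polymorphic when the signed motif lengths differ
#' by at least `min_diff` bp; a cultivar without a call contributes length
#' 0, and identical calls in both cultivars cancel out.  Flanking
#' sequences of up to `flank_len` bp are extracted from the reference on
#' each side and their uniqueness (exact single occurrence in the whole
#' reference) recorded in `flank_ok`.
#'
#' @param calls_a,calls_b per-cultivar call tibbles.
#' @param reference named character vector (or DNAStringSet) of reference
#'   sequences.
#' @param max_len longest InDel considered (default 6 bp).
#' @param min_diff minimum length difference in bp (default 1).
#' @param flank_len flank length (default 195 bp).
#' @return marker tibble: `marker_type = "InDel"`, `chrom`, `pos`, `motif`,
#'   `type` (ins/del relative to the reference in the differing cultivar),
#'   `length` (absolute cross-cultivar length difference), `len_a`,
#'   `len_b` (signed: + insertion, - deletion), `cultivar`, `flank_ok`.
#' @export
call_indel_polymorphisms <- function(calls_a, calls_b, reference,
                                     max_len = 6L, min_diff = 1L,
                                     flank_len = 195L) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  prep <- function(calls, cv) {
    x <- calls %>% filter(.data$type %in% c("ins", "del"),
                          .data$length >= 1L, .data$length <= max_len)
    bad <- !x$chrom %in% names(reference)
    if (any(bad)) {
      abort(sprintf("InDel call on unknown chromosome '%s' at pos %d",
                    x$chrom[which(bad)[1]], x$pos[which(bad)[1]]))
    }
    x %>% transmute(
      chrom = .data$chrom, pos = .data$pos,
      motif = ifelse(.data$type == "ins", .data$alt, .data$ref),
      signed_len = ifelse(.data$type == "ins", .data$length, -.data$length)
    ) %>%
      setNames(c("chrom", "pos", paste0("motif_", cv), paste0("len_", cv)))
  }
  joined <- dplyr::full_join(prep(calls_a, "a"), prep(calls_b, "b"),
                             by = c("chrom", "pos")) %>%
    mutate(
      len_a = dplyr::coalesce(.data$len_a, 0L),
      len_b = dplyr::coalesce(.data$len_b, 0L)
    ) %>%
    filter(abs(.data$len_a - .data$len_b) >= min_diff)
  if (nrow(joined) == 0) {
    return(tibble(marker_type = character(), chrom = character(),
                  pos = integer(), motif = character(), type = character(),
                  length = integer(), len_a = integer(), len_b = integer(),
                  cultivar = character(), flank_ok = logical()))
  }
  fl <- reference_flanks(joined$chrom, joined$pos, reference, flank_len)
  joined %>%
    mutate(
      marker_type = "InDel",
      # the cultivar whose allele departs further from the reference
      cultivar = dplyr::case_when(
        abs(.data$len_a) > 0 & abs(.data$len_b) > 0 ~ "both",
        abs(.data$len_a) > 0 ~ "A",
        TRUE ~ "B"
      ),
      motif = dplyr::coalesce(.data$motif_a, .data$motif_b),
      net = ifelse(.data$cultivar == "B", .data$len_b, .data$len_a),
      type = ifelse(.data$net > 0, "ins", "del"),
      length = abs(.data$len_a - .data$len_b),
      flank_ok = purrr::map_lgl(fl, "flank_ok")
    ) %>%
    select("marker_type", "chrom", "pos", "motif", "type", "length",
           "len_a", "len_b", "cultivar", "flank_ok") %>%
    arrange(.data$chrom, .data$pos)
}

# maximal perfect run of period p covering `anchor` in a sequence
ref_run_length <- function(sequence, anchor, period) {
  n <- nchar(sequence)
  if (anchor < 1 || anchor > n) return(0L)
  chars <- strsplit(sequence, "")[[1]]
  lo <- anchor
  while (lo - period >= 1 && chars[lo - period] == chars[lo]) lo <- lo - 1L
  hi <- anchor
  while (hi + period <= n && chars[hi + period] == chars[hi]) hi <- hi + 1L
  len <- hi - lo + 1L + period - 1L          # run of equalities spans lo..hi at lag p
  len <- min(len, n - lo + 1L)
  as.integer((len %/% period) * period)
}

#' Call SSR polymorphisms between two cultivars
#'
#' Matches per-cultivar SSR scans through the reference: each locus is
#' anchored by locating its left flank (exact `anchor_flank`-bp match) in
#' the reference, and two loci pair up when they sit on the same
#' chromosome, share a canonical motif, and their reference anchors are
#' within `anchor_tol` bp (flank anchoring absorbs the coordinate shifts
#' that upstream InDels introduce between consensus sequences).  A matched
#' pair is polymorphic when the tract lengths differ by at least
#' `min_diff` bp.  A locus detected in only one cultivar is compared
#' against the reference's own run length at the anchor, and ambiguous
#' many-to-many matches are dropped with a warning rather than mispaired.
#'
#' @param ssrs_a,ssrs_b SSR tibbles from [scan_ssrs()] run on the cultivar
#'   consensus sequences.
#' @param reference named character vector of reference sequences (names
#'   must match the cultivar `seq_id`s).
#' @param seqs_a,seqs_b the cultivar consensus sequences the scans refer
#'   to (needed to pull anchor flanks).
#' @param min_diff minimum tract-length difference in bp (default 2).
#' @param anchor_flank bp of left flank used to anchor a locus (default 30).
#' @param anchor_tol anchor-matching tolerance in bp (default 10).
#' @return marker tibble: `marker_type = "SSR"`, `chrom`, `pos` (reference
#'   anchor), `motif` (canonical), `length` (absolute length difference),
#'   `len_a`, `len_b` (tract lengths), `repeat_count_a`, `repeat_count_b`,
#'   `matched` ("pair" or the single cultivar compared to the reference).
#' @export
call_ssr_polymorphisms <- function(ssrs_a, ssrs_b, reference,
                                   seqs_a, seqs_b, min_diff = 2L,
                                   anchor_flank = 30L, anchor_tol = 10L) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  anchor_loci <- function(ssrs, seqs) {
    if (nrow(ssrs) == 0) {
      return(mutate(ssrs, ref_anchor = integer()))
    }
    anchors <- purrr::pmap_int(
      list(ssrs$seq_id, ssrs$start), function(id, s) {
        if (s - anchor_flank < 1L) return(NA_integer_)
        fl <- substring(seqs[[id]], s - anchor_flank, s - 1L)
        hits <- Biostrings::matchPattern(fl, Biostrings::DNAString(reference[[id]]))
        if (length(hits) != 1L) return(NA_integer_)
        as.integer(BiocGenerics::end(hits)[1] + 1L)
      })
    dropped <- sum(is.na(anchors))
    if (dropped > 0) {
      warn(sprintf("%d SSR locus/loci dropped: left flank not uniquely anchorable in the reference", dropped))
    }
    ssrs %>% mutate(ref_anchor = anchors) %>% filter(!is.na(.data$ref_anchor))
  }
  a <- anchor_loci(ssrs_a, seqs_a) %>% mutate(.id = row_number())
  b <- anchor_loci(ssrs_b, seqs_b) %>% mutate(.id = row_number())

  pairs <- dplyr::inner_join(
    a %>% select("seq_id", "canonical_motif", ".id",
                 anchor_a = "ref_anchor", len_a = "total_length",
                 reps_a = "repeat_count", motif_a = "motif"),
    b %>% select("seq_id", "canonical_motif", ".id",
                 anchor_b = "ref_anchor", len_b = "total_length",
                 reps_b = "repeat_count", motif_b = "motif"),
    by = c("seq_id", "canonical_motif"), suffix = c("_a", "_b"),
    relationship = "many-to-many") %>%
    filter(abs(.data$anchor_a - .data$anchor_b) <= anchor_tol)

  # ambiguous many-to-many matches are dropped, never mispaired
  amb_a <- pairs$.id_a[duplicated(pairs$.id_a) | duplicated(pairs$.id_a, fromLast = TRUE)]
  amb_b <- pairs$.id_b[duplicated(pairs$.id_b) | duplicated(pairs$.id_b, fromLast = TRUE)]
  if (length(amb_a) + length(amb_b) > 0) {
    warn(sprintf("%d ambiguously matched SSR pair(s) dropped",
                 length(unique(c(amb_a, amb_b)))))
    pairs <- pairs %>% filter(!.data$.id_a %in% amb_a, !.data$.id_b %in% amb_b)
  }

  matched <- pairs %>% transmute(
    chrom = .data$seq_id, pos = pmin(.data$anchor_a, .data$anchor_b),
    motif = .data$canonical_motif,
    len_a = .data$len_a, len_b = .data$len_b,
    repeat_count_a = .data$reps_a, repeat_count_b = .data$reps_b,
    matched = "pair"
  )

  # loci seen in exactly one cultivar: compare to the reference run length
  single <- function(tbl, pairs_ids, cv) {
    solo <- tbl %>% filter(!.data$.id %in% pairs_ids)
    if (nrow(solo) == 0) return(NULL)
    inform(sprintf("%d SSR locus/loci found only in cultivar %s; compared to the reference run length",
                   nrow(solo), cv))
    ref_len <- purrr::pmap_int(list(solo$seq_id, solo$ref_anchor, nchar(solo$motif)),
                               function(cn, p, per) ref_run_length(reference[[cn]], p, per))
    out <- solo %>% mutate(other_len = ref_len) %>% transmute(
      chrom = .data$seq_id, pos = .data$ref_anchor, motif = .data$canonical_motif,
      this_len = .data$total_length, other_len = .data$other_len,
      this_reps = .data$repeat_count, matched = cv
    )
    if (cv == "A") {
      out %>% rename(len_a = "this_len", len_b = "other_len",
                     repeat_count_a = "this_reps") %>%
        mutate(repeat_count_b = NA_integer_)
    } else {
      out %>% rename(len_b = "this_len", len_a = "other_len",
                     repeat_count_b = "this_reps") %>%
        mutate(repeat_count_a = NA_integer_)
    }
  }
  solos <- bind_rows(single(a, pairs$.id_a, "A"), single(b, pairs$.id_b, "B"))

  bind_rows(matched, solos) %>%
    filter(abs(.data$len_a - .data$len_b) >= min_diff) %>%
    mutate(marker_type = "SSR", length = abs(.data$len_a - .data$len_b)) %>%
    select("marker_type", "chrom", "pos", "motif", "length", "len_a", "len_b",
           "repeat_count_a", "repeat_count_b", "matched") %>%
    arrange(.data$chrom, .data$pos)
}
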