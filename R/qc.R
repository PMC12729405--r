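# Duplicate and artificial-sequence removal with per-rule accounting.

#' Is a sequence composed only of canonical residues?
#'
#' `TRUE` iff every character is one of the 20 canonical one-letter codes.
#' Empty or missing sequences are not biological and return `FALSE`.
#' Ambiguity codes (X/B/Z/*) reject the record at QC; gap masking with
#' `"-"` happens only inside the alignment module.
#'
#' @param sequence character vector of sequences.
#' @return Logical vector.
#' @examples
#' isCanonicalSequence(c("QVQLVESGGG", "QVXLVESGGG", ""))
#' @export
isCanonicalSequence <- function(sequence) {
  out <- !is.na(sequence) & nzchar(sequence) &
    !grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"), sequence)
  out
}

#' Is a sequence alphabetically ordered?
#'
#' Detects deliberately obscured deposits whose residues were sorted (the
#' classic give-away being the full alphabet string
#' `"ACDEFGHIKLMNPQRSTVWY"`). `TRUE` iff the residues are in non-decreasing
#' alphabetical order over the whole string AND the number of distinct
#' residues is at least `min_distinct` — the latter keeps this rule from
#' double-firing on homopolymers, which the low-complexity rule owns.
#'
#' @param sequence character vector of canonical sequences.
#' @param min_distinct minimum number of distinct residues (default 5).
#' @return Logical vector.
#' @export
isAlphabeticallyOrdered <- function(sequence, min_distinct = 5L) {
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    codes <- utf8ToInt(s)
    !is.unsorted(codes) && length(unique(codes)) >= min_distinct
  }, logical(1), USE.NAMES = FALSE)
}

#' Is a sequence a homopolymer / low-complexity string?
#'
#' `TRUE` iff the longest single-residue run reaches `max_run_length`
#' (default 10) OR the most frequent residue accounts for strictly more
#' than `max_run_fraction` (default 0.5) of the sequence. Real VHHs rarely
#' exceed runs of five, so the defaults are conservative.
#'
#' @param sequence character vector of canonical sequences.
#' @param max_run_length run length at or above which the rule fires.
#' @param max_run_fraction residue fraction strictly above which the rule
#'   fires (a 50/50 dinucleotide-style repeat does not fire at the default).
#' @return Logical vector.
#' @export
isLowComplexity <- function(sequence, max_run_length = 10L,
                            max_run_fraction = 0.5) {
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) return(TRUE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    runs <- rle(chars)
    max(runs$lengths) >= max_run_length ||
      max(table(chars)) / length(chars) > max_run_fraction
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove exact duplicates keyed on the full-length sequence
#'
#' Exactly one record survives per distinct full sequence. The survivor is
#' chosen by `source_priority` (earlier tags win), then by lexicographic
#' record identifier, so the surviving set is invariant under record
#' shuffling. Removals get a `duplicate` verdict naming the survivor.
#'
#' @param set an [SdAbSet-class]; all records must carry a full sequence.
#' @param source_priority ordered character vector of source tags; tags
#'   not listed rank after all listed ones.
#' @return Deduplicated [SdAbSet-class] with funnel step
#'   `"duplicate_removal"`.
#' @export
deduplicateRecords <- function(set, source_priority = character(0)) {
  rec <- records(set)
  if (nrow(rec) == 0L)
    return(replaceRecords(set, rec, step = "duplicate_removal", removed = 0L))
  pr <- match(rec$source_db, source_priority)
  pr[is.na(pr)] <- length(source_priority) + 1L
  ord <- order(rec$full_sequence, pr, rec$record_id)
  first <- !duplicated(rec$full_sequence[ord])
  keep_idx <- sort(ord[first])
  ordered_ids <- rec$record_id[ord]
  survivor_of <- ordered_ids[first][cumsum(first)][order(ord)]
  dup_idx <- setdiff(seq_len(nrow(rec)), keep_idx)
  vd <- verdictRows(rec$record_id[dup_idx], "duplicate",
                    paste("duplicate of", survivor_of[dup_idx]))
  replaceRecords(set, rec[keep_idx, , drop = FALSE],
                 step = "duplicate_removal", removed = length(dup_idx),
                 new_verdicts = vd)
}

#' Filter thresholds and ordering options
#'
#' @param min_distinct see [isAlphabeticallyOrdered()].
#' @param max_run_length,max_run_fraction see [isLowComplexity()].
#' @param source_priority see [deduplicateRecords()].
#' @return Named list of options.
#' @export
filterConfig <- function(min_distinct = 5L, max_run_length = 10L,
                         max_run_fraction = 0.5,
                         source_priority = character(0)) {
  list(min_distinct = as.integer(min_distinct),
       max_run_length = as.integer(max_run_length),
       max_run_fraction = max_run_fraction,
       source_priority = source_priority)
}

#' Apply the QC filter battery in its fixed order
#'
#' Filters run in a fixed order so funnel counts are reproducible:
#' canonical-alphabet check, completeness of the full sequence, exact
#' duplicate removal, artificial-sequence removal (alphabetical order,
#' then homopolymer/low complexity). Every removal is recorded both in the
#' funnel and as a per-record verdict; the operation is idempotent.
#'
#' @param set an [SdAbSet-class].
#' @param config see [filterConfig()].
#' @return Filtered [SdAbSet-class].
#' @export
applyFilters <- function(set, config = filterConfig()) {
  rec <- records(set)

  # 1. canonical alphabet (non-canonical characters flag the record)
  ok <- is.na(rec$full_sequence) | isCanonicalSequence(rec$full_sequence)
  bad <- !ok
  vd <- verdictRows(rec$record_id[bad], "non_canonical_alphabet",
                    "sequence contains non-canonical characters")
  set <- replaceRecords(set, rec[ok, , drop = FALSE],
                        step = "canonical_alphabet", removed = sum(bad),
                        new_verdicts = vd)
  rec <- records(set)

  # 2. reconstruction/annotation completeness: a usable full sequence
  ok <- isPresent(rec$full_sequence)
  vd <- verdictRows(rec$record_id[!ok], "incomplete_record",
                    "no full sequence after reconstruction")
  set <- replaceRecords(set, rec[ok, , drop = FALSE],
                        step = "completeness", removed = sum(!ok),
                        new_verdicts = vd)

  # 3. exact duplicates on the full-length sequence
  set <- deduplicateRecords(set, config$source_priority)
  rec <- records(set)

  # 4. artificially ordered / non-biological sequences
  alpha <- isAlphabeticallyOrdered(rec$full_sequence, config$min_distinct)
  homo <- !alpha & isLowComplexity(rec$full_sequence, config$max_run_length,
                                   config$max_run_fraction)
  vd <- rbind(
    verdictRows(rec$record_id[alpha], "alphabetical_order",
                "residues in non-decreasing alphabetical order"),
    verdictRows(rec$record_id[homo], "homopolymer_low_complexity",
                "extended single-residue run or dominant residue"))
  keep <- !(alpha | homo)
  replaceRecords(set, rec[keep, , drop = FALSE],
                 step = "artificial_removal", removed = sum(!keep),
                 new_verdicts = vd)
}
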