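# Reconstruction of full sequences from region fragments and delineation
# of FR/CDR boundaries on full sequences.

#' Configuration of the motif-anchored fallback annotator
#'
#' The fallback annotator exploits the invariant residues of the
#' immunoglobulin fold instead of a full numbering scheme: the canonical
#' FR1 cysteine, the tryptophan that opens FR2, the canonical FR3 cysteine,
#' and the W-G-x-G motif that opens FR4. Framework lengths in VHHs are
#' near-fixed (~25/17/38/11 residues), which pins the two boundaries the
#' anchors alone cannot see.
#'
#' @param fr1_cys_window 1-based inclusive window in which the canonical
#'   FR1 cysteine is sought (first Cys wins).
#' @param cys_offset FR1 and FR3 end this many residues after their
#'   canonical cysteine.
#' @param trp_window FR2's opening tryptophan is sought within this many
#'   residues after the FR1/CDR1 junction.
#' @param fr2_length,fr3_length fixed framework lengths used to place the
#'   boundaries without an anchor of their own.
#' @param fr4_motif regular expression for the FR4 anchor; the
#'   C-terminal-most match wins.
#' @param min_length,max_length admissible full-sequence length range.
#' @return Named list of options.
#' @export
annotationConfig <- function(fr1_cys_window = c(16L, 35L), cys_offset = 3L,
                             trp_window = 20L, fr2_length = 17L,
                             fr3_length = 38L, fr4_motif = "WG.G",
                             min_length = 90L, max_length = 180L) {
  list(fr1_cys_window = as.integer(fr1_cys_window),
       cys_offset = as.integer(cys_offset),
       trp_window = as.integer(trp_window),
       fr2_length = as.integer(fr2_length),
       fr3_length = as.integer(fr3_length),
       fr4_motif = fr4_motif,
       min_length = as.integer(min_length),
       max_length = as.integer(max_length))
}

#' Reconstruct a full sequence from its seven regions
#'
#' Order-preserving concatenation FR1+CDR1+FR2+CDR2+FR3+CDR3+FR4. If any
#' region is absent or empty the reconstruction fails and `NA` is returned
#' as the failure signal, so the caller can route the record to annotation
#' or drop it.
#'
#' @param regions named character vector or list containing the seven
#'   region strings.
#' @return Single string, or `NA_character_` on failure.
#' @examples
#' reconstructFullSequence(c(FR1 = "QVQLV", CDR1 = "GRT", FR2 = "WFRQA",
#'   CDR2 = "ISS", FR3 = "RFTIS", CDR3 = "AKDY", FR4 = "WGQGT"))
#' @export
reconstructFullSequence <- function(regions) {
  r <- unlist(regions[REGIONS7])
  if (length(r) != 7L || anyNA(r) || any(!nzchar(r))) return(NA_character_)
  paste0(r, collapse = "")
}

# Locate all boundaries on one sequence with the anchor heuristic.
# Returns integer vector of 7 region start positions (1-based) plus the
# sequence end, or NULL on failure.
anchorBoundaries <- function(seq, config) {
  n <- nchar(seq)
  chars <- splitChars(seq)[[1]]
  # (a) FR1 ends cys_offset residues after the first Cys in the window
  win <- config$fr1_cys_window
  win_idx <- seq.int(win[1], min(win[2], n))
  c1 <- win_idx[which(chars[win_idx] == "C")[1]]
  if (is.na(c1)) return(NULL)
  fr1_end <- c1 + config$cys_offset            # last position of FR1
  # (b) FR2 starts at the first Trp after the FR1/CDR1 junction
  trp_idx <- seq.int(fr1_end + 1L, min(fr1_end + config$trp_window, n))
  w <- trp_idx[which(chars[trp_idx] == "W")[1]]
  if (is.na(w) || w <= fr1_end + 1L) return(NULL)  # CDR1 must be non-empty
  fr2_start <- w
  fr2_end <- fr2_start + config$fr2_length - 1L
  if (fr2_end >= n) return(NULL)
  # (e) FR4 starts at the C-terminal-most W-G-x-G match
  m <- gregexpr(config$fr4_motif, seq)[[1]]
  m <- m[m > fr2_end]
  if (length(m) == 0L || m[1] == -1L) return(NULL)
  fr4_start <- m[length(m)]
  # (d) FR3 ends cys_offset residues after its canonical cysteine. The
  # canonical Cys is the FIRST Cys compatible with the near-fixed FR3
  # length, i.e. at or beyond CDR2 start + (fr3_length - cys_offset - 1);
  # scanning forward keeps non-canonical cysteines inserted in CDR3 (or a
  # conserved FR2 cysteine) from being mistaken for the junction anchor.
  cdr2_start <- fr2_end + 1L
  c_min <- cdr2_start + config$fr3_length - config$cys_offset - 1L + 1L
  c_max <- fr4_start - config$cys_offset - 2L  # CDR3 must be non-empty
  if (c_min > c_max) return(NULL)
  cys_idx <- seq.int(c_min, c_max)
  c3 <- cys_idx[which(chars[cys_idx] == "C")[1]]
  if (is.na(c3)) return(NULL)
  fr3_end <- c3 + config$cys_offset
  fr3_start <- fr3_end - config$fr3_length + 1L
  if (fr3_start <= cdr2_start) return(NULL)    # CDR2 must be non-empty
  starts <- c(FR1 = 1L, CDR1 = fr1_end + 1L, FR2 = fr2_start,
              CDR2 = cdr2_start, FR3 = fr3_start, CDR3 = fr3_end + 1L,
              FR4 = fr4_start)
  if (is.unsorted(starts, strictly = TRUE)) return(NULL)
  starts
}

#' Delineate FR/CDR regions on a full sequence
#'
#' Uses externally supplied boundaries (e.g. from an IMGT/ANARCI-style
#' numbering run) when given; otherwise falls back to the deterministic
#' motif-anchored heuristic described in [annotationConfig()]. The
#' concatenation of the returned regions always equals the input sequence.
#'
#' @param full_sequence one amino-acid string (canonical residues only,
#'   length within the configured range).
#' @param external_boundaries optional data.frame with columns `region`,
#'   `start`, `end` (1-based inclusive) covering the whole sequence
#'   contiguously; takes precedence over the heuristic.
#' @param config see [annotationConfig()].
#' @return A list with elements `regions` (named character vector of the
#'   seven region strings), `scheme` (`"imgt-external"` or
#'   `"anchor-heuristic"`), and `boundaries` (data.frame region/start/end,
#'   1-based inclusive); or `NULL` when no anchors are found and no
#'   external boundaries are given (annotation failure).
#' @export
annotateRegions <- function(full_sequence, external_boundaries = NULL,
                            config = annotationConfig()) {
  stopifnot(length(full_sequence) == 1L)
  if (is.na(full_sequence)) return(NULL)
  n <- nchar(full_sequence)
  if (!is.null(external_boundaries)) {
    b <- external_boundaries
    stopifnot(all(c("region", "start", "end") %in% names(b)))
    b <- b[match(REGIONS7, b$region), , drop = FALSE]
    if (anyNA(b$start) || b$start[1] != 1L || b$end[7] != n ||
        any(b$start[-1] != b$end[-7] + 1L))
      stop("external boundaries must cover the sequence contiguously")
    regions <- substring(full_sequence, b$start, b$end)
    names(regions) <- REGIONS7
    return(list(regions = regions, scheme = "imgt-external",
                boundaries = data.frame(region = REGIONS7, start = b$start,
                                        end = b$end,
                                        stringsAsFactors = FALSE)))
  }
  if (n < config$min_length || n > config$max_length) return(NULL)
  if (!isCanonicalSequence(full_sequence)) return(NULL)
  starts <- anchorBoundaries(full_sequence, config)
  if (is.null(starts)) return(NULL)
  ends <- c(starts[-1] - 1L, n)
  regions <- substring(full_sequence, starts, ends)
  names(regions) <- REGIONS7
  list(regions = regions, scheme = "anchor-heuristic",
       boundaries = data.frame(region = REGIONS7, start = unname(starts),
                               end = unname(ends), stringsAsFactors = FALSE))
}

#' Reconstruct missing full sequences from complete region sets
#'
#' Dataset-level pass over case (i) of [annotateDataset()] only: records
#' with all seven regions but no full sequence get the concatenation and
#' the `reconstructed_sequence` flag; records whose deposited sequence
#' disagrees with their deposited regions are reset to the concatenation
#' (region-keyed analyses win) and flagged `sequence_region_mismatch`.
#' Nothing is removed, so this can run before duplicate removal (which is
#' keyed on the full-length sequence).
#'
#' @param set an [SdAbSet-class].
#' @return The set with full sequences completed; funnel step
#'   `"reconstruction"` (0 removed).
#' @export
reconstructDataset <- function(set) {
  rec <- records(set)
  for (i in seq_len(nrow(rec))) {
    complete <- all(isPresent(unlist(rec[i, REGIONS7])))
    if (!complete) next
    concat <- reconstructFullSequence(unlist(rec[i, REGIONS7]))
    if (!isPresent(rec$full_sequence[i])) {
      rec$full_sequence[i] <- concat
      rec$flags <- addFlag(rec$flags, i, "reconstructed_sequence")
      if (!isPresent(rec$scheme[i])) rec$scheme[i] <- "as-deposited"
    } else if (!identical(concat, rec$full_sequence[i])) {
      rec$full_sequence[i] <- concat
      rec$flags <- addFlag(rec$flags, i, "sequence_region_mismatch")
    }
  }
  replaceRecords(set, rec, step = "reconstruction", removed = 0L)
}

#' Complete a dataset: reconstruct sequences and annotate regions
#'
#' Three cases per record: (i) regions complete but no full sequence -> the
#' sequence is reconstructed by concatenation and the record flagged
#' `reconstructed_sequence`; (ii) full sequence but incomplete regions ->
#' regions are derived, from `external_boundaries` when available for that
#' record, else by the fallback heuristic (flag `fallback_annotation`);
#' records for which annotation fails are removed and funnel-logged under
#' step `"annotation"`; (iii) both deposited and disagreeing -> deposited
#' regions win, the full sequence is reset to their concatenation and the
#' record flagged `sequence_region_mismatch` (downstream analyses are
#' region-keyed).
#'
#' @param set an [SdAbSet-class].
#' @param external_boundaries optional data.frame with columns `record_id`,
#'   `region`, `start`, `end` (1-based inclusive).
#' @param config see [annotationConfig()].
#' @return The completed [SdAbSet-class].
#' @export
annotateDataset <- function(set, external_boundaries = NULL,
                            config = annotationConfig()) {
  rec <- records(set)
  n <- nrow(rec)
  failed <- logical(n)
  if (n > 0L) for (i in seq_len(n)) {
    has_seq <- isPresent(rec$full_sequence[i])
    complete <- all(isPresent(unlist(rec[i, REGIONS7])))
    if (complete && !has_seq) {
      rec$full_sequence[i] <- reconstructFullSequence(unlist(rec[i, REGIONS7]))
      rec$flags <- addFlag(rec$flags, i, "reconstructed_sequence")
      if (!isPresent(rec$scheme[i])) rec$scheme[i] <- "as-deposited"
    } else if (has_seq && !complete) {
      ext <- NULL
      if (!is.null(external_boundaries)) {
        ext <- external_boundaries[external_boundaries$record_id ==
                                     rec$record_id[i], , drop = FALSE]
        if (nrow(ext) != 7L) ext <- NULL
      }
      ann <- annotateRegions(rec$full_sequence[i], ext, config)
      if (is.null(ann)) {
        failed[i] <- TRUE
      } else {
        rec[i, REGIONS7] <- as.list(ann$regions)
        rec$scheme[i] <- ann$scheme
        if (ann$scheme == "anchor-heuristic")
          rec$flags <- addFlag(rec$flags, i, "fallback_annotation")
      }
    } else if (has_seq && complete) {
      concat <- reconstructFullSequence(unlist(rec[i, REGIONS7]))
      if (!identical(concat, rec$full_sequence[i])) {
        rec$full_sequence[i] <- concat
        rec$flags <- addFlag(rec$flags, i, "sequence_region_mismatch")
      }
      if (!isPresent(rec$scheme[i])) rec$scheme[i] <- "as-deposited"
    } else {
      failed[i] <- TRUE
    }
  }
  vd <- verdictRows(rec$record_id[failed], "annotation_failure",
                    "no anchors found and no external boundaries")
  replaceRecords(set, rec[!failed, , drop = FALSE], step = "annotation",
                 removed = sum(failed), new_verdicts = vd)
}

#' Validate internal consistency of an annotated record
#'
#' Report-only checks: the concatenated regions must equal the full
#' sequence; region lengths must fall in empirically sane ranges
#' (FR1 15-35, FR2 10-25, FR3 25-50, FR4 5-15, CDR1 3-20, CDR2 3-20,
#' CDR3 1-40 residues); FR1 and FR3 must contain the canonical cysteines.
#'
#' @param record a one-row data.frame (or single-row subset of
#'   `records(set)`) carrying a full sequence and all seven regions.
#' @return data.frame with columns `check`, `status` (`"pass"`/`"warn"`/
#'   `"fail"`), `detail`.
#' @export
validateRegionConsistency <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  regions <- unlist(record[1, REGIONS7])
  out <- list()
  concat <- reconstructFullSequence(regions)
  out[["concatenation"]] <- if (identical(concat, record$full_sequence[1]))
    c("pass", "regions concatenate to full_sequence")
  else c("fail", "concatenated regions differ from full_sequence")
  bounds <- list(FR1 = c(15, 35), CDR1 = c(3, 20), FR2 = c(10, 25),
                 CDR2 = c(3, 20), FR3 = c(25, 50), CDR3 = c(1, 40),
                 FR4 = c(5, 15))
  for (r in REGIONS7) {
    len <- if (is.na(regions[r])) 0L else nchar(regions[r])
    b <- bounds[[r]]
    out[[paste0("length_", r)]] <- if (len >= b[1] && len <= b[2])
      c("pass", sprintf("%s length %d within [%d, %d]", r, len, b[1], b[2]))
    else c("warn", sprintf("%s length %d outside [%d, %d]", r, len, b[1], b[2]))
  }
  for (r in c("FR1", "FR3")) {
    has_c <- !is.na(regions[r]) && grepl("C", regions[r], fixed = TRUE)
    out[[paste0("canonical_cys_", r)]] <- if (has_c)
      c("pass", paste("canonical cysteine present in", r))
    else c("warn", paste("no cysteine in", r))
  }
  data.frame(check = names(out),
             status = vapply(out, `[`, character(1), 1L),
             detail = vapply(out, `[`, character(1), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}
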