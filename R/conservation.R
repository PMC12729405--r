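# Region-specific rectangular alignments, per-column consensus,
# consensus frequency and Shannon entropy.

#' Build a gap-padded rectangular alignment for one region
#'
#' Each region is analyzed independently: no multiple sequence alignment
#' is performed (conventional MSAs introduce artifacts in hypervariable
#' loops). Region strings of one cohort are padded with `"-"` to the
#' length of the longest member; any non-canonical residue that survived
#' upstream QC is masked to `"-"` at this stage. Padding is right-sided by
#' default, keeping the N-terminal residue of every member in column 1.
#'
#' @param set an [SdAbSet-class] (curated).
#' @param region one of [regionNames()].
#' @param cohort a species label or `"all"`.
#' @param pad `"right"` (default), `"left"` or `"center"`.
#' @return A [RegionAlignment-class]; an empty cohort yields an alignment
#'   with zero rows and width 0.
#' @export
buildRegionAlignment <- function(set, region, cohort = "all",
                                 pad = c("right", "left", "center")) {
  pad <- match.arg(pad)
  stopifnot(region %in% REGIONS7)
  rec <- records(set)
  if (cohort != "all") rec <- rec[!is.na(rec$species) &
                                    rec$species == cohort, , drop = FALSE]
  s <- rec[[region]]
  keep <- isPresent(s)
  s <- s[keep]
  ids <- rec$record_id[keep]
  if (length(s) == 0L)
    return(new("RegionAlignment", region = region, cohort = cohort,
               sequences = character(0), ids = character(0), width = 0L))
  s <- toupper(s)
  s <- gsub(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"),
            GAP_CHAR, s)
  width <- max(nchar(s))
  npad <- width - nchar(s)
  padded <- switch(pad,
    right = paste0(s, strrep(GAP_CHAR, npad)),
    left = paste0(strrep(GAP_CHAR, npad), s),
    center = paste0(strrep(GAP_CHAR, npad %/% 2L), s,
                    strrep(GAP_CHAR, npad - npad %/% 2L)))
  new("RegionAlignment", region = region, cohort = cohort,
      sequences = padded, ids = ids, width = as.integer(width))
}

#' Per-column consensus, consensus frequency and Shannon entropy
#'
#' For column j let n(a,j) be the count of residue a excluding gaps and
#' N(j) their sum. The consensus is the residue of maximum count (ties
#' broken alphabetically), the consensus frequency is max_a n(a,j) / N(j),
#' and the Shannon entropy is H(j) = -sum_a p log2 p over residues with
#' n > 0, expressed in bits, ranging from 0 (perfect conservation) to
#' log2 20 ~ 4.32 (maximal diversity). All-gap columns report N = 0, a
#' `"-"` consensus and missing frequency/entropy.
#'
#' @param alignment a [RegionAlignment-class].
#' @param positions 1-based column positions, or `NULL` for all columns.
#' @return data.frame with one row per column: `position`, `n`,
#'   `consensus`, `consensus_frequency`, `entropy`, `coverage`.
#' @examples
#' s <- SdAbSet(data.frame(record_id = c("a", "b", "c"),
#'                         species = "Lama glama", CDR3 = c("AA", "AA", "CA")))
#' aln <- buildRegionAlignment(s, "CDR3")
#' columnStats(aln)
#' @export
columnStats <- function(alignment, positions = NULL) {
  stopifnot(is(alignment, "RegionAlignment"))
  w <- alignment@width
  if (is.null(positions)) positions <- seq_len(w)
  if (length(positions) > 0L && (min(positions) < 1L || max(positions) > w))
    stop("column position out of range [1, ", w, "]")
  m <- as.matrix(alignment)
  nrows <- nrow(m)
  out <- data.frame(position = integer(0), n = integer(0),
                    consensus = character(0),
                    consensus_frequency = double(0), entropy = double(0),
                    coverage = double(0), stringsAsFactors = FALSE)
  if (length(positions) == 0L) return(out)
  idx <- matrix(match(m[, positions, drop = FALSE], AA_ALPHABET20),
                nrow = nrows)
  res <- lapply(seq_along(positions), function(k) {
    counts <- tabulate(idx[, k], nbins = 20L)
    N <- sum(counts)
    if (N == 0L)
      return(list(N = 0L, consensus = GAP_CHAR, freq = NA_real_,
                  H = NA_real_))
    p <- counts[counts > 0L] / N
    list(N = N, consensus = AA_ALPHABET20[which.max(counts)],
         freq = max(counts) / N, H = -sum(p * log2(p)))
  })
  data.frame(position = as.integer(positions),
             n = vapply(res, function(r) as.integer(r$N), integer(1)),
             consensus = vapply(res, function(r) r$consensus, character(1)),
             consensus_frequency = vapply(res, function(r) r$freq, double(1)),
             entropy = vapply(res, function(r) r$H, double(1)),
             coverage = vapply(res, function(r) r$N / nrows, double(1)),
             stringsAsFactors = FALSE)
}

#' Column statistics for every region and cohort
#'
#' Runs [buildRegionAlignment()] + [columnStats()] for each requested
#' region, globally (`cohort = "all"`) and, when stratified, for every
#' species present in the dataset. The long-format result feeds both the
#' per-position heatmap layout (rows = cohorts, columns = positions) and
#' the per-region summaries.
#'
#' @param set an [SdAbSet-class].
#' @param regions character vector of region names (default all seven).
#' @param stratify_by_species also profile each species separately?
#' @param pad see [buildRegionAlignment()].
#' @return data.frame: `cohort`, `region`, `position`, `n`, `consensus`,
#'   `consensus_frequency`, `entropy`, `coverage`.
#' @export
regionProfile <- function(set, regions = regionNames(),
                          stratify_by_species = TRUE, pad = "right") {
  rec <- records(set)
  cohorts <- "all"
  if (stratify_by_species)
    cohorts <- c("all", SPECIES4[SPECIES4 %in% unique(rec$species)])
  out <- list()
  for (cohort in cohorts) for (region in regions) {
    aln <- buildRegionAlignment(set, region, cohort, pad = pad)
    cs <- columnStats(aln)
    if (nrow(cs) > 0L)
      out[[length(out) + 1L]] <- cbind(
        data.frame(cohort = cohort, region = region,
                   stringsAsFactors = FALSE), cs)
  }
  if (length(out) == 0L)
    return(data.frame(cohort = character(0), region = character(0),
                      position = integer(0), n = integer(0),
                      consensus = character(0),
                      consensus_frequency = double(0), entropy = double(0),
                      coverage = double(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-region scalar summaries of a conservation profile
#'
#' Mean consensus frequency and mean entropy per (cohort, region) over
#' columns with at least one non-gap residue, optionally weighting each
#' column by its coverage so sparsely populated padding columns count
#' less.
#'
#' @param profile output of [regionProfile()].
#' @param weight_by_coverage logical.
#' @return data.frame: `cohort`, `region`, `n_columns`,
#'   `mean_conservation`, `mean_entropy`.
#' @export
meanRegionSummary <- function(profile, weight_by_coverage = FALSE) {
  stopifnot(nrow(profile) > 0L)
  keep <- profile$n >= 1L
  p <- profile[keep, , drop = FALSE]
  key <- interaction(p$cohort, p$region, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(p)), key), function(i) {
    w <- if (weight_by_coverage) p$coverage[i] else rep(1, length(i))
    data.frame(cohort = p$cohort[i[1]], region = p$region[i[1]],
               n_columns = length(i),
               mean_conservation =
                 sum(w * p$consensus_frequency[i]) / sum(w),
               mean_entropy = sum(w * p$entropy[i]) / sum(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$cohort, c("all", SPECIES4)),
            match(out$region, REGIONS7)), , drop = FALSE]
}

#' Wide heatmap matrix for one region statistic
#'
#' Pivot of [regionProfile()] output for one region: rows are cohorts,
#' columns are 1-based positions, values are the chosen statistic.
#'
#' @param profile output of [regionProfile()].
#' @param region one region name.
#' @param stat `"consensus_frequency"` or `"entropy"`.
#' @return Numeric matrix.
#' @export
profileMatrix <- function(profile, region,
                          stat = c("consensus_frequency", "entropy")) {
  stat <- match.arg(stat)
  p <- profile[profile$region == region, , drop = FALSE]
  cohorts <- unique(p$cohort)
  width <- max(p$position)
  m <- matrix(NA_real_, nrow = length(cohorts), ncol = width,
              dimnames = list(cohorts, seq_len(width)))
  for (i in seq_len(nrow(p))) m[p$cohort[i], p$position[i]] <- p[[stat]][i]
  m
}
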