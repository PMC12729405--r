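# Amino-acid composition, Lys/Cys regional distributions, region-length
# statistics and the non-parametric group-comparison battery.

cohortRecords <- function(set, cohort) {
  rec <- records(set)
  if (cohort != "all")
    rec <- rec[!is.na(rec$species) & rec$species == cohort, , drop = FALSE]
  rec
}

scopeStrings <- function(rec, scope) {
  s <- if (scope == "full") rec$full_sequence else rec[[scope]]
  s[isPresent(s)]
}

countResidues <- function(strings) {
  if (length(strings) == 0L)
    return(structure(integer(20), names = AA_ALPHABET20))
  chars <- unlist(splitChars(strings), use.names = FALSE)
  counts <- tabulate(match(chars, AA_ALPHABET20), nbins = 20L)
  structure(as.integer(counts), names = AA_ALPHABET20)
}

#' Relative amino-acid frequencies
#'
#' Pooled frequencies f(a) = sum_i n(a,i) / sum_i L_i over the chosen
#' scope: residue counts are aggregated over all sequences and normalized
#' by the total residue count (length-weighted pooling, not an average of
#' per-sequence frequencies). Reported as fractions; multiply by 100 for
#' the percentage convention used in tabular outputs.
#'
#' @param set an [SdAbSet-class] (curated/deduplicated).
#' @param scope `"full"` or one of [regionNames()].
#' @param cohort species label or `"all"`.
#' @return data.frame with 20 rows: `residue`, `count`, `frequency`;
#'   attributes `n_total` (total residues) and `n_sequences`. Empty scopes
#'   yield zero counts and `NaN`-free zero frequencies.
#' @examples
#' s <- SdAbSet(data.frame(record_id = c("a", "b"),
#'                         full_sequence = c("GG", "SSSS")))
#' aaFrequency(s)  # f(G) = 2/6, f(S) = 4/6
#' @export
aaFrequency <- function(set, scope = "full", cohort = "all") {
  stopifnot(scope %in% c("full", REGIONS7))
  strings <- scopeStrings(cohortRecords(set, cohort), scope)
  counts <- countResidues(strings)
  n_total <- sum(counts)
  freq <- if (n_total > 0L) counts / n_total else rep(0, 20L)
  out <- data.frame(residue = AA_ALPHABET20, count = unname(counts),
                    frequency = unname(freq), stringsAsFactors = FALSE)
  attr(out, "n_total") <- n_total
  attr(out, "n_sequences") <- length(strings)
  attr(out, "scope") <- scope
  attr(out, "cohort") <- cohort
  out
}

#' Regional distribution of one residue across cohorts
#'
#' For every (cohort, region) three complementary metrics for a residue of
#' interest (typically cysteine or lysine, the bioconjugation handles):
#' the relative frequency of the residue among the region's residues, the
#' mean count per sequence, and the fraction of sequences carrying at
#' least one occurrence (presence).
#'
#' @param set an [SdAbSet-class].
#' @param residue one canonical one-letter code.
#' @param cohorts character vector; default `"all"` plus every species
#'   present.
#' @return data.frame: `cohort`, `region`, `n_sequences`, `frequency`,
#'   `mean_count`, `presence`.
#' @export
residueRegionDistribution <- function(set, residue, cohorts = NULL) {
  stopifnot(residue %in% AA_ALPHABET20)
  rec <- records(set)
  if (is.null(cohorts))
    cohorts <- c("all", SPECIES4[SPECIES4 %in% unique(rec$species)])
  rows <- list()
  for (cohort in cohorts) for (region in REGIONS7) {
    strings <- scopeStrings(cohortRecords(set, cohort), region)
    nseq <- length(strings)
    if (nseq == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cohort, region = region, n_sequences = 0L,
        frequency = 0, mean_count = 0, presence = 0,
        stringsAsFactors = FALSE)
      next
    }
    per_seq <- vapply(strsplit(strings, "", fixed = TRUE),
                      function(ch) sum(ch == residue), integer(1))
    total_res <- sum(nchar(strings))
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = cohort, region = region, n_sequences = nseq,
      frequency = sum(per_seq) / total_res,
      mean_count = mean(per_seq),
      presence = mean(per_seq >= 1L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Molecular weight of amino-acid sequences
#'
#' Sum of average (not monoisotopic) residue masses plus one water mass
#' (18.01528 Da). A typical 124-residue VHH comes out near 13.6 kDa,
#' i.e. roughly 110 Da per residue.
#'
#' @param sequence character vector of canonical sequences.
#' @param unit `"kDa"` (default) or `"Da"`.
#' @return Numeric vector.
#' @export
molecularWeight <- function(sequence, unit = c("kDa", "Da")) {
  unit <- match.arg(unit)
  mw <- vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(RESIDUE_MASS_DA[chars]) + WATER_MASS_DA
  }, double(1), USE.NAMES = FALSE)
  if (unit == "kDa") mw / 1000 else mw
}

#' Length statistics per cohort and scope
#'
#' Count, mean, sample standard deviation (n-1 denominator), relative
#' standard deviation (RSD = 100 * sd / mean, in percent), minimum and
#' maximum of sequence or region lengths. For `scope = "full"` the
#' molecular-weight mean and SD in kDa are included. Cohorts with no
#' records are omitted.
#'
#' @param set an [SdAbSet-class].
#' @param scope `"full"` or one of [regionNames()].
#' @param cohorts character vector; default `"all"` plus every species
#'   present.
#' @return data.frame: `cohort`, `scope`, `n`, `mean`, `sd`, `rsd`,
#'   `min`, `max` and, for full sequences, `mw_mean_kda`, `mw_sd_kda`.
#' @export
lengthStats <- function(set, scope = "full", cohorts = NULL) {
  stopifnot(scope %in% c("full", REGIONS7))
  rec <- records(set)
  if (is.null(cohorts))
    cohorts <- c("all", SPECIES4[SPECIES4 %in% unique(rec$species)])
  rows <- list()
  for (cohort in cohorts) {
    strings <- scopeStrings(cohortRecords(set, cohort), scope)
    n <- length(strings)
    if (n == 0L) next
    len <- nchar(strings)
    m <- mean(len)
    s <- stats::sd(len)
    if (n == 1L) s <- 0
    row <- data.frame(cohort = cohort, scope = scope, n = n, mean = m,
                      sd = s, rsd = if (m > 0) 100 * s / m else 0,
                      min = min(len), max = max(len),
                      stringsAsFactors = FALSE)
    if (scope == "full") {
      mw <- molecularWeight(strings, unit = "kDa")
      row$mw_mean_kda <- mean(mw)
      row$mw_sd_kda <- if (n > 1L) stats::sd(mw) else 0
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) return(invisible(NULL))
  do.call(rbind, rows)
}

#' Non-parametric comparison of a scalar across groups
#'
#' The full battery: Shapiro-Wilk normality per eligible group, a
#' Kruskal-Wallis omnibus test, and all pairwise two-sided Mann-Whitney
#' (Wilcoxon rank-sum) tests with Holm adjustment across the pairs.
#' Groups below `min_n` are excluded from testing but reported in the
#' `excluded` slot, never silently dropped; with fewer than two eligible
#' groups the comparison is skipped with a reason. Significance tiers are
#' labelled at 0.05 (*), 0.01 (**) and 0.001 (***).
#'
#' @param values numeric vector of the measured quantity.
#' @param groups group labels, parallel to `values`.
#' @param min_n minimum group size for inclusion (default 50, small
#'   single-source cohorts are not informative).
#' @param variable description used in reports.
#' @return A [GroupComparison-class].
#' @export
compareGroups <- function(values, groups, min_n = 50L, variable = "value") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  tab <- table(groups)
  eligible <- names(tab)[tab >= min_n]
  small <- names(tab)[tab < min_n]
  excluded <- data.frame(group = small, n = as.integer(tab[small]),
                         reason = rep(sprintf("n below min_n = %d", min_n),
                                      length(small)),
                         stringsAsFactors = FALSE)
  norm <- data.frame(group = character(0), W = double(0), p = double(0),
                     stringsAsFactors = FALSE)
  pairwise <- data.frame(group1 = character(0), group2 = character(0),
                         statistic = double(0), p = double(0),
                         p_holm = double(0), signif = character(0),
                         stringsAsFactors = FALSE)
  if (length(eligible) < 2L)
    return(new("GroupComparison", variable = variable,
               groups = character(0),
               group_n = structure(integer(0), names = character(0)),
               normality = norm,
               omnibus = list(method = "skipped",
                              reason = "fewer than 2 eligible groups",
                              statistic = NA_real_, df = NA_integer_,
                              p = NA_real_),
               pairwise = pairwise, excluded = excluded))
  sel <- groups %in% eligible
  v <- values[sel]
  g <- factor(groups[sel], levels = eligible)
  norm <- do.call(rbind, lapply(eligible, function(grp) {
    x <- v[g == grp]
    res <- tryCatch(stats::shapiro.test(x[seq_len(min(length(x), 5000L))]),
                    error = function(e) NULL)
    data.frame(group = grp,
               W = if (is.null(res)) NA_real_ else unname(res$statistic),
               p = if (is.null(res)) NA_real_ else res$p.value,
               stringsAsFactors = FALSE)
  }))
  kw <- stats::kruskal.test(v, g)
  omnibus <- list(method = "Kruskal-Wallis",
                  statistic = unname(kw$statistic),
                  df = unname(kw$parameter), p = kw$p.value)
  pairs <- utils::combn(eligible, 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    wt <- stats::wilcox.test(v[g == a], v[g == b], exact = FALSE,
                             correct = TRUE)
    data.frame(group1 = a, group2 = b, statistic = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, pw)
  pairwise$p_holm <- stats::p.adjust(pairwise$p, method = "holm")
  pairwise$signif <- significanceStars(pairwise$p_holm)
  new("GroupComparison", variable = variable, groups = eligible,
      group_n = structure(as.integer(tab[eligible]), names = eligible),
      normality = norm, omnibus = omnibus, pairwise = pairwise,
      excluded = excluded)
}

#' Compare a region's length across species
#'
#' Convenience wrapper: extracts per-record region (or full-sequence)
#' lengths and runs [compareGroups()] across species cohorts.
#'
#' @param set an [SdAbSet-class].
#' @param region one of [regionNames()] or `"full"`.
#' @param min_n see [compareGroups()].
#' @return A [GroupComparison-class].
#' @export
compareRegionLengths <- function(set, region, min_n = 50L) {
  stopifnot(region %in% c("full", REGIONS7))
  rec <- records(set)
  s <- if (region == "full") rec$full_sequence else rec[[region]]
  keep <- isPresent(s) & !is.na(rec$species)
  compareGroups(nchar(s[keep]), rec$species[keep], min_n = min_n,
                variable = paste(if (region == "full") "sequence" else region,
                                 "length (aa)"))
}
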