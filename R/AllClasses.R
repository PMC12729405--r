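# S4 classes for curated sdAb datasets, region alignments, generator
# profiles and group comparisons.

#' SdAbSet: a curated collection of single-domain antibody records
#'
#' The central container of the package. Holds one row per sdAb record in a
#' canonical schema (identifier, source tag, species, full sequence, the
#' seven FR/CDR region strings, optional metadata, provenance flags), the
#' step-by-step eligibility funnel, per-rule filter verdicts, and per-source
#' ingestion counts.
#'
#' @slot records data.frame in the canonical column order (see
#'   [canonicalColumns()]); extra metadata columns from a source are carried
#'   through verbatim after the canonical block.
#' @slot funnel data.frame with columns `step`, `n_in`, `n_removed`;
#'   consecutive rows chain: the records entering step k+1 equal the records
#'   entering step k minus the records step k removed.
#' @slot verdicts data.frame with columns `record_id`, `rule`, `detail`
#'   recording why each removed record was removed.
#' @slot sourceCounts data.frame with columns `source_db`, `n` giving
#'   per-source ingestion counts (filled by [mergeSources()]).
#'
#' @seealso [SdAbSet()] for construction, [records()], [funnel()],
#'   [verdicts()] for access.
#' @export
setClass("SdAbSet",
  representation(records = "data.frame", funnel = "data.frame",
                 verdicts = "data.frame", sourceCounts = "data.frame"))

setValidity("SdAbSet", function(object) {
  msgs <- character(0)
  rec <- object@records
  missing_cols <- setdiff(CANONICAL_COLUMNS, names(rec))
  if (length(missing_cols) > 0L)
    msgs <- c(msgs, paste("records lacks canonical columns:",
                          paste(missing_cols, collapse = ", ")))
  fn <- object@funnel
  if (!all(c("step", "n_in", "n_removed") %in% names(fn))) {
    msgs <- c(msgs, "funnel must have columns step, n_in, n_removed")
  } else if (nrow(fn) > 1L) {
    lhs <- fn$n_in[-1L]
    rhs <- fn$n_in[-nrow(fn)] - fn$n_removed[-nrow(fn)]
    if (!all(lhs == rhs))
      msgs <- c(msgs, "funnel rows do not chain (n_in[k+1] != n_in[k] - n_removed[k])")
  }
  if (!all(c("record_id", "rule", "detail") %in% names(object@verdicts)))
    msgs <- c(msgs, "verdicts must have columns record_id, rule, detail")
  if (length(msgs)) msgs else TRUE
})

#' Canonical column order of a curated record table
#'
#' @return Character vector of the canonical `SdAbSet` record columns.
#' @export
canonicalColumns <- function() CANONICAL_COLUMNS

#' Construct an SdAbSet
#'
#' Coerces a record table into the canonical schema: canonical columns are
#' created (as `NA`) when absent, placed first in canonical order, and all
#' sequence-bearing fields are normalized so that empty strings and
#' placeholder tokens (`"NA"`, `"N/A"`, `"-"`) become `NA` rather than
#' masquerading as values.
#'
#' @param records data.frame with at least a `record_id` column.
#' @param funnel optional funnel data.frame; defaults to a single
#'   `"ingest"` accounting row.
#' @param verdicts optional verdict data.frame.
#' @param sourceCounts optional per-source count data.frame.
#' @return An [SdAbSet-class] object.
#' @examples
#' s <- SdAbSet(data.frame(record_id = "r1", species = "Lama glama",
#'                         full_sequence = "QVQLVESG"))
#' nRecords(s)
#' @export
SdAbSet <- function(records, funnel = NULL, verdicts = NULL,
                    sourceCounts = NULL) {
  stopifnot(is.data.frame(records))
  if (!"record_id" %in% names(records))
    stop("records must contain a 'record_id' column")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in CANONICAL_COLUMNS) {
    if (!col %in% names(records)) {
      records[[col]] <- rep(if (col == "flags") "" else NA_character_,
                            nrow(records))
    } else {
      records[[col]] <- as.character(records[[col]])
    }
  }
  norm_cols <- setdiff(CANONICAL_COLUMNS, "flags")
  for (col in norm_cols) records[[col]] <- normalizeMissing(records[[col]])
  records$flags[is.na(records$flags)] <- ""
  extra <- setdiff(names(records), CANONICAL_COLUMNS)
  records <- records[, c(CANONICAL_COLUMNS, extra), drop = FALSE]
  rownames(records) <- NULL
  if (is.null(funnel)) funnel <- funnelRow("ingest", nrow(records), 0L)
  if (is.null(verdicts)) verdicts <- emptyVerdicts()
  if (is.null(sourceCounts))
    sourceCounts <- data.frame(source_db = character(0), n = integer(0),
                               stringsAsFactors = FALSE)
  new("SdAbSet", records = records, funnel = funnel, verdicts = verdicts,
      sourceCounts = sourceCounts)
}

setMethod("show", "SdAbSet", function(object) {
  rec <- object@records
  cat("SdAbSet with", nrow(rec), "records\n")
  if (nrow(rec) > 0L) {
    tab <- table(factor(rec$species,
                        levels = c(SPECIES4, AMBIGUOUS_SPECIES)))
    tab <- tab[tab > 0L]
    if (length(tab))
      cat("  species:",
          paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                collapse = ", "), "\n")
    src <- table(rec$source_db, useNA = "no")
    if (length(src))
      cat("  sources:",
          paste(sprintf("%s (%d)", names(src), as.integer(src)),
                collapse = ", "), "\n")
  }
  cat("  funnel steps:", nrow(object@funnel),
      "| verdicts:", nrow(object@verdicts), "\n")
  invisible(NULL)
})

#' RegionAlignment: a rectangular gap-padded region alignment
#'
#' One FR or CDR region for one cohort, padded with `"-"` to the length of
#' the longest member so the block is rectangular. No residues are ever
#' inserted or reordered: each row with its gaps removed equals the
#' corresponding record's region string.
#'
#' @slot region one of the seven region names.
#' @slot cohort species label or `"all"`.
#' @slot sequences character vector of equal-length padded rows.
#' @slot ids record identifiers, parallel to `sequences`.
#' @slot width integer, the common row width.
#' @export
setClass("RegionAlignment",
  representation(region = "character", cohort = "character",
                 sequences = "character", ids = "character",
                 width = "integer"))

setValidity("RegionAlignment", function(object) {
  msgs <- character(0)
  if (length(object@region) != 1L || !object@region %in% REGIONS7)
    msgs <- c(msgs, "region must be one of the seven region names")
  if (length(object@sequences) != length(object@ids))
    msgs <- c(msgs, "sequences and ids must be parallel")
  if (length(object@sequences) > 0L &&
      !all(nchar(object@sequences) == object@width))
    msgs <- c(msgs, "all rows must have nchar equal to width")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RegionAlignment", function(object) {
  cat(sprintf("RegionAlignment: %s [%s], %d rows x %d columns\n",
              object@region, object@cohort, length(object@sequences),
              object@width))
  invisible(NULL)
})

#' @describeIn RegionAlignment-class number of rows.
#' @param x a `RegionAlignment`.
#' @export
setMethod("length", "RegionAlignment", function(x) length(x@sequences))

#' Character matrix view of a region alignment
#'
#' @param x a [RegionAlignment-class].
#' @param ... ignored.
#' @return Character matrix (rows = records, columns = positions), possibly
#'   with zero columns for an empty cohort.
#' @export
setMethod("as.matrix", "RegionAlignment", function(x, ...) {
  if (length(x@sequences) == 0L || x@width == 0L)
    return(matrix(character(0), nrow = length(x@sequences), ncol = x@width))
  m <- matrix(unlist(splitChars(x@sequences), use.names = FALSE),
              nrow = length(x@sequences), ncol = x@width, byrow = TRUE)
  rownames(m) <- x@ids
  m
})

#' SpeciesProfile: generative parameters for one species
#'
#' Bundles everything the repertoire generator needs for one camelid
#' species: CDR length laws (rounded normal with a floor of 3), fixed
#' framework consensus strings, the per-position framework substitution
#' rate, residue sampling weights for CDR positions and for substitution
#' replacements, lysine enrichment multipliers for FR2/FR3 replacements,
#' and per-region probabilities of carrying one non-canonical cysteine.
#'
#' @slot species one of the four accepted species labels.
#' @slot cdr_length_mean,cdr_length_sd named numeric (CDR1, CDR2, CDR3).
#' @slot fr_consensus named character (FR1..FR4) consensus strings; their
#'   lengths fix the framework region lengths.
#' @slot substitution_rate per-position probability that a non-anchor
#'   framework position deviates from consensus.
#' @slot cdr_weights named residue sampling weights for CDR positions.
#' @slot background_weights named residue weights for substitution
#'   replacements (consensus residue excluded at draw time).
#' @slot fr2_lysine_weight,fr3_lysine_weight multiplicative enrichment of K
#'   in the FR2/FR3 replacement distributions.
#' @slot noncanonical_cys_prob named numeric (CDR1, CDR3, FR2): probability
#'   of placing one extra cysteine in that region.
#' @slot fr2_cys_position 1-based position within FR2 where a
#'   non-canonical FR2 cysteine sits (a conserved position in real VHHs).
#' @slot protected_positions list (FR1..FR4) of 1-based positions never
#'   substituted: the canonical FR1/FR3 cysteines, the FR2 tryptophan and
#'   the FR4 W-G-x-G motif, i.e. the invariant residues of the Ig fold.
#' @export
setClass("SpeciesProfile",
  representation(species = "character",
                 cdr_length_mean = "numeric", cdr_length_sd = "numeric",
                 fr_consensus = "character", substitution_rate = "numeric",
                 cdr_weights = "numeric", background_weights = "numeric",
                 fr2_lysine_weight = "numeric", fr3_lysine_weight = "numeric",
                 noncanonical_cys_prob = "numeric",
                 fr2_cys_position = "integer",
                 protected_positions = "list"))

setValidity("SpeciesProfile", function(object) {
  msgs <- character(0)
  if (!object@species %in% SPECIES4)
    msgs <- c(msgs, "species must be one of the four accepted labels")
  for (nm in c("CDR1", "CDR2", "CDR3")) {
    if (is.na(object@cdr_length_mean[nm]) || is.na(object@cdr_length_sd[nm]))
      msgs <- c(msgs, paste("missing CDR length law for", nm))
  }
  if (!all(c("FR1", "FR2", "FR3", "FR4") %in% names(object@fr_consensus)))
    msgs <- c(msgs, "fr_consensus must name FR1..FR4")
  if (object@substitution_rate < 0 || object@substitution_rate > 1)
    msgs <- c(msgs, "substitution_rate must lie in [0,1]")
  p <- object@noncanonical_cys_prob
  if (!all(c("CDR1", "CDR3", "FR2") %in% names(p)) ||
      any(p < 0) || any(p > 1))
    msgs <- c(msgs, "noncanonical_cys_prob must name CDR1, CDR3, FR2 with values in [0,1]")
  if (any(object@cdr_weights < 0) || sum(object@cdr_weights) <= 0)
    msgs <- c(msgs, "cdr_weights must be non-negative and normalizable")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SpeciesProfile", function(object) {
  cat("SpeciesProfile:", object@species, "\n")
  cat(sprintf("  CDR length laws: CDR1 %.1f+/-%.1f, CDR2 %.1f+/-%.1f, CDR3 %.1f+/-%.1f\n",
              object@cdr_length_mean["CDR1"], object@cdr_length_sd["CDR1"],
              object@cdr_length_mean["CDR2"], object@cdr_length_sd["CDR2"],
              object@cdr_length_mean["CDR3"], object@cdr_length_sd["CDR3"]))
  cat(sprintf("  FR lengths: %s | substitution rate %.3f\n",
              paste(nchar(object@fr_consensus), collapse = "/"),
              object@substitution_rate))
  cat(sprintf("  non-canonical Cys prob: CDR1 %.2f, CDR3 %.2f, FR2 %.2f\n",
              object@noncanonical_cys_prob["CDR1"],
              object@noncanonical_cys_prob["CDR3"],
              object@noncanonical_cys_prob["FR2"]))
  invisible(NULL)
})

#' GroupComparison: the non-parametric group-comparison battery
#'
#' Result of comparing one scalar variable across species cohorts:
#' per-group Shapiro-Wilk normality checks, a Kruskal-Wallis omnibus test,
#' all pairwise Mann-Whitney tests with Holm adjustment, and the cohorts
#' excluded for small sample size (never silently dropped).
#'
#' @slot variable description of the compared quantity.
#' @slot groups eligible group labels.
#' @slot group_n named integer of eligible group sizes.
#' @slot normality data.frame: group, W, p.
#' @slot omnibus list: method, statistic, df, p.
#' @slot pairwise data.frame: group1, group2, statistic, p, p_holm, signif.
#' @slot excluded data.frame: group, n, reason.
#' @export
setClass("GroupComparison",
  representation(variable = "character", groups = "character",
                 group_n = "integer", normality = "data.frame",
                 omnibus = "list", pairwise = "data.frame",
                 excluded = "data.frame"))

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison:", object@variable, "\n")
  if (length(object@groups) >= 2L) {
    cat("  groups:",
        paste(sprintf("%s (n=%d)", object@groups,
                      object@group_n[object@groups]), collapse = ", "), "\n")
    cat(sprintf("  Kruskal-Wallis: chi-sq = %.3f, df = %d, p = %.3g\n",
                object@omnibus$statistic, object@omnibus$df,
                object@omnibus$p))
    pw <- object@pairwise
    for (i in seq_len(nrow(pw)))
      cat(sprintf("  %s vs %s: Mann-Whitney p = %.3g, Holm p = %.3g %s\n",
                  pw$group1[i], pw$group2[i], pw$p[i], pw$p_holm[i],
                  pw$signif[i]))
  } else {
    cat("  comparison skipped: fewer than 2 eligible groups\n")
  }
  if (nrow(object@excluded) > 0L)
    cat("  excluded:",
        paste(sprintf("%s (n=%d, %s)", object@excluded$group,
                      object@excluded$n, object@excluded$reason),
              collapse = "; "), "\n")
  invisible(NULL)
})
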