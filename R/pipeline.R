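# Orchestration: curate -> annotate -> filter -> analyze as one
# reproducible run with a serialized configuration and report bundle.

#' Pipeline run configuration
#'
#' Surfaces every threshold of the other modules in one place so a run is
#' fully pinned by its configuration; the effective configuration is
#' serialized verbatim into the output bundle.
#'
#' @param synonym_table see [harmonizeSpecies()].
#' @param filter see [filterConfig()].
#' @param annotation see [annotationConfig()].
#' @param min_n minimum cohort size for the statistical battery.
#' @param regions regions to analyze.
#' @param stratify_by_species stratify conservation/composition by species?
#' @param analyses run the analysis stage at all (curation-only bundles
#'   when `FALSE`)?
#' @return Named list.
#' @export
pipelineConfig <- function(synonym_table = defaultSynonymTable(),
                           filter = filterConfig(),
                           annotation = annotationConfig(),
                           min_n = 50L, regions = regionNames(),
                           stratify_by_species = TRUE, analyses = TRUE) {
  list(synonym_table = synonym_table, filter = filter,
       annotation = annotation, min_n = as.integer(min_n),
       regions = regions, stratify_by_species = isTRUE(stratify_by_species),
       analyses = isTRUE(analyses))
}

#' Write the curated dataset as CSV and FASTA
#'
#' @param set an [SdAbSet-class].
#' @param outdir output directory (created if needed).
#' @param prefix file name stem.
#' @return Invisibly, the paths written.
#' @export
writeCuratedOutputs <- function(set, outdir, prefix = "curated") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rec <- records(set)
  csv <- file.path(outdir, paste0(prefix, ".csv"))
  utils::write.csv(rec, csv, row.names = FALSE, na = "")
  fasta <- file.path(outdir, paste0(prefix, ".fasta"))
  keep <- isPresent(rec$full_sequence)
  aa <- Biostrings::AAStringSet(structure(
    rec$full_sequence[keep],
    names = paste(rec$record_id[keep], rec$species[keep],
                  rec$source_db[keep], sep = "|")))
  Biostrings::writeXStringSet(aa, fasta)
  invisible(c(csv = csv, fasta = fasta))
}

#' Write the funnel as JSON
#'
#' JSON list of `{step, in, removed}` entries shared by all modules.
#'
#' @param set an [SdAbSet-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeFunnelJson <- function(set, path) {
  fn <- funnel(set)
  entries <- lapply(seq_len(nrow(fn)), function(i)
    list(step = fn$step[i], `in` = fn$n_in[i], removed = fn$n_removed[i]))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full curation and analysis pipeline
#'
#' Stages, in order: merge the sources; harmonize species labels; enforce
#' the mandatory-field eligibility criteria; reconstruct full sequences
#' from complete region sets; apply the QC filter battery (canonical
#' alphabet, completeness, exact duplicates, artificial sequences);
#' annotate FR/CDR boundaries for records still missing regions; then run
#' the analyses (conservation/entropy profiles, per-region summaries,
#' amino-acid composition, Lys/Cys distributions, length statistics,
#' species comparisons of region lengths). Every removal anywhere in the
#' run is attributable in the funnel.
#'
#' @param sources a single [SdAbSet-class] or a list of them (as produced
#'   by [readSourceTable()] or [generateRepertoire()]).
#' @param outdir optional output directory for the report bundle:
#'   `curated.csv`/`curated.fasta`, `funnel.json`, `verdicts.tsv`,
#'   `conservation_profile.tsv`, `region_summary.tsv`, `composition.tsv`,
#'   `lysine_distribution.tsv`, `cysteine_distribution.tsv`,
#'   `length_stats.tsv`, `comparisons.tsv`, `run_config.json`.
#' @param config see [pipelineConfig()].
#' @param external_boundaries optional external numbering table passed to
#'   [annotateDataset()].
#' @return Invisibly, a list with the curated `set` and all analysis
#'   tables.
#' @export
runPipeline <- function(sources, outdir = NULL, config = pipelineConfig(),
                        external_boundaries = NULL) {
  if (is(sources, "SdAbSet")) sources <- list(sources)
  stopifnot(length(sources) >= 1L,
            all(vapply(sources, is, logical(1), "SdAbSet")))
  set <- mergeSources(sources)
  message("merged ", nRecords(set), " records from ", length(sources),
          " source(s)")
  set <- harmonizeSpeciesLabels(set, config$synonym_table)
  set <- enforceMandatoryFields(set)
  set <- reconstructDataset(set)
  set <- applyFilters(set, config$filter)
  set <- annotateDataset(set, external_boundaries = external_boundaries,
                         config = config$annotation)
  message("curated dataset: ", nRecords(set), " records")

  out <- list(set = set, census = summarizeCounts(set))
  if (config$analyses && nRecords(set) > 0L) {
    out$profile <- regionProfile(set, regions = config$regions,
                                 stratify_by_species =
                                   config$stratify_by_species)
    out$region_summary <- meanRegionSummary(out$profile)
    comp <- list()
    cohorts <- unique(out$profile$cohort)
    for (cohort in cohorts) {
      for (scope in c("full", config$regions)) {
        af <- aaFrequency(set, scope = scope, cohort = cohort)
        comp[[length(comp) + 1L]] <- data.frame(
          cohort = cohort, region = scope, residue = af$residue,
          frequency_percent = 100 * af$frequency,
          stringsAsFactors = FALSE)
      }
    }
    out$composition <- do.call(rbind, comp)
    out$lysine <- residueRegionDistribution(set, "K")
    out$cysteine <- residueRegionDistribution(set, "C")
    lens <- lapply(c("full", config$regions), function(scope)
      lengthStats(set, scope = scope))
    lens <- lens[!vapply(lens, is.null, logical(1))]
    lens <- lapply(lens, function(df) {
      for (col in c("mw_mean_kda", "mw_sd_kda"))
        if (!col %in% names(df)) df[[col]] <- NA_real_
      df
    })
    out$length_stats <- do.call(rbind, lens)
    cmp_rows <- list()
    for (region in c("full", "CDR1", "CDR2", "CDR3")) {
      gc <- compareRegionLengths(set, region, min_n = config$min_n)
      pw <- gc@pairwise
      if (nrow(pw) > 0L)
        cmp_rows[[length(cmp_rows) + 1L]] <- cbind(
          data.frame(variable = gc@variable, stringsAsFactors = FALSE), pw)
    }
    out$comparisons <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else
      NULL
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeCuratedOutputs(set, outdir)
    writeFunnelJson(set, file.path(outdir, "funnel.json"))
    utils::write.table(verdicts(set), file.path(outdir, "verdicts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tsv <- function(df, name) if (!is.null(df))
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    tsv(out$profile, "conservation_profile.tsv")
    tsv(out$region_summary, "region_summary.tsv")
    tsv(out$composition, "composition.tsv")
    tsv(out$lysine, "lysine_distribution.tsv")
    tsv(out$cysteine, "cysteine_distribution.tsv")
    tsv(out$length_stats, "length_stats.tsv")
    tsv(out$comparisons, "comparisons.tsv")
    cfg <- config
    cfg$synonym_table <- as.list(cfg$synonym_table)
    jsonlite::write_json(cfg, file.path(outdir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Census of a curated dataset
#'
#' Per-species and per-source record counts and proportions. Species with
#' zero records are emitted as zero rows, not omitted; per-species source
#' proportions are normalized within each species.
#'
#' @param set an [SdAbSet-class].
#' @return List of data.frames: `per_species`, `per_source`,
#'   `species_by_source`.
#' @export
summarizeCounts <- function(set) {
  rec <- records(set)
  sp <- factor(rec$species, levels = SPECIES4)
  per_species <- as.data.frame(table(species = sp),
                               stringsAsFactors = FALSE)
  names(per_species) <- c("species", "n")
  per_species$proportion <- if (nrow(rec) > 0L)
    per_species$n / nrow(rec) else 0
  per_source <- as.data.frame(table(source_db = rec$source_db),
                              stringsAsFactors = FALSE)
  names(per_source) <- c("source_db", "n")
  cross <- as.data.frame(table(species = sp, source_db = rec$source_db),
                         stringsAsFactors = FALSE)
  names(cross) <- c("species", "source_db", "n")
  totals <- tapply(cross$n, cross$species, sum)
  cross$proportion_of_species <- ifelse(
    totals[cross$species] > 0, cross$n / totals[cross$species], 0)
  list(per_species = per_species, per_source = per_source,
       species_by_source = cross)
}
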