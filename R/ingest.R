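# Ingestion and harmonization of heterogeneous sdAb source exports.

#' Default species synonym table
#'
#' Case-insensitive, whitespace-trimmed mapping from raw species labels to
#' the four accepted categories. Generic or ambiguous labels ("camel",
#' "camelid", "mixed library") map to `"AMBIGUOUS"` so that they can never
#' be mistaken for a dromedary or Bactrian assignment. The table is an
#' ordinary named character vector and can be extended or replaced.
#'
#' @return Named character vector: `names` are lower-case raw labels,
#'   values the harmonized category.
#' @export
defaultSynonymTable <- function() {
  c(
    "llama"               = "Lama glama",
    "lama glama"          = "Lama glama",
    "llama glama"         = "Lama glama",
    "l. glama"            = "Lama glama",
    "alpaca"              = "Vicugna pacos",
    "vicugna pacos"       = "Vicugna pacos",
    "lama pacos"          = "Vicugna pacos",
    "v. pacos"            = "Vicugna pacos",
    "dromedary"           = "Camelus dromedarius",
    "dromedary camel"     = "Camelus dromedarius",
    "camelus dromedarius" = "Camelus dromedarius",
    "arabian camel"       = "Camelus dromedarius",
    "c. dromedarius"      = "Camelus dromedarius",
    "bactrian"            = "Camelus bactrianus",
    "bactrian camel"      = "Camelus bactrianus",
    "camelus bactrianus"  = "Camelus bactrianus",
    "c. bactrianus"       = "Camelus bactrianus",
    "camel"               = "AMBIGUOUS",
    "camelid"             = "AMBIGUOUS",
    "camelidae"           = "AMBIGUOUS",
    "mixed library"       = "AMBIGUOUS",
    "mixed"               = "AMBIGUOUS",
    "unknown"             = "AMBIGUOUS"
  )
}

#' Harmonize raw species labels into the four accepted categories
#'
#' Labels are matched case-insensitively after trimming whitespace; labels
#' already in canonical form are returned unchanged (the operation is
#' idempotent). Unseen labels never raise an error: they become
#' `"AMBIGUOUS"`, which marks the record for exclusion. A bare "Camel"
#' label is deliberately ambiguous because it cannot distinguish Bactrian
#' from dromedary origin.
#'
#' @param raw_label character vector of raw labels.
#' @param synonym_table named character vector as produced by
#'   [defaultSynonymTable()].
#' @return Character vector of harmonized labels (one of the four species
#'   or `"AMBIGUOUS"`).
#' @examples
#' harmonizeSpecies(c("Llama", "camelid", "Vicugna pacos"))
#' @export
harmonizeSpecies <- function(raw_label, synonym_table = defaultSynonymTable()) {
  raw <- tolower(trimws(as.character(raw_label)))
  out <- unname(synonym_table[raw])
  canon <- match(raw, tolower(SPECIES4))
  out[is.na(out) & !is.na(canon)] <- SPECIES4[canon[is.na(out) & !is.na(canon)]]
  out[is.na(out)] <- AMBIGUOUS_SPECIES
  out[is.na(raw_label)] <- AMBIGUOUS_SPECIES
  out
}

#' Relabel the species column of a dataset in place
#'
#' @param set an [SdAbSet-class].
#' @param synonym_table see [harmonizeSpecies()].
#' @return The set with harmonized species labels (no records removed;
#'   ambiguous records are removed later by [enforceMandatoryFields()]).
#' @export
harmonizeSpeciesLabels <- function(set, synonym_table = defaultSynonymTable()) {
  rec <- records(set)
  rec$species <- harmonizeSpecies(rec$species, synonym_table)
  replaceRecords(set, rec)
}

#' Read one source export into the canonical schema
#'
#' Reads a delimited table (CSV/TSV) or a FASTA file and maps source column
#' names onto the canonical fields. The mandatory fields are an identifier,
#' a species label, and either a full amino-acid sequence or all seven
#' region strings; a `column_map` that covers none of the sequence routes
#' is a configuration error. Optional metadata columns that are absent stay
#' absent (`NA`), never empty strings posing as values; unmapped source
#' columns are carried through verbatim.
#'
#' @param path file path.
#' @param source_tag short tag naming the originating resource.
#' @param column_map named character vector mapping canonical field names
#'   (names) to source column names (values), e.g.
#'   `c(record_id = "id", species = "organism", full_sequence = "seq")`.
#'   Ignored for FASTA input.
#' @param delim field delimiter for tabular input; `","` or `"\t"`.
#' @param format `"auto"` (by extension), `"table"` or `"fasta"`.
#' @param species_table for FASTA input: data.frame with columns
#'   `record_id`, `species` (a sidecar table), or `NULL`.
#' @param default_species for FASTA input without a sidecar: one species
#'   label applied to every record.
#' @return An [SdAbSet-class] with one record per row/sequence.
#' @export
readSourceTable <- function(path, source_tag, column_map = NULL,
                            delim = ",", format = c("auto", "table", "fasta"),
                            species_table = NULL, default_species = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read source file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "table"

  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    df <- data.frame(record_id = ids, full_sequence = as.character(aa),
                     stringsAsFactors = FALSE)
    if (!is.null(species_table)) {
      df$species <- species_table$species[match(df$record_id,
                                                species_table$record_id)]
    } else if (!is.null(default_species)) {
      df$species <- default_species
    } else {
      stop("configuration error: FASTA input needs species_table or default_species")
    }
  } else {
    raw <- utils::read.table(path, header = TRUE, sep = delim,
                             quote = "\"", comment.char = "",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")
    if (is.null(column_map)) {
      column_map <- intersect(CANONICAL_COLUMNS, names(raw))
      names(column_map) <- column_map
    }
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0L)
      stop("configuration error: mapped columns absent from ", path, ": ",
           paste(missing_src, collapse = ", "))
    mandatory <- c("record_id", "species")
    if (!all(mandatory %in% names(column_map)))
      stop("configuration error: column_map must map record_id and species")
    has_seq <- "full_sequence" %in% names(column_map)
    has_regions <- all(REGIONS7 %in% names(column_map))
    if (!has_seq && !has_regions)
      stop("configuration error: column_map must map full_sequence or all ",
           "seven regions (FR1..FR4, CDR1..CDR3)")
    df <- raw
    names(df)[match(unname(column_map), names(df))] <- names(column_map)
  }
  df$source_db <- source_tag
  set <- SdAbSet(df)
  set@sourceCounts <- data.frame(source_db = source_tag, n = nrow(df),
                                 stringsAsFactors = FALSE)
  set
}

#' Merge several ingested datasets into one
#'
#' Plain concatenation: nothing is removed at this stage (duplicate removal
#' is sequence-keyed and happens later in QC), so the merged size is the sum
#' of the input sizes. Source tags and per-source counts are preserved.
#'
#' @param datasets list of [SdAbSet-class] objects (may be empty).
#' @return A merged [SdAbSet-class] whose funnel starts at the merge step.
#' @export
mergeSources <- function(datasets) {
  if (length(datasets) == 0L)
    return(SdAbSet(data.frame(record_id = character(0),
                              stringsAsFactors = FALSE),
                   funnel = funnelRow("merge", 0L, 0L)))
  recs <- lapply(datasets, records)
  all_cols <- unique(unlist(lapply(recs, names)))
  recs <- lapply(recs, function(df) {
    for (col in setdiff(all_cols, names(df))) df[[col]] <- NA_character_
    df[, all_cols, drop = FALSE]
  })
  merged <- do.call(rbind, recs)
  counts <- do.call(rbind, lapply(datasets, function(d) d@sourceCounts))
  out <- SdAbSet(merged, funnel = funnelRow("merge", nrow(merged), 0L))
  if (!is.null(counts)) out@sourceCounts <- counts
  out
}

#' Enforce the mandatory-field eligibility criteria
#'
#' A record survives only if it carries a non-empty identifier, a species
#' label harmonized to one of the four accepted categories, and either a
#' full sequence or the complete set of seven region strings (a record
#' missing any single region, with no deposited full sequence, cannot be
#' reconstructed by concatenation and is removed here). Records lacking
#' only optional metadata (antigen, DOI, PDB code, affinity) are retained.
#' Removals are appended to the funnel under step `"mandatory_fields"`;
#' the operation is idempotent.
#'
#' @param set an [SdAbSet-class] with harmonized species labels.
#' @return Filtered [SdAbSet-class]; emits a warning (not an error) if the
#'   result is empty.
#' @export
enforceMandatoryFields <- function(set) {
  rec <- records(set)
  ok_id <- isPresent(rec$record_id)
  ok_species <- !is.na(rec$species) & rec$species %in% SPECIES4
  ok_seq <- isPresent(rec$full_sequence) | hasCompleteRegions(rec)
  keep <- ok_id & ok_species & ok_seq
  removed <- rec[!keep, , drop = FALSE]
  detail <- character(nrow(removed))
  if (nrow(removed) > 0L) {
    detail <- ifelse(!isPresent(removed$record_id), "missing identifier",
              ifelse(!(removed$species %in% SPECIES4),
                     "ambiguous or missing species",
                     "no full sequence and incomplete regions"))
  }
  vd <- verdictRows(removed$record_id, "mandatory_fields", detail)
  out <- replaceRecords(set, rec[keep, , drop = FALSE],
                        step = "mandatory_fields", removed = sum(!keep),
                        new_verdicts = vd)
  if (nRecords(out) == 0L && nrow(rec) > 0L)
    warning("no records survived the mandatory-field criteria")
  out
}
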