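# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Heterogeneous exports encode "missing" in many ways; normalize all of them
# to NA before any eligibility decision is taken.
normalizeMissing <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  x <- trimws(x)
  x[x %in% c("", "NA", "N/A", "n/a", "na", "-", "NULL", "None")] <- NA_character_
  x
}

isPresent <- function(x) !is.na(x) & nzchar(x)

# Split sequences into single-character vectors; returns a list.
splitChars <- function(x) strsplit(x, "", fixed = TRUE)

# Append a flag token to the semicolon-separated flags field of selected rows.
addFlag <- function(flags, idx, flag) {
  cur <- flags[idx]
  cur[is.na(cur)] <- ""
  flags[idx] <- ifelse(nzchar(cur), paste(cur, flag, sep = ";"), flag)
  flags
}

hasFlag <- function(flags, flag) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

# One funnel accounting row: records entering a step and records it removed.
funnelRow <- function(step, n_in, n_removed) {
  data.frame(step = step, n_in = as.integer(n_in),
             n_removed = as.integer(n_removed), stringsAsFactors = FALSE)
}

emptyFunnel <- function() {
  data.frame(step = character(0), n_in = integer(0), n_removed = integer(0),
             stringsAsFactors = FALSE)
}

emptyVerdicts <- function() {
  data.frame(record_id = character(0), rule = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

verdictRows <- function(record_id, rule, detail) {
  if (length(record_id) == 0L) return(emptyVerdicts())
  data.frame(record_id = record_id, rule = rule, detail = detail,
             stringsAsFactors = FALSE)
}

# Significance tier labels attached to reported p-values.
significanceStars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

hasCompleteRegions <- function(df) {
  ok <- rep(TRUE, nrow(df))
  for (r in REGIONS7) ok <- ok & isPresent(df[[r]])
  ok
}
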