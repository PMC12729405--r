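# Shared fixtures and independent oracles used across the suite.

AA20 <- aminoAcidAlphabet()

# Small hand-built curated set.
toySet <- function() {
  SdAbSet(data.frame(
    record_id = c("r1", "r2", "r3", "r4"),
    source_db = "toy",
    species = c("Lama glama", "Lama glama", "Vicugna pacos",
                "Vicugna pacos"),
    full_sequence = c("GGSS", "GGSA", "AAAA", "AACA"),
    stringsAsFactors = FALSE))
}

# Brute-force column tally: independent of the package's vectorized path.
# Straight transcription of the definitions: count each residue by looping,
# take the arg-max (alphabetical tie-break), and accumulate -p*log2(p).
bruteColumnStats <- function(column_chars) {
  counts <- integer(0)
  for (a in AA20) {
    k <- 0L
    for (ch in column_chars) if (ch == a) k <- k + 1L
    counts[a] <- k
  }
  N <- sum(counts)
  if (N == 0L)
    return(list(n = 0L, consensus = "-", freq = NA_real_, H = NA_real_))
  best <- names(counts)[1]
  for (a in names(counts)) if (counts[a] > counts[best]) best <- a
  H <- 0
  for (a in names(counts)) {
    if (counts[[a]] > 0L) {
      p <- counts[[a]] / N
      H <- H - p * log2(p)
    }
  }
  list(n = N, consensus = best, freq = counts[[best]] / N, H = H)
}

# Alignment wrapper around raw region strings (bypasses dataset plumbing).
alignmentFromStrings <- function(strings, region = "CDR3") {
  ids <- paste0("s", seq_along(strings))
  df <- data.frame(record_id = ids, species = "Lama glama",
                   stringsAsFactors = FALSE)
  df[[region]] <- strings
  buildRegionAlignment(SdAbSet(df), region)
}

# A generator config small enough for unit tests.
smallGeneratorConfig <- function(seed = 7L, n = 25L, duplicate_rate = 0,
                                 n_alphabetical = 0L, n_homopolymer = 0L,
                                 substitution_rate = 0.02) {
  generatorConfig(
    seed = seed,
    n_per_species = c("Vicugna pacos" = n, "Camelus bactrianus" = n,
                      "Camelus dromedarius" = n, "Lama glama" = n),
    duplicate_rate = duplicate_rate, n_alphabetical = n_alphabetical,
    n_homopolymer = n_homopolymer,
    profiles = defaultSpeciesProfiles(substitution_rate = substitution_rate))
}

# --- Analytic expectations under a SpeciesProfile ------------------------
# Used for parameter recovery: what the generator's parameters imply for
# the statistics the analysis modules recover.

# Exact moments of the CDR length law: a normal rounded to the nearest
# integer and floored at 3. P(L = 3) absorbs the whole lower tail.
cdrLawMoments <- function(mean, sd) {
  k <- 3:200
  p <- pnorm(k + 0.5, mean, sd) - pnorm(k - 0.5, mean, sd)
  p[1] <- pnorm(3.5, mean, sd)
  m1 <- sum(k * p)
  list(mean = m1, sd = sqrt(sum(k^2 * p) - m1^2))
}

# Replacement distribution at one framework position (consensus excluded),
# mirroring the generator's definition.
expectedReplacementShare <- function(profile, region, consensus_char,
                                     residue) {
  w <- profile@background_weights
  if (region == "FR2") w["K"] <- w["K"] * profile@fr2_lysine_weight
  if (region == "FR3") w["K"] <- w["K"] * profile@fr3_lysine_weight
  w[consensus_char] <- 0
  unname(w[residue] / sum(w))
}

# Expected per-column consensus frequency of one framework region, and its
# sampling variance for a cohort of n records. Accounts for protected
# anchors, substitution noise, and the fixed-position FR2 cysteine.
expectedFrConservation <- function(profile, region, n) {
  cons <- strsplit(profile@fr_consensus[[region]], "")[[1]]
  s <- profile@substitution_rate
  prot <- profile@protected_positions[[region]]
  q_fr2 <- profile@noncanonical_cys_prob[["FR2"]]
  f <- numeric(length(cons))
  for (j in seq_along(cons)) {
    keep <- if (j %in% prot) 1 else 1 - s
    if (region == "FR2" && j == profile@fr2_cys_position) keep <-
        keep * (1 - q_fr2)
    f[j] <- keep
  }
  list(mean = mean(f), se_mean = sqrt(sum(f * (1 - f) / n)) / length(f))
}

# Expected fraction of records carrying >= 1 cysteine in FR2: the
# non-canonical insertion at the designated position, plus the small
# chance that substitution noise writes a C at any free position.
expectedFr2CysPresence <- function(profile) {
  cons <- strsplit(profile@fr_consensus[["FR2"]], "")[[1]]
  s <- profile@substitution_rate
  prot <- profile@protected_positions[["FR2"]]
  q <- profile@noncanonical_cys_prob[["FR2"]]
  p_no_c <- 1
  for (j in seq_along(cons)) {
    if (j %in% prot) next
    p_sub_c <- s * expectedReplacementShare(profile, "FR2", cons[j], "C")
    p_here <- if (j == profile@fr2_cys_position)
      q + (1 - q) * p_sub_c else p_sub_c
    p_no_c <- p_no_c * (1 - p_here)
  }
  1 - p_no_c
}

# Expected frequency of one residue within one framework region (fraction
# of all residues in that region), with sampling SE for n records.
expectedFrResidueFrequency <- function(profile, region, residue, n) {
  cons <- strsplit(profile@fr_consensus[[region]], "")[[1]]
  s <- profile@substitution_rate
  prot <- profile@protected_positions[[region]]
  q_fr2 <- profile@noncanonical_cys_prob[["FR2"]]
  pj <- numeric(length(cons))
  for (j in seq_along(cons)) {
    is_prot <- j %in% prot
    base <- if (cons[j] == residue) {
      if (is_prot) 1 else (1 - s)
    } else {
      if (is_prot) 0 else s * expectedReplacementShare(profile, region,
                                                       cons[j], residue)
    }
    if (region == "FR2" && j == profile@fr2_cys_position) {
      base <- base * (1 - q_fr2) + q_fr2 * as.numeric(residue == "C")
    }
    pj[j] <- base
  }
  L <- length(cons)
  list(mean = sum(pj) / L, se = sqrt(sum(pj * (1 - pj))) / (L * sqrt(n)))
}
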