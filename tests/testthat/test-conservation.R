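# Rectangular region alignments and per-column conservation/entropy.

test_that("padding yields a rectangular matrix preserving every string", {
  aln <- alignmentFromStrings(c("ACD", "ACDE"))
  expect_equal(aln@width, 4L)
  expect_equal(aln@sequences, c("ACD-", "ACDE"))
  # gaps removed, every row equals its region string
  expect_equal(gsub("-", "", aln@sequences), c("ACD", "ACDE"))
  # equal-length input introduces no gaps
  aln2 <- alignmentFromStrings(c("ACD", "EFG"))
  expect_false(any(grepl("-", aln2@sequences, fixed = TRUE)))
  # empty cohort gives an empty alignment of width zero
  s <- toySet()
  empty <- buildRegionAlignment(s, "CDR3", cohort = "Camelus bactrianus")
  expect_equal(length(empty), 0L)
  expect_equal(empty@width, 0L)
  # left and center padding are available
  expect_equal(buildRegionAlignment(
    SdAbSet(data.frame(record_id = "x", CDR3 = "AC", species = "Lama glama",
                       stringsAsFactors = FALSE)),
    "CDR3")@sequences, "AC")
  aln3 <- alignmentFromStrings(c("AC", "ACDE"))
  expect_equal(aln3@sequences[1], "AC--")
})

test_that("ambiguous residues are masked to gaps at alignment time", {
  aln <- alignmentFromStrings(c("AXC", "ABC"))
  expect_equal(aln@sequences, c("A-C", "A-C"))
})

test_that("column statistics match hand-computed values", {
  # one of each canonical residue: maximal diversity, H = log2 20
  aln <- alignmentFromStrings(AA20)
  cs <- columnStats(aln, 1)
  expect_equal(cs$entropy, log2(20), tolerance = 1e-12)
  expect_equal(cs$entropy, 4.3219, tolerance = 1e-4)
  expect_equal(cs$consensus_frequency, 1 / 20)
  # constant column: perfect conservation
  cs2 <- columnStats(alignmentFromStrings(rep("A", 4)), 1)
  expect_equal(cs2$consensus, "A")
  expect_equal(cs2$consensus_frequency, 1)
  expect_equal(cs2$entropy, 0)
  # {A, A, C}: direct evaluation of -(2/3)log2(2/3) - (1/3)log2(1/3)
  cs3 <- columnStats(alignmentFromStrings(c("A", "A", "C")), 1)
  expect_equal(cs3$consensus, "A")
  expect_equal(cs3$consensus_frequency, 2 / 3)
  expect_equal(cs3$entropy, 0.9182958, tolerance = 1e-7)
  # consensus ties break alphabetically
  cs4 <- columnStats(alignmentFromStrings(c("C", "A")), 1)
  expect_equal(cs4$consensus, "A")
  # out-of-range position errors
  expect_error(columnStats(aln, 2), "out of range")
})

test_that("gap handling: counts exclude gaps, all-gap columns are missing", {
  aln <- alignmentFromStrings(c("AC", "A"))
  cs <- columnStats(aln)
  expect_equal(cs$n, c(2L, 1L))
  expect_equal(cs$coverage, c(1, 0.5))
  # column 2 has one non-gap residue: fully conserved among observed
  expect_equal(cs$consensus_frequency[2], 1)
  expect_equal(cs$entropy[2], 0)
  # an all-gap column (from masking) reports missing stats
  aln2 <- alignmentFromStrings(c("AX", "AX"))
  cs2 <- columnStats(aln2)
  expect_equal(cs2$n[2], 0L)
  expect_equal(cs2$consensus[2], "-")
  expect_true(is.na(cs2$consensus_frequency[2]))
  expect_true(is.na(cs2$entropy[2]))
  # deleting the all-gap column changes no other column's stats
  cs1 <- columnStats(alignmentFromStrings(c("A", "A")))
  expect_equal(cs2[1, c("n", "consensus", "consensus_frequency", "entropy")],
               cs1[1, c("n", "consensus", "consensus_frequency", "entropy")])
})

test_that("vectorized column stats agree with a brute-force tally", {
  # oracle equivalence over random small columns, to 1e-12
  set.seed(101)
  for (rep in 1:300) {
    nrows <- sample(1:8, 1)
    width <- sample(1:5, 1)
    strings <- vapply(seq_len(nrows), function(i)
      paste(sample(c(AA20, "-"), width, replace = TRUE), collapse = ""),
      character(1))
    # trailing all-gap strings shrink on ingestion; rebuild via data frame
    aln <- alignmentFromStrings(strings)
    m <- as.matrix(aln)
    cs <- columnStats(aln)
    for (j in seq_len(ncol(m))) {
      oracle <- bruteColumnStats(m[, j])
      expect_identical(cs$n[j], oracle$n)
      expect_identical(cs$consensus[j], oracle$consensus)
      if (oracle$n > 0) {
        expect_equal(cs$consensus_frequency[j], oracle$freq,
                     tolerance = 1e-12)
        expect_equal(cs$entropy[j], oracle$H, tolerance = 1e-12)
      }
    }
  }
})

test_that("entropy stays within [0, log2 20] and duplicates cannot raise it", {
  set.seed(107)
  strings <- vapply(1:50, function(i)
    paste(sample(AA20, 12, replace = TRUE), collapse = ""), character(1))
  cs <- columnStats(alignmentFromStrings(strings))
  expect_true(all(cs$entropy >= 0 & cs$entropy <= log2(20) + 1e-12))
  # duplicating a row that matches the consensus everywhere cannot
  # increase entropy, and never changes the consensus identity
  cons <- paste(cs$consensus, collapse = "")
  cs_dup <- columnStats(alignmentFromStrings(c(strings, cons)))
  expect_equal(cs_dup$consensus, cs$consensus)
  expect_true(all(cs_dup$entropy <= cs$entropy + 1e-12))
})

test_that("profiles are permutation-invariant and counts are additive", {
  cfg <- smallGeneratorConfig(seed = 53L, n = 15L)
  set <- generateRepertoire(cfg)$dataset
  prof <- regionProfile(set)
  rec <- records(set)
  shuffled <- SdAbSet(rec[rev(seq_len(nrow(rec))), ])
  prof2 <- regionProfile(shuffled)
  expect_equal(prof2[order(prof2$cohort, prof2$region, prof2$position),
                     c("n", "consensus", "consensus_frequency", "entropy")],
               prof[order(prof$cohort, prof$region, prof$position),
                    c("n", "consensus", "consensus_frequency", "entropy")],
               ignore_attr = TRUE)
  # pooled N(j) equals the sum over disjoint cohorts
  all_fr3 <- prof[prof$cohort == "all" & prof$region == "FR3", ]
  by_sp <- prof[prof$cohort != "all" & prof$region == "FR3", ]
  expect_equal(all_fr3$n, as.integer(tapply(by_sp$n, by_sp$position, sum)),
               ignore_attr = TRUE)
})

test_that("mean summaries average columns and preserve built-in ordering", {
  prof <- data.frame(cohort = "all", region = "FR4",
                     position = 1:2, n = c(10L, 10L), consensus = "A",
                     consensus_frequency = c(0.9, 0.7),
                     entropy = c(0, 1), coverage = c(1, 1),
                     stringsAsFactors = FALSE)
  s <- meanRegionSummary(prof)
  expect_equal(s$mean_entropy, 0.5)
  expect_equal(s$mean_conservation, 0.8)
  # single-column profile: summary equals the column
  s1 <- meanRegionSummary(prof[1, ])
  expect_equal(s1$mean_conservation, 0.9)
  # coverage weighting
  prof$coverage <- c(1, 0.5)
  sw <- meanRegionSummary(prof, weight_by_coverage = TRUE)
  expect_equal(sw$mean_entropy, (0 * 1 + 1 * 0.5) / 1.5)
  # a cohort built more conserved in FR4 than FR2 summarizes that way
  cfg <- smallGeneratorConfig(seed = 59L, n = 40L)
  set <- generateRepertoire(cfg)$dataset
  sm <- meanRegionSummary(regionProfile(set, stratify_by_species = FALSE))
  fr4 <- sm$mean_conservation[sm$region == "FR4"]
  fr2 <- sm$mean_conservation[sm$region == "FR2"]
  expect_gt(fr4, fr2)
})
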