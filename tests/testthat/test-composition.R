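# Amino-acid composition, Lys/Cys distributions, lengths, comparisons.

test_that("frequencies are pooled residue counts over total residues", {
  s <- SdAbSet(data.frame(record_id = c("a", "b"),
                          full_sequence = c("GG", "SSSS"),
                          species = "Lama glama", stringsAsFactors = FALSE))
  af <- aaFrequency(s)
  f <- structure(af$frequency, names = af$residue)
  # length-weighted pooling: sum n(a,i) / sum L_i, NOT the mean of
  # per-sequence frequencies (which would give 0.25/0.75)
  expect_equal(unname(f["G"]), 2 / 6)
  expect_equal(unname(f["S"]), 4 / 6)
  expect_equal(sum(af$frequency), 1, tolerance = 1e-12)
  expect_true(all(f[setdiff(AA20, c("G", "S"))] == 0))
  # single sequence
  af2 <- aaFrequency(SdAbSet(data.frame(record_id = "x",
                                        full_sequence = "GGSS",
                                        stringsAsFactors = FALSE)))
  f2 <- structure(af2$frequency, names = af2$residue)
  expect_equal(unname(f2[c("G", "S")]), c(0.5, 0.5))
})

test_that("profiles normalize and pool consistently across regions", {
  cfg <- smallGeneratorConfig(seed = 61L, n = 20L)
  set <- generateRepertoire(cfg)$dataset
  totals <- 0
  weighted <- numeric(20)
  for (r in regionNames()) {
    af <- aaFrequency(set, scope = r)
    expect_equal(sum(af$frequency), 1, tolerance = 1e-12)
    totals <- totals + attr(af, "n_total")
    weighted <- weighted + af$frequency * attr(af, "n_total")
  }
  # global frequencies equal the region profiles combined with
  # region-residue-count weights
  global <- aaFrequency(set, scope = "full")
  expect_equal(attr(global, "n_total"), totals)
  expect_equal(global$frequency, weighted / totals, tolerance = 1e-12)
  # duplicating every record leaves frequencies unchanged
  rec <- records(set)
  rec2 <- rec; rec2$record_id <- paste0(rec2$record_id, "_bis")
  doubled <- SdAbSet(rbind(rec, rec2))
  expect_equal(aaFrequency(doubled)$frequency, global$frequency,
               tolerance = 1e-12)
})

test_that("residue-region distribution computes all three metrics", {
  df <- data.frame(record_id = c("a", "b"), species = "Lama glama",
                   stringsAsFactors = FALSE)
  df$FR1 <- strrep("QVQLVESGGGLVQPGGSLRLSCAAS", 1)  # one C of 25
  for (r in setdiff(regionNames(), "FR1")) df[[r]] <- "GGG"
  df$full_sequence <- NA
  dist <- residueRegionDistribution(SdAbSet(df), "C",
                                    cohorts = "Lama glama")
  fr1 <- dist[dist$region == "FR1", ]
  expect_equal(fr1$frequency, 1 / 25)
  expect_equal(fr1$mean_count, 1)
  expect_equal(fr1$presence, 1)
  # residue absent everywhere: all three metrics zero
  other <- dist[dist$region == "CDR2", ]
  expect_equal(unlist(other[, c("frequency", "mean_count", "presence")]),
               c(frequency = 0, mean_count = 0, presence = 0))
})

test_that("length statistics: sample SD, RSD, molecular weight", {
  df <- data.frame(record_id = c("a", "b"),
                   full_sequence = c(strrep("G", 8), strrep("G", 12)),
                   species = "Lama glama", stringsAsFactors = FALSE)
  ls <- lengthStats(SdAbSet(df), "full", cohorts = "all")
  expect_equal(ls$mean, 10)
  expect_equal(ls$sd, 2.828427, tolerance = 1e-6)   # sqrt(8), n-1 form
  expect_equal(ls$rsd, 28.28427, tolerance = 1e-4)
  expect_equal(ls$min, 8); expect_equal(ls$max, 12)
  # degenerate: equal lengths
  df2 <- df; df2$full_sequence <- rep(strrep("G", 10), 2)
  ls2 <- lengthStats(SdAbSet(df2), "full", cohorts = "all")
  expect_equal(ls2$sd, 0); expect_equal(ls2$rsd, 0)
  # molecular weight: glycine decapeptide = 10 * 57.0519 + water
  expect_equal(molecularWeight(strrep("G", 10), unit = "Da"),
               10 * 57.0519 + 18.01528, tolerance = 1e-6)
  # a synthetic VHH cohort averages near the canonical ~13.6 +/- 0.9 kDa
  cfg <- smallGeneratorConfig(seed = 67L, n = 30L)
  set <- generateRepertoire(cfg)$dataset
  lsf <- lengthStats(set, "full", cohorts = "all")
  expect_gt(lsf$mw_mean_kda, 12.7)
  expect_lt(lsf$mw_mean_kda, 14.5)
  expect_gt(lsf$mean, 115); expect_lt(lsf$mean, 132)
})

test_that("group comparison runs the battery and excludes small cohorts", {
  set.seed(71)
  values <- c(rnorm(60, 10), rnorm(60, 10), rnorm(35, 12))
  groups <- rep(c("g1", "g2", "small"), c(60, 60, 35))
  gc <- compareGroups(values, groups, min_n = 50)
  # the n=35 cohort is excluded from testing but reported, never dropped
  expect_equal(gc@excluded$group, "small")
  expect_equal(gc@excluded$n, 35L)
  expect_setequal(gc@groups, c("g1", "g2"))
  expect_equal(nrow(gc@normality), 2L)
  expect_equal(nrow(gc@pairwise), 1L)
  # two identical groups: no significance
  expect_gt(gc@pairwise$p_holm, 0.05)
  expect_equal(gc@pairwise$signif, "ns")
  # fewer than two eligible groups: skipped with a reason
  gc2 <- compareGroups(values, groups, min_n = 100)
  expect_equal(length(gc2@groups), 0L)
  expect_match(gc2@omnibus$reason, "fewer than 2")
  expect_equal(nrow(gc2@excluded), 3L)
})

test_that("Holm adjustment is monotone and never below the raw p", {
  set.seed(73)
  values <- c(rnorm(60, 0), rnorm(60, 0.2), rnorm(60, 1), rnorm(60, 1.1))
  groups <- rep(paste0("g", 1:4), each = 60)
  gc <- compareGroups(values, groups, min_n = 50)
  pw <- gc@pairwise
  expect_equal(nrow(pw), 6L)
  expect_true(all(pw$p_holm >= pw$p))
  ord <- order(pw$p)
  expect_true(all(diff(pw$p_holm[ord]) >= -1e-15))
  expect_equal(pw$p_holm, p.adjust(pw$p, method = "holm"))
})

test_that("region-length comparison detects a built-in shift", {
  # llama CDR1 laws are longer than alpaca/dromedary in the defaults;
  # verify the wrapper wires lengths through to the tests
  cfg <- smallGeneratorConfig(seed = 79L, n = 150L)
  set <- generateRepertoire(cfg)$dataset
  gc <- compareRegionLengths(set, "CDR1", min_n = 50)
  expect_equal(length(gc@groups), 4L)
  pair <- gc@pairwise
  ll_dr <- pair[(pair$group1 == "Lama glama" &
                   pair$group2 == "Camelus dromedarius") |
                  (pair$group2 == "Lama glama" &
                     pair$group1 == "Camelus dromedarius"), ]
  expect_lt(ll_dr$p_holm, 0.05)
  # small cohorts are excluded by min_n
  gc2 <- compareRegionLengths(set, "CDR1", min_n = 151)
  expect_equal(length(gc2@groups), 0L)
})
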