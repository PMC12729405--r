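# Ingestion, species harmonization and mandatory-field eligibility.

test_that("delimited source tables are ingested through a column map", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,organism,seq,target",
               "a1,Llama,QVQLVESGGG,lysozyme",
               "a2,alpaca,EVQLVESGGG,",
               "a3,camelid,QVKLEESGGG,albumin"), path)
  set <- readSourceTable(path, "srcA",
                         column_map = c(record_id = "id",
                                        species = "organism",
                                        full_sequence = "seq",
                                        antigen = "target"))
  expect_s4_class(set, "SdAbSet")
  expect_equal(nRecords(set), 3L)
  rec <- records(set)
  expect_equal(rec$source_db, rep("srcA", 3))
  # missing optional metadata is NA, not an empty string posing as a value
  expect_true(is.na(rec$antigen[2]))
  expect_equal(rec$antigen[c(1, 3)], c("lysozyme", "albumin"))
})

test_that("region-only tables ingest with empty full sequences", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- paste(c("id", "sp", regionNames()), collapse = ",")
  row <- paste(c("r1", "Llama", "QVQLV", "GRT", "WFRQA", "ISS", "RFTIS",
                 "AKDY", "WGQGT"), collapse = ",")
  writeLines(c(header, row), path)
  cmap <- c(record_id = "id", species = "sp",
            structure(regionNames(), names = regionNames()))
  set <- readSourceTable(path, "srcB", column_map = cmap)
  rec <- records(set)
  expect_true(is.na(rec$full_sequence))
  expect_equal(rec$FR2, "WFRQA")
})

test_that("a column map without a sequence route is a configuration error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,seq", "r1,QVQLV"), path)
  expect_error(
    readSourceTable(path, "srcC",
                    column_map = c(record_id = "id", full_sequence = "seq")),
    "configuration error")
  expect_error(
    readSourceTable(path, "srcC",
                    column_map = c(record_id = "id", species = "absent",
                                   full_sequence = "seq")),
    "configuration error")
})

test_that("FASTA ingestion takes identifiers from the header token", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">nb-007 anti-GFP clone", "QVQLVESGGGLVQ",
               ">nb-008", "EVQLVESGGGLVQ"), path)
  set <- readSourceTable(path, "fsrc", default_species = "Lama glama")
  rec <- records(set)
  expect_equal(rec$record_id, c("nb-007", "nb-008"))
  expect_equal(rec$species, rep("Lama glama", 2))
  expect_error(readSourceTable(path, "fsrc"), "configuration error")
})

test_that("species labels harmonize into four categories, idempotently", {
  expect_equal(harmonizeSpecies("Llama"), "Lama glama")
  expect_equal(harmonizeSpecies(" ALPACA "), "Vicugna pacos")
  expect_equal(harmonizeSpecies("Arabian camel"), "Camelus dromedarius")
  expect_equal(harmonizeSpecies("bactrian camel"), "Camelus bactrianus")
  # generic labels cannot be assigned: a bare "Camel" could be either
  # dromedary or Bactrian
  expect_equal(harmonizeSpecies("camelid"), "AMBIGUOUS")
  expect_equal(harmonizeSpecies("Camel"), "AMBIGUOUS")
  expect_equal(harmonizeSpecies("mixed library"), "AMBIGUOUS")
  # unseen labels never throw
  expect_equal(harmonizeSpecies("guanaco?!"), "AMBIGUOUS")
  expect_equal(harmonizeSpecies(NA), "AMBIGUOUS")
  # idempotence on already-canonical labels
  for (sp in speciesLevels())
    expect_equal(harmonizeSpecies(harmonizeSpecies(sp)), sp)
})

test_that("mandatory-field enforcement keeps exactly the eligible records", {
  df <- data.frame(
    record_id = c("k1", "k2", "k3", "", "k5", "k6"),
    species = c("Lama glama", "AMBIGUOUS", "Vicugna pacos", "Lama glama",
                NA, "Lama glama"),
    full_sequence = c("QVQLV", "QVQLV", NA, "QVQLV", "QVQLV", NA),
    stringsAsFactors = FALSE)
  # k3 has all seven regions and no sequence: eligible (reconstructable)
  for (r in regionNames()) df[[r]] <- NA_character_
  df[3, regionNames()] <- as.list(c("QVQLV", "GRT", "WFRQA", "ISS",
                                    "RFTIS", "AKDY", "WGQGT"))
  # k6 misses FR2 only: not reconstructable, must go
  df[6, setdiff(regionNames(), "FR2")] <-
    as.list(c("QVQLV", "GRT", "ISS", "RFTIS", "AKDY", "WGQGT"))
  set <- enforceMandatoryFields(SdAbSet(df))
  expect_setequal(records(set)$record_id, c("k1", "k3"))
  fn <- funnel(set)
  expect_equal(fn$n_removed[fn$step == "mandatory_fields"], 4L)
  # idempotent: applying twice removes nothing new
  again <- enforceMandatoryFields(set)
  expect_equal(nRecords(again), nRecords(set))
  tail_fn <- funnel(again)
  expect_equal(tail_fn$n_removed[nrow(tail_fn)], 0L)
})

test_that("records lacking only optional metadata are retained", {
  df <- data.frame(record_id = "r1", species = "Lama glama",
                   full_sequence = "QVQLVESGGG", antigen = NA,
                   doi = NA, pdb_code = NA, affinity = NA,
                   stringsAsFactors = FALSE)
  expect_equal(nRecords(enforceMandatoryFields(SdAbSet(df))), 1L)
})

test_that("merging concatenates sources and preserves counts", {
  mk <- function(ids, tag) {
    s <- SdAbSet(data.frame(record_id = ids, species = "Lama glama",
                            full_sequence = "QVQLV",
                            stringsAsFactors = FALSE))
    s@sourceCounts <- data.frame(source_db = tag, n = length(ids),
                                 stringsAsFactors = FALSE)
    rec <- records(s); rec$source_db <- tag
    SdAbSet(rec, sourceCounts = s@sourceCounts)
  }
  a <- mk(c("a1", "a2", "a3"), "A")
  b <- mk(c("b1", "b2", "b3", "b4"), "B")
  m <- mergeSources(list(a, b))
  expect_equal(nRecords(m), 7L)
  # same identifier in two sources: both retained (dedup is sequence-keyed
  # and happens later)
  c1 <- mk("x1", "A"); c2 <- mk("x1", "B")
  expect_equal(nRecords(mergeSources(list(c1, c2))), 2L)
  # empty input list
  expect_equal(nRecords(mergeSources(list())), 0L)
})
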