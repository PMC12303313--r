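test_that("feature table survives a write/read round trip", {
  ft <- tiny_feature_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_s3_class(back, "feature_table")
  expect_equal(nrow(back), 3)
  expect_equal(sample_ids(back), c("s1", "s2"))
  expect_equal(as.data.frame(back), as.data.frame(ft))
})

test_that("feature-table validation names the offending row and column", {
  df <- tibble::as_tibble(tiny_feature_table())
  df$mz_min[2] <- df$mz_max[2] + 1
  expect_error(feature_table(df), "FT2", class = "cocultr_validation_error")

  df2 <- tibble::as_tibble(tiny_feature_table())[, -3]  # drop mz_med
  expect_error(feature_table(df2), "mz_med", class = "cocultr_schema_error")

  df3 <- tibble::as_tibble(tiny_feature_table())
  df3$s1[1] <- -5
  expect_error(feature_table(df3), "s1", class = "cocultr_validation_error")
})

test_that("blank intensity cells are read as 0 and non-numeric cells rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "feature_id\tmz_min\tmz_med\tmz_max\trt_min\trt_med\trt_max\ts1",
    "FT1\t100\t100.1\t100.2\t10\t11\t12\t",
    "FT2\t200\t200.1\t200.2\t20\t21\t22\t99"
  ), path)
  ft <- read_feature_table(path)
  expect_equal(ft$s1, c(0, 99))

  writeLines(c(
    "feature_id\tmz_min\tmz_med\tmz_max\trt_min\trt_med\trt_max\ts1",
    "FT1\t100\t100.1\t100.2\t10\t11\t12\tlots"
  ), path)
  expect_error(read_feature_table(path), class = "cocultr_validation_error")
})

test_that("phenodata reader validates the 24-sample design", {
  ph <- design24_phenodata()
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenodata(ph, path)
  back <- read_phenodata(path)
  expect_equal(nrow(back), 24)
  expect_equal(as.data.frame(back), as.data.frame(ph))
})

test_that("phenodata rejects unknown tokens and duplicate keys", {
  df <- tibble::as_tibble(design24_phenodata())
  df$species[1] <- "S.m"
  err <- expect_error(phenodata(df), class = "cocultr_validation_error")
  expect_match(conditionMessage(err), "SM, PP, BLANK")

  df2 <- tibble::as_tibble(design24_phenodata())
  df2$sample_id[2] <- df2$sample_id[1]
  expect_error(phenodata(df2), df2$sample_id[1], class = "cocultr_duplicate_error",
               fixed = TRUE)

  # enum normalization is case-insensitive
  df3 <- tibble::as_tibble(design24_phenodata())
  df3$species <- tolower(df3$species)
  df3$culture <- toupper(df3$culture)
  expect_silent(ph3 <- phenodata(df3))
  expect_setequal(unique(ph3$species), c("SM", "PP"))
})

test_that("growth series round-trips through the wide S1-style layout", {
  g <- generate_growth_study(seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_growth_series(g, path)
  back <- read_growth_series(path)
  expect_equal(as.data.frame(back), as.data.frame(g))

  bad <- tibble::as_tibble(g)
  bad$day[1] <- 3L
  expect_error(growth_series(bad), class = "cocultr_validation_error")
})

test_that("suspect lists parse with missing masses and source tags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tformula\tmonoisotopic_mass\tsmiles\tsource_species",
    "all-trans-Fucoxanthin\tC42H58O6\t658.42\tCC1=CC(=O)CC(C)(C)C1\tBOTH",
    "Viburnitol\tC6H12O5\tn/a\tC1C(C(C(C(C1O)O)O)O)O\tPP"
  ), path)
  sl <- read_suspect_list(path)
  expect_equal(nrow(sl), 2)
  expect_equal(sl$source_species, c("BOTH", "PP"))
  expect_true(is.na(sl$monoisotopic_mass[2]))
})

test_that("a 222-entry suspect list is read in full", {
  df <- tibble::tibble(
    name = paste0("metabolite_", 1:222),
    formula = "C6H12O6",
    monoisotopic_mass = runif(222, 100, 900),
    smiles = rep(c("CCO", "CCC", "C1CCCCC1"), length.out = 222),
    source_species = rep(c("SM", "PP", "BOTH"), length.out = 222)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  expect_equal(nrow(read_suspect_list(path)), 222)
})

test_that("suspect list with no parseable rows errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tsmiles", "\t", "\t"), path)
  expect_error(read_suspect_list(path), class = "cocultr_empty_error")
})

test_that("annotation tables enforce MSI level/source consistency", {
  good <- tibble::tibble(precursor_mz = 340.2467, rt = 289,
                         msi_level = 2L, source = "spectral_db")
  expect_s3_class(annotation_table(good), "annotation_table")
  bad <- tibble::tibble(precursor_mz = 340.2467, rt = 289,
                        msi_level = 2L, source = "compound_db")
  expect_error(annotation_table(bad), class = "cocultr_validation_error")
})

test_that("retention times in minutes are converted on ingest", {
  ft <- tiny_feature_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::as_tibble(ft)
  df[, c("rt_min", "rt_med", "rt_max")] <- df[, c("rt_min", "rt_med", "rt_max")] / 60
  readr::write_tsv(df, path)
  back <- read_feature_table(path, rt_minutes = TRUE)
  expect_equal(back$rt_med, ft$rt_med)
})
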