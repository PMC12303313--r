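test_that("the generator is bitwise deterministic under fixed seeds", {
  cfg <- generator_config(n_features = 60, n_differential = 5, design_seed = 7, noise_seed = 7)
  a <- generate_feature_dataset(cfg)
  b <- generate_feature_dataset(cfg)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(as.data.frame(a$pheno), as.data.frame(b$pheno))
  expect_identical(a$truth$differential, b$truth$differential)
})

test_that("changing only the noise seed keeps planted memberships fixed", {
  cfg1 <- generator_config(n_features = 60, n_differential = 5, design_seed = 7, noise_seed = 1)
  cfg2 <- generator_config(n_features = 60, n_differential = 5, design_seed = 7, noise_seed = 2)
  a <- generate_feature_dataset(cfg1)
  b <- generate_feature_dataset(cfg2)
  expect_identical(a$truth$differential, b$truth$differential)
  expect_identical(a$truth$exchange, b$truth$exchange)
  expect_identical(a$table$mz_med, b$table$mz_med)
  expect_false(identical(intensity_matrix(a$table), intensity_matrix(b$table)))
})

test_that("a null effect makes planted features indistinguishable from noise", {
  cfg <- generator_config(n_features = 200, n_differential = 10,
                          zero_inflation = 0, exchange_counts = NULL,
                          effect_size = 0, design_seed = 5, noise_seed = 6)
  ds <- generate_feature_dataset(cfg)
  sel <- suppressMessages(
    select_differential(ds$table, ds$pheno, "SM", "endo", seed = 1)
  )
  truth <- ds$truth$differential
  truth <- truth$feature_id[truth$species == "SM" & truth$compartment == "endo"]
  # ~5% of features are selected; planted nulls should hit at about that rate
  expect_lte(mean(truth %in% sel$feature_id[sel$selected]), 0.3)
})

test_that("full-fraction inclusion lists link back to every feature", {
  cfg <- generator_config(n_features = 50, n_differential = 4, exchange_counts = NULL, zero_inflation = 0,
                          design_seed = 3, noise_seed = 4)
  ds <- generate_feature_dataset(cfg)
  ia <- generate_inclusion_and_annotations(ds$table, ds$truth, fraction = 1,
                                           seed = 9)
  expect_equal(nrow(ia$inclusion), 50)
  lm <- link_inclusion_to_features(ia$inclusion, ds$table)
  expect_true(all(lm$match_status == "full"))
  expect_identical(lm$feature_id, ia$truth$fragmented$feature_id)
})

test_that("designated far-jitter entries fail to link cleanly", {
  cfg <- generator_config(n_features = 50, n_differential = 4, exchange_counts = NULL, design_seed = 3, noise_seed = 4)
  ds <- generate_feature_dataset(cfg)
  ia <- generate_inclusion_and_annotations(ds$table, ds$truth, fraction = 1,
                                           n_bad_jitter = 5, seed = 9)
  lm <- link_inclusion_to_features(ia$inclusion, ds$table)
  bad <- ia$truth$fragmented$far_jitter
  expect_equal(sum(bad), 5)
  expect_true(all(lm$match_status[bad] %in% c("mz_only", "unlinked")))
  expect_true(all(lm$match_status[!bad] == "full"))
})

test_that("overlapping m/z envelopes exercise the tie-break with a comment", {
  df <- tibble::tibble(
    feature_id = c("F1", "F2"),
    mz_min = c(200.000, 200.001), mz_med = c(200.002, 200.003),
    mz_max = c(200.004, 200.005),
    rt_min = c(90, 95), rt_med = c(100, 105), rt_max = c(110, 115),
    s1 = c(1, 1)
  )
  inc <- inclusion_list(tibble::tibble(precursor_mz = 200.0025, rt_min_s = 80,
                                       rt_max_s = 120, polarity = "pos"))
  lm <- link_inclusion_to_features(inc, feature_table(df))
  expect_true(nzchar(lm$comment))
})

test_that("logistic growth hits its closed-form midpoint and null case", {
  g <- generate_growth_curves(K = 2000, r = 1, t0 = 4, suppression = 0.7,
                              noise_sd = 0, replicates = c(mono = 2, co = 2),
                              seed = 1)
  mid_co <- g$rfu[g$day == 4 & g$culture == "co"]
  expect_equal(mid_co, rep(2000 / 2 * 0.7, 2))
  g1 <- generate_growth_curves(suppression = 1, noise_sd = 0,
                               replicates = c(mono = 2, co = 2), seed = 1)
  wide <- tidyr::pivot_wider(g1, names_from = "culture", values_from = "rfu")
  expect_equal(wide$mono, wide$co)
})

test_that("generator configs are validated", {
  expect_error(generator_config(zero_inflation = 1.5),
               class = "cocultr_validation_error")
  expect_error(generator_config(mono_replicates = 1),
               class = "cocultr_validation_error")
  expect_error(generator_config(rt_range = c(0, 900)),
               class = "cocultr_validation_error")
  expect_error(generator_config(n_features = 50, n_differential = 40),
               class = "cocultr_validation_error")
})

test_that("bundles write to disk with a truth sidecar", {
  dir <- withr::local_tempdir()
  bundle <- generate_study(generator_config(n_features = 80, n_differential = 5, design_seed = 1,
                                            noise_seed = 2))
  write_study(bundle, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "feature_table.tsv", "phenodata.tsv", "inclusion_list.tsv",
    "annotations.tsv", "growth_series.tsv", "truth.json"
  )))))
  back <- read_feature_table(file.path(dir, "feature_table.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(bundle$table))
})
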