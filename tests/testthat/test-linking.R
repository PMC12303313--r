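make_features <- function(...) {
  feature_table(tibble::tibble(...))
}

test_that("inclusion precursors link by m/z envelope then retention window", {
  feats <- make_features(
    feature_id = c("F1", "F2"),
    mz_min = c(340.2460, 500.0), mz_med = c(340.2468, 500.1),
    mz_max = c(340.2475, 500.2),
    rt_min = c(270, 100), rt_med = c(289, 120), rt_max = c(310, 140),
    s1 = c(1, 1)
  )
  inc <- inclusion_list(tibble::tibble(
    precursor_mz = c(340.2467, 340.2467, 999.9),
    rt_min_s = c(280, 280, 280), rt_max_s = c(300, 300, 300),
    polarity = "pos"
  ))
  lm1 <- link_inclusion_to_features(inc, feats)
  expect_equal(lm1$feature_id[1], "F1")
  expect_equal(lm1$match_status[1], "full")
  expect_equal(lm1$comment[1], "")
  expect_equal(lm1$match_status[3], "unlinked")
  expect_true(is.na(lm1$feature_id[3]))

  # same envelope but rt_med outside the window -> mz_only with a comment
  feats2 <- make_features(
    feature_id = "F1",
    mz_min = 340.2460, mz_med = 340.2468, mz_max = 340.2475,
    rt_min = 340, rt_med = 350, rt_max = 360, s1 = 1
  )
  lm2 <- link_inclusion_to_features(
    inclusion_list(tibble::tibble(precursor_mz = 340.2467, rt_min_s = 280,
                                  rt_max_s = 300, polarity = "pos")),
    feats2
  )
  expect_equal(lm2$match_status, "mz_only")
  expect_equal(lm2$feature_id, "F1")
  expect_match(lm2$comment, "350")
  expect_match(lm2$comment, "280")
})

test_that("ties between enclosing features resolve by closest mz_med, logged", {
  feats <- make_features(
    feature_id = c("FA", "FB"),
    mz_min = c(100.000, 100.000), mz_med = c(100.0010, 100.0030),
    mz_max = c(100.005, 100.005),
    rt_min = c(10, 10), rt_med = c(20, 20), rt_max = c(30, 30),
    s1 = c(1, 1)
  )
  inc <- inclusion_list(tibble::tibble(precursor_mz = 100.0012, rt_min_s = 10,
                                       rt_max_s = 30, polarity = "pos"))
  lm <- link_inclusion_to_features(inc, feats)
  expect_equal(lm$feature_id, "FA")
  expect_equal(lm$match_status, "full")
  expect_match(lm$comment, "FB")
})

test_that("linking agrees with the brute-force oracle on random instances", {
  withr::local_seed(61)
  for (i in 1:100) {
    inst <- random_link_instance()
    got <- link_inclusion_to_features(inst$inclusion, inst$features)
    want <- brute_force_link(inst$inclusion, inst$features)
    expect_identical(got$feature_id, want$feature_id)
    expect_identical(got$match_status, want$match_status)
  }
})

test_that("linking is deterministic and order independent", {
  withr::local_seed(67)
  inst <- random_link_instance(40, 15)
  base <- link_inclusion_to_features(inst$inclusion, inst$features)
  perm_feat <- feature_table(tibble::as_tibble(inst$features)[sample(40), ])
  perm_inc <- inclusion_list(tibble::as_tibble(inst$inclusion)[sample(15), ])
  again <- link_inclusion_to_features(perm_inc, perm_feat)
  key <- function(x) x[order(x$precursor_mz), c("precursor_mz", "feature_id", "match_status")]
  expect_equal(key(base), key(again), ignore_attr = TRUE)
})

test_that("every full link re-checks against both containment conditions", {
  withr::local_seed(71)
  inst <- random_link_instance(60, 30)
  lm <- link_inclusion_to_features(inst$inclusion, inst$features)
  full <- lm[lm$match_status == "full", ]
  ft <- tibble::as_tibble(inst$features)
  for (i in seq_len(nrow(full))) {
    f <- ft[ft$feature_id == full$feature_id[i], ]
    expect_true(f$mz_min <= full$precursor_mz[i] && full$precursor_mz[i] <= f$mz_max)
    expect_true(full$rt_min_s[i] <= f$rt_med && f$rt_med <= full$rt_max_s[i])
  }
})

test_that("annotations inherit feature ids through the inclusion list", {
  feats <- make_features(
    feature_id = "F1",
    mz_min = 340.2460, mz_med = 340.2468, mz_max = 340.2475,
    rt_min = 270, rt_med = 289, rt_max = 310, s1 = 1
  )
  inc <- inclusion_list(tibble::tibble(precursor_mz = 340.2467, rt_min_s = 280,
                                       rt_max_s = 300, polarity = "pos"))
  lm <- link_inclusion_to_features(inc, feats)
  ann <- annotation_table(tibble::tibble(
    precursor_mz = c(340.2467, 340.2468, 340.2467, 800.5),
    rt = c(289, 295, 500, 289),
    msi_level = c(2L, 3L, 3L, 4L),
    source = c("spectral_db", "compound_db", "compound_db", "none"),
    name = c("tumonoic acid A", "b", "c", "d")
  ))
  linked <- link_annotations_to_features(ann, lm)
  expect_equal(nrow(linked), 4)  # nothing dropped
  expect_equal(linked$feature_id[1:2], c("F1", "F1"))  # shared precursor
  expect_equal(linked$match_status[3], "unlinked")     # rt outside the window
  expect_equal(linked$match_status[4], "unlinked")     # mz outside tolerance
})

test_that("MSI tallies count levels per condition", {
  linked <- structure(
    tibble::tibble(
      precursor_mz = runif(10, 100, 900), rt = runif(10, 0, 700),
      msi_level = c(rep(2L, 3), rep(3L, 5), rep(4L, 2)),
      feature_id = paste0("F", 1:10), match_status = "full", comment = "",
      compartment = "endo", polarity = "pos"
    ),
    class = c("linked_annotations", "tbl_df", "tbl", "data.frame")
  )
  tal <- tally_msi_levels(linked)
  expect_equal(tal$condition, "endo_pos")
  expect_equal(c(tal$total, tal$msi2, tal$msi3, tal$msi45), c(10, 3, 5, 2))

  diff <- tibble::tibble(feature_id = c("F1", "F2", "F3"),
                         species = c("SM", "SM", "PP"))
  tal2 <- tally_msi_levels(linked, diff)
  expect_equal(tal2$n_differential_SM, 2L)
  expect_equal(tal2$n_differential_PP, 1L)

  expect_equal(nrow(tally_msi_levels(linked[0, ])), 0)
})

test_that("suspect screening matches on structure first, then name", {
  fuco <- "O=C(OC1CC(O)(CC(C)(C)C1)C)C"  # stand-in structure shared by both lists
  linked <- tibble::tibble(
    name = c("all-trans-Fucoxanthin", "Viburnitol", "nothing"),
    smiles = c(fuco, NA, "CCCC"),
    feature_id = c("F1", "F2", "F3")
  )
  suspects <- structure(
    tibble::tibble(
      name = c("Fucoxanthin", "Viburnitol", "Toluene"),
      formula = NA_character_, monoisotopic_mass = NA_real_,
      smiles = c(fuco, "C1C(C(C(C(C1O)O)O)O)O", "CC1=CC=CC=C1"),
      inchi = NA_character_,
      source_species = c("BOTH", "PP", "SM")
    ),
    class = c("suspect_list", "tbl_df", "tbl", "data.frame")
  )
  hits <- screen_suspects(linked, suspects)
  struct <- hits[hits$match_level == "structure", ]
  expect_equal(struct$source_species, "BOTH")
  expect_equal(struct$feature_id, "F1")
  name_hit <- hits[hits$match_level == "name", ]
  expect_equal(name_hit$suspect_name, "Viburnitol")

  none <- screen_suspects(tibble::tibble(name = "x", smiles = "CCCCCCCC",
                                         feature_id = "F9"), suspects)
  expect_equal(nrow(none), 0)
})

test_that("name matches with conflicting structures are flagged", {
  linked <- tibble::tibble(name = "Viburnitol", smiles = "CCO", feature_id = "F1")
  suspects <- structure(
    tibble::tibble(name = "Viburnitol", formula = NA_character_,
                   monoisotopic_mass = NA_real_,
                   smiles = "C1C(C(C(C(C1O)O)O)O)O", inchi = NA_character_,
                   source_species = "PP"),
    class = c("suspect_list", "tbl_df", "tbl", "data.frame")
  )
  hits <- screen_suspects(linked, suspects)
  expect_equal(hits$match_level, "name")
  expect_true(hits$structure_mismatch)
})
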