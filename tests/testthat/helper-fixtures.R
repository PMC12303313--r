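# Shared fixtures, built in code at test time.

# Minimal 3-feature, 2-sample raw feature table.
tiny_feature_table <- function() {
  feature_table(tibble::tibble(
    feature_id = c("FT1", "FT2", "FT3"),
    mz_min = c(100.000, 200.000, 300.000),
    mz_med = c(100.001, 200.002, 300.003),
    mz_max = c(100.002, 200.004, 300.006),
    rt_min = c(50, 150, 250),
    rt_med = c(55, 155, 255),
    rt_max = c(60, 160, 260),
    s1 = c(1024, 0, 8),
    s2 = c(512, 4, 0)
  ))
}

tiny_phenodata <- function() {
  phenodata(tibble::tibble(
    sample_id = c("s1", "s2"),
    species = "SM", compartment = "endo", culture = c("mono", "co"),
    polarity = "pos", replicate = c(1L, 1L)
  ))
}

# Full 24-sample design for one compartment/polarity (2 species x mono 8 / co 4).
design24_phenodata <- function(compartment = "endo", polarity = "pos") {
  rows <- list()
  for (sp in c("SM", "PP")) {
    for (cult in c("mono", "co")) {
      n <- if (cult == "mono") 8 else 4
      rows[[paste(sp, cult)]] <- tibble::tibble(
        sample_id = paste(sp, compartment, cult, polarity, seq_len(n), sep = "_"),
        species = sp, compartment = compartment, culture = cult,
        polarity = polarity, replicate = seq_len(n)
      )
    }
  }
  phenodata(dplyr::bind_rows(rows))
}

# All-pairs brute-force oracle for inclusion-list linking: literal interval
# containment plus the documented tie-break, written independently of the
# implementation (no shared helpers).
brute_force_link <- function(inclusion, features) {
  out <- list()
  for (i in seq_len(nrow(inclusion))) {
    mz <- inclusion$precursor_mz[i]
    lo <- inclusion$rt_min_s[i]
    hi <- inclusion$rt_max_s[i]
    cand_idx <- c()
    for (j in seq_len(nrow(features))) {
      if (features$mz_min[j] <= mz && mz <= features$mz_max[j]) {
        cand_idx <- c(cand_idx, j)
      }
    }
    if (length(cand_idx) == 0) {
      out[[i]] <- list(feature_id = NA_character_, match_status = "unlinked")
      next
    }
    in_rt <- cand_idx[features$rt_med[cand_idx] >= lo & features$rt_med[cand_idx] <= hi]
    pool <- if (length(in_rt) > 0) in_rt else cand_idx
    status <- if (length(in_rt) > 0) "full" else "mz_only"
    mid <- (lo + hi) / 2
    key <- order(abs(features$mz_med[pool] - mz),
                 abs(features$rt_med[pool] - mid),
                 features$feature_id[pool])
    out[[i]] <- list(feature_id = features$feature_id[pool[key[1]]],
                     match_status = status)
  }
  tibble::tibble(
    feature_id = vapply(out, `[[`, "", "feature_id"),
    match_status = vapply(out, `[[`, "", "match_status")
  )
}

# Random (inclusion, feature) instance for the linking oracle check.
random_link_instance <- function(n_features = 30, n_inclusion = 10) {
  mz_med <- runif(n_features, 100, 1000)
  half <- mz_med * runif(n_features, 2, 20) * 1e-6
  rt_med <- runif(n_features, 0, 700)
  rt_half <- runif(n_features, 2, 20)
  features <- feature_table(tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(n_features)),
    mz_min = mz_med - half, mz_med = mz_med, mz_max = mz_med + half,
    rt_min = pmax(rt_med - rt_half, 0), rt_med = rt_med,
    rt_max = rt_med + rt_half,
    s1 = runif(n_features, 0, 10), s2 = runif(n_features, 0, 10)
  ))
  # precursors: mix of on-target (near a feature mz) and random misses
  anchor <- sample(seq_len(n_features), n_inclusion, replace = TRUE)
  on_target <- runif(n_inclusion) < 0.7
  mz <- ifelse(on_target,
               mz_med[anchor] * (1 + runif(n_inclusion, -15, 15) * 1e-6),
               runif(n_inclusion, 100, 1000))
  rt_c <- ifelse(runif(n_inclusion) < 0.7, rt_med[anchor],
                 runif(n_inclusion, 0, 700))
  w <- runif(n_inclusion, 5, 40)
  inclusion <- inclusion_list(tibble::tibble(
    precursor_mz = mz,
    rt_min_s = pmax(rt_c - w, 0), rt_max_s = pmin(rt_c + w, 700),
    polarity = "pos"
  ))
  list(inclusion = inclusion, features = features)
}
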