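# Synthetic-data generator: produces every pipeline input with the
# statistical structure the analysis assumes (log-normal intensities with
# zero inflation, planted differential features, planted exchange-category
# occurrence patterns, inclusion lists with m/z / RT windows, logistic growth
# with a co-culture suppression factor) plus ground-truth bookkeeping.
#
# Two seeds: the design seed fixes planted memberships and feature
# coordinates; the noise seed fixes intensity realizations and dropout, so
# power curves can vary noise while holding the truth fixed.

#' Generator configuration
#'
#' Defaults mirror the study design: 2 species x {endo, exo} x
#' {mono: 8 replicates, co: 4 replicates}, m/z 80-1200 Th, retention time
#' 0-700 s, log2-normal intensities with zero inflation, and per-contrast
#' planted differential features with a log2 effect size.
#'
#' @param n_features Number of LC-MS features.
#' @param mono_replicates,co_replicates Replicates per culture condition.
#' @param polarity Ionization polarity of the dataset.
#' @param mz_range,rt_range Feature coordinate ranges (Th, seconds).
#' @param baseline_log2_mean,baseline_log2_sd Between-feature distribution of
#'   baseline log2 intensity.
#' @param noise_sd Within-feature between-sample log2 noise sd (sigma).
#' @param zero_inflation Probability pi that an observed intensity drops to 0
#'   (applied after effect planting).
#' @param effect_size Planted log2 shift delta for differential features in
#'   the focal co-culture condition.
#' @param n_differential Planted differential features per
#'   (species, compartment) contrast.
#' @param exchange_counts Named counts of planted exchange categories among
#'   the focal species' endometabolome differential features (default the
#'   7/10/6/7 partition). Applied for focal species `"PP"`; set to `NULL` to
#'   plant none.
#' @param exchange_focal Focal species whose endo differential features carry
#'   the planted exchange patterns.
#' @param design_seed,noise_seed Integer seeds (memberships / realizations).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_features = 500,
                             mono_replicates = 8, co_replicates = 4,
                             polarity = "pos",
                             mz_range = c(80, 1200), rt_range = c(0, 700),
                             baseline_log2_mean = 20, baseline_log2_sd = 1.5,
                             noise_sd = 1, zero_inflation = 0.2,
                             effect_size = 2, n_differential = 20,
                             exchange_counts = c(EXCLUSIVE_CO = 7,
                                                 PARTNER_RELEASED = 10,
                                                 PARTNER_ENDOGENOUS = 6,
                                                 SHARED_ALL = 7),
                             exchange_focal = "PP",
                             design_seed = 1, noise_seed = 2) {
  cfg <- as.list(environment())
  if (zero_inflation < 0 || zero_inflation > 1) {
    abort("zero_inflation must be in [0, 1]", class = "cocultr_validation_error")
  }
  if (mono_replicates < 2 || co_replicates < 2) {
    abort("replicate counts must be >= 2", class = "cocultr_validation_error")
  }
  if (rt_range[1] < 0 || rt_range[2] > 700) {
    abort("rt_range must lie within [0, 700] seconds", class = "cocultr_validation_error")
  }
  # the focal endo contrast is widened to hold all planted exchange features
  n_exch <- if (is.null(exchange_counts)) 0L else sum(exchange_counts)
  n_planted <- 3 * n_differential + max(n_differential, n_exch)
  if (n_planted > n_features) {
    abort("more planted features than n_features", class = "cocultr_validation_error")
  }
  structure(cfg, class = "generator_config")
}

design_phenodata <- function(cfg) {
  grid <- tidyr::expand_grid(
    species = c("SM", "PP"),
    compartment = COMPARTMENT_LEVELS,
    culture = CULTURE_LEVELS
  )
  rows <- pmap(grid, function(species, compartment, culture) {
    n <- if (culture == "mono") cfg$mono_replicates else cfg$co_replicates
    tibble(
      sample_id = paste(species, compartment, culture, cfg$polarity,
                        seq_len(n), sep = "_"),
      species = species, compartment = compartment, culture = culture,
      polarity = cfg$polarity, replicate = seq_len(n)
    )
  })
  phenodata(list_rbind(rows))
}

#' Generate a synthetic feature dataset with planted truth
#'
#' Draws feature coordinates (m/z uniform with +/-10 ppm envelopes, retention
#' time uniform with +/-15 s envelopes), log2-normal intensities around a
#' per-feature baseline, plants differential features (log2 shift
#' `effect_size` in the focal species' co-culture samples of the designated
#' compartment), realizes planted exchange-category occurrence patterns by
#' construction of condition-wise presence, then injects zeros with
#' probability `zero_inflation`.
#'
#' @param config A [generator_config()].
#' @return A list with `table` (a [feature_table()]), `pheno`
#'   (a [phenodata()]) and `truth` (list: `differential` tibble with
#'   `species`, `compartment`, `feature_id`, `delta`; `exchange` tibble with
#'   `feature_id`, `focal_species`, `category`; `config`).
#' @export
generate_feature_dataset <- function(config = generator_config()) {
  cfg <- config
  pheno <- design_phenodata(cfg)
  n <- cfg$n_features
  ids <- sprintf("FT%04d", seq_len(n))

  design <- with_local_seed(cfg$design_seed, {
    mz_med <- runif(n, cfg$mz_range[1], cfg$mz_range[2])
    rt_med <- runif(n, cfg$rt_range[1], cfg$rt_range[2])
    baseline <- rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)

    contrasts <- tidyr::expand_grid(species = c("SM", "PP"),
                                    compartment = COMPARTMENT_LEVELS)
    pool <- sample(ids)
    used <- 0
    differential <- pmap(contrasts, function(species, compartment) {
      n_d <- cfg$n_differential
      if (!is.null(cfg$exchange_counts) && species == cfg$exchange_focal &&
          compartment == "endo") {
        n_d <- max(n_d, sum(cfg$exchange_counts))
      }
      picked <- pool[used + seq_len(n_d)]
      used <<- used + n_d
      tibble(species = species, compartment = compartment,
             feature_id = picked, delta = cfg$effect_size)
    }) |> list_rbind()

    exchange <- NULL
    if (!is.null(cfg$exchange_counts)) {
      focal_endo <- differential$feature_id[
        differential$species == cfg$exchange_focal &
          differential$compartment == "endo"
      ]
      picked <- focal_endo[seq_len(sum(cfg$exchange_counts))]
      exchange <- tibble(
        feature_id = picked,
        focal_species = cfg$exchange_focal,
        category = rep(names(cfg$exchange_counts), cfg$exchange_counts)
      )
    }
    list(mz_med = mz_med, rt_med = rt_med, baseline = baseline,
         differential = differential, exchange = exchange)
  })

  # condition-level presence flags implied by the planted exchange categories
  partner <- setdiff(c("SM", "PP"), cfg$exchange_focal)
  absent <- list()  # sample ids where a feature is forced absent
  if (!is.null(design$exchange)) {
    ph <- as_tibble(pheno)
    cond_ids <- function(sp, comp, cult) {
      ph$sample_id[ph$species == sp & ph$compartment == comp & ph$culture == cult]
    }
    for (i in seq_len(nrow(design$exchange))) {
      fid <- design$exchange$feature_id[i]
      cat_i <- design$exchange$category[i]
      off <- switch(
        cat_i,
        EXCLUSIVE_CO = c(cond_ids(partner, "exo", "mono"),
                         cond_ids(partner, "endo", "mono"),
                         cond_ids(partner, "endo", "co"),
                         cond_ids(partner, "exo", "co"),
                         cond_ids(cfg$exchange_focal, "endo", "mono")),
        PARTNER_RELEASED = c(cond_ids(partner, "endo", "mono"),
                             cond_ids(partner, "endo", "co")),
        PARTNER_ENDOGENOUS = c(cond_ids(partner, "exo", "mono")),
        SHARED_ALL = character(0)
      )
      absent[[fid]] <- off
    }
  }

  samples <- pheno$sample_id
  log2_int <- with_local_seed(cfg$noise_seed, {
    m <- matrix(rnorm(n * length(samples), 0, cfg$noise_sd), n, length(samples),
                dimnames = list(ids, samples))
    m <- m + design$baseline
    # plant differential log2 shifts in focal co-culture samples
    ph <- as_tibble(pheno)
    for (i in seq_len(nrow(design$differential))) {
      d <- design$differential[i, ]
      cols <- ph$sample_id[ph$species == d$species &
                             ph$compartment == d$compartment &
                             ph$culture == "co"]
      m[d$feature_id, cols] <- m[d$feature_id, cols] + d$delta
    }
    raw <- 2^m
    for (fid in names(absent)) {
      raw[fid, absent[[fid]]] <- 0
    }
    if (cfg$zero_inflation > 0) {
      drop <- matrix(
        rbinom(n * length(samples), 1, cfg$zero_inflation) == 1,
        n, length(samples)
      )
      raw[drop] <- 0
    }
    raw
  })

  ppm10 <- design$mz_med * 10e-6
  table <- feature_table(dplyr::bind_cols(
    tibble(
      feature_id = ids,
      mz_min = design$mz_med - ppm10, mz_med = design$mz_med,
      mz_max = design$mz_med + ppm10,
      rt_min = pmax(design$rt_med - 15, 0), rt_med = design$rt_med,
      rt_max = pmin(design$rt_med + 15, 700)
    ),
    as_tibble(log2_int)
  ))
  truth <- list(
    differential = design$differential,
    exchange = design$exchange,
    config = cfg
  )
  list(table = table, pheno = pheno, truth = truth)
}

#' Generate an inclusion list and MS2 annotations for a feature dataset
#'
#' A random subset of features (`fraction`) receives inclusion entries with
#' `precursor_mz = mz_med` jittered by at most 3 ppm and a retention window
#' of `rt_med` +/- 30 s. A subset of inclusion entries (`annotate_fraction`)
#' receives annotations whose precursor and retention time fall within the
#' linking tolerances, with MSI levels sampled over {2, 3, 4, 5} and sources
#' consistent with the level. `n_bad_jitter` designated entries get their
#' precursor jittered far beyond the m/z envelope (constructed negatives for
#' the linker).
#'
#' @param table A [feature_table()] from [generate_feature_dataset()].
#' @param truth Its truth list (gains `fragmented` and `annotated` records).
#' @param fraction Fraction of features given inclusion entries.
#' @param annotate_fraction Fraction of inclusion entries given annotations.
#' @param n_bad_jitter Number of designated far-jitter inclusion entries.
#' @param msi_probs Sampling weights for MSI levels 2/3/4/5.
#' @param seed Integer seed.
#' @return A list with `inclusion` (an [inclusion_list()]), `annotations`
#'   (an [annotation_table()]) and the updated `truth`.
#' @export
generate_inclusion_and_annotations <- function(table, truth, fraction = 0.3,
                                               annotate_fraction = 0.7,
                                               n_bad_jitter = 0,
                                               msi_probs = c(0.08, 0.62, 0.15, 0.15),
                                               seed = 3) {
  stopifnot(fraction > 0, fraction <= 1)
  cfg <- truth$config
  with_local_seed(seed, {
    n_inc <- max(1, round(fraction * nrow(table)))
    chosen <- sort(sample(seq_len(nrow(table)), n_inc))
    bad <- if (n_bad_jitter > 0) chosen[seq_len(min(n_bad_jitter, n_inc))] else integer(0)
    jitter_ppm <- runif(n_inc, -3, 3)
    mz <- table$mz_med[chosen] * (1 + jitter_ppm * 1e-6)
    mz[chosen %in% bad] <- table$mz_med[chosen %in% bad] * (1 + 50e-6)
    inc <- inclusion_list(tibble(
      precursor_mz = mz,
      rt_min_s = pmax(table$rt_med[chosen] - 30, 0),
      rt_max_s = pmin(table$rt_med[chosen] + 30, 700),
      polarity = cfg$polarity
    ))
    n_ann <- max(1, round(annotate_fraction * n_inc))
    ann_idx <- sort(sample(seq_len(n_inc), n_ann))
    lev <- sample(2:5, n_ann, replace = TRUE, prob = msi_probs)
    ann <- annotation_table(tibble(
      precursor_mz = inc$precursor_mz[ann_idx] *
        (1 + runif(n_ann, -2, 2) * 1e-6),
      rt = pmax(pmin(table$rt_med[chosen][ann_idx] + runif(n_ann, -20, 20), 700), 0),
      smiles = NA_character_,
      name = paste0("compound_", table$feature_id[chosen][ann_idx]),
      formula = NA_character_,
      chemont_class = sample(c("Fatty Acyls", "Prenol lipids",
                               "Organooxygen compounds", "Glycerolipids"),
                             n_ann, replace = TRUE),
      msi_level = lev,
      source = dplyr::case_when(lev == 2L ~ "spectral_db",
                                lev == 3L ~ "compound_db",
                                TRUE ~ "none"),
      species_attribution = NA_character_,
      compartment = sample(COMPARTMENT_LEVELS, n_ann, replace = TRUE),
      polarity = cfg$polarity
    ))
    truth$fragmented <- tibble(
      feature_id = table$feature_id[chosen],
      precursor_mz = inc$precursor_mz,
      far_jitter = chosen %in% bad
    )
    truth$annotated <- tibble(
      feature_id = table$feature_id[chosen][ann_idx],
      msi_level = lev
    )
    list(inclusion = inc, annotations = ann, truth = truth)
  })
}

#' Generate logistic growth curves with a co-culture suppression factor
#'
#' `RFU(day) = K / (1 + exp(-r (day - t0))) * s + noise`, truncated at 0,
#' where `s = suppression` for co-culture series and 1 for mono-culture.
#' Optionally a per-day multiplicative factor on the co-culture mean models
#' late-onset deviations (e.g. a day-8-only increase).
#'
#' @param K Carrying capacity (RFU).
#' @param r Growth rate per day.
#' @param t0 Inflection day.
#' @param suppression Multiplicative co-culture factor in (0, 1].
#' @param noise_sd Gaussian noise sd (RFU).
#' @param replicates Named counts, `c(mono = 8, co = 4)`.
#' @param days Sampling days.
#' @param species Species label for the output.
#' @param co_day_factor Optional named numeric, e.g. `c("8" = 1.12)`: extra
#'   multiplicative factor on the co-culture mean for specific days.
#' @param seed Integer seed.
#' @return A [growth_series()] tibble.
#' @export
generate_growth_curves <- function(K = 3000, r = 0.8, t0 = 3, suppression = 1,
                                   noise_sd = 150,
                                   replicates = c(mono = 8, co = 4),
                                   days = c(0, 2, 4, 6, 8), species = "SM",
                                   co_day_factor = NULL, seed = NULL) {
  stopifnot(K > 0, noise_sd >= 0, suppression > 0, suppression <= 1)
  logistic <- K / (1 + exp(-r * (days - t0)))
  with_local_seed(seed, {
    rows <- map(CULTURE_LEVELS, function(cult) {
      n_rep <- replicates[[cult]]
      mu <- logistic * if (cult == "co") suppression else 1
      if (cult == "co" && !is.null(co_day_factor)) {
        idx <- match(names(co_day_factor), as.character(days))
        mu[idx] <- mu[idx] * co_day_factor
      }
      map(seq_len(n_rep), function(rep_i) {
        tibble(
          species = species, culture = cult, replicate = rep_i,
          day = as.integer(days),
          rfu = pmax(mu + rnorm(length(days), 0, noise_sd), 0)
        )
      }) |> list_rbind()
    })
    growth_series(list_rbind(rows))
  })
}

#' Generate the full growth study (both species)
#'
#' The diatom (`SM`) grows suppressed in co-culture; the haptophyte (`PP`)
#' is indistinguishable between conditions except for a late (day-8) increase
#' in co-culture -- the pattern the fluorescence data of the study design
#' exhibits.
#'
#' @param sm_suppression Co-culture suppression factor for SM (default 0.7).
#' @param pp_day8_factor Day-8 co-culture factor for PP (default 1.12).
#' @inheritParams generate_growth_curves
#' @return A [growth_series()] tibble covering both species.
#' @export
generate_growth_study <- function(K = 3000, r = 0.8, t0 = 3, noise_sd = 150,
                                  replicates = c(mono = 8, co = 4),
                                  sm_suppression = 0.7, pp_day8_factor = 1.12,
                                  seed = NULL) {
  with_local_seed(seed, {
    sm <- generate_growth_curves(K = K, r = r, t0 = t0,
                                 suppression = sm_suppression,
                                 noise_sd = noise_sd, replicates = replicates,
                                 species = "SM")
    pp <- generate_growth_curves(K = K, r = r, t0 = t0, suppression = 1,
                                 noise_sd = noise_sd, replicates = replicates,
                                 species = "PP",
                                 co_day_factor = c("8" = pp_day8_factor))
    growth_series(dplyr::bind_rows(sm, pp))
  })
}

#' Generate the complete synthetic input bundle
#'
#' One call producing every pipeline input: feature table, phenodata,
#' inclusion list, annotations, growth series, and the planted truth.
#'
#' @param config A [generator_config()].
#' @param fragment_fraction Fraction of features given inclusion entries.
#' @param growth_seed Seed for the growth series.
#' @return A list: `table`, `pheno`, `inclusion`, `annotations`, `growth`,
#'   `truth`.
#' @export
generate_study <- function(config = generator_config(), fragment_fraction = 0.3,
                           growth_seed = 4) {
  ds <- generate_feature_dataset(config)
  ia <- generate_inclusion_and_annotations(ds$table, ds$truth,
                                           fraction = fragment_fraction,
                                           seed = config$design_seed + 1000)
  growth <- generate_growth_study(seed = growth_seed)
  list(
    table = ds$table, pheno = ds$pheno,
    inclusion = ia$inclusion, annotations = ia$annotations,
    growth = growth, truth = ia$truth
  )
}

#' Write a synthetic input bundle to a directory
#'
#' @param bundle Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(bundle$table, file.path(dir, "feature_table.tsv"))
  write_phenodata(bundle$pheno, file.path(dir, "phenodata.tsv"))
  readr::write_delim(as_tibble(bundle$inclusion),
                     file.path(dir, "inclusion_list.tsv"), delim = "\t")
  readr::write_delim(as_tibble(bundle$annotations),
                     file.path(dir, "annotations.tsv"), delim = "\t")
  write_growth_series(bundle$growth, file.path(dir, "growth_series.tsv"))
  jsonlite::write_json(
    list(
      differential = bundle$truth$differential,
      exchange = bundle$truth$exchange,
      fragmented = bundle$truth$fragmented
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}
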