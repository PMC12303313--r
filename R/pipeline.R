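# Pipeline orchestration: preprocess -> diversity/ordination -> PLS selection
# -> annotation linking -> MSI tally -> suspect screen -> exchange inference
# -> growth statistics, with a machine-readable report.

REPORT_SCHEMA_VERSION <- "1"

#' Preprocess a feature table into transformed intensities and presence calls
#'
#' Log-transforms the table and derives one presence/absence cutoff per
#' (compartment, polarity) dataset from the pooled positive transformed
#' intensities of that dataset's samples (lower normal tail at `q`), then
#' binarizes each dataset's columns at its own cutoff. Per-sample cutoffs are
#' deliberately not used: one cutoff per dataset keeps presence calls
#' comparable across the samples being contrasted.
#'
#' @param table A raw-intensity [feature_table()].
#' @param pheno A [phenodata()].
#' @param q Lower-tail probability for the cutoff (default 0.05).
#' @param base Log base (default 2).
#' @return A list: `transformed` ([feature_table()]), `presence`
#'   (`presence_matrix` spanning all samples), `cutoffs` (tibble
#'   `compartment`, `polarity`, `cutoff`).
#' @export
preprocess_dataset <- function(table, pheno, q = 0.05, base = 2) {
  check_samples_covered(table, pheno)
  transformed <- log_transform(table, base = base)
  datasets <- dplyr::distinct(
    as_tibble(pheno)[pheno$sample_id %in% sample_ids(table), ],
    .data$compartment, .data$polarity
  )
  pres <- tibble(feature_id = table$feature_id)
  cutoffs <- list()
  for (i in seq_len(nrow(datasets))) {
    ids <- pheno$sample_id[pheno$compartment == datasets$compartment[i] &
                             pheno$polarity == datasets$polarity[i] &
                             pheno$sample_id %in% sample_ids(table)]
    vals <- unlist(as_tibble(transformed)[, ids], use.names = FALSE)
    cutoff <- estimate_presence_cutoff(vals, q = q)
    sub <- to_presence_matrix(transformed, cutoff)
    for (s in ids) pres[[s]] <- sub[[s]]
    cutoffs[[i]] <- tibble(compartment = datasets$compartment[i],
                           polarity = datasets$polarity[i],
                           cutoff = as.numeric(cutoff))
  }
  presence <- structure(
    pres[, c("feature_id", sample_ids(table))],
    class = c("presence_matrix", class(pres)),
    cutoff = NA_real_, cutoff_method = "per compartment x polarity dataset",
    q = q
  )
  list(transformed = transformed, presence = presence,
       cutoffs = list_rbind(cutoffs))
}

#' Pipeline configuration
#'
#' @param inputs Either a named list of in-memory objects (`table`, `pheno`,
#'   and optionally `inclusion`, `annotations`, `suspects`, `growth`) or a
#'   named list of file paths to the corresponding delimited files.
#' @param q Presence-cutoff tail probability.
#' @param log_base Log base for the transform.
#' @param components,tune_length,folds,quantile PLS selection parameters.
#' @param min_fraction Replicate fraction for condition-level presence.
#' @param ppm_tol Annotation-to-inclusion precursor tolerance (ppm).
#' @param alpha ANOVA significance level.
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs, q = 0.05, log_base = 2, components = 5,
                            tune_length = 10, folds = 5, quantile = 0.95,
                            min_fraction = 0.5, ppm_tol = 5, alpha = 0.05,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_inputs <- function(inputs) {
  get_in <- function(name, reader) {
    x <- inputs[[name]]
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1) reader(x) else x
  }
  list(
    table = get_in("table", read_feature_table),
    pheno = get_in("pheno", read_phenodata),
    inclusion = get_in("inclusion", read_inclusion_list),
    annotations = get_in("annotations", read_annotations),
    suspects = get_in("suspects", read_suspect_list),
    growth = get_in("growth", read_growth_series)
  )
}

#' Run the full co-culture analysis pipeline
#'
#' Executes, in order: preprocessing (log transform + presence calls),
#' chemodiversity, PCA ordination (including the combined-monoculture
#' comparison on the exometabolome), PLS-VIP selection per
#' (species, compartment) contrast, inclusion-list linking, MSI tally,
#' suspect screening, exchange inference (both focal species), and growth
#' statistics. Stages whose inputs are absent are reported with status
#' `"skipped"`; every executed stage's parameters are echoed into the report.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: named list of stage sections plus
#'   `parameters` and `schema_version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- load_inputs(config$inputs)
  if (is.null(inp$table) || is.null(inp$pheno)) {
    abort("pipeline needs at least a feature table and phenodata",
          class = "cocultr_validation_error")
  }
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    parameters = config[setdiff(names(config), "inputs")]
  )

  # 1. preprocess
  prep <- preprocess_dataset(inp$table, inp$pheno, q = config$q,
                             base = config$log_base)
  report$preprocess <- list(
    status = "ok",
    n_features = nrow(inp$table),
    n_samples = length(sample_ids(inp$table)),
    cutoffs = prep$cutoffs
  )

  # 2. diversity
  div <- group_diversity(prep$presence, inp$pheno)
  report$diversity <- list(status = "ok", table = div)

  # 3. ordination
  pca_all <- pca_feature_table(prep$transformed, inp$pheno, transformed = TRUE,
                               n_components = 2)
  comb <- tryCatch(
    combined_mono_pca(inp$table, inp$pheno, compartment = "exo",
                      polarity = inp$pheno$polarity[1], n_components = 2),
    error = function(e) NULL
  )
  report$ordination <- list(
    status = "ok",
    explained_fraction = pca_all$explained_fraction,
    scores = pca_all$scores,
    combined_mono = if (is.null(comb)) NULL else list(
      explained_fraction = comb$explained_fraction,
      scores = comb$scores
    )
  )

  # 4. PLS selection per contrast
  contrasts <- tidyr::expand_grid(species = c("SM", "PP"),
                                  compartment = COMPARTMENT_LEVELS)
  selections <- pmap(contrasts, function(species, compartment) {
    tryCatch(
      select_differential(prep$transformed, inp$pheno, species, compartment,
                          transformed = TRUE, components = config$components,
                          tune_length = config$tune_length,
                          folds = config$folds, quantile = config$quantile,
                          seed = config$seed),
      error = function(e) NULL
    )
  })
  sel_all <- list_rbind(map(purrr::compact(selections), as_tibble))
  differential <- sel_all[sel_all$selected, c("feature_id", "species", "compartment", "direction")]
  report$selection <- list(
    status = "ok",
    counts = dplyr::count(differential, .data$species, .data$compartment,
                          .data$direction),
    selected = differential
  )

  # 5-7. linking, MSI tally, suspect screen
  if (!is.null(inp$inclusion)) {
    link_map <- link_inclusion_to_features(inp$inclusion, inp$table)
    linked <- if (!is.null(inp$annotations)) {
      link_annotations_to_features(inp$annotations, link_map,
                                   ppm_tol = config$ppm_tol)
    } else NULL
    report$linking <- list(
      status = "ok",
      n_inclusion = nrow(link_map),
      status_counts = dplyr::count(link_map, .data$match_status),
      link_map = link_map
    )
    report$msi_tally <- if (is.null(linked)) {
      list(status = "skipped", reason = "no annotations")
    } else {
      list(status = "ok", table = tally_msi_levels(linked, differential))
    }
    report$suspect_screen <- if (is.null(linked) || is.null(inp$suspects)) {
      list(status = "skipped", reason = "no annotations or suspect list")
    } else {
      list(status = "ok", matches = screen_suspects(linked, inp$suspects))
    }
  } else {
    report$linking <- list(status = "skipped", reason = "no inclusion list")
    report$msi_tally <- list(status = "skipped", reason = "no inclusion list")
    report$suspect_screen <- list(status = "skipped", reason = "no inclusion list")
  }

  # 8. exchange inference
  cond_pres <- condition_presence(prep$presence, inp$pheno,
                                  min_fraction = config$min_fraction)
  exch <- map(c("SM", "PP"), function(focal) {
    feats <- differential$feature_id[differential$species == focal &
                                       differential$compartment == "endo" &
                                       differential$direction == "co-enriched"]
    if (length(feats) == 0) return(NULL)
    classify_exchange(feats, cond_pres, focal)
  })
  exch_all <- list_rbind(map(purrr::compact(exch), as_tibble))
  report$exchange <- if (nrow(exch_all) == 0) {
    list(status = "skipped", reason = "no differential endometabolome features")
  } else {
    s <- summarize_exchange(exch_all)
    list(status = "ok", results = exch_all, crosstab = s$counts, total = s$total)
  }

  # 9. growth statistics
  report$growth <- if (is.null(inp$growth)) {
    list(status = "skipped", reason = "no growth series")
  } else {
    per_species <- map(intersect(unique(inp$growth$species), c("SM", "PP")),
                       function(sp) {
      an <- two_way_anova(inp$growth, species = sp, alpha = config$alpha)
      list(species = sp, anova = tidy(an), welch = welch_by_day(inp$growth, sp))
    })
    list(status = "ok", per_species = per_species)
  }

  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  stages <- setdiff(names(x), c("schema_version", "parameters"))
  cat("pipeline report (schema", x$schema_version, ")\n")
  for (s in stages) cat(sprintf("  %-15s %s\n", s, x[[s]]$status))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full report; tibbles as column-wise JSON) and one
#' TSV per tabular stage output. Output is deterministic: no timestamps, so
#' re-running on identical inputs is byte-identical.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  ok <- tryCatch({
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !dir.exists(dir)) {
    abort(paste0("cannot create output directory: ", dir), class = "cocultr_io_error")
  }
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), paths[1], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  emit <- function(tbl, name) {
    if (is.null(tbl) || nrow(tbl) == 0) return(invisible(NULL))
    p <- file.path(dir, name)
    readr::write_delim(as_tibble(tbl), p, delim = "\t")
    paths <<- c(paths, p)
  }
  emit(report$diversity$table, "diversity.tsv")
  emit(report$selection$selected, "differential_features.tsv")
  if (identical(report$linking$status, "ok")) {
    emit(report$linking$link_map, "link_map.tsv")
  }
  if (identical(report$msi_tally$status, "ok")) {
    emit(report$msi_tally$table, "msi_tally.tsv")
  }
  if (identical(report$exchange$status, "ok")) {
    emit(report$exchange$results, "exchange_results.tsv")
    emit(report$exchange$crosstab, "exchange_crosstab.tsv")
  }
  if (identical(report$growth$status, "ok")) {
    for (g in report$growth$per_species) {
      emit(g$anova, paste0("anova_", g$species, ".tsv"))
      emit(g$welch, paste0("welch_", g$species, ".tsv"))
    }
  }
  invisible(paths)
}
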