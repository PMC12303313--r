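# Metabolic-exchange inference: classify each differentially produced
# co-culture endometabolome feature by its occurrence pattern across the
# partner species' conditions.

#' Condition-level presence from replicate presence calls
#'
#' A feature is present in a (species, compartment, culture) condition iff it
#' is present in strictly more than `min_fraction` of that condition's
#' replicates (strict majority at the default 0.5; `min_fraction = 0` means
#' any single replicate suffices).
#'
#' @param presence A `presence_matrix` from [to_presence_matrix()].
#' @param pheno A [phenodata()] covering its samples.
#' @param min_fraction Replicate fraction that must be exceeded (default 0.5).
#' @return A `condition_presence` tibble: `feature_id` plus one 0/1 column
#'   per condition, named `<species>_<compartment>_<culture>`.
#' @export
condition_presence <- function(presence, pheno, min_fraction = 0.5) {
  stopifnot(inherits(presence, "presence_matrix"), inherits(pheno, "phenodata"))
  m <- presence_values(presence)
  ph <- as_tibble(pheno)[pheno$sample_id %in% colnames(m) & pheno$species != "BLANK", ]
  conds <- dplyr::distinct(ph, .data$species, .data$compartment, .data$culture)
  out <- tibble(feature_id = rownames(m))
  for (i in seq_len(nrow(conds))) {
    ids <- ph$sample_id[ph$species == conds$species[i] &
                          ph$compartment == conds$compartment[i] &
                          ph$culture == conds$culture[i]]
    if (length(ids) == 0) {
      abort(paste0("condition with zero samples: ",
                   paste(conds[i, ], collapse = "_")),
            class = "cocultr_validation_error")
    }
    key <- paste(conds$species[i], conds$compartment[i], conds$culture[i], sep = "_")
    frac <- rowSums(m[, ids, drop = FALSE]) / length(ids)
    out[[key]] <- as.integer(frac > min_fraction)
  }
  structure(out, class = c("condition_presence", class(out)),
            min_fraction = min_fraction)
}

# Pure category rules on the partner-condition boolean pattern, in fixed
# precedence order. exo_co is recorded but excluded: the shared co-culture
# exometabolome cannot be attributed to either species.
classify_pattern <- function(exo_mono, endo_mono, endo_co, exo_co = NA) {
  if (!exo_mono && !endo_mono && !endo_co) return("EXCLUSIVE_CO")
  if (exo_mono && endo_mono && endo_co) return("SHARED_ALL")
  if (exo_mono && !endo_mono && !endo_co) return("PARTNER_RELEASED")
  if (!exo_mono && endo_mono && endo_co) return("PARTNER_ENDOGENOUS")
  "MIXED"
}

#' Classify differential co-culture endometabolome features by exchange pattern
#'
#' For each differentially produced feature of the focal species' co-culture
#' endometabolome, looks up its presence across the partner species'
#' conditions (exometabolome mono, endometabolome mono, endometabolome co;
#' the partner's co-culture exometabolome is recorded in the pattern but not
#' used by the rules) and assigns one category, evaluated in fixed order:
#'
#' * `EXCLUSIVE_CO` -- absent from every queried partner condition: produced
#'   only by the focal species in co-culture.
#' * `SHARED_ALL` -- present in all queried partner conditions.
#' * `PARTNER_RELEASED` -- present in the partner's mono-culture
#'   exometabolome but absent from its endometabolome: released by the
#'   partner and taken up.
#' * `PARTNER_ENDOGENOUS` -- present in the partner's mono- and co-culture
#'   endometabolome but not released in mono-culture.
#' * `MIXED` -- any other pattern (kept with its raw flags).
#'
#' @param differential Character vector of differential feature ids (the
#'   focal species' co-culture endometabolome selection).
#' @param presence A `condition_presence` from [condition_presence()].
#' @param focal Focal species (`"SM"` or `"PP"`); the partner is the other.
#' @return An `exchange_result` tibble: `feature_id`, `focal_species`,
#'   `partner_exo_mono`, `partner_endo_mono`, `partner_endo_co`,
#'   `partner_exo_co`, `category`.
#' @export
classify_exchange <- function(differential, presence, focal) {
  stopifnot(inherits(presence, "condition_presence"))
  if (!focal %in% c("SM", "PP")) {
    abort("focal species must be 'SM' or 'PP'", class = "cocultr_validation_error")
  }
  partner <- setdiff(c("SM", "PP"), focal)
  missing <- setdiff(differential, presence$feature_id)
  if (length(missing) > 0) {
    abort(paste0("differential feature(s) absent from presence table: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "cocultr_validation_error")
  }
  need <- paste0(partner, c("_exo_mono", "_endo_mono", "_endo_co", "_exo_co"))
  for (col in need[1:3]) {
    if (!col %in% names(presence)) {
      abort(paste0("presence table lacks partner condition ", col),
            class = "cocultr_validation_error")
    }
  }
  sub <- presence[match(differential, presence$feature_id), ]
  out <- tibble(
    feature_id = differential,
    focal_species = focal,
    partner_exo_mono = as.integer(sub[[need[1]]]),
    partner_endo_mono = as.integer(sub[[need[2]]]),
    partner_endo_co = as.integer(sub[[need[3]]]),
    partner_exo_co = if (need[4] %in% names(presence)) {
      as.integer(sub[[need[4]]])
    } else NA_integer_
  )
  out$category <- purrr::pmap_chr(
    out[, c("partner_exo_mono", "partner_endo_mono", "partner_endo_co")],
    function(partner_exo_mono, partner_endo_mono, partner_endo_co) {
      classify_pattern(partner_exo_mono == 1, partner_endo_mono == 1,
                       partner_endo_co == 1)
    }
  )
  structure(out, class = c("exchange_result", class(out)))
}

#' Summarize exchange categories
#'
#' Category counts for an [classify_exchange()] result, with the partition
#' identity asserted (every feature falls in exactly one category), plus the
#' cross-tab used for the exchange figure.
#'
#' @param results An `exchange_result` tibble (possibly covering both focal
#'   species).
#' @return A list with `counts` (tibble `focal_species` x `category` x `n`,
#'   all categories present including zeros) and `total`.
#' @export
summarize_exchange <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    counts <- tidyr::expand_grid(
      focal_species = character(0), category = EXCHANGE_CATEGORIES
    ) |> dplyr::mutate(n = integer(0))
    return(list(counts = counts[0, ], total = 0L))
  }
  df <- as_tibble(results)
  counts <- tidyr::expand_grid(
    focal_species = unique(df$focal_species),
    category = EXCHANGE_CATEGORIES
  ) |>
    dplyr::left_join(
      dplyr::count(df, .data$focal_species, .data$category),
      by = c("focal_species", "category")
    ) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
  stopifnot(sum(counts$n) == nrow(df))
  list(counts = counts, total = nrow(df))
}
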