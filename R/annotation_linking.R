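# Resolve MS2 annotations to MS1 feature ids through the DDA inclusion list,
# tally MSI confidence levels, and screen annotations against suspect lists.

# Pick the best candidate among features enclosing a precursor:
# smallest |mz_med - precursor|, then |rt_med - window midpoint|, then
# feature_id (so the result is independent of row order).
order_candidates <- function(cand, precursor_mz, rt_mid) {
  cand[order(abs(cand$mz_med - precursor_mz),
             abs(cand$rt_med - rt_mid),
             cand$feature_id), , drop = FALSE]
}

#' Link inclusion-list precursors to MS1 features
#'
#' For each inclusion precursor, candidate features are those whose m/z
#' envelope encloses the precursor (`mz_min <= precursor_mz <= mz_max`).
#' Among candidates, the link is `full` when the feature's median retention
#' time falls inside the inclusion retention window, otherwise `mz_only` with
#' a comment recording the mismatch; a precursor with no enclosing envelope
#' is `unlinked`. When several features qualify, the one with the smallest
#' `|mz_med - precursor_mz|` (then `|rt_med - window midpoint|`) wins and the
#' losing candidates are listed in the comment.
#'
#' @param inclusion An [inclusion_list()] tibble.
#' @param features A [feature_table()] of the same polarity dataset.
#' @return A `link_map` tibble: one row per inclusion entry with
#'   `precursor_mz`, `rt_min_s`, `rt_max_s`, `polarity`, `feature_id`
#'   (NA when unlinked), `match_status` (`full`/`mz_only`/`unlinked`),
#'   `comment`.
#' @export
link_inclusion_to_features <- function(inclusion, features) {
  stopifnot(inherits(inclusion, "inclusion_list"))
  if (!inherits(features, "feature_table") || nrow(features) == 0) {
    abort("empty or invalid feature table", class = "cocultr_empty_error")
  }
  feats <- as_tibble(features)[, c("feature_id", ENVELOPE_COLS)]
  rows <- pmap(as_tibble(inclusion), function(precursor_mz, rt_min_s, rt_max_s,
                                              polarity, ...) {
    cand <- feats[feats$mz_min <= precursor_mz & precursor_mz <= feats$mz_max, ]
    base <- tibble(precursor_mz = precursor_mz, rt_min_s = rt_min_s,
                   rt_max_s = rt_max_s, polarity = polarity)
    if (nrow(cand) == 0) {
      return(dplyr::mutate(base, feature_id = NA_character_,
                           match_status = "unlinked", comment = ""))
    }
    rt_mid <- (rt_min_s + rt_max_s) / 2
    rt_ok <- cand[cand$rt_med >= rt_min_s & cand$rt_med <= rt_max_s, ]
    if (nrow(rt_ok) > 0) {
      ranked <- order_candidates(rt_ok, precursor_mz, rt_mid)
      status <- "full"
      note <- ""
    } else {
      ranked <- order_candidates(cand, precursor_mz, rt_mid)
      status <- "mz_only"
      note <- paste0("rt_med ", signif(ranked$rt_med[1], 6), " outside [",
                     rt_min_s, ", ", rt_max_s, "]")
    }
    losers <- setdiff(ranked$feature_id, ranked$feature_id[1])
    if (length(losers) > 0) {
      note <- paste0(note, if (nzchar(note)) "; " else "",
                     "other m/z candidates: ", paste(losers, collapse = ", "))
    }
    dplyr::mutate(base, feature_id = ranked$feature_id[1],
                  match_status = status, comment = note)
  })
  out <- list_rbind(rows)
  structure(out, class = c("link_map", class(out)))
}

#' Link MS2 annotations to MS1 features through the inclusion list
#'
#' Each annotation is matched to an inclusion precursor under the same
#' conditions used for feature linking: the annotation precursor must lie
#' within `ppm_tol` ppm of the inclusion precursor and the annotation
#' retention time inside the inclusion retention window. Matched annotations
#' inherit the inclusion entry's feature id and match status; unmatched
#' annotations are kept with status `unlinked` (no annotation is dropped).
#'
#' @param annotations An [annotation_table()] tibble.
#' @param link_map Output of [link_inclusion_to_features()] for the same
#'   polarity dataset.
#' @param ppm_tol Precursor m/z tolerance in ppm (default 5).
#' @return A `linked_annotations` tibble: annotation columns plus
#'   `feature_id`, `match_status`, `comment`.
#' @export
link_annotations_to_features <- function(annotations, link_map, ppm_tol = 5) {
  stopifnot(inherits(annotations, "annotation_table"), inherits(link_map, "link_map"))
  ann <- as_tibble(annotations)
  rows <- map(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    tol <- ppm_tol * 1e-6 * link_map$precursor_mz
    hit <- abs(a$precursor_mz - link_map$precursor_mz) <= tol &
      a$rt >= link_map$rt_min_s & a$rt <= link_map$rt_max_s
    if (!any(hit)) {
      return(dplyr::mutate(a, feature_id = NA_character_,
                           match_status = "unlinked", comment = ""))
    }
    cand <- link_map[hit, ]
    cand <- cand[order(abs(cand$precursor_mz - a$precursor_mz)), ]
    dplyr::mutate(a, feature_id = cand$feature_id[1],
                  match_status = cand$match_status[1],
                  comment = cand$comment[1])
  })
  out <- list_rbind(rows)
  structure(out, class = c("linked_annotations", class(out)))
}

#' Tally annotations per condition and MSI confidence level
#'
#' Counts annotated features per experimental condition
#' (compartment x polarity): total, MSI level 2 (spectral-database match),
#' MSI level 3 (compound-database candidate), MSI levels 4 and 5 pooled, and
#' -- when a differential-feature table is supplied -- how many annotations
#' fall on differential features of each species.
#'
#' @param linked A `linked_annotations` tibble.
#' @param differential Optional tibble with columns `feature_id` and
#'   `species` listing differentially produced features (e.g. stacked
#'   [select_differential()] results filtered to `selected`).
#' @return Tibble with one row per condition: `condition`, `total`, `msi2`,
#'   `msi3`, `msi45`, `n_differential_SM`, `n_differential_PP`.
#' @export
tally_msi_levels <- function(linked, differential = NULL) {
  empty <- tibble(
    condition = character(), total = integer(), msi2 = integer(),
    msi3 = integer(), msi45 = integer(),
    n_differential_SM = integer(), n_differential_PP = integer()
  )
  if (is.null(linked) || nrow(linked) == 0) return(empty)
  df <- as_tibble(linked)
  cond <- if (all(c("compartment", "polarity") %in% names(df)) &&
              !all(is.na(df$compartment))) {
    paste0(df$compartment, "_", df$polarity)
  } else {
    rep("all", nrow(df))
  }
  df$condition <- cond
  diff_sm <- if (!is.null(differential)) {
    unique(differential$feature_id[differential$species == "SM"])
  } else character()
  diff_pp <- if (!is.null(differential)) {
    unique(differential$feature_id[differential$species == "PP"])
  } else character()
  df |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      total = dplyr::n(),
      msi2 = sum(.data$msi_level == 2L),
      msi3 = sum(.data$msi_level == 3L),
      msi45 = sum(.data$msi_level %in% c(4L, 5L)),
      n_differential_SM = sum(!is.na(.data$feature_id) & .data$feature_id %in% diff_sm),
      n_differential_PP = sum(!is.na(.data$feature_id) & .data$feature_id %in% diff_pp),
      .groups = "drop"
    )
}

# Structure key for suspect screening: the InChIKey connectivity block
# (first 14 characters) via OpenBabel when ChemmineOB is available,
# otherwise a normalized-SMILES fallback key (exact-string level only).
structure_key <- function(smiles, inchi = NULL) {
  n <- length(smiles)
  if (is.null(inchi)) inchi <- rep(NA_character_, n)
  keys <- rep(NA_character_, n)
  has_ob <- requireNamespace("ChemmineOB", quietly = TRUE)
  if (has_ob) {
    conv <- function(src, from) {
      tryCatch({
        out <- ChemmineOB::convertFormat(from = from, to = "inchikey", source = src)
        key <- stringr::str_trim(strsplit(out, "\n")[[1]][1])
        if (nchar(key) >= 14) substr(key, 1, 14) else NA_character_
      }, error = function(e) NA_character_)
    }
    for (i in seq_len(n)) {
      if (!is.na(inchi[i]) && nzchar(inchi[i])) {
        keys[i] <- conv(inchi[i], "INCHI")
      }
      if (is.na(keys[i]) && !is.na(smiles[i]) && nzchar(smiles[i])) {
        keys[i] <- conv(smiles[i], "SMI")
      }
    }
  }
  fallback <- is.na(keys) & !is.na(smiles) & nzchar(smiles)
  keys[fallback] <- paste0("SMI:", toupper(gsub("\\s+", "", smiles[fallback])))
  keys
}

#' Screen linked annotations against suspect lists
#'
#' Matches annotations to suspect-list entries at two levels, strongest
#' first: structure-key equality (InChIKey connectivity block when OpenBabel
#' conversion is available, exact normalized SMILES otherwise), then
#' case-insensitive name equality. A name-level match whose structures are
#' present but disagree is kept and flagged. Each match carries the suspect
#' entry's source-species tag.
#'
#' @param linked A `linked_annotations` tibble (or any tibble with `name`,
#'   `smiles` and optionally `feature_id` columns).
#' @param suspects A [read_suspect_list()] tibble.
#' @return Tibble of matches: `annotation_name`, `feature_id`,
#'   `suspect_name`, `match_level` (`structure`/`name`), `source_species`,
#'   `structure_mismatch`.
#' @export
screen_suspects <- function(linked, suspects) {
  ann <- as_tibble(linked)
  sus <- as_tibble(suspects)
  if (nrow(ann) == 0 || nrow(sus) == 0) {
    return(tibble(
      annotation_name = character(), feature_id = character(),
      suspect_name = character(), match_level = character(),
      source_species = character(), structure_mismatch = logical()
    ))
  }
  if (!"feature_id" %in% names(ann)) ann$feature_id <- NA_character_
  ann_key <- structure_key(ann$smiles)
  sus_key <- structure_key(sus$smiles, sus$inchi)
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    hit_struct <- !is.na(ann_key[i]) & !is.na(sus_key) & sus_key == ann_key[i]
    hit_name <- !is.na(ann$name[i]) & !is.na(sus$name) &
      tolower(trimws(sus$name)) == tolower(trimws(ann$name[i]))
    for (j in which(hit_struct)) {
      rows[[length(rows) + 1]] <- tibble(
        annotation_name = ann$name[i], feature_id = ann$feature_id[i],
        suspect_name = sus$name[j], match_level = "structure",
        source_species = sus$source_species[j], structure_mismatch = FALSE
      )
    }
    for (j in which(hit_name & !hit_struct)) {
      mismatch <- !is.na(ann_key[i]) && !is.na(sus_key[j]) && ann_key[i] != sus_key[j]
      rows[[length(rows) + 1]] <- tibble(
        annotation_name = ann$name[i], feature_id = ann$feature_id[i],
        suspect_name = sus$name[j], match_level = "name",
        source_species = sus$source_species[j], structure_mismatch = mismatch
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      annotation_name = character(), feature_id = character(),
      suspect_name = character(), match_level = character(),
      source_species = character(), structure_mismatch = logical()
    ))
  }
  list_rbind(rows)
}
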