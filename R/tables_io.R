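# Readers, validators and writers for the pipeline's tabular inputs/outputs.
#
# All tables are tibbles. A feature table carries the seven m/z / retention
# time envelope columns followed by one numeric intensity column per sample;
# matrices are always addressed by sample_id, never by column position.

ENVELOPE_COLS <- c("mz_min", "mz_med", "mz_max", "rt_min", "rt_med", "rt_max")
PHENO_COLS <- c("sample_id", "species", "compartment", "culture", "polarity", "replicate")

# Delimiter auto-detection from file extension, overridable.
detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", "\t")
}

read_delim_quiet <- function(path, sep) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "cocultr_io_error")
  }
  readr::read_delim(
    path,
    delim = sep, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE, na = c("", "NA", "n/a", "N/A")
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      paste0(what, " is missing required column(s): ", paste(missing, collapse = ", ")),
      class = "cocultr_schema_error"
    )
  }
  invisible(df)
}

# Case-insensitive enum normalization with an informative error.
normalize_enum <- function(x, levels, field) {
  up <- toupper(trimws(as.character(x)))
  lut <- setNames(levels, toupper(levels))
  out <- unname(lut[up])
  bad <- unique(x[is.na(out) & !is.na(x)])
  if (length(bad) > 0) {
    abort(
      paste0(
        "unknown ", field, " token(s): ", paste(bad, collapse = ", "),
        "; allowed: {", paste(levels, collapse = ", "), "}"
      ),
      class = "cocultr_validation_error"
    )
  }
  out
}

#' Construct and validate a feature table
#'
#' A feature table holds one row per LC-MS feature: an opaque `feature_id`,
#' the m/z envelope (`mz_min`, `mz_med`, `mz_max`, in Th), the retention-time
#' envelope (`rt_min`, `rt_med`, `rt_max`, in seconds) and one non-negative
#' intensity column per sample. Intensity 0 is the canonical missing value.
#'
#' @param df A data frame with `feature_id`, the six envelope columns and at
#'   least one sample intensity column.
#' @return A tibble of class `feature_table`.
#' @export
feature_table <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("feature_id", ENVELOPE_COLS), "feature table")
  sample_cols <- setdiff(names(df), c("feature_id", ENVELOPE_COLS))
  if (length(sample_cols) == 0) {
    abort("feature table has no sample intensity columns", class = "cocultr_schema_error")
  }
  df$feature_id <- as.character(df$feature_id)
  if (anyDuplicated(df$feature_id)) {
    abort(
      paste0(
        "duplicate feature_id: ",
        paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", ")
      ),
      class = "cocultr_duplicate_error"
    )
  }
  for (col in c(ENVELOPE_COLS, sample_cols)) {
    if (!is.numeric(df[[col]])) {
      bad <- df[[col]][is.na(suppressWarnings(as.numeric(df[[col]])))]
      bad <- bad[!is.na(bad)]
      if (length(bad) > 0) {
        abort(
          paste0("non-numeric values in column ", col, ": ", paste(head(bad, 3), collapse = ", ")),
          class = "cocultr_validation_error"
        )
      }
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  # blank intensity cells are missing values, imputed to 0
  for (col in sample_cols) {
    df[[col]][is.na(df[[col]])] <- 0
  }
  bad_mz <- which(!(df$mz_min <= df$mz_med & df$mz_med <= df$mz_max))
  if (length(bad_mz) > 0) {
    abort(
      paste0("m/z envelope violated (mz_min <= mz_med <= mz_max) for feature_id: ",
             paste(df$feature_id[bad_mz], collapse = ", ")),
      class = "cocultr_validation_error"
    )
  }
  bad_rt <- which(!(df$rt_min <= df$rt_med & df$rt_med <= df$rt_max))
  if (length(bad_rt) > 0) {
    abort(
      paste0("retention-time envelope violated for feature_id: ",
             paste(df$feature_id[bad_rt], collapse = ", ")),
      class = "cocultr_validation_error"
    )
  }
  neg <- sample_cols[map_lgl(sample_cols, function(s) any(df[[s]] < 0))]
  if (length(neg) > 0) {
    abort(
      paste0("negative intensities in sample(s): ", paste(neg, collapse = ", ")),
      class = "cocultr_validation_error"
    )
  }
  structure(df, class = c("feature_table", class(df)))
}

#' Sample columns of a feature table
#' @param table A [feature_table()].
#' @return Character vector of sample ids, in file order.
#' @export
sample_ids <- function(table) {
  setdiff(names(table), c("feature_id", ENVELOPE_COLS))
}

#' Intensity matrix of a feature table
#' @param table A [feature_table()].
#' @return Numeric matrix, features x samples, dimnames from feature/sample ids.
#' @export
intensity_matrix <- function(table) {
  m <- as.matrix(table[, sample_ids(table), drop = FALSE])
  rownames(m) <- table$feature_id
  m
}

#' Read a feature table from a delimited file
#'
#' @param path File path (TSV or CSV; delimiter auto-detected from extension).
#' @param sep Optional delimiter override.
#' @param rt_minutes If `TRUE`, retention times in the file are minutes and
#'   are converted to seconds on ingest.
#' @return A validated [feature_table()]. Blank intensity cells read as 0.
#' @export
read_feature_table <- function(path, sep = NULL, rt_minutes = FALSE) {
  df <- read_delim_quiet(path, detect_sep(path, sep))
  require_columns(df, c("feature_id", ENVELOPE_COLS), "feature table")
  if (isTRUE(rt_minutes)) {
    for (col in c("rt_min", "rt_med", "rt_max")) df[[col]] <- df[[col]] * 60
  }
  feature_table(df)
}

#' Write a feature table
#' @param table A [feature_table()].
#' @param path Output path; delimiter from extension.
#' @param sep Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = NULL) {
  readr::write_delim(as_tibble(table), path, delim = detect_sep(path, sep))
  invisible(path)
}

#' Construct and validate a phenodata table
#'
#' Maps each sample to its design cell: species (`SM`, `PP`, `BLANK`),
#' compartment (`endo`/`exo`), culture (`mono`/`co`), ionization polarity
#' (`pos`/`neg`) and replicate index. Blank samples carry `culture = "mono"`
#' by convention.
#'
#' @param df Data frame with columns `sample_id`, `species`, `compartment`,
#'   `culture`, `polarity`, `replicate`.
#' @return A tibble of class `phenodata`.
#' @export
phenodata <- function(df) {
  df <- as_tibble(df)
  require_columns(df, PHENO_COLS, "phenodata")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    abort(
      paste0("duplicate sample_id: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")),
      class = "cocultr_duplicate_error"
    )
  }
  df$species <- normalize_enum(df$species, SPECIES_LEVELS, "species")
  df$compartment <- normalize_enum(df$compartment, COMPARTMENT_LEVELS, "compartment")
  df$culture <- normalize_enum(df$culture, CULTURE_LEVELS, "culture")
  df$polarity <- normalize_enum(df$polarity, POLARITY_LEVELS, "polarity")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1)) {
    abort("replicate must be a positive integer", class = "cocultr_validation_error")
  }
  key <- paste(df$species, df$compartment, df$culture, df$polarity, df$replicate)
  if (anyDuplicated(key)) {
    abort(
      paste0("duplicate design cell (species, compartment, culture, polarity, replicate): ",
             paste(unique(key[duplicated(key)]), collapse = "; ")),
      class = "cocultr_duplicate_error"
    )
  }
  structure(df, class = c("phenodata", class(df)))
}

#' Read a phenodata table
#' @inheritParams read_feature_table
#' @return A validated [phenodata()] tibble; enum tokens normalized
#'   case-insensitively.
#' @export
read_phenodata <- function(path, sep = NULL) {
  phenodata(read_delim_quiet(path, detect_sep(path, sep)))
}

#' Write a phenodata table
#' @param pheno A [phenodata()] tibble.
#' @inheritParams write_feature_table
#' @return `path`, invisibly.
#' @export
write_phenodata <- function(pheno, path, sep = NULL) {
  readr::write_delim(as_tibble(pheno), path, delim = detect_sep(path, sep))
  invisible(path)
}

# Check that every sample column of a feature table has a phenodata row.
check_samples_covered <- function(table, pheno) {
  missing <- setdiff(sample_ids(table), pheno$sample_id)
  if (length(missing) > 0) {
    abort(
      paste0("sample column(s) without a phenodata row: ", paste(missing, collapse = ", ")),
      class = "cocultr_validation_error"
    )
  }
  invisible(TRUE)
}

#' Read chlorophyll-a fluorescence growth series
#'
#' Accepts the wide layout (columns `species`, `culture`, `replicate`, then
#' one column per sampling day named `d0`, `d2`, ... in relative fluorescence
#' units) or an already-long layout with columns `day` and `rfu`.
#'
#' @inheritParams read_feature_table
#' @return A long tibble of class `growth_series` with columns `species`,
#'   `culture`, `replicate`, `day` (integer), `rfu`.
#' @export
read_growth_series <- function(path, sep = NULL) {
  df <- read_delim_quiet(path, detect_sep(path, sep))
  require_columns(df, c("species", "culture", "replicate"), "growth series")
  if (!all(c("day", "rfu") %in% names(df))) {
    day_cols <- grep("^d[0-9]+$", names(df), value = TRUE)
    if (length(day_cols) == 0) {
      abort("growth series needs day/rfu columns or wide d0..d8 columns",
            class = "cocultr_schema_error")
    }
    df <- tidyr::pivot_longer(df, dplyr::all_of(day_cols),
                              names_to = "day", values_to = "rfu")
    df$day <- as.integer(sub("^d", "", df$day))
  }
  growth_series(df)
}

#' Construct and validate a growth series
#' @param df Long data frame with `species`, `culture`, `replicate`, `day`, `rfu`.
#' @return A tibble of class `growth_series`.
#' @export
growth_series <- function(df) {
  df <- as_tibble(df)[, c("species", "culture", "replicate", "day", "rfu")]
  df$species <- normalize_enum(df$species, SPECIES_LEVELS, "species")
  df$culture <- normalize_enum(df$culture, CULTURE_LEVELS, "culture")
  df$replicate <- as.integer(df$replicate)
  df$day <- as.integer(df$day)
  if (!all(df$day %in% c(0L, 2L, 4L, 6L, 8L))) {
    abort("growth-series days must be a subset of {0, 2, 4, 6, 8}",
          class = "cocultr_validation_error")
  }
  if (any(!is.finite(df$rfu)) || any(df$rfu < 0)) {
    abort("RFU values must be finite and >= 0", class = "cocultr_validation_error")
  }
  structure(df, class = c("growth_series", class(df)))
}

#' Write a growth series (wide S1-style layout)
#' @param series A [growth_series()] tibble.
#' @inheritParams write_feature_table
#' @return `path`, invisibly.
#' @export
write_growth_series <- function(series, path, sep = NULL) {
  wide <- tidyr::pivot_wider(
    as_tibble(series),
    names_from = "day", values_from = "rfu", names_prefix = "d"
  )
  readr::write_delim(wide, path, delim = detect_sep(path, sep))
  invisible(path)
}

#' Read a suspect list
#'
#' A suspect list catalogues metabolites known for an organism: name, formula,
#' monoisotopic mass (Da), SMILES and/or InChI, and the source species tag
#' (`SM`, `PP` or `BOTH`). At least one of name/SMILES/InChI must be present
#' per row; unparseable masses (e.g. "n/a") are kept as `NA`.
#'
#' @inheritParams read_feature_table
#' @return A tibble of class `suspect_list` with columns `name`, `formula`,
#'   `monoisotopic_mass`, `smiles`, `inchi`, `source_species`.
#' @export
read_suspect_list <- function(path, sep = NULL) {
  df <- read_delim_quiet(path, detect_sep(path, sep))
  names(df) <- tolower(names(df))
  if (!"name" %in% names(df)) {
    abort("suspect list needs a name column", class = "cocultr_schema_error")
  }
  out <- tibble(
    name = as.character(df$name),
    formula = if ("formula" %in% names(df)) as.character(df$formula) else NA_character_,
    monoisotopic_mass = if ("monoisotopic_mass" %in% names(df)) {
      suppressWarnings(as.numeric(df$monoisotopic_mass))
    } else NA_real_,
    smiles = if ("smiles" %in% names(df)) as.character(df$smiles) else NA_character_,
    inchi = if ("inchi" %in% names(df)) as.character(df$inchi) else NA_character_,
    source_species = if ("source_species" %in% names(df)) {
      normalize_enum(df$source_species, c("SM", "PP", "BOTH"), "source_species")
    } else NA_character_
  )
  keep <- !(is.na(out$name) & is.na(out$smiles) & is.na(out$inchi))
  out <- out[keep, ]
  if (nrow(out) == 0) {
    abort("suspect list has no parseable rows", class = "cocultr_empty_error")
  }
  if (any(!is.na(out$monoisotopic_mass) & out$monoisotopic_mass <= 0)) {
    abort("monoisotopic_mass must be > 0 when given", class = "cocultr_validation_error")
  }
  structure(out, class = c("suspect_list", class(out)))
}

#' Read a DDA inclusion list
#'
#' Columns: `precursor_mz` (Th), `rt_min_s`, `rt_max_s` (seconds), `polarity`.
#'
#' @inheritParams read_feature_table
#' @return A tibble of class `inclusion_list`.
#' @export
read_inclusion_list <- function(path, sep = NULL) {
  df <- read_delim_quiet(path, detect_sep(path, sep))
  inclusion_list(df)
}

#' Construct and validate an inclusion list
#' @param df Data frame with `precursor_mz`, `rt_min_s`, `rt_max_s`, `polarity`.
#' @return A tibble of class `inclusion_list`.
#' @export
inclusion_list <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("precursor_mz", "rt_min_s", "rt_max_s", "polarity"), "inclusion list")
  df$precursor_mz <- as.numeric(df$precursor_mz)
  df$rt_min_s <- as.numeric(df$rt_min_s)
  df$rt_max_s <- as.numeric(df$rt_max_s)
  df$polarity <- normalize_enum(df$polarity, POLARITY_LEVELS, "polarity")
  if (any(df$precursor_mz <= 0)) {
    abort("precursor_mz must be > 0", class = "cocultr_validation_error")
  }
  if (any(df$rt_min_s > df$rt_max_s)) {
    abort("inclusion rt_min_s must be <= rt_max_s", class = "cocultr_validation_error")
  }
  structure(df, class = c("inclusion_list", class(df)))
}

#' Read an annotation table (MS2 structure annotations)
#'
#' Mirrors the candidate-list export of an MS2 annotation workflow: precursor
#' m/z, retention time (s), SMILES, name, formula, ChemONT class, MSI level
#' (2-5), annotation source and the experimental condition fields.
#'
#' @inheritParams read_feature_table
#' @return A tibble of class `annotation_table`.
#' @export
read_annotations <- function(path, sep = NULL) {
  annotation_table(read_delim_quiet(path, detect_sep(path, sep)))
}

#' Construct and validate an annotation table
#' @param df Data frame with at least `precursor_mz`, `rt`, `msi_level`;
#'   optional `smiles`, `name`, `formula`, `chemont_class`, `source`,
#'   `species_attribution`, `compartment`, `polarity`.
#' @return A tibble of class `annotation_table`.
#' @export
annotation_table <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("precursor_mz", "rt", "msi_level"), "annotation table")
  for (col in c("smiles", "name", "formula", "chemont_class", "species_attribution",
                "compartment", "polarity")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$precursor_mz <- as.numeric(df$precursor_mz)
  df$rt <- as.numeric(df$rt)
  df$msi_level <- as.integer(df$msi_level)
  if (!all(df$msi_level %in% 2:5)) {
    abort("msi_level must be one of {2, 3, 4, 5}", class = "cocultr_validation_error")
  }
  src <- tolower(as.character(df$source))
  # MSI semantics: level 2 = spectral-database match, level 3 = compound-database
  bad2 <- which(df$msi_level == 2L & !is.na(src) & src != "spectral_db")
  bad3 <- which(df$msi_level == 3L & !is.na(src) & src != "compound_db")
  if (length(c(bad2, bad3)) > 0) {
    abort(
      paste0("msi_level/source inconsistency on row(s): ",
             paste(c(bad2, bad3), collapse = ", "),
             " (level 2 requires spectral_db, level 3 requires compound_db)"),
      class = "cocultr_validation_error"
    )
  }
  df$source <- src
  structure(df, class = c("annotation_table", class(df)))
}
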