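# Feature-table preprocessing: log transform, normal-tail presence cutoff,
# presence/absence matrix, and the combined-monoculture pseudo-replicates
# used for the ordination comparison against co-cultures.

#' Log-transform feature intensities
#'
#' Replaces every positive intensity by its logarithm; zeros (the canonical
#' missing value) stay 0. Raw intensities in (0, 1) would transform negative
#' and are floored to 0 with a warning, preserving missing-value semantics.
#'
#' @param table A [feature_table()] of raw intensities.
#' @param base Logarithm base (default 2, for fold-change interpretability).
#' @return A [feature_table()] on the transformed scale; envelope columns
#'   untouched.
#' @export
log_transform <- function(table, base = 2) {
  stopifnot(inherits(table, "feature_table"))
  samples <- sample_ids(table)
  out <- as_tibble(table)
  floored <- 0L
  for (s in samples) {
    x <- out[[s]]
    if (any(x < 0)) {
      abort(paste0("negative intensity in sample ", s), class = "cocultr_validation_error")
    }
    pos <- x > 0
    y <- x
    y[pos] <- log(x[pos], base = base)
    sub1 <- y < 0
    floored <- floored + sum(sub1)
    y[sub1] <- 0
    out[[s]] <- y
  }
  if (floored > 0) {
    warn(paste0(floored, " sub-1 raw intensities transformed negative; floored to 0"))
  }
  res <- feature_table(out)
  attr(res, "log_base") <- base
  attr(res, "transformed") <- TRUE
  res
}

#' Presence/absence cutoff from the lower normal tail
#'
#' Fits a normal distribution to the positive transformed intensities pooled
#' across all samples of one dataset and returns its lower `q` quantile,
#' `mu + z_q * sigma` (sample mean, n-1 denominator standard deviation;
#' `z_0.05 = -1.6449`). Intensities below this cutoff are treated as absent.
#'
#' @param values Numeric vector of transformed intensities (zeros ignored).
#' @param q Lower-tail probability (default 0.05).
#' @return The cutoff, a single number on the transformed scale, with
#'   attributes `mu`, `sigma`, `q`.
#' @export
estimate_presence_cutoff <- function(values, q = 0.05) {
  stopifnot(is.numeric(values), q > 0, q < 1)
  pos <- values[values > 0 & is.finite(values)]
  if (length(pos) == 0) {
    abort("all values are zero: no intensity distribution to fit",
          class = "cocultr_empty_error")
  }
  if (length(pos) < 2) {
    abort("need at least 2 positive values to fit a normal", class = "cocultr_validation_error")
  }
  mu <- mean(pos)
  sigma <- sd(pos)
  if (sigma == 0) {
    warn("degenerate intensity distribution (sigma = 0); cutoff set to the mean")
    cutoff <- mu
  } else {
    cutoff <- mu + qnorm(q) * sigma
  }
  structure(cutoff, mu = mu, sigma = sigma, q = q)
}

#' Binarize a transformed feature table at a cutoff
#'
#' @param table A transformed [feature_table()].
#' @param cutoff Intensity threshold on the transformed scale (see
#'   [estimate_presence_cutoff()]). An intensity exactly equal to the cutoff
#'   counts as present.
#' @return A `presence_matrix`: tibble with `feature_id` and one 0/1 column
#'   per sample; attributes `cutoff`, `cutoff_method`, `q`.
#' @export
to_presence_matrix <- function(table, cutoff) {
  stopifnot(inherits(table, "feature_table"), is.finite(cutoff))
  samples <- sample_ids(table)
  out <- tibble(feature_id = table$feature_id)
  for (s in samples) {
    out[[s]] <- as.integer(table[[s]] >= cutoff)
  }
  structure(
    out,
    class = c("presence_matrix", class(out)),
    cutoff = as.numeric(cutoff),
    cutoff_method = "normal lower tail on pooled positive transformed intensities",
    q = attr(cutoff, "q") %||% NA_real_
  )
}

#' Presence matrix as a 0/1 matrix
#' @param presence A `presence_matrix` from [to_presence_matrix()].
#' @return Integer matrix features x samples.
#' @export
presence_values <- function(presence) {
  m <- as.matrix(presence[, setdiff(names(presence), "feature_id"), drop = FALSE])
  rownames(m) <- presence$feature_id
  m
}

#' Write a presence matrix with its JSON sidecar
#' @param presence A `presence_matrix`.
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(presence, path) {
  readr::write_delim(as_tibble(presence), path, delim = "\t")
  jsonlite::write_json(
    list(
      cutoff = attr(presence, "cutoff"),
      method = attr(presence, "cutoff_method"),
      q = attr(presence, "q")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Combine mono-culture replicates into summed pseudo-replicates
#'
#' For the ordination comparison against co-cultures, the 8 mono-culture
#' replicates of a (species, compartment, polarity) group are paired by
#' ascending replicate index -- (1,2), (3,4), ... -- and each pair is summed
#' on the untransformed intensity scale, yielding half as many pseudo-samples
#' (ids suffixed `_comb1`, `_comb2`, ...). Total signal is conserved per
#' feature.
#'
#' @param table A [feature_table()] of raw (untransformed) intensities.
#' @param pheno A [phenodata()] covering the table's samples.
#' @param species,compartment,polarity The mono-culture group to combine.
#' @param pairing Optional list of integer pairs overriding the default
#'   ascending pairing, e.g. `list(c(1, 3), c(2, 4))`.
#' @return A list with `table` (a [feature_table()] of the pseudo-samples
#'   only) and `pheno` (their [phenodata()] rows, `culture = "mono"`).
#' @export
combine_monoculture_pairs <- function(table, pheno, species, compartment, polarity,
                                      pairing = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(pheno, "phenodata"))
  check_samples_covered(table, pheno)
  grp <- pheno[pheno$species == species & pheno$compartment == compartment &
                 pheno$polarity == polarity & pheno$culture == "mono" &
                 pheno$sample_id %in% sample_ids(table), ]
  if (nrow(grp) == 0) {
    abort(
      paste0("no mono-culture samples for group (", species, ", ", compartment,
             ", ", polarity, ")"),
      class = "cocultr_validation_error"
    )
  }
  if (nrow(grp) %% 2 != 0) {
    abort(
      paste0("odd mono-culture replicate count (", nrow(grp), ") for group (",
             species, ", ", compartment, ", ", polarity, "): cannot pair"),
      class = "cocultr_validation_error"
    )
  }
  grp <- grp[order(grp$replicate), ]
  if (is.null(pairing)) {
    idx <- seq_len(nrow(grp))
    pairing <- split(idx, ceiling(idx / 2))
  } else {
    pairing <- map(pairing, function(p) match(p, grp$replicate))
    if (any(is.na(unlist(pairing)))) {
      abort("pairing refers to replicate indices absent from the group",
            class = "cocultr_validation_error")
    }
  }
  env <- as_tibble(table)[, c("feature_id", ENVELOPE_COLS)]
  out <- env
  new_pheno <- list()
  for (k in seq_along(pairing)) {
    pair_samples <- grp$sample_id[pairing[[k]]]
    new_id <- paste0(species, "_", compartment, "_mono_", polarity, "_comb", k)
    out[[new_id]] <- rowSums(as_tibble(table)[, pair_samples, drop = FALSE])
    new_pheno[[k]] <- tibble(
      sample_id = new_id, species = species, compartment = compartment,
      culture = "mono", polarity = polarity, replicate = k
    )
  }
  list(
    table = feature_table(out),
    pheno = phenodata(dplyr::bind_rows(new_pheno))
  )
}
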