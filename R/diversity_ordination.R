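# Chemodiversity (Shannon index over presence/absence features) per sample
# origin, and PCA ordination of log intensities, including the
# combined-monoculture versus co-culture comparison.

#' Shannon diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over the positive entries of a non-negative
#' weight vector, with `p_i = w_i / sum(w)`. Zero entries contribute nothing.
#' Applied to a 0/1 presence vector this is `log(richness)`. Natural
#' logarithm by default.
#'
#' @param weights Non-negative numeric vector (e.g. pooled presence calls).
#' @param base Logarithm base (default `exp(1)`, nats).
#' @return The Shannon index, a single non-negative number.
#' @export
shannon_index <- function(weights, base = exp(1)) {
  if (any(weights < 0) || any(!is.finite(weights))) {
    abort("weights must be finite and >= 0", class = "cocultr_validation_error")
  }
  w <- weights[weights > 0]
  if (length(w) == 0) {
    abort("all-zero weight vector: Shannon index undefined", class = "cocultr_empty_error")
  }
  p <- w / sum(w)
  -sum(p * log(p, base = base))
}

#' Chemodiversity per sample origin
#'
#' Computes the Shannon index and feature richness for every
#' (species, compartment, culture) group of a presence matrix. Replicates are
#' pooled either by the union of their presence calls (default; a feature is
#' counted once if present in any replicate) or by averaging per-replicate
#' Shannon indices.
#'
#' @param presence A `presence_matrix` from [to_presence_matrix()].
#' @param pheno A [phenodata()] covering its samples.
#' @param pooling `"union"` (default) or `"mean"`.
#' @param base Logarithm base passed to [shannon_index()].
#' @return Tibble with columns `species`, `compartment`, `culture`,
#'   `h_prime`, `richness`, `n_replicates`, `pooling`. Empty groups are
#'   skipped with a warning.
#' @export
group_diversity <- function(presence, pheno, pooling = c("union", "mean"),
                            base = exp(1)) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(presence, "presence_matrix"), inherits(pheno, "phenodata"))
  m <- presence_values(presence)
  ph <- as_tibble(pheno)[pheno$sample_id %in% colnames(m), ]
  groups <- dplyr::distinct(ph[ph$species != "BLANK", ],
                            .data$species, .data$compartment, .data$culture)
  out <- pmap(groups, function(species, compartment, culture) {
    ids <- ph$sample_id[ph$species == species & ph$compartment == compartment &
                          ph$culture == culture]
    if (length(ids) == 0) {
      warn(paste0("empty group (", species, ", ", compartment, ", ", culture,
                  "): skipped"))
      return(NULL)
    }
    sub <- m[, ids, drop = FALSE]
    if (pooling == "union") {
      pooled <- as.integer(rowSums(sub) > 0)
      h <- shannon_index(pooled, base = base)
      rich <- sum(pooled)
    } else {
      h <- mean(apply(sub, 2, shannon_index, base = base))
      rich <- as.integer(round(mean(colSums(sub))))
    }
    tibble(
      species = species, compartment = compartment, culture = culture,
      h_prime = h, richness = rich, n_replicates = length(ids), pooling = pooling
    )
  })
  list_rbind(purrr::compact(out))
}

#' Principal component analysis of a sample x feature matrix
#'
#' Singular-value decomposition of the (column-centered) data, as in
#' `prcomp`: centered by default, unscaled. Component signs are fixed by
#' making each component's largest-magnitude loading positive, so results are
#' deterministic.
#'
#' @param x Numeric matrix, samples in rows, features in columns (e.g.
#'   `t(intensity_matrix(log_transform(table)))`).
#' @param center,scale Passed to [stats::prcomp()] (defaults `TRUE`, `FALSE`).
#' @param n_components Number of components to retain (default: all).
#' @return An object of class `pca_result`: list with `scores` (tibble,
#'   `sample_id` + `PC1..PCk`), `loadings` (feature x component matrix),
#'   `explained_fraction`, `center`, `scale`.
#' @export
pca <- function(x, center = TRUE, scale = FALSE, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("PCA needs >= 2 samples", class = "cocultr_validation_error")
  if (anyNA(x)) abort("PCA input must have no missing entries", class = "cocultr_validation_error")
  max_comp <- min(nrow(x) - if (center) 1 else 0, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    abort(
      paste0("n_components (", n_components, ") exceeds min(n_samples - 1, n_features) = ",
             max_comp),
      class = "cocultr_validation_error"
    )
  }
  fit <- prcomp(x, center = center, scale. = scale)
  k <- n_components
  rot <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)]
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble(sample_id = rownames(x) %||% as.character(seq_len(nrow(x)))),
        as_tibble(scores)
      ),
      loadings = rot,
      explained_fraction = expl,
      center = center,
      scale = scale
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", length(x$explained_fraction), "components\n")
  cat("explained fraction:", paste0(round(100 * x$explained_fraction, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pca
#' @param ... Unused.
#' @export
tidy.pca_result <- function(x, ...) {
  pcs <- grep("^PC[0-9]+$", names(x$scores), value = TRUE)
  tidyr::pivot_longer(x$scores[, c("sample_id", pcs)], -"sample_id",
                      names_to = "component", values_to = "score")
}

#' @rdname pca
#' @export
glance.pca_result <- function(x, ...) {
  tibble(
    n_components = length(x$explained_fraction),
    pc1_fraction = x$explained_fraction[1],
    pc2_fraction = if (length(x$explained_fraction) >= 2) x$explained_fraction[2] else NA_real_,
    centered = x$center, scaled = x$scale
  )
}

#' PCA of a feature table
#'
#' Convenience wrapper: log-transforms (unless already transformed),
#' transposes to samples x features, and runs [pca()]. Sample groups from the
#' phenodata are attached to the scores.
#'
#' @param table A [feature_table()].
#' @param pheno A [phenodata()].
#' @param transformed Set `TRUE` if `table` is already log-transformed.
#' @inheritParams pca
#' @return A `pca_result`; `scores` gains `species`, `compartment`,
#'   `culture`, `group` columns.
#' @export
pca_feature_table <- function(table, pheno, transformed = FALSE, center = TRUE,
                              scale = FALSE, n_components = NULL) {
  check_samples_covered(table, pheno)
  if (!transformed) table <- log_transform(table)
  res <- pca(t(intensity_matrix(table)), center = center, scale = scale,
             n_components = n_components)
  ph <- as_tibble(pheno)[, c("sample_id", "species", "compartment", "culture")]
  res$scores <- dplyr::left_join(res$scores, ph, by = "sample_id")
  res$scores$group <- paste(res$scores$species, res$scores$culture, sep = "_")
  res
}

#' Combined-monoculture versus co-culture PCA
#'
#' Builds the comparison ordination for one (compartment, polarity) dataset:
#' the mono-culture replicates of each species are pooled into summed
#' pseudo-replicates ([combine_monoculture_pairs()]) so that each species
#' contributes as many combined-mono pseudo-samples as co-culture replicates;
#' pseudo-samples and co-culture samples are then log-transformed and
#' ordinated together. Under a genuine co-culture metabolome shift, the
#' combined-mono pseudo-samples of both species cluster together while each
#' species' co-culture separates.
#'
#' @param table A raw-intensity [feature_table()].
#' @param pheno A [phenodata()].
#' @param compartment,polarity Dataset to compare (e.g. `"exo"`, `"pos"`).
#' @inheritParams pca
#' @return A `pca_result` whose scores carry a 3-level `group` label:
#'   `combined_mono`, `SM_co`, `PP_co`.
#' @export
combined_mono_pca <- function(table, pheno, compartment, polarity,
                              center = TRUE, scale = FALSE, n_components = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(pheno, "phenodata"))
  parts <- map(c("SM", "PP"), function(sp) {
    combine_monoculture_pairs(table, pheno, sp, compartment, polarity)
  })
  co_ids <- pheno$sample_id[pheno$compartment == compartment &
                              pheno$polarity == polarity &
                              pheno$culture == "co" & pheno$species != "BLANK" &
                              pheno$sample_id %in% sample_ids(table)]
  env <- as_tibble(table)[, c("feature_id", ENVELOPE_COLS)]
  combined <- dplyr::bind_cols(
    env,
    as_tibble(parts[[1]]$table)[, sample_ids(parts[[1]]$table)],
    as_tibble(parts[[2]]$table)[, sample_ids(parts[[2]]$table)],
    as_tibble(table)[, co_ids, drop = FALSE]
  )
  ph <- dplyr::bind_rows(
    as_tibble(parts[[1]]$pheno), as_tibble(parts[[2]]$pheno),
    as_tibble(pheno)[pheno$sample_id %in% co_ids, PHENO_COLS]
  )
  res <- pca_feature_table(feature_table(combined), phenodata(ph),
                           center = center, scale = scale,
                           n_components = n_components)
  res$scores$group <- ifelse(
    res$scores$culture == "mono", "combined_mono",
    paste0(res$scores$species, "_co")
  )
  res
}
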