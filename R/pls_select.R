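# Supervised differential-feature selection: two-class PLS (PLS1, NIPALS)
# with cross-validated component tuning and VIP-quantile thresholding.

# Run code under a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

encode_classes <- function(y, positive = NULL) {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) < 2) {
    abort("y has a single class: two classes required", class = "cocultr_validation_error")
  }
  if (length(lev) > 2) {
    abort("y has more than two classes", class = "cocultr_validation_error")
  }
  if (is.null(positive)) positive <- if ("co" %in% lev) "co" else lev[2]
  if (!positive %in% lev) {
    abort(paste0("positive class '", positive, "' not among labels: ",
                 paste(lev, collapse = ", ")), class = "cocultr_validation_error")
  }
  list(
    y = ifelse(y == positive, 1, -1),
    positive = positive,
    negative = setdiff(lev, positive)
  )
}

#' Fit a two-class PLS model (NIPALS)
#'
#' Sequential NIPALS extraction for a single response: at each component the
#' weight vector is `w_a = X't y / ||X't y||` on the current deflated data,
#' scores `t_a = X w_a`, X is deflated by `t_a p_a'` and y by `q_a t_a`.
#' Score vectors are mutually orthogonal by construction and every `w_a` has
#' unit norm. `ss[a]` records the response variance explained by component a
#' (`q_a^2 * t_a't_a`), the weighting used by the VIP score.
#'
#' @param X Numeric matrix, samples x features. Centered internally
#'   (column means stored for prediction).
#' @param y Two-class labels (any two distinct values; encoded +1/-1 and
#'   centered internally) or an already-numeric +1/-1 vector.
#' @param ncomp Number of components A, `<= min(n_samples - 1, n_features)`.
#' @param positive Label treated as the +1 class (default `"co"` when
#'   present, else the alphabetically larger label).
#' @return An object of class `pls_model`: list with `weights` (p x A, unit
#'   columns), `loadings`, `scores` (n x A), `q` (response loadings), `ss`
#'   (explained response variance per component), `ncomp`, `x_means`,
#'   `y_mean`, `feature_ids`, `classes`.
#' @export
fit_pls <- function(X, y, ncomp, positive = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("length(y) != nrow(X)", class = "cocultr_validation_error")
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    enc <- list(y = y, positive = "+1", negative = "-1")
    if (length(unique(y)) < 2) {
      abort("y has a single class: two classes required", class = "cocultr_validation_error")
    }
  } else {
    enc <- encode_classes(y, positive)
  }
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    abort(paste0("ncomp must be in 1..min(n_samples - 1, n_features) = ",
                 min(n - 1, p)), class = "cocultr_validation_error")
  }
  if (all(apply(X, 2, var) == 0)) {
    abort("X has no variance", class = "cocultr_validation_error")
  }
  x_means <- colMeans(X)
  y_mean <- mean(enc$y)
  Xc <- sweep(X, 2, x_means)
  yc <- enc$y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp); ss <- numeric(ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    ss[a] <- q_a^2 * tt
    a_used <- a
  }
  if (a_used == 0) {
    abort("no PLS component could be extracted (X'y is zero)",
          class = "cocultr_validation_error")
  }
  keep <- seq_len(a_used)
  structure(
    list(
      weights = W[, keep, drop = FALSE],
      loadings = P[, keep, drop = FALSE],
      scores = Tm[, keep, drop = FALSE],
      q = q[keep],
      ss = ss[keep],
      ncomp = a_used,
      x_means = x_means,
      y_mean = y_mean,
      feature_ids = colnames(X) %||% paste0("V", seq_len(p)),
      classes = c(positive = enc$positive, negative = enc$negative)
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS model:", length(x$feature_ids), "features,", x$ncomp, "component(s)\n")
  invisible(x)
}

#' Predict the (centered-scale) response of a PLS model
#' @param object A `pls_model`.
#' @param newdata Matrix samples x features (same columns as the fit).
#' @param ... Unused.
#' @return Numeric predictions on the +1/-1 scale; threshold at 0 for class.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  # B = W (P'W)^{-1} q maps centered X to centered y for the deflated fit
  PW <- crossprod(object$loadings, object$weights)
  B <- object$weights %*% solve(PW, object$q)
  drop(sweep(newdata, 2, object$x_means) %*% B) + object$y_mean
}

#' VIP (variable importance in projection) scores
#'
#' `VIP_j = sqrt( p * sum_a ss_a * w_ja^2 / sum_a ss_a )` with unit-norm
#' weight vectors, so the squared VIPs always average to 1 across the p
#' features.
#'
#' @param model A fitted [fit_pls()] model.
#' @return Named numeric vector of VIP scores (names = feature ids).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ss) <= 0) {
    abort("model explains no response variance: VIP undefined",
          class = "cocultr_validation_error")
  }
  p <- nrow(model$weights)
  w2 <- model$weights^2
  vip <- sqrt(p * drop(w2 %*% model$ss) / sum(model$ss))
  names(vip) <- model$feature_ids
  vip
}

# Stratified k-fold assignment; classes are dealt round-robin with a fold
# counter continuing across classes, so overall fold sizes stay as equal as
# possible (n = 8, folds = 5 gives sizes {2, 2, 2, 1, 1}).
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  nxt <- 0
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- ((nxt + seq_along(idx) - 1) %% folds) + 1
    nxt <- nxt + length(idx)
  }
  fold_id
}

#' Tune the PLS component count by cross-validation
#'
#' Searches A = 1..`max_components` (capped at the rank bound
#' `min(smallest training size - 1, n_features)`) for the component count
#' maximizing mean held-out classification accuracy (prediction thresholded
#' at 0), over stratified k-fold cross-validation. Ties break toward the
#' smaller A.
#'
#' @inheritParams fit_pls
#' @param max_components Upper end of the search (tune length, default 10).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed making the fold assignment reproducible.
#' @return Integer `A*`, with attribute `accuracy` (mean CV accuracy per A).
#' @export
tune_ncomp <- function(X, y, max_components = 10, folds = 5, seed = NULL,
                       positive = NULL) {
  X <- as.matrix(X)
  enc <- encode_classes(y, positive)
  yn <- enc$y
  if (min(table(yn)) < 2 || folds < 2) {
    abort("cross-validation infeasible (a class has < 2 members); consider leave-one-out",
          class = "cocultr_validation_error")
  }
  fold_id <- with_local_seed(seed, stratified_folds(yn, folds))
  # every training split must retain both classes
  for (k in sort(unique(fold_id))) {
    if (length(unique(yn[fold_id != k])) < 2) {
      abort(paste0("fold ", k, " leaves a single-class training set; ",
                   "use fewer folds or leave-one-out"),
            class = "cocultr_validation_error")
    }
  }
  n_train_min <- min(vapply(unique(fold_id), function(k) sum(fold_id != k), 0L))
  a_max <- min(max_components, n_train_min - 1, ncol(X))
  acc <- vapply(seq_len(a_max), function(a) {
    hits <- vapply(sort(unique(fold_id)), function(k) {
      tr <- fold_id != k
      Xtr <- X[tr, , drop = FALSE]
      keep <- apply(Xtr, 2, var) > 0
      if (!any(keep)) return(NA_real_)
      fit <- fit_pls(Xtr[, keep, drop = FALSE], yn[tr],
                     min(a, sum(tr) - 1, sum(keep)))
      pred <- predict(fit, X[!tr, keep, drop = FALSE])
      mean(ifelse(pred > 0, 1, -1) == yn[!tr])
    }, 0)
    mean(hits, na.rm = TRUE)
  }, 0)
  best <- which(acc == max(acc))[1]
  structure(as.integer(best), accuracy = acc)
}

#' Differential-feature selection by PLS-VIP
#'
#' The study's selection recipe: tune the component count by cross-validation
#' over `1..tune_length`, cap it at `components`, refit on all samples,
#' compute VIP scores, and select every feature whose VIP exceeds the
#' empirical `quantile` quantile of the VIP distribution (type-7 linear
#' interpolation). Zero-variance features are dropped before fitting (they
#' appear in the result with `vip = NA`, never selected). Each selected
#' feature is labelled by the sign of its class-mean difference
#' (`<positive>-enriched` vs `<negative>-enriched`).
#'
#' @inheritParams tune_ncomp
#' @param components Cap on the tuned component count (default 5).
#' @param tune_length Upper end of the tuning search (default 10).
#' @param quantile VIP quantile defining the selection threshold
#'   (default 0.95).
#' @return An object of class `selection_result`: tibble with `feature_id`,
#'   `vip`, `threshold`, `selected`, `direction`; attributes `ncomp`,
#'   `threshold`, `quantile`, `model`.
#' @export
select_features <- function(X, y, components = 5, tune_length = 10, folds = 5,
                            quantile = 0.95, seed = NULL, positive = NULL) {
  stopifnot(quantile > 0, quantile < 1)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  enc <- encode_classes(y, positive)
  keep <- apply(X, 2, var) > 0
  if (sum(keep) == 0) abort("X has no variance", class = "cocultr_validation_error")
  if (any(!keep)) {
    inform(paste0(sum(!keep), " zero-variance feature(s) dropped before fitting"))
  }
  Xk <- X[, keep, drop = FALSE]
  a_star <- tune_ncomp(Xk, y, max_components = tune_length, folds = folds,
                       seed = seed, positive = enc$positive)
  a_final <- min(as.integer(a_star), components, nrow(X) - 1, ncol(Xk))
  model <- fit_pls(Xk, y, a_final, positive = enc$positive)
  vip <- vip_scores(model)
  threshold <- unname(quantile(vip, probs = quantile, type = 7))
  pos_mean <- colMeans(Xk[enc$y == 1, , drop = FALSE])
  neg_mean <- colMeans(Xk[enc$y == -1, , drop = FALSE])
  direction_kept <- unname(ifelse(pos_mean - neg_mean >= 0,
                                  paste0(enc$positive, "-enriched"),
                                  paste0(enc$negative, "-enriched")))
  out <- tibble(feature_id = colnames(X)) |>
    dplyr::left_join(
      tibble(feature_id = colnames(Xk), vip = unname(vip),
             direction = direction_kept),
      by = "feature_id"
    ) |>
    dplyr::mutate(
      threshold = threshold,
      selected = !is.na(.data$vip) & .data$vip > threshold
    ) |>
    dplyr::select("feature_id", "vip", "threshold", "selected", "direction")
  structure(
    out,
    class = c("selection_result", class(out)),
    ncomp = model$ncomp,
    threshold = threshold,
    quantile = quantile,
    model = model
  )
}

#' @rdname select_features
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_selected = sum(x$selected),
    ncomp = attr(x, "ncomp"),
    threshold = attr(x, "threshold"),
    quantile = attr(x, "quantile")
  )
}

#' Differential features of one mono-vs-co contrast
#'
#' Runs [select_features()] on the log-transformed intensities of one
#' (species, compartment) dataset, mono-culture versus co-culture samples,
#' as one panel of the study's four contrasts.
#'
#' @param table A raw-intensity [feature_table()] (or transformed, with
#'   `transformed = TRUE`).
#' @param pheno A [phenodata()].
#' @param species,compartment Contrast to run (`"SM"`/`"PP"`,
#'   `"endo"`/`"exo"`).
#' @param polarity Optional polarity filter.
#' @param transformed Set `TRUE` if `table` is already log-transformed.
#' @inheritParams select_features
#' @return A `selection_result` with added `species` and `compartment`
#'   columns.
#' @export
select_differential <- function(table, pheno, species, compartment,
                                polarity = NULL, transformed = FALSE,
                                components = 5, tune_length = 10, folds = 5,
                                quantile = 0.95, seed = NULL) {
  check_samples_covered(table, pheno)
  if (!transformed) table <- log_transform(table)
  ph <- as_tibble(pheno)
  sel <- ph$species == species & ph$compartment == compartment
  if (!is.null(polarity)) sel <- sel & ph$polarity == polarity
  ph <- ph[sel & ph$sample_id %in% sample_ids(table), ]
  if (nrow(ph) == 0) {
    abort(paste0("no samples for contrast (", species, ", ", compartment, ")"),
          class = "cocultr_validation_error")
  }
  X <- t(intensity_matrix(table)[, ph$sample_id, drop = FALSE])
  res <- select_features(X, ph$culture, components = components,
                         tune_length = tune_length, folds = folds,
                         quantile = quantile, seed = seed, positive = "co")
  res$species <- species
  res$compartment <- compartment
  res
}
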