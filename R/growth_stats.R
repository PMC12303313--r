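# Growth-curve statistics on chlorophyll-a fluorescence: two-way ANOVA with
# replication (culture condition x sampling day) and per-day Welch t-tests
# comparing mono- versus co-culture.

#' Two-way ANOVA with replication on growth curves
#'
#' Fixed-effects two-factor ANOVA of RFU on culture condition (mono vs co)
#' and sampling day, with the interaction term ("with replication"). The
#' design must be balanced: every (culture, day) cell needs the same
#' replicate count r >= 2. When more mono- than co-culture replicates exist,
#' mono replicates are subset (default: indices 1-4) so both conditions
#' contribute equally, mirroring a 4-vs-4 analysis.
#'
#' @param series A [growth_series()] tibble (one species).
#' @param species Optional species filter applied first.
#' @param alpha Significance level for the critical F value (default 0.05).
#' @param mono_replicates Mono-culture replicate indices to keep when the
#'   mono count exceeds the co count (default `1:4`). Use `NULL` to keep all.
#' @param interaction Include the interaction term (default `TRUE`); the
#'   additive model is available with `FALSE`.
#' @return An object of class `growth_anova`: list with `table` (tibble with
#'   columns `source`, `ss`, `df`, `ms`, `f`, `p`, `f_crit` for sources
#'   condition/days/interaction/within/total), `alpha`, `n`, `replicates`.
#' @export
two_way_anova <- function(series, species = NULL, alpha = 0.05,
                          mono_replicates = 1:4, interaction = TRUE) {
  df <- as_tibble(series)
  if (!is.null(species)) df <- df[df$species == species, ]
  if (nrow(df) == 0) abort("no growth observations", class = "cocultr_empty_error")
  if (!is.null(mono_replicates)) {
    n_mono <- length(unique(df$replicate[df$culture == "mono"]))
    n_co <- length(unique(df$replicate[df$culture == "co"]))
    if (n_mono > n_co) {
      df <- df[df$culture == "co" | df$replicate %in% mono_replicates, ]
    }
  }
  cells <- dplyr::count(df, .data$culture, .data$day)
  if (length(unique(cells$n)) != 1) {
    bad <- cells[cells$n != max(cells$n), ]
    abort(
      paste0("unbalanced design: cell (", bad$culture[1], ", day ", bad$day[1],
             ") has ", bad$n[1], " replicates, others have ", max(cells$n)),
      class = "cocultr_validation_error"
    )
  }
  r <- unique(cells$n)
  if (r < 2) {
    abort("need >= 2 replicates per (culture, day) cell for a within-cell variance",
          class = "cocultr_validation_error")
  }
  if (sd(df$rfu) == 0) {
    abort("degenerate data: all observations equal, no variance to partition",
          class = "cocultr_validation_error")
  }
  df$culture <- factor(df$culture)
  df$day_f <- factor(df$day)
  form <- if (interaction) rfu ~ culture * day_f else rfu ~ culture + day_f
  fit <- aov(form, data = df)
  at <- as.data.frame(anova(fit))
  src_map <- c(culture = "condition", day_f = "days", `culture:day_f` = "interaction",
               Residuals = "within")
  tab <- tibble(
    source = unname(src_map[rownames(at)]),
    ss = at$`Sum Sq`,
    df = as.integer(at$Df),
    ms = at$`Mean Sq`,
    f = at$`F value`,
    p = at$`Pr(>F)`
  )
  df_within <- tab$df[tab$source == "within"]
  tab$f_crit <- ifelse(tab$source == "within", NA_real_,
                       qf(1 - alpha, tab$df, df_within))
  total <- tibble(
    source = "total", ss = sum(tab$ss), df = sum(tab$df),
    ms = NA_real_, f = NA_real_, p = NA_real_, f_crit = NA_real_
  )
  structure(
    list(
      table = dplyr::bind_rows(tab, total),
      alpha = alpha,
      n = nrow(df),
      replicates = r,
      interaction = interaction
    ),
    class = "growth_anova"
  )
}

#' @export
print.growth_anova <- function(x, ...) {
  cat("Two-way ANOVA with replication (r =", x$replicates, "per cell)\n")
  print(x$table)
  invisible(x)
}

#' @rdname two_way_anova
#' @param x A `growth_anova` object.
#' @param ... Unused.
#' @export
tidy.growth_anova <- function(x, ...) x$table

#' @rdname two_way_anova
#' @export
glance.growth_anova <- function(x, ...) {
  tab <- x$table
  tibble(
    p_condition = tab$p[tab$source == "condition"],
    p_days = tab$p[tab$source == "days"],
    p_interaction = if ("interaction" %in% tab$source) {
      tab$p[tab$source == "interaction"]
    } else NA_real_,
    n = x$n,
    replicates = x$replicates,
    alpha = x$alpha
  )
}

#' Sensitivity of the condition p-value to the mono-replicate choice
#'
#' Recomputes the condition p over every size-matched subset of mono-culture
#' replicates, since which mono replicates enter the balanced ANOVA is an
#' analysis choice.
#'
#' @inheritParams two_way_anova
#' @return Tibble with one row per subset: `mono_replicates` (string) and
#'   `p_condition`.
#' @export
anova_mono_sensitivity <- function(series, species = NULL, alpha = 0.05,
                                   interaction = TRUE) {
  df <- as_tibble(series)
  if (!is.null(species)) df <- df[df$species == species, ]
  mono <- sort(unique(df$replicate[df$culture == "mono"]))
  n_co <- length(unique(df$replicate[df$culture == "co"]))
  if (length(mono) <= n_co) {
    subsets <- list(mono)
  } else {
    subsets <- utils::combn(mono, n_co, simplify = FALSE)
  }
  purrr::map(subsets, function(s) {
    fit <- two_way_anova(df, alpha = alpha, mono_replicates = s,
                         interaction = interaction)
    tibble(
      mono_replicates = paste(s, collapse = ","),
      p_condition = glance(fit)$p_condition
    )
  }) |> list_rbind()
}

#' Welch two-sample t-test
#'
#' Two-tailed t-test with unequal variances (Welch-Satterthwaite degrees of
#' freedom): `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)`. When both
#' groups have zero variance and equal means the test is vacuous and `p = 1`
#' is returned by convention (with `t = 0`, `df = NA`); zero variance in both
#' groups with different means gives `p = 0`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A `welch_result` tibble with columns `t`, `df`, `p`, `mean_diff`
#'   (`mean(a) - mean(b)`), `n_a`, `n_b`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("both groups need at least 2 observations", class = "cocultr_validation_error")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("non-finite values in input", class = "cocultr_validation_error")
  }
  mean_diff <- mean(a) - mean(b)
  if (var(a) == 0 && var(b) == 0) {
    res <- tibble(
      t = if (mean_diff == 0) 0 else sign(mean_diff) * Inf,
      df = NA_real_,
      p = if (mean_diff == 0) 1 else 0,
      mean_diff = mean_diff, n_a = length(a), n_b = length(b)
    )
    return(structure(res, class = c("welch_result", class(res))))
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  res <- tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    mean_diff = mean_diff,
    n_a = length(a),
    n_b = length(b)
  )
  structure(res, class = c("welch_result", class(res)))
}

#' Per-day Welch tests, mono- versus co-culture
#'
#' For one species, runs [welch_t_test()] on each sampling day, mono-culture
#' RFU against co-culture RFU (all replicates of each condition).
#'
#' @param series A [growth_series()] tibble.
#' @param species Optional species filter.
#' @return Tibble with one row per day: `day`, `t`, `df`, `p`, `mean_diff`,
#'   `n_mono`, `n_co`.
#' @export
welch_by_day <- function(series, species = NULL) {
  df <- as_tibble(series)
  if (!is.null(species)) df <- df[df$species == species, ]
  days <- sort(unique(df$day))
  purrr::map(days, function(d) {
    a <- df$rfu[df$day == d & df$culture == "mono"]
    b <- df$rfu[df$day == d & df$culture == "co"]
    res <- welch_t_test(a, b)
    tibble(day = d, t = res$t, df = res$df, p = res$p,
           mean_diff = res$mean_diff, n_mono = length(a), n_co = length(b))
  }) |> list_rbind()
}
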