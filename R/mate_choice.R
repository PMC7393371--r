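#' Tally copulation types per drop
#'
#' Counts, per mating-arena drop, the conspecific *M. lignano* (`LL`),
#' heterospecific (`LJ`) and conspecific *M. janickei* (`JJ`) copulations
#' over the whole observation window.
#'
#' @param events A validated drop-schema event tibble
#'   (see [read_event_log()]); every copulation must be typed.
#' @return A tibble with `drop_id`, `m_LL`, `m_LJ`, `m_JJ`, `m_T`.
#' @export
count_copulation_types <- function(events) {
  ev <- tibble::as_tibble(events)
  cops <- ev[ev$event_kind == "copulation", , drop = FALSE]
  if (nrow(cops) > 0 && any(!cops$copulation_type %in% COPULATION_TYPES)) {
    abort("untyped (NA) copulation in a drop log")
  }
  ids <- unique(ev$record_id)
  tab <- table(factor(cops$record_id, levels = ids),
               factor(cops$copulation_type, levels = COPULATION_TYPES))
  tibble::tibble(
    drop_id = ids,
    m_LL = as.integer(tab[, "LL"]),
    m_LJ = as.integer(tab[, "LJ"]),
    m_JJ = as.integer(tab[, "JJ"]),
    m_T = as.integer(rowSums(tab))
  )
}

#' Type of the first copulation in each drop
#'
#' The earliest copulation (smallest `start_s`; exact ties broken by event
#' row order, deterministically) determines the drop's first copulation
#' type.
#'
#' @inheritParams count_copulation_types
#' @return A tibble with `drop_id` and `first_type` (`LL`/`LJ`/`JJ`;
#'   `NA` for drops without copulations).
#' @export
first_copulation_types <- function(events) {
  ev <- tibble::as_tibble(events)
  cops <- ev[ev$event_kind == "copulation", , drop = FALSE]
  ids <- unique(ev$record_id)
  firsts <- purrr::map_chr(ids, function(id) {
    e <- cops[cops$record_id == id, , drop = FALSE]
    if (nrow(e) == 0) return(NA_character_)
    e$copulation_type[which.min(e$start_s)]
  })
  tibble::tibble(drop_id = ids, first_type = firsts)
}

# Shared constructor for goodness-of-fit reports.
.gof_report <- function(statistic, df, observed, expected, method,
                        n_tests = 1L) {
  p <- pchisq(statistic, df, lower.tail = FALSE)
  structure(
    list(statistic = statistic, df = df, p_value = p,
         p_bonferroni = min(1, p * n_tests), n_tests = n_tests,
         observed = observed, expected = expected, method = method),
    class = "gof_test"
  )
}

#' @export
print.gof_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %d, p = %.4g", x$method,
              x$statistic, x$df, x$p_value))
  if (x$n_tests > 1) cat(sprintf(" (Bonferroni x%d: %.4g)", x$n_tests,
                                 x$p_bonferroni))
  cat("\n  observed:", paste(names(x$observed), x$observed, sep = "=",
                             collapse = ", "), "\n")
  cat("  expected:", paste(names(x$expected), round(x$expected, 3),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy gof_test
#' @export
tidy.gof_test <- function(x, ...) {
  tibble::tibble(category = names(x$observed),
                 observed = as.numeric(x$observed),
                 expected = as.numeric(x$expected))
}

#' @method glance gof_test
#' @export
glance.gof_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p_value = x$p_value, p_bonferroni = x$p_bonferroni)
}

# Pearson chi-square with 0/0 categories contributing 0.
.chisq_stat <- function(observed, expected) {
  keep <- !(expected == 0 & observed == 0)
  if (any(expected[keep] == 0)) return(Inf)
  sum((observed[keep] - expected[keep])^2 / expected[keep])
}

#' Chi-square test of first-copulation proportions
#'
#' Under random mating in a drop of two individuals of each species, the
#' six possible pairs split 1 LL : 4 LJ : 1 JJ, so the null proportions of
#' first-copulation types are 0.25 : 0.50 : 0.25. This tests observed
#' first-copulation tallies against that (or any supplied) null by Pearson
#' chi-square goodness of fit.
#'
#' @param first_types Either the tibble from [first_copulation_types()], a
#'   character vector of types, or a named count vector/table over
#'   `LL`,`LJ`,`JJ`.
#' @param expected_props Null proportions for (LL, LJ, JJ).
#' @return A `"gof_test"` object (Pearson chi-square, df = 2).
#' @export
#' @examples
#' first_copulation_test(c(LL = 34, LJ = 18, JJ = 7))
first_copulation_test <- function(first_types,
                                  expected_props = c(0.25, 0.50, 0.25)) {
  if (is.data.frame(first_types)) first_types <- first_types$first_type
  if (is.character(first_types) || is.factor(first_types)) {
    first_types <- first_types[!is.na(first_types)]
    obs <- table(factor(first_types, levels = COPULATION_TYPES))
  } else {
    obs <- first_types[COPULATION_TYPES]
  }
  obs <- setNames(as.numeric(obs), COPULATION_TYPES)
  n <- sum(obs)
  if (n == 0) abort("no drops with a first copulation")
  stopifnot(length(expected_props) == 3, abs(sum(expected_props) - 1) < 1e-8)
  exp <- setNames(expected_props * n, COPULATION_TYPES)
  .gof_report(.chisq_stat(obs, exp), df = 2L, observed = obs,
              expected = exp, method = "chisq_gof")
}

#' G-test goodness of fit
#'
#' Log-likelihood-ratio goodness-of-fit statistic
#' `G = 2 * sum(o * ln(o / e))` with the convention `0 * ln(0) = 0`,
#' `df = k - 1`. If a category has expected proportion 0 but positive
#' observed count, `G` is infinite and flagged (`infinite_g`), not thrown.
#'
#' @param observed Nonnegative counts (optionally named).
#' @param expected_props Null proportions summing to 1.
#' @param n_tests Bonferroni family size for the corrected p-value.
#' @return A `"gof_test"` object with method `"g_gof"`.
#' @export
#' @examples
#' g_goodness_of_fit(c(10, 0), c(0.5, 0.5)) # G = 2 * 10 * ln 2
g_goodness_of_fit <- function(observed, expected_props, n_tests = 1L) {
  stopifnot(length(observed) == length(expected_props),
            all(observed >= 0), all(expected_props >= 0))
  if (abs(sum(expected_props) - 1) > 1e-8) {
    abort("expected_props must sum to 1")
  }
  n <- sum(observed)
  if (n <= 0) abort("observed total must be positive")
  exp <- expected_props * n
  pos <- observed > 0
  g <- if (any(pos & exp == 0)) Inf else
    2 * sum(observed[pos] * log(observed[pos] / exp[pos]))
  nm <- if (!is.null(names(observed))) names(observed) else
    paste0("cat", seq_along(observed))
  rep <- .gof_report(g, df = length(observed) - 1L,
                     observed = setNames(as.numeric(observed), nm),
                     expected = setNames(exp, nm), method = "g_gof",
                     n_tests = n_tests)
  rep$infinite_g <- !is.finite(g)
  rep
}

# G independence statistic on a counts matrix (rows = replicates).
.g_independence <- function(tab) {
  n <- sum(tab)
  exp <- outer(rowSums(tab), colSums(tab)) / n
  pos <- tab > 0
  2 * sum(tab[pos] * log(tab[pos] / exp[pos]))
}

#' Repeated G-tests of goodness of fit across drops
#'
#' Runs the sequential hierarchy of G-tests for replicated count data:
#' (1) a per-drop G goodness-of-fit test against the null proportions,
#' Bonferroni-corrected over the included drops; (2) a heterogeneity G —
#' the G-test of independence on the drops-by-types table, df =
#' (drops - 1) * (types - 1) — asking whether drops share the same
#' proportions; (3) a pooled G on the summed counts; (4) the total G, the
#' sum of per-drop G values. The identity
#' `total G = pooled G + heterogeneity G` holds exactly. When
#' heterogeneity is significant the pooled test is still reported but
#' flagged not interpretable (the data are heterogeneous, so pooling is
#' not justified and the conclusion rests on the per-drop tests).
#'
#' @param counts A tibble from [count_copulation_types()] (columns
#'   `drop_id`, `m_LL`, `m_LJ`, `m_JJ`). Drops with zero copulations are
#'   excluded with a message.
#' @param expected_props Null proportions for (LL, LJ, JJ); default the
#'   random-mating 0.25:0.50:0.25.
#' @param alpha Significance level for the heterogeneity stopping rule.
#' @return An object of class `"repeated_g"`: `per_drop` tibble (G, df,
#'   raw and Bonferroni p per drop), `heterogeneity`, `pooled`, `total`
#'   (`gof_test`-like rows), `pooling_valid`, and `n_drops`.
#' @export
repeated_g_tests <- function(counts, expected_props = c(0.25, 0.50, 0.25),
                             alpha = 0.05) {
  ct <- tibble::as_tibble(counts)
  tab <- as.matrix(ct[, c("m_LL", "m_LJ", "m_JJ")])
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    inform(paste0("excluding ", sum(empty), " drop(s) with zero copulations"))
    ct <- ct[!empty, , drop = FALSE]
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2) abort("need at least 2 drops with copulations")
  n_drops <- nrow(tab)

  per <- purrr::map(seq_len(n_drops), function(i) {
    gt <- g_goodness_of_fit(setNames(tab[i, ], COPULATION_TYPES),
                            expected_props, n_tests = n_drops)
    tibble::tibble(drop_id = ct$drop_id[i], g = gt$statistic, df = gt$df,
                   p_value = gt$p_value, p_bonferroni = gt$p_bonferroni)
  }) |> dplyr::bind_rows()

  het_g <- .g_independence(tab)
  het_df <- (n_drops - 1L) * 2L
  het_p <- pchisq(het_g, het_df, lower.tail = FALSE)

  pooled <- g_goodness_of_fit(setNames(colSums(tab), COPULATION_TYPES),
                              expected_props)
  total_g <- sum(per$g)
  total_df <- n_drops * 2L
  structure(
    list(
      per_drop = per,
      heterogeneity = tibble::tibble(statistic = het_g, df = het_df,
                                     p_value = het_p),
      pooled = pooled,
      total = tibble::tibble(statistic = total_g, df = total_df,
                             p_value = pchisq(total_g, total_df,
                                              lower.tail = FALSE)),
      pooling_valid = het_p >= alpha,
      n_drops = n_drops,
      expected_props = expected_props
    ),
    class = "repeated_g"
  )
}

#' @export
print.repeated_g <- function(x, ...) {
  cat("Repeated G-tests of goodness of fit over", x$n_drops, "drops\n")
  cat(sprintf("  per-drop: %d/%d significant at Bonferroni-corrected 0.05\n",
              sum(x$per_drop$p_bonferroni < 0.05), x$n_drops))
  cat(sprintf("  heterogeneity G = %.2f, df = %d, p = %.3g\n",
              x$heterogeneity$statistic, x$heterogeneity$df,
              x$heterogeneity$p_value))
  if (x$pooling_valid) {
    cat(sprintf("  pooled G = %.2f, df = %d, p = %.3g\n",
                x$pooled$statistic, x$pooled$df, x$pooled$p_value))
  } else {
    cat("  pooled test not interpretable - data heterogeneous",
        sprintf("(pooled G = %.2f would have df = %d)\n",
                x$pooled$statistic, x$pooled$df))
  }
  cat(sprintf("  total G = %.2f, df = %d\n", x$total$statistic, x$total$df))
  invisible(x)
}

#' @method tidy repeated_g
#' @export
tidy.repeated_g <- function(x, ...) x$per_drop

#' @method glance repeated_g
#' @export
glance.repeated_g <- function(x, ...) {
  tibble::tibble(
    n_drops = x$n_drops,
    heterogeneity_g = x$heterogeneity$statistic,
    heterogeneity_df = x$heterogeneity$df,
    heterogeneity_p = x$heterogeneity$p_value,
    pooled_g = x$pooled$statistic,
    total_g = x$total$statistic,
    pooling_valid = x$pooling_valid
  )
}

#' Per-drop mating rates of the two species
#'
#' The mating rate of *M. lignano* in a drop is its share of copulation
#' participations, `p = (2 m_LL + m_LJ) / (2 m_T)`, and of *M. janickei*
#' `q = (2 m_JJ + m_LJ) / (2 m_T)`; `p + q = 1` by construction. Equal
#' mating rates give `p = q = 0.5`.
#'
#' @param counts Tibble with `m_LL`, `m_LJ`, `m_JJ` (and usually
#'   `drop_id`, `m_T`).
#' @return The input with `p` and `q` columns appended (`NA` where
#'   `m_T = 0`).
#' @export
mating_rates <- function(counts) {
  ct <- tibble::as_tibble(counts)
  m_t <- ct$m_LL + ct$m_LJ + ct$m_JJ
  p <- ifelse(m_t > 0, (2 * ct$m_LL + ct$m_LJ) / (2 * m_t), NA_real_)
  dplyr::mutate(ct, p = p, q = ifelse(is.na(p), NA_real_, 1 - p))
}

#' Mating-rate-adjusted expected copulation-type counts
#'
#' Given per-drop mating rates `p` and `q`, the expected counts under
#' random pairing are the Hardy-Weinberg-style
#' `e_LL = p^2 m_T`, `e_LJ = 2 p q m_T`, `e_JJ = q^2 m_T`; they sum to
#' `m_T` because `(p + q)^2 = 1`.
#'
#' @param p,q Mating rates (scalars or vectors, `p + q = 1`).
#' @param m_T Total copulation count(s).
#' @return A tibble with `e_LL`, `e_LJ`, `e_JJ`.
#' @export
rate_adjusted_expected <- function(p, q, m_T) {
  stopifnot(all(abs(p + q - 1) < 1e-8 | (is.na(p) & is.na(q))))
  tibble::tibble(e_LL = p^2 * m_T, e_LJ = 2 * p * q * m_T, e_JJ = q^2 * m_T)
}

#' Per-drop chi-square test against the rate-adjusted null
#'
#' Tests, drop by drop, whether observed copulation-type counts deviate
#' from the expectations implied by that drop's own mating rates
#' ([rate_adjusted_expected()]), i.e. whether any assortative (or
#' disassortative) mating remains once intrinsic mating-rate differences
#' between the species are accounted for. Pearson chi-square with
#' Bonferroni correction over the tested drops.
#'
#' The reference distribution is genuinely ambiguous: one parameter (`p`)
#' is estimated from each drop's counts, suggesting `3 - 1 - 1 = 1` df
#' (the Hardy-Weinberg analogy), while `df = 2` treats the expectations
#' as externally given. Because copulations within a drop are serially
#' dependent (partners are blocked for the duration of each copulation),
#' per-drop counts are overdispersed relative to the multinomial null and
#' the df = 1 reference is anticonservative in calibration experiments;
#' `df = 2` holds the type-I error below nominal there, so it is the
#' default. Both p-values are always reported; `df` selects which one the
#' Bonferroni decision uses.
#'
#' @param counts Tibble with `drop_id`, `m_LL`, `m_LJ`, `m_JJ`.
#' @param df Degrees of freedom for the decision, 2 (default) or 1.
#' @param n_tests Bonferroni family size; defaults to the number of drops
#'   with `m_T > 0`.
#' @return A tibble with one row per tested drop: observed counts, `p`,
#'   `q`, expected counts, `statistic`, `p_df1`, `p_df2`, `p_value`
#'   (at the chosen df), `p_bonferroni`.
#' @export
rate_adjusted_test <- function(counts, df = 2L, n_tests = NULL) {
  stopifnot(df %in% c(1L, 2L))
  ct <- mating_rates(counts)
  ct$m_T <- ct$m_LL + ct$m_LJ + ct$m_JJ
  ct <- ct[ct$m_T > 0, , drop = FALSE]
  if (is.null(n_tests)) n_tests <- nrow(ct)
  exp <- rate_adjusted_expected(ct$p, ct$q, ct$m_T)

  stat <- purrr::map_dbl(seq_len(nrow(ct)), function(i) {
    o <- c(ct$m_LL[i], ct$m_LJ[i], ct$m_JJ[i])
    e <- as.numeric(exp[i, ])
    # q = 0 forces m_LJ = m_JJ = 0, so expected 0 with observed > 0 is
    # impossible under these formulas
    stopifnot(!any(e == 0 & o > 0))
    .chisq_stat(o, e)
  })
  p1 <- pchisq(stat, 1, lower.tail = FALSE)
  p2 <- pchisq(stat, 2, lower.tail = FALSE)
  p_sel <- if (df == 1L) p1 else p2
  dplyr::bind_cols(ct, exp) |>
    dplyr::mutate(statistic = stat, df = df, p_df1 = p1, p_df2 = p2,
                  p_value = p_sel,
                  p_bonferroni = pmin(1, p_sel * n_tests))
}
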