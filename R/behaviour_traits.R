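#' Derive behavioural traits from a scored pair log
#'
#' Computes, per mating pair, the six behavioural traits scored in the
#' mating movies: copulation latency (time to the first copulation),
#' mean copulation duration, mean copulation interval, mean time until suck
#' (after copulation), mean suck duration, and the number of sucks —
#' together with fecundity. All traits except latency are averaged over
#' occurrences among the first five copulations; scoring stops at the fifth
#' copulation.
#'
#' Windowing and exclusion rules:
#' * pairs with zero copulations are flagged `excluded` and contribute no
#'   trait values;
#' * the copulation interval needs at least two copulations, else `NA`;
#' * a suck is attributed to a copulation if it is the first suck starting
#'   at or after that copulation's end and before the next scored
#'   copulation's start (the last scored copulation's window runs to the
#'   end of observation); unattributed sucks are ignored;
#' * the number of sucks is only defined on the subset of pairs with at
#'   least five copulations, else `NA`;
#' * for heterospecific pairs the offspring number is the average over the
#'   two maternal individuals (both were isolated), for conspecific pairs
#'   the count of the single isolated maternal individual.
#'
#' Undefined traits are `NA`, never silent zeros.
#'
#' @param events A validated pair-schema event tibble
#'   (see [read_event_log()]) covering one or more pairs.
#' @param offspring Optional tibble of post-pairing fecundity with columns
#'   `record_id`, `maternal_id`, `n_offspring` (one row per isolated
#'   maternal individual).
#' @param max_copulations Number of copulations scored per pair (default 5).
#'
#' @return A tibble with one row per `record_id`: `pairing_type`,
#'   `n_copulations`, `copulation_latency_s`, `mean_copulation_duration_s`,
#'   `mean_copulation_interval_s`, `mean_time_until_suck_s`,
#'   `mean_suck_duration_s`, `n_sucks`, `offspring_number`, `excluded`.
#' @export
extract_traits <- function(events, offspring = NULL, max_copulations = 5L) {
  ev <- tibble::as_tibble(events)
  ids <- unique(ev$record_id)
  rows <- purrr::map(ids, function(id) {
    rec <- ev[ev$record_id == id, , drop = FALSE]
    rec <- rec[order(rec$start_s, rec$end_s), , drop = FALSE]
    cops <- rec[rec$event_kind == "copulation", , drop = FALSE]
    sucks <- rec[rec$event_kind == "suck", , drop = FALSE]
    pt <- rec$pairing_type[!is.na(rec$pairing_type)]
    pt <- if (length(pt) > 0) pt[1] else NA_character_
    n_cop <- nrow(cops)

    out <- tibble::tibble(
      record_id = id, pairing_type = pt, n_copulations = n_cop,
      copulation_latency_s = NA_real_, mean_copulation_duration_s = NA_real_,
      mean_copulation_interval_s = NA_real_, mean_time_until_suck_s = NA_real_,
      mean_suck_duration_s = NA_real_, n_sucks = NA_integer_,
      offspring_number = NA_real_, excluded = n_cop == 0
    )
    if (n_cop == 0) return(out)

    scored <- head(cops, max_copulations)
    k <- nrow(scored)
    out$copulation_latency_s <- scored$start_s[1]
    out$mean_copulation_duration_s <- mean(scored$end_s - scored$start_s)
    if (k >= 2) {
      out$mean_copulation_interval_s <-
        mean(scored$start_s[-1] - head(scored$end_s, -1))
    }

    # Attribute to copulation i the first suck in (end_i, next start); the
    # last scored copulation's window extends to the end of observation.
    win_end <- c(scored$start_s[-1], Inf)
    delays <- durations <- rep(NA_real_, k)
    for (i in seq_len(k)) {
      cand <- sucks$start_s >= scored$end_s[i] & sucks$start_s < win_end[i]
      if (any(cand)) {
        j <- which(cand)[1]
        delays[i] <- sucks$start_s[j] - scored$end_s[i]
        durations[i] <- sucks$end_s[j] - sucks$start_s[j]
      }
    }
    if (any(!is.na(delays))) {
      out$mean_time_until_suck_s <- mean(delays, na.rm = TRUE)
      out$mean_suck_duration_s <- mean(durations, na.rm = TRUE)
    }
    if (n_cop >= max_copulations) {
      out$n_sucks <- sum(!is.na(delays))
    }
    out
  })
  traits <- dplyr::bind_rows(rows)

  if (!is.null(offspring)) {
    off <- offspring |>
      dplyr::group_by(.data$record_id) |>
      dplyr::summarise(offspring_number = mean(.data$n_offspring),
                       .groups = "drop")
    traits <- traits |>
      dplyr::select(-"offspring_number") |>
      dplyr::left_join(off, by = "record_id") |>
      dplyr::relocate("offspring_number", .before = "excluded")
  }
  traits
}

#' Coefficient of variation from the log scale
#'
#' Back-transformed CV for log-normally distributed traits:
#' `CV = 100 * sqrt(exp(sd_log^2) - 1)` where `sd_log` is the standard
#' deviation of the natural-log-transformed data.
#'
#' @param sd_log Nonnegative standard deviation(s) on the natural-log
#'   scale.
#' @return CV in percent.
#' @export
#' @examples
#' cv_lognormal(1) # 100 * sqrt(e - 1)
cv_lognormal <- function(sd_log) {
  if (any(is.na(sd_log)) || any(sd_log < 0)) {
    abort("sd_log must be nonnegative")
  }
  100 * sqrt(exp(sd_log^2) - 1)
}

#' Coefficient of variation on the raw scale
#'
#' `CV = 100 * sd(x) / mean(x)` with the sample (n - 1) standard
#' deviation. Used for count-like traits (number of sucks) that are not
#' log-transformed.
#'
#' @param values Numeric vector with positive mean.
#' @return CV in percent.
#' @export
cv_raw <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  if (!is.finite(m) || m <= 0) abort("cv_raw needs a positive mean")
  100 * sd(values) / m
}

# Traits log-transformed for analysis, with the additive offset applied
# before the log (time until suck gets +1: sucks can start immediately
# after copulation, so zeros occur).
.trait_spec <- function() {
  tibble::tibble(
    trait = c("copulation_latency_s", "mean_copulation_duration_s",
              "mean_copulation_interval_s", "mean_time_until_suck_s",
              "mean_suck_duration_s", "n_sucks", "offspring_number"),
    family = c(rep("parametric", 5L), "nonparametric", "nonparametric"),
    log_offset = c(0, 0, 0, 1, 0, NA, NA),
    cv_scale = c(rep("lognormal", 5L), "raw", "raw")
  )
}

#' Per-pairing-type coefficients of variation
#'
#' Summarises how stereotypic each behaviour is per pairing type. Traits
#' analysed on the log scale get the back-transformed CV
#' ([cv_lognormal()] of the sd of natural-log data, with the same +1
#' offset for time until suck used in the group tests); the number of
#' sucks and offspring number get the raw-scale CV ([cv_raw()]).
#'
#' @param traits A trait table from [extract_traits()].
#' @return A tibble with `pairing_type`, `trait`, `n`, `mean_log`,
#'   `sd_log` (NA for raw-scale traits) and `cv` in percent.
#' @export
trait_cv_summary <- function(traits) {
  spec <- .trait_spec()
  tr <- traits[!traits$excluded, , drop = FALSE]
  purrr::pmap(spec, function(trait, family, log_offset, cv_scale) {
    tr |>
      dplyr::filter(!is.na(.data[[trait]])) |>
      dplyr::group_by(.data$pairing_type) |>
      dplyr::summarise(
        trait = trait,
        n = dplyr::n(),
        mean_log = if (cv_scale == "lognormal")
          mean(log(.data[[trait]] + log_offset)) else NA_real_,
        sd_log = if (cv_scale == "lognormal")
          sd(log(.data[[trait]] + log_offset)) else NA_real_,
        cv = if (cv_scale == "lognormal")
          cv_lognormal(sd(log(.data[[trait]] + log_offset)))
        else cv_raw(.data[[trait]]),
        .groups = "drop"
      )
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("trait", .after = "pairing_type")
}

#' Compare one behavioural trait across pairing types
#'
#' Runs the omnibus and post-hoc comparisons used for the behavioural
#' traits: a one-way ANOVA on natural-log-transformed data followed by
#' Tukey HSD (`family = "parametric"`), or a Kruskal-Wallis test followed
#' by pairwise Wilcoxon rank-sum tests with Bonferroni correction
#' (`family = "nonparametric"`, used for counts that resist
#' transformation). Compact letter groupings are computed at `alpha`.
#'
#' @param data A trait table (e.g. from [extract_traits()]).
#' @param trait Name of the trait column to analyse.
#' @param family `"parametric"` or `"nonparametric"`.
#' @param group Name of the grouping column (default `"pairing_type"`).
#' @param log_offset Added to the trait before log-transformation in the
#'   parametric family (use 1 for time until suck, which contains zeros).
#' @param log_transform Log-transform (natural log) before the parametric
#'   tests? Default `TRUE`, the convention for the duration/latency
#'   traits; set `FALSE` for responses analysed on the raw scale
#'   (centroid size, relative warp scores).
#' @param alpha Significance level for letter groupings.
#'
#' @return An object of class `"group_comparison"` with [tidy()] (pairwise
#'   post-hoc rows) and [glance()] (omnibus row) methods. Components:
#'   `omnibus`, `posthoc`, `letters`, `group_n`, `trait`, `family`.
#' @export
compare_groups <- function(data, trait, family = c("parametric", "nonparametric"),
                           group = "pairing_type", log_offset = 0,
                           log_transform = TRUE, alpha = 0.05) {
  family <- match.arg(family)
  df <- tibble::as_tibble(data)
  if (!trait %in% names(df)) abort(paste0("no column '", trait, "'"))
  df <- df[!is.na(df[[trait]]) & !is.na(df[[group]]), c(group, trait)]
  names(df) <- c("group", "y")
  canonical <- c("lignano", "hetero", "hybrid", "janickei")
  lev <- if (all(df$group %in% canonical)) {
    intersect(canonical, unique(df$group))
  } else {
    unique(df$group)
  }
  df$group <- factor(df$group, levels = lev)
  counts <- table(df$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort(paste0("each group needs n >= 2 for '", trait, "'; got ",
                 paste(names(counts), counts, sep = "=", collapse = ", ")))
  }

  if (family == "parametric") {
    if (log_transform) {
      if (any(df$y + log_offset <= 0)) {
        abort(paste0("nonpositive values after offset ", log_offset,
                     " cannot be log-transformed for '", trait, "'"))
      }
      df$resp <- log(df$y + log_offset)
    } else {
      df$resp <- df$y
    }
    fit <- aov(resp ~ group, data = df)
    an <- summary(fit)[[1]]
    omnibus <- tibble::tibble(
      trait = trait, test = "anova",
      statistic = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
      p_value = an$`Pr(>F)`[1]
    )
    tk <- TukeyHSD(fit)$group
    posthoc <- tibble::tibble(
      contrast = rownames(tk), estimate = tk[, "diff"],
      conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
      p_value = tk[, "p adj"], method = "tukey_hsd"
    )
  } else {
    kw <- kruskal.test(df$y, df$group)
    omnibus <- tibble::tibble(
      trait = trait, test = "kruskal_wallis",
      statistic = unname(kw$statistic), df1 = unname(kw$parameter),
      df2 = NA_real_, p_value = kw$p.value
    )
    pw <- suppressWarnings(
      pairwise.wilcox.test(df$y, df$group, p.adjust.method = "bonferroni")
    )$p.value
    cons <- which(!is.na(pw), arr.ind = TRUE)
    posthoc <- tibble::tibble(
      contrast = paste(rownames(pw)[cons[, 1]], colnames(pw)[cons[, 2]],
                       sep = "-"),
      estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
      p_value = pw[cons], method = "wilcoxon_bonferroni"
    )
  }

  means <- tapply(df$y, df$group, mean)
  letters <- .letter_groups(names(means)[order(-means)],
                            posthoc$contrast, posthoc$p_value, alpha)

  structure(
    list(trait = trait, family = family, omnibus = omnibus,
         posthoc = posthoc, letters = letters,
         group_n = tibble::tibble(group = names(counts),
                                  n = as.integer(counts),
                                  mean = as.numeric(means[names(counts)])),
         alpha = alpha),
    class = "group_comparison"
  )
}

# Compact letter display by insert-and-absorb on the significant pairs.
.letter_groups <- function(groups_ordered, contrasts, p_values, alpha) {
  cols <- list(groups_ordered)
  sig <- which(p_values < alpha)
  for (idx in sig) {
    pair <- strsplit(contrasts[idx], "-", fixed = TRUE)[[1]]
    new_cols <- list()
    for (col in cols) {
      if (all(pair %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, pair[1])),
                      list(setdiff(col, pair[2])))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            !(all(new_cols[[j]] %in% new_cols[[i]]) && i < j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  labs <- setNames(rep("", length(groups_ordered)), groups_ordered)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) labs[g] <- paste0(labs[g], letters[i])
  }
  tibble::tibble(group = names(labs), letters = unname(labs))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of", x$trait, "(", x$family, ")\n")
  om <- x$omnibus
  cat(sprintf("  %s: statistic = %.4g, df = %s, p = %.3g\n", om$test,
              om$statistic,
              if (is.na(om$df2)) om$df1 else paste0(om$df1, ",", om$df2),
              om$p_value))
  ph <- merge(x$letters, x$group_n, by = "group")
  for (i in seq_len(nrow(ph))) {
    cat(sprintf("  %-10s n=%3d mean=%.4g  %s\n", ph$group[i], ph$n[i],
                ph$mean[i], ph$letters[i]))
  }
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$posthoc

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$omnibus

#' Run the full behavioural-trait comparison suite
#'
#' Applies [compare_groups()] to every trait with its conventional family:
#' parametric on natural-log data for latency, copulation duration,
#' copulation interval, time until suck (with +1 offset) and suck
#' duration; nonparametric (Kruskal-Wallis + Bonferroni Wilcoxon) for the
#' number of sucks and offspring number.
#'
#' @param traits A trait table from [extract_traits()]; excluded pairs
#'   (no copulations) are removed first.
#' @return A named list of `"group_comparison"` objects.
#' @export
analyse_traits <- function(traits) {
  spec <- .trait_spec()
  tr <- traits[!traits$excluded, , drop = FALSE]
  res <- purrr::pmap(spec, function(trait, family, log_offset, cv_scale) {
    compare_groups(tr, trait, family = family,
                   log_offset = ifelse(is.na(log_offset), 0, log_offset))
  })
  setNames(res, spec$trait)
}
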