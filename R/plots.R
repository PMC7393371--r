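#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_path
#'   geom_boxplot geom_text labs theme_minimal coord_equal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot aligned shapes and consensus
#'
#' Scatter of all Procrustes-aligned landmark positions with the
#' consensus shape overlaid.
#'
#' @param object A `"gpa_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gpa_fit
#' @export
autoplot.gpa_fit <- function(object, ...) {
  pts <- array_to_landmarks(object$aligned, groups = object$groups)
  cons <- tibble::tibble(x = object$consensus[, 1],
                         y = object$consensus[, 2])
  p <- ggplot(pts, aes(x = .data$x, y = .data$y))
  p <- if ("group" %in% names(pts)) {
    p + geom_point(aes(colour = .data$group), alpha = 0.3, size = 0.5)
  } else {
    p + geom_point(alpha = 0.3, size = 0.5)
  }
  p + geom_point(data = cons, colour = "black", size = 1.2) +
    coord_equal() + theme_minimal() +
    labs(title = "Procrustes-aligned landmarks", x = NULL, y = NULL)
}

#' Plot the first two relative warps
#'
#' @param object A `"relative_warps"` object.
#' @param ... Unused.
#' @return A ggplot (RWS1 against RWS2, coloured by group when known).
#' @method autoplot relative_warps
#' @export
autoplot.relative_warps <- function(object, ...) {
  sc <- object$scores
  p <- ggplot(sc, aes(x = .data$RWS1, y = .data$RWS2))
  p <- if ("group" %in% names(sc)) {
    p + geom_point(aes(colour = .data$group))
  } else {
    p + geom_point()
  }
  p + theme_minimal() +
    labs(x = sprintf("RWS1 (%.1f%%)", object$var_explained[1]),
         y = sprintf("RWS2 (%.1f%%)", object$var_explained[2]))
}

#' Plot a thin-plate-spline deformation grid
#'
#' @param object A `"tps_grid"`.
#' @param ... Unused.
#' @return A ggplot of the deformed grid with the target landmarks.
#' @method autoplot tps_grid
#' @export
autoplot.tps_grid <- function(object, ...) {
  g <- object$grid
  tgt <- tibble::tibble(x = object$target[, 1], y = object$target[, 2])
  ggplot() +
    geom_path(data = g, aes(x = .data$x, y = .data$y, group = .data$row),
              linewidth = 0.2, colour = "grey50") +
    geom_path(data = g, aes(x = .data$x, y = .data$y, group = .data$col),
              linewidth = 0.2, colour = "grey50") +
    geom_point(data = tgt, aes(x = .data$x, y = .data$y), colour = "red",
               size = 0.8) +
    coord_equal() + theme_minimal() + labs(x = NULL, y = NULL)
}

#' Boxplot of a group comparison with letter groupings
#'
#' @param object A `"group_comparison"` from [compare_groups()].
#' @param data The data the comparison was run on (trait and group
#'   columns), needed because the fitted object stores only summaries.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, data, ...) {
  trait <- object$trait
  grp <- object$letters
  df <- tibble::as_tibble(data)
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  gcol <- intersect(c("pairing_type", "group"), names(df))[1]
  df$group <- factor(df[[gcol]], levels = object$group_n$group)
  ytop <- max(df[[trait]], na.rm = TRUE)
  ggplot(df, aes(x = .data$group, y = .data[[trait]])) +
    geom_boxplot(outlier.size = 0.6) +
    geom_text(data = dplyr::mutate(grp, y = ytop * 1.08),
              aes(x = .data$group, y = .data$y, label = .data$letters)) +
    theme_minimal() + labs(x = NULL, y = trait)
}

#' Per-drop copulation-type frequency profile
#'
#' One line per drop across the three copulation types (conspecific
#' *M. lignano*, heterospecific, conspecific *M. janickei*), showing
#' between-drop heterogeneity in mating patterns.
#'
#' @param counts A tibble from [count_copulation_types()].
#' @return A ggplot.
#' @export
plot_copulation_frequencies <- function(counts) {
  long <- counts |>
    tidyr::pivot_longer(c("m_LL", "m_LJ", "m_JJ"),
                        names_to = "type", values_to = "n") |>
    dplyr::mutate(type = factor(.data$type,
                                levels = c("m_LL", "m_LJ", "m_JJ"),
                                labels = c("LL", "LJ", "JJ")))
  ggplot(long, aes(x = .data$type, y = .data$n, group = .data$drop_id)) +
    geom_line(alpha = 0.4) + geom_point(alpha = 0.4, size = 0.7) +
    theme_minimal() +
    labs(x = "copulation type", y = "copulations per drop")
}

#' Paired mating-rate plot
#'
#' Boxplots of the per-drop mating rates `p` (*M. lignano*) and `q`
#' (*M. janickei*), with lines connecting the two rates of each drop.
#'
#' @param rates A tibble from [mating_rates()].
#' @return A ggplot.
#' @export
plot_mating_rates <- function(rates) {
  long <- rates |>
    dplyr::filter(!is.na(.data$p)) |>
    tidyr::pivot_longer(c("p", "q"), names_to = "species",
                        values_to = "rate") |>
    dplyr::mutate(species = factor(.data$species, levels = c("p", "q"),
                                   labels = c("M. lignano", "M. janickei")))
  ggplot(long, aes(x = .data$species, y = .data$rate)) +
    geom_line(aes(group = .data$drop_id), alpha = 0.3) +
    geom_boxplot(width = 0.3, outlier.shape = NA, alpha = 0.6) +
    theme_minimal() + labs(x = NULL, y = "mating rate")
}
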