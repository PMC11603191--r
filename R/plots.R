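#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Hox profile into a long tibble
#'
#' @param x A `hox_profile`.
#' @param ... Unused.
#' @return Tibble with columns `group`, `column`, `residue`, `log_odds`
#'   (bits), `prob`.
#' @export
tidy.hox_profile <- function(x, ...) {
  tibble(
    group = x$group,
    column = rep(seq_len(x$L), each = 20),
    residue = rep(AA20, times = x$L),
    log_odds = as.numeric(x$M),
    prob = as.numeric(x$p)
  )
}

#' One-row summary of a Hox profile
#'
#' @param x A `hox_profile`.
#' @param ... Unused.
#' @return One-row tibble: `group`, `L`, `n_members`, `alpha`, `mu`,
#'   `lambda`, `threshold_E`, `max_score` (consensus score).
#' @export
glance.hox_profile <- function(x, ...) {
  tibble(
    group = x$group, L = x$L, n_members = x$n_rows, alpha = x$alpha,
    mu = if (is.null(x$calib)) NA_real_ else x$calib$mu,
    lambda = if (is.null(x$calib)) NA_real_ else x$calib$lambda,
    threshold_E = x$threshold_E,
    max_score = score_window(x, consensus_window(x))
  )
}

#' @export
tidy.hox_complement <- function(x, ...) complement_long(x)

#' @export
glance.hox_complement <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(
    n_species = nrow(tb),
    n_groups_present = sum(colSums(tb[hox_groups()]) > 0),
    n_loci = sum(as.matrix(tb[hox_groups()])) + sum(tb$ambiguous),
    n_ambiguous = sum(tb$ambiguous)
  )
}

#' @export
tidy.hox_events <- function(x, ...) x$events

#' @export
glance.hox_events <- function(x, ...) {
  tibble(group = x$group, gain_edge = x$gain_edge, n_losses = x$n_losses)
}

#' Complement-matrix plot
#'
#' Species-by-group tile matrix in the style of published Hox complement
#' figures: absent groups are marked "X", duplications "x2".
#'
#' @param object A `hox_complement`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hox_complement <- function(object, ...) {
  long <- complement_long(object) |>
    mutate(group = factor(.data$group, levels = hox_groups()),
           label = dplyr::case_when(
             .data$count == 0 ~ "X",
             .data$count == 1 ~ "",
             TRUE ~ paste0("x", .data$count)
           ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$species)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count > 0),
                       colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#8dd3c7", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL, title = "Hox gene complement") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cluster architecture plot
#'
#' Arrow boxes for each cluster member along the scaffold coordinate,
#' coloured by orthology group, arrowheads giving transcriptional
#' orientation; one facet per cluster.
#'
#' @param object A `hox_clusters` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hox_clusters <- function(object, ...) {
  if (nrow(object) == 0) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "No Hox clusters"))
  }
  members <- purrr::map2(object$members, object$cluster_id, function(m, id) {
    mutate(m, cluster_id = id)
  }) |> bind_rows()
  members <- mutate(
    members,
    x0 = ifelse(.data$strand == "+", .data$nt_start, .data$nt_end) / 1e3,
    x1 = ifelse(.data$strand == "+", .data$nt_end, .data$nt_start) / 1e3,
    group = factor(.data$best_group, levels = hox_groups())
  )
  ggplot2::ggplot(members) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = 0, yend = 0,
                   colour = .data$group),
      linewidth = 4,
      arrow = ggplot2::arrow(length = ggplot2::unit(8, "pt"), type = "closed")
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$x0 + .data$x1) / 2, y = 0.12,
                   label = .data$best_group),
      size = 2.6, angle = 30, hjust = 0
    ) +
    ggplot2::facet_wrap(~cluster_id, scales = "free_x", ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(-0.3, 0.5), breaks = NULL) +
    ggplot2::labs(x = "scaffold position (kb)", y = NULL,
                  colour = "orthology group",
                  title = "Hox cluster architecture") +
    ggplot2::theme_minimal()
}

#' Event-count plot for a loss-history table
#'
#' @param object Event tibble from [summarize_events()] / [loss_history()].
#' @param ... Unused.
#' @return A ggplot of per-group gain/loss counts.
#' @export
plot_loss_events <- function(object, ...) {
  counts <- object |>
    group_by(.data$group, .data$event) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(group = factor(.data$group, levels = hox_groups()))
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$group, y = .data$n, fill = .data$event)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "events", fill = NULL,
                  title = "Dollo gain/loss events per orthology group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
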