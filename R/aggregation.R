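# Cumulative PPP scores across ports, vessel types and time periods.

#' Cumulative PPP scores by grouping
#'
#' Adds per-arrival PPP scores and their ballast-water and biofouling
#' components within groups (port, vessel type, any column of the scored
#' table, or a combination) to locate where cumulative potential propagule
#' pressure concentrates. Group order is deterministic: descending
#' cumulative total, then key.
#'
#' @param scored Scored arrivals (from [score_batch()]).
#' @param group_by Character vector of grouping column names, default
#'   `"vessel_type"`.
#' @return A tibble with the grouping columns plus `n_arrivals`, `cum_bw`,
#'   `cum_bf`, `cum_total`, `mean_score` and `se_score` (sample standard
#'   deviation of the per-arrival scores divided by sqrt(n); `NA` for
#'   singleton groups).
#' @export
#' @examples
#' fleet <- generate_fleet(fleet_config(n_arrivals = 300), seed = 1)
#' scored <- score_batch(fleet, compute_baseline(fleet))
#' cumulative_scores(scored, c("port", "vessel_type"))
cumulative_scores <- function(scored, group_by = "vessel_type") {
  missing <- setdiff(group_by, names(scored))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("unknown grouping field(s): ", paste(missing, collapse = ", "),
             ". Available: ", paste(names(scored), collapse = ", ")),
      class = "pppscore_validation_error"
    )
  }
  out <- scored |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_arrivals = dplyr::n(),
      cum_bw = sum(.data$bw_component),
      cum_bf = sum(.data$bf_component),
      cum_total = sum(.data$ppp_score),
      mean_score = sum(.data$ppp_score) / dplyr::n(),
      se_score = stats::sd(.data$ppp_score) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  out[do.call(order, c(list(-out$cum_total),
                       lapply(group_by, function(g) out[[g]]))), ]
}

#' Component shares of a cumulative score
#'
#' For each group, the fraction of the cumulative PPP contributed by ballast
#' water discharge and by total wetted surface area. The two shares sum
#' to 1; a group with zero cumulative total has no defined shares and is an
#' error.
#'
#' @param groups Output of [cumulative_scores()].
#' @return `groups` with added `bw_share` and `bf_share` columns.
#' @export
component_shares <- function(groups) {
  if (any(groups$cum_total <= 0)) {
    rlang::abort("component shares are undefined for groups with cum_total <= 0",
                 class = "pppscore_domain_error")
  }
  dplyr::mutate(groups,
                bw_share = .data$cum_bw / .data$cum_total,
                bf_share = .data$cum_bf / .data$cum_total)
}

#' Drop sparsely visited groups
#'
#' Retains groups with at least `threshold` arrivals, the convention used
#' when summarizing ports so that rarely visited locations do not clutter a
#' regional comparison.
#'
#' @param groups Output of [cumulative_scores()].
#' @param threshold Minimum arrival count, `>= 0`.
#' @return The filtered tibble.
#' @export
min_arrival_filter <- function(groups, threshold = 50) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0) {
    rlang::abort("threshold must be a single number >= 0",
                 class = "pppscore_validation_error")
  }
  groups[groups$n_arrivals >= threshold, ]
}

#' Map ports onto port complexes
#'
#' Neighbouring ports are often reported jointly (e.g. a Los Angeles/Long
#' Beach complex). Supply a mapping — a named character vector
#' (`c("Los Angeles" = "LA/LB", "Long Beach" = "LA/LB")`), a two-column
#' data frame (`port`, `complex`), or a path to such a CSV — and every
#' mapped `port` value is replaced by its complex; unmapped ports pass
#' through unchanged.
#'
#' @param x A tibble with a `port` column (arrivals or scored arrivals).
#' @param mapping Named character vector, data frame, or CSV path.
#' @return `x` with `port` rewritten.
#' @export
apply_port_complexes <- function(x, mapping) {
  if (is.character(mapping) && is.null(names(mapping)) &&
      length(mapping) == 1) {
    mapping <- readr::read_csv(mapping, show_col_types = FALSE, comment = "#")
  }
  if (is.data.frame(mapping)) {
    if (!all(c("port", "complex") %in% names(mapping))) {
      rlang::abort("port-complex mapping needs 'port' and 'complex' columns",
                   class = "pppscore_validation_error")
    }
    mapping <- stats::setNames(mapping$complex, mapping$port)
  }
  hit <- x$port %in% names(mapping)
  x$port[hit] <- unname(mapping[x$port[hit]])
  x
}

#' Plot cumulative PPP by port and vessel type
#'
#' A compact regional overview: one bubble per port x vessel-type cell,
#' sized by the cumulative PPP score and coloured by the biofouling share of
#' that total, so ports and types dominated by wetted surface area stand
#' apart from those dominated by ballast discharge.
#'
#' @param scored Scored arrivals.
#' @param min_arrivals Drop cells with fewer arrivals than this.
#' @return A ggplot object.
#' @export
plot_cumulative_scores <- function(scored, min_arrivals = 0) {
  cells <- cumulative_scores(scored, c("port", "vessel_type")) |>
    min_arrival_filter(min_arrivals) |>
    component_shares()
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$port, y = .data$vessel_type,
                               size = .data$cum_total,
                               colour = .data$bf_share)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 14, name = "Cumulative PPP") +
    ggplot2::scale_colour_gradient(low = "#1b7837", high = "#2166ac",
                                   limits = c(0, 1),
                                   name = "Biofouling share") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
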