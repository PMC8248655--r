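# Daily inspection priority lists under a capacity constraint.

#' Rank one day's scored arrivals
#'
#' Sorts scored arrivals by descending PPP score with a fully deterministic
#' tie rule: descending ballast discharge volume, then ascending
#' `arrival_id`, so repeated runs produce identical lists.
#'
#' @param scored Scored arrivals (from [score_batch()]) all sharing one
#'   arrival date.
#' @param date Optional day to check against; an error is raised if the
#'   table mixes dates.
#' @return The scored tibble in priority order.
#' @export
rank_daily <- function(scored, date = NULL) {
  dates <- unique(scored$arrival_date)
  if (!is.null(date)) {
    scored <- scored[scored$arrival_date == as.Date(date), ]
    dates <- unique(scored$arrival_date)
  }
  if (length(dates) > 1) {
    rlang::abort(
      paste0("rank_daily expects a single day; got ", length(dates),
             " distinct dates (pass `date` to select one)"),
      class = "pppscore_validation_error"
    )
  }
  scored[order(-scored$ppp_score, -scored$bwd_volume, scored$arrival_id), ]
}

#' Select a day's high-priority arrivals
#'
#' Takes a ranked day of arrivals and a daily inspection capacity `k` and
#' returns the day's priority list. Arrivals flagged noncompliant are
#' selected first, with reason `"noncompliant"`, regardless of score —
#' suspected noncompliance trumps the score — and by default do not consume
#' capacity (`count_noncompliant = TRUE` makes them count against `k`). The
#' remaining slots go to the `k` greatest scores, reason `"score"`.
#'
#' @param ranked Output of [rank_daily()].
#' @param capacity Number of score-based inspections available, `>= 0`.
#' @param noncompliant_ids Extra arrival ids to treat as noncompliant, in
#'   addition to rows with `compliant == FALSE`; unknown ids produce a
#'   warning and are ignored.
#' @param count_noncompliant Should noncompliant overrides consume capacity?
#' @return A list of class `ppp_priority_list` with elements `date`,
#'   `capacity`, `entries` (tibble with `rank` and `reason` columns) and
#'   `excluded` (scored rows not selected).
#' @export
select_priorities <- function(ranked, capacity = 6,
                              noncompliant_ids = character(),
                              count_noncompliant = FALSE) {
  if (length(capacity) != 1 || is.na(capacity) || capacity < 0) {
    rlang::abort("capacity must be a single number >= 0",
                 class = "pppscore_validation_error")
  }
  unknown <- setdiff(noncompliant_ids, ranked$arrival_id)
  if (length(unknown) > 0) {
    rlang::warn(paste0("ignoring unknown noncompliant arrival id(s): ",
                       paste(unknown, collapse = ", ")))
  }
  flagged <- ranked$arrival_id %in% noncompliant_ids
  if ("compliant" %in% names(ranked)) {
    flagged <- flagged | (!is.na(ranked$compliant) & !ranked$compliant)
  }

  nc <- ranked[flagged, ]
  rest <- ranked[!flagged, ]
  slots <- if (count_noncompliant) max(0, capacity - nrow(nc)) else capacity
  by_score <- utils::head(rest, slots)
  excluded <- rest[-seq_len(nrow(by_score)), ]
  if (nrow(by_score) == 0) excluded <- rest

  entries <- dplyr::bind_rows(
    if (nrow(nc) > 0) dplyr::mutate(nc, reason = "noncompliant"),
    if (nrow(by_score) > 0) dplyr::mutate(by_score, reason = "score")
  )
  if (is.null(entries) || ncol(entries) == 0) {
    entries <- dplyr::mutate(ranked[0, ], reason = character())
  }
  entries$rank <- seq_len(nrow(entries))

  structure(
    list(date = if (nrow(ranked) > 0) ranked$arrival_date[1] else as.Date(NA),
         capacity = capacity,
         entries = tibble::as_tibble(entries),
         excluded = tibble::as_tibble(excluded)),
    class = "ppp_priority_list"
  )
}

#' @export
print.ppp_priority_list <- function(x, ...) {
  cat(sprintf("Priority list for %s (capacity %d): %d selected, %d excluded\n",
              format(x$date), x$capacity, nrow(x$entries), nrow(x$excluded)))
  if (nrow(x$entries) > 0) {
    cols <- intersect(c("rank", "arrival_id", "vessel_id", "vessel_type",
                        "port", "ppp_score", "reason"), names(x$entries))
    print(x$entries[cols], n = nrow(x$entries))
  }
  invisible(x)
}

#' Build daily priority lists over a period
#'
#' Splits scored arrivals by calendar day (the date recorded in the input;
#' no timestamp arithmetic), ranks each day and selects up to `capacity`
#' arrivals per day plus noncompliant overrides. Optionally applies the
#' first-arrival policy beforehand so frequent callers are only prioritized
#' on their first visit.
#'
#' @inheritParams select_priorities
#' @param scored Scored arrivals spanning any number of days.
#' @param first_arrival_only Apply [apply_first_arrival_policy()] first?
#' @return A tibble of selected entries across all days, with `date`,
#'   `rank` and `reason` columns.
#' @export
daily_priorities <- function(scored, capacity = 6,
                             noncompliant_ids = character(),
                             count_noncompliant = FALSE,
                             first_arrival_only = FALSE) {
  if (first_arrival_only) {
    scored <- apply_first_arrival_policy(scored)
  }
  days <- sort(unique(scored$arrival_date))
  picked <- lapply(days, function(d) {
    pl <- select_priorities(rank_daily(scored, d), capacity,
                            noncompliant_ids, count_noncompliant)
    if (nrow(pl$entries) == 0) return(NULL)
    dplyr::mutate(pl$entries, date = pl$date, .before = 1)
  })
  out <- dplyr::bind_rows(picked)
  if (nrow(out) == 0) {
    out <- dplyr::mutate(scored[0, ], reason = character(),
                         rank = integer(), date = as.Date(character()))
  }
  out
}

#' Keep only each vessel's first arrival
#'
#' Repeat-visit policy: for each `vessel_id` only the chronologically first
#' arrival remains eligible for prioritization; later arrivals by the same
#' vessel are excluded from selection (they remain scored and reportable).
#' Avoids spending the daily inspection budget repeatedly on the same
#' frequent caller.
#'
#' @param scored Scored arrivals carrying `vessel_id` and `arrival_date`.
#' @return The filtered tibble in chronological order.
#' @export
apply_first_arrival_policy <- function(scored) {
  ordered <- scored[order(scored$arrival_date, scored$arrival_id), ]
  ordered[!duplicated(ordered$vessel_id), ]
}
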