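# Baseline medians and per-arrival PPP scores.

#' Compute baseline population medians
#'
#' Summarizes a historical arrival population (one month, one year, multiple
#' years) into the two medians that normalize PPP scores: `med_twsa`, the
#' median per-arrival total wetted surface area, and `med_bwd`, the median
#' ballast water discharge volume. Because most arrivals discharge no
#' ballast, the default `bwd_policy = "discharging"` takes the median over
#' arrivals with positive discharge only; `"all"` uses every arrival and
#' errors loudly if that median is zero (a zero median would break the score
#' normalization). `median_unit = "vessel"` replaces per-arrival medians
#' with the median over each vessel's own median, so frequent callers do not
#' dominate the baseline.
#'
#' @param population Arrivals tibble (see [read_arrivals()]).
#' @param params Vessel-type parameter table.
#' @param bwd_policy `"discharging"` (default) or `"all"`.
#' @param median_unit `"arrival"` (default) or `"vessel"`.
#' @param niche_mode Barge+tug niche handling, see [compute_twsa_composite()].
#' @return A list of class `ppp_baseline`: `med_bwd` (m^3), `med_twsa`
#'   (m^2), `window_start`, `window_end`, `n_arrivals`, `n_discharging`,
#'   `bwd_policy`, `median_unit`, `niche_mode`.
#' @export
#' @examples
#' fleet <- generate_fleet(fleet_config(n_arrivals = 200), seed = 1)
#' compute_baseline(fleet)
compute_baseline <- function(population, params = vessel_type_params(),
                             bwd_policy = c("discharging", "all"),
                             median_unit = c("arrival", "vessel"),
                             niche_mode = c("per_component", "summed")) {
  bwd_policy <- match.arg(bwd_policy)
  median_unit <- match.arg(median_unit)
  niche_mode <- match.arg(niche_mode)
  if (is.null(population) || nrow(population) == 0) {
    rlang::abort("baseline population is empty",
                 class = "pppscore_validation_error")
  }

  twsa <- arrival_twsa(population, params, niche_mode)
  problems <- attr(twsa, "problems")
  if (nrow(problems) > 0) {
    rlang::warn(paste0(nrow(problems), " arrival(s) dropped from the ",
                       "baseline population (unresolvable TWSA)"))
  }
  keep <- !is.na(twsa)
  pop <- population[keep, ]
  twsa <- twsa[keep]
  if (nrow(pop) == 0) {
    rlang::abort("no arrival in the population has a resolvable TWSA",
                 class = "pppscore_validation_error")
  }

  bwd <- pop$bwd_volume
  if (anyNA(bwd)) {
    rlang::warn("missing bwd_volume treated as 0 (no discharge reported)")
    bwd[is.na(bwd)] <- 0
  }

  per_vessel_median <- function(values, vessel) {
    stats::median(tapply(values, vessel, stats::median))
  }

  med_twsa <- if (median_unit == "arrival") {
    stats::median(twsa)
  } else {
    per_vessel_median(twsa, pop$vessel_id)
  }

  discharging <- bwd > 0
  if (bwd_policy == "discharging") {
    if (!any(discharging)) {
      rlang::abort(
        paste0("no arrival with positive ballast discharge: the ",
               "'discharging' median policy is undefined for this population"),
        class = "pppscore_validation_error"
      )
    }
    med_bwd <- if (median_unit == "arrival") {
      stats::median(bwd[discharging])
    } else {
      per_vessel_median(bwd[discharging], pop$vessel_id[discharging])
    }
  } else {
    med_bwd <- if (median_unit == "arrival") {
      stats::median(bwd)
    } else {
      per_vessel_median(bwd, pop$vessel_id)
    }
    if (med_bwd <= 0) {
      rlang::abort(
        paste0("median ballast discharge over all arrivals is 0; the 'all' ",
               "policy cannot normalize scores for this population ",
               "(use bwd_policy = 'discharging')"),
        class = "pppscore_validation_error"
      )
    }
  }

  structure(
    list(med_bwd = med_bwd, med_twsa = med_twsa,
         window_start = min(pop$arrival_date),
         window_end = max(pop$arrival_date),
         n_arrivals = nrow(pop), n_discharging = sum(discharging),
         bwd_policy = bwd_policy, median_unit = median_unit,
         niche_mode = niche_mode),
    class = "ppp_baseline"
  )
}

#' @export
print.ppp_baseline <- function(x, ...) {
  cat("PPP baseline\n")
  cat(sprintf("  med_bwd:  %.4g m^3 (policy: %s, unit: %s)\n",
              x$med_bwd, x$bwd_policy, x$median_unit))
  cat(sprintf("  med_twsa: %.4g m^2\n", x$med_twsa))
  cat(sprintf("  window:   %s to %s (%d arrivals, %d discharging)\n",
              x$window_start, x$window_end, x$n_arrivals, x$n_discharging))
  invisible(x)
}

#' Freeze or restore a baseline as plain text
#'
#' A jurisdiction can compute its baseline once, freeze it to a small YAML
#' document, version it, and score future arrivals against the frozen
#' values.
#'
#' @param baseline A `ppp_baseline` object.
#' @param path File path for the YAML document.
#' @return `write_baseline()` returns `path` invisibly; `read_baseline()`
#'   returns the restored `ppp_baseline`.
#' @export
write_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "ppp_baseline"))
  out <- unclass(baseline)
  out$window_start <- as.character(out$window_start)
  out$window_end <- as.character(out$window_end)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  x <- yaml::read_yaml(path)
  x$window_start <- as.Date(x$window_start)
  x$window_end <- as.Date(x$window_end)
  if (is.null(x$med_bwd) || is.null(x$med_twsa) ||
      x$med_bwd <= 0 || x$med_twsa <= 0) {
    rlang::abort("baseline file must carry positive med_bwd and med_twsa",
                 class = "pppscore_validation_error")
  }
  structure(x, class = "ppp_baseline")
}

#' Score one arrival against a baseline
#'
#' The potential propagule pressure (PPP) score of an arrival is the sum of
#' its two median-normalized components:
#' `PPP = BWD / med_bwd + TWSA / med_twsa`. An arrival discharging exactly
#' the median volume with exactly the median TWSA scores exactly 2; a
#' no-discharge arrival's score is its biofouling component alone.
#'
#' @param arrival A one-row arrivals tibble.
#' @param baseline A `ppp_baseline` (from [compute_baseline()] or
#'   [read_baseline()]).
#' @param params Vessel-type parameter table.
#' @param niche_mode Barge+tug niche handling.
#' @return A one-row scored tibble: the arrival columns plus `twsa`,
#'   `bw_component`, `bf_component`, `ppp_score`.
#' @export
score_arrival <- function(arrival, baseline, params = vessel_type_params(),
                          niche_mode = c("per_component", "summed")) {
  if (nrow(arrival) != 1) {
    rlang::abort("score_arrival expects exactly one arrival row",
                 class = "pppscore_validation_error")
  }
  score_batch(arrival, baseline, params = params, niche_mode = niche_mode,
              strict = TRUE)
}

#' Score a batch of arrivals
#'
#' Applies [score_arrival()] element-wise, preserving input order. By
#' default rows that cannot be scored (unresolvable vessel type or missing
#' barge/tug WSA) are dropped from the result and collected — with their
#' `arrival_id` and reason — into the `"failures"` attribute, so one bad row
#' never aborts a day's scoring; `strict = TRUE` raises the first failure
#' instead.
#'
#' @param arrivals Arrivals tibble.
#' @param baseline A `ppp_baseline`.
#' @param params Vessel-type parameter table.
#' @param niche_mode Barge+tug niche handling.
#' @param strict Abort on the first unscorable arrival?
#' @return Scored tibble (arrival columns plus `twsa`, `bw_component`,
#'   `bf_component`, `ppp_score`) with attribute `"failures"`.
#' @export
score_batch <- function(arrivals, baseline, params = vessel_type_params(),
                        niche_mode = c("per_component", "summed"),
                        strict = FALSE) {
  niche_mode <- match.arg(niche_mode)
  stopifnot(inherits(baseline, "ppp_baseline"))
  if (baseline$med_bwd <= 0 || baseline$med_twsa <= 0) {
    rlang::abort("baseline medians must be strictly positive",
                 class = "pppscore_validation_error")
  }
  if (nrow(arrivals) == 0) {
    out <- arrivals
    out$twsa <- out$bw_component <- out$bf_component <-
      out$ppp_score <- numeric(0)
    attr(out, "failures") <-
      tibble::tibble(arrival_id = character(), problem = character())
    return(out)
  }

  twsa <- arrival_twsa(arrivals, params, niche_mode)
  failures <- attr(twsa, "problems")
  if (strict && nrow(failures) > 0) {
    rlang::abort(
      paste0("cannot score arrival ", failures$arrival_id[1], ": ",
             failures$problem[1]),
      class = "pppscore_scoring_error", arrival_id = failures$arrival_id[1]
    )
  }

  bwd <- arrivals$bwd_volume
  if (anyNA(bwd)) {
    rlang::warn("missing bwd_volume treated as 0 (no discharge reported)")
    bwd[is.na(bwd)] <- 0
  }

  out <- arrivals
  out$twsa <- as.vector(twsa)
  out$bw_component <- unname(bwd) / baseline$med_bwd
  out$bf_component <- out$twsa / baseline$med_twsa
  out$ppp_score <- out$bw_component + out$bf_component
  out <- out[!is.na(twsa), ]
  if (nrow(failures) > 0) {
    rlang::warn(paste0(nrow(failures),
                       " arrival(s) could not be scored; see the ",
                       "'failures' attribute"))
  }
  attr(out, "failures") <- failures
  out
}
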