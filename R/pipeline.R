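# End-to-end workflow: baseline -> scores -> priorities -> aggregates.

#' Workflow configuration
#'
#' Collects every tunable of the scoring and prioritization workflow in one
#' object so a run is a pure function of (inputs, config). Defaults match
#' the model's standard operating point: 6 score-based inspections per day,
#' medians over discharging arrivals, per-component barge/tug niche
#' handling.
#'
#' @param capacity Daily inspection capacity (score-based selections).
#' @param bwd_policy,median_unit,niche_mode See [compute_baseline()].
#' @param count_noncompliant Do noncompliant overrides consume capacity?
#' @param first_arrival_only Prioritize only each vessel's first arrival?
#' @param group_by Grouping columns for cumulative scores.
#' @param min_arrivals Minimum group size retained in cumulative output.
#' @param params Vessel-type parameter table (or path to a CSV override).
#' @param port_complex_map Optional port-to-complex mapping (named vector,
#'   data frame or CSV path), applied before aggregation only.
#' @return A list of class `ppp_config`.
#' @export
ppp_config <- function(capacity = 6,
                       bwd_policy = c("discharging", "all"),
                       median_unit = c("arrival", "vessel"),
                       niche_mode = c("per_component", "summed"),
                       count_noncompliant = FALSE,
                       first_arrival_only = FALSE,
                       group_by = c("port", "vessel_type"),
                       min_arrivals = 0,
                       params = vessel_type_params(),
                       port_complex_map = NULL) {
  if (is.character(params)) params <- read_vessel_type_params(params)
  .validate_params(params)
  structure(
    list(capacity = capacity,
         bwd_policy = match.arg(bwd_policy),
         median_unit = match.arg(median_unit),
         niche_mode = match.arg(niche_mode),
         count_noncompliant = count_noncompliant,
         first_arrival_only = first_arrival_only,
         group_by = group_by,
         min_arrivals = min_arrivals,
         params = params,
         port_complex_map = port_complex_map),
    class = "ppp_config"
  )
}

.config_hash <- function(config) {
  rlang::hash(lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }))
}

#' Run the full prioritization workflow
#'
#' Computes a baseline from a historical population, scores a set of
#' arrivals against it, builds daily priority lists under the configured
#' capacity, and aggregates cumulative scores. When `out_dir` is given, all
#' four artifacts are written as delimited text, each stamped with the
#' configuration hash and baseline provenance so outputs are traceable to
#' their inputs; logging goes to standard error.
#'
#' @param population Historical arrivals: a tibble or a path readable by
#'   [read_arrivals()].
#' @param arrivals Arrivals to score and prioritize: tibble or path.
#' @param config A [ppp_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `ppp_results`: `baseline`, `scores`,
#'   `priorities`, `group_scores`, `config`, `config_hash`.
#' @export
#' @examples
#' pop <- generate_fleet(fleet_config(n_arrivals = 200), seed = 1)
#' arr <- generate_fleet(fleet_config(n_arrivals = 50), seed = 2)
#' res <- run_pipeline(pop, arr)
#' res$baseline
run_pipeline <- function(population, arrivals, config = ppp_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "ppp_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "pppscore_pipeline_error", parent = e)
    })
  }
  if (is.character(population)) {
    population <- stage("read population", read_arrivals(population))
  }
  if (is.character(arrivals)) {
    arrivals <- stage("read arrivals", read_arrivals(arrivals))
  }

  message("pppscore: computing baseline from ", nrow(population),
          " arrivals")
  baseline <- stage("baseline",
                    compute_baseline(population, config$params,
                                     config$bwd_policy, config$median_unit,
                                     config$niche_mode))
  message("pppscore: scoring ", nrow(arrivals), " arrivals")
  scores <- stage("score",
                  score_batch(arrivals, baseline, config$params,
                              config$niche_mode))
  message("pppscore: building daily priority lists (capacity ",
          config$capacity, "/day)")
  priorities <- stage("prioritize",
                      daily_priorities(scores, config$capacity,
                                       count_noncompliant =
                                         config$count_noncompliant,
                                       first_arrival_only =
                                         config$first_arrival_only))
  grouped_in <- scores
  if (!is.null(config$port_complex_map)) {
    grouped_in <- apply_port_complexes(grouped_in, config$port_complex_map)
  }
  group_scores <- stage("aggregate",
                        min_arrival_filter(
                          cumulative_scores(grouped_in, config$group_by),
                          config$min_arrivals))

  hash <- .config_hash(config)
  res <- structure(
    list(baseline = baseline, scores = scores, priorities = priorities,
         group_scores = group_scores, config = config, config_hash = hash),
    class = "ppp_results"
  )
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.ppp_results <- function(x, ...) {
  cat("PPP workflow results (config ", x$config_hash, ")\n", sep = "")
  print(x$baseline)
  cat(sprintf("  %d arrivals scored (mean PPP %.3f), %d prioritized, %d groups\n",
              nrow(x$scores), mean(x$scores$ppp_score), nrow(x$priorities),
              nrow(x$group_scores)))
  invisible(x)
}

#' Write workflow results to a directory
#'
#' @param results A `ppp_results` object from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- c(
    paste0("config_hash: ", results$config_hash),
    paste0("baseline: med_bwd=", format(results$baseline$med_bwd),
           " m^3, med_twsa=", format(results$baseline$med_twsa),
           " m^2, window=", results$baseline$window_start, "..",
           results$baseline$window_end,
           ", policy=", results$baseline$bwd_policy, "/",
           results$baseline$median_unit)
  )
  write_baseline(results$baseline, file.path(out_dir, "baseline.yaml"))
  .write_result(results$scores, file.path(out_dir, "scores.csv"), provenance)
  .write_result(results$priorities, file.path(out_dir, "priorities.csv"),
                provenance)
  .write_result(results$group_scores,
                file.path(out_dir, "group_scores.csv"), provenance)
  message("pppscore: results written to ", out_dir)
  invisible(out_dir)
}
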