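# Synthetic multi-year arrival populations for testing and calibration.

#' Configuration for the synthetic fleet generator
#'
#' Describes an arrival population with the statistical structure the PPP
#' model assumes: a vessel-type mix, right-skewed (log-normal) per-type
#' gross tonnage, zero-inflated log-normal ballast discharge (most arrivals
#' discharge nothing), a weighted port list, a multi-year calendar window, a
#' small noncompliance rate, and a vessel pool smaller than the arrival
#' count so repeat visits occur. The default type mix is proportional to a
#' year of California arrivals by type (container 3608, tanker 2194, bulker
#' 1135, roro 951, passenger 628, barge_tug 382, atb 303, general 227); the
#' remaining defaults are field-realistic choices documented in the methods
#' vignette. Distributions are structural emulation, not a statistical fit
#' to any real dataset.
#'
#' @param n_arrivals Number of arrivals to generate.
#' @param start_date,end_date Calendar window (inclusive).
#' @param type_weights Named numeric vector of arrival weights by type code.
#' @param gt_meanlog,gt_sdlog Named per-type log-normal gross-tonnage
#'   parameters.
#' @param discharge_prob Named per-type probability that an arrival
#'   discharges any ballast.
#' @param bwd_meanlog,bwd_sdlog Named per-type log-normal discharge-volume
#'   parameters (m^3), conditional on discharging.
#' @param ports,port_weights Port codes and sampling weights.
#' @param noncompliance_rate Probability an arrival is flagged
#'   noncompliant.
#' @param vessel_pool_frac Vessel pool size as a fraction of the per-type
#'   arrival count (smaller values mean more repeat visits).
#' @return A list of class `ppp_fleet_config`.
#' @export
fleet_config <- function(n_arrivals = 2000,
                         start_date = "2015-01-01",
                         end_date = "2018-12-31",
                         type_weights = c(container = 3608, tanker = 2194,
                                          bulker = 1135, roro = 951,
                                          passenger = 628, barge_tug = 382,
                                          atb = 303, general = 227),
                         gt_meanlog = c(general = log(9000),
                                        passenger = log(90000),
                                        roro = log(55000),
                                        bulker = log(32000),
                                        container = log(40000),
                                        tanker = log(30000),
                                        atb = log(8000),
                                        barge_tug = log(5000)),
                         gt_sdlog = c(general = 0.7, passenger = 0.5,
                                      roro = 0.2, bulker = 0.35,
                                      container = 0.5, tanker = 0.4,
                                      atb = 0.3, barge_tug = 0.4),
                         discharge_prob = c(general = 0.35,
                                            passenger = 0.5, roro = 0.15,
                                            bulker = 0.75, container = 0.25,
                                            tanker = 0.6, atb = 0.4,
                                            barge_tug = 0.05),
                         bwd_meanlog = c(general = log(1000),
                                         passenger = log(1000),
                                         roro = log(500),
                                         bulker = log(8000),
                                         container = log(1500),
                                         tanker = log(5000),
                                         atb = log(1500),
                                         barge_tug = log(300)),
                         bwd_sdlog = c(general = 1, passenger = 0.8,
                                       roro = 1, bulker = 1,
                                       container = 1, tanker = 1,
                                       atb = 0.8, barge_tug = 0.8),
                         ports = c("Los Angeles", "Long Beach", "Oakland",
                                   "San Francisco", "Richmond", "Stockton",
                                   "San Diego", "Hueneme", "El Segundo",
                                   "Benicia"),
                         port_weights = c(30, 25, 18, 5, 6, 3, 4, 3, 4, 2),
                         noncompliance_rate = 0.01,
                         vessel_pool_frac = 0.3) {
  cfg <- structure(
    list(n_arrivals = n_arrivals,
         start_date = as.Date(start_date), end_date = as.Date(end_date),
         type_weights = type_weights, gt_meanlog = gt_meanlog,
         gt_sdlog = gt_sdlog, discharge_prob = discharge_prob,
         bwd_meanlog = bwd_meanlog, bwd_sdlog = bwd_sdlog,
         ports = ports, port_weights = port_weights,
         noncompliance_rate = noncompliance_rate,
         vessel_pool_frac = vessel_pool_frac),
    class = "ppp_fleet_config"
  )
  .validate_fleet_config(cfg)
  cfg
}

.validate_fleet_config <- function(cfg) {
  types <- names(cfg$type_weights)
  known <- c(.regression_types, .direct_types)
  if (length(types) == 0 || !all(types %in% known)) {
    rlang::abort("type_weights must be named with canonical type codes",
                 class = "pppscore_validation_error")
  }
  if (any(cfg$type_weights < 0) || sum(cfg$type_weights) <= 0) {
    rlang::abort("type_weights must be non-negative and not all zero",
                 class = "pppscore_validation_error")
  }
  for (field in c("gt_meanlog", "gt_sdlog", "discharge_prob",
                  "bwd_meanlog", "bwd_sdlog")) {
    if (!all(types %in% names(cfg[[field]]))) {
      rlang::abort(paste0(field, " must cover every type in type_weights"),
                   class = "pppscore_validation_error")
    }
  }
  if (any(cfg$discharge_prob < 0) || any(cfg$discharge_prob > 1) ||
      cfg$noncompliance_rate < 0 || cfg$noncompliance_rate > 1) {
    rlang::abort("probabilities must lie in [0, 1]",
                 class = "pppscore_validation_error")
  }
  if (cfg$n_arrivals < 1 || cfg$start_date > cfg$end_date ||
      length(cfg$ports) != length(cfg$port_weights) ||
      cfg$vessel_pool_frac <= 0 || cfg$vessel_pool_frac > 1) {
    rlang::abort("invalid fleet configuration",
                 class = "pppscore_validation_error")
  }
  invisible(cfg)
}

## plausible barge / tug hull dimensions for the direct WSA route
.random_hulls <- function(n, kind = c("barge", "tug")) {
  kind <- match.arg(kind)
  if (kind == "barge") {
    L <- stats::runif(n, 60, 120)
    list(length_waterline = L,
         beam = L * stats::runif(n, 0.22, 0.30),
         draft = stats::runif(n, 3.5, 6),
         midship_coeff = stats::runif(n, 0.96, 0.995),
         block_coeff = stats::runif(n, 0.85, 0.95),
         waterplane_coeff = stats::runif(n, 0.90, 0.97),
         bulb_transverse_area = rep(0, n))
  } else {
    L <- stats::runif(n, 25, 40)
    list(length_waterline = L,
         beam = L * stats::runif(n, 0.28, 0.35),
         draft = stats::runif(n, 3, 5),
         midship_coeff = stats::runif(n, 0.85, 0.95),
         block_coeff = stats::runif(n, 0.50, 0.65),
         waterplane_coeff = stats::runif(n, 0.80, 0.90),
         bulb_transverse_area = rep(0, n))
  }
}

#' Generate a synthetic arrival population
#'
#' Draws `config$n_arrivals` vessel arrivals under [fleet_config()]. Each
#' vessel belongs to a per-type vessel pool smaller than the arrival count,
#' so the same vessel arrives repeatedly, as real fleets do. `atb` and
#' `barge_tug` arrivals carry full hull dimensions for both the barge and
#' the tug component (the direct WSA route); regression types carry gross
#' tonnage. The same seed always yields the identical table.
#'
#' @param config A [fleet_config()].
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return An arrivals tibble that passes [read_arrivals()] validation.
#' @export
#' @examples
#' generate_fleet(fleet_config(n_arrivals = 5), seed = 42)
generate_fleet <- function(config = fleet_config(), seed = NULL) {
  .validate_fleet_config(config)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  n <- config$n_arrivals
  types <- names(config$type_weights)
  vessel_type <- sample(types, n, replace = TRUE,
                        prob = config$type_weights / sum(config$type_weights))

  ## per-type vessel pools so repeat visits occur
  vessel_id <- character(n)
  for (t in types) {
    idx <- which(vessel_type == t)
    if (length(idx) == 0) next
    pool <- max(1, ceiling(length(idx) * config$vessel_pool_frac))
    code <- toupper(substr(gsub("_", "", t), 1, 3))
    vessel_id[idx] <- sample(sprintf("%s%04d", code, seq_len(pool)),
                             length(idx), replace = TRUE)
  }

  gt <- unname(stats::rlnorm(n, config$gt_meanlog[vessel_type],
                             config$gt_sdlog[vessel_type]))
  discharging <- stats::runif(n) < unname(config$discharge_prob[vessel_type])
  bwd <- ifelse(discharging,
                unname(stats::rlnorm(n, config$bwd_meanlog[vessel_type],
                                     config$bwd_sdlog[vessel_type])),
                0)
  days <- seq(config$start_date, config$end_date, by = "day")
  arrival_date <- sort(sample(days, n, replace = TRUE))
  port <- sample(config$ports, n, replace = TRUE,
                 prob = config$port_weights / sum(config$port_weights))
  compliant <- stats::runif(n) >= config$noncompliance_rate

  out <- tibble::tibble(
    arrival_id = sprintf("A%06d", seq_len(n)),
    vessel_id = vessel_id,
    vessel_type = vessel_type,
    gross_tonnage = round(gt),
    bwd_volume = round(bwd, 1),
    port = port,
    arrival_date = arrival_date,
    compliant = compliant
  )

  ## hull dimensions for the direct-WSA types; same vessel keeps one hull
  direct <- which(vessel_type %in% .direct_types)
  for (f in .hull_fields) {
    out[[paste0("hull_", f)]] <- NA_real_
    out[[paste0("tug_", f)]] <- NA_real_
  }
  if (length(direct) > 0) {
    ids <- unique(vessel_id[direct])
    barges <- .random_hulls(length(ids), "barge")
    tugs <- .random_hulls(length(ids), "tug")
    j <- match(vessel_id[direct], ids)
    for (f in .hull_fields) {
      out[[paste0("hull_", f)]][direct] <- round(barges[[f]][j], 3)
      out[[paste0("tug_", f)]][direct] <- round(tugs[[f]][j], 3)
    }
  }
  out
}

## deliberately naive re-implementation of the TWSA and PPP arithmetic,
## kept separate from the production code path for oracle testing
.naive_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

.naive_twsa_one <- function(row) {
  tab <- list(general = c(20.02, 0.5728, 0.09),
              passenger = c(5.46, 0.6951, 0.27),
              roro = c(25.04, 0.5309, 0.09),
              bulker = c(15, 0.6294, 0.07),
              container = c(10.66, 0.6501, 0.09),
              tanker = c(17.57, 0.6105, 0.08))
  holtrop <- function(L, B, T, cm, cb, cwp, abt) {
    L * (2 * T + B) * sqrt(cm) *
      (0.453 + 0.4425 * cb - 0.2862 * cm - 0.003467 * B / T +
         0.3696 * cwp) + 2.38 * abt / cb
  }
  if (row$vessel_type %in% names(tab)) {
    p <- tab[[row$vessel_type]]
    p[1] * row$gross_tonnage^p[2] * (1 + p[3])
  } else {
    barge <- holtrop(row$hull_length_waterline, row$hull_beam,
                     row$hull_draft, row$hull_midship_coeff,
                     row$hull_block_coeff, row$hull_waterplane_coeff,
                     row$hull_bulb_transverse_area)
    tug <- holtrop(row$tug_length_waterline, row$tug_beam, row$tug_draft,
                   row$tug_midship_coeff, row$tug_block_coeff,
                   row$tug_waterplane_coeff, row$tug_bulb_transverse_area)
    barge * 1.033 + tug * 1.25
  }
}

#' Generate arrivals with independently computed expected scores
#'
#' Produces a synthetic arrival set together with the TWSA, baseline
#' medians, and PPP scores computed by a deliberately separate, naive
#' re-implementation of the model arithmetic (straight-line formula
#' evaluation in a per-row loop, its own median). Intended as a
#' known-answer oracle: the production scoring path must agree with the
#' naive values to near machine precision.
#'
#' @param config A [fleet_config()]; keep `n_arrivals` small.
#' @param seed Integer seed passed to [generate_fleet()].
#' @return A list: `arrivals`, `med_bwd`, `med_twsa` (naive medians over
#'   the set itself, discharge median over discharging arrivals), and
#'   `expected` (tibble of `arrival_id`, `twsa`, `bw_component`,
#'   `bf_component`, `ppp_score`).
#' @export
generate_known_answer_set <- function(config = fleet_config(n_arrivals = 20),
                                      seed = 1) {
  arrivals <- generate_fleet(config, seed = seed)
  n <- nrow(arrivals)
  twsa <- numeric(n)
  for (i in seq_len(n)) {
    twsa[i] <- .naive_twsa_one(as.list(arrivals[i, ]))
  }
  med_twsa <- .naive_median(twsa)
  pos <- arrivals$bwd_volume[arrivals$bwd_volume > 0]
  if (length(pos) == 0) {
    rlang::abort("known-answer set has no discharging arrival; raise n",
                 class = "pppscore_validation_error")
  }
  med_bwd <- .naive_median(pos)
  bw <- numeric(n)
  bf <- numeric(n)
  for (i in seq_len(n)) {
    bw[i] <- arrivals$bwd_volume[i] / med_bwd
    bf[i] <- twsa[i] / med_twsa
  }
  list(arrivals = arrivals, med_bwd = med_bwd, med_twsa = med_twsa,
       expected = tibble::tibble(arrival_id = arrivals$arrival_id,
                                 twsa = twsa, bw_component = bw,
                                 bf_component = bf, ppp_score = bw + bf))
}
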