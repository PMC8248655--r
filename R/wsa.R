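# Wetted surface area (WSA) and total wetted surface area (TWSA).

#' Estimate wetted surface area from gross tonnage
#'
#' Evaluates the per-type power law `WSA = m * GT^b` for the six regression
#' vessel types. ATB and barge+tug arrivals have no regression; their WSA is
#' computed directly from hull dimensions with [compute_direct_wsa()].
#'
#' @param gross_tonnage Numeric vector of gross tonnage values (> 0).
#' @param vessel_type Character vector of vessel types (recycled), any label
#'   accepted by [normalize_vessel_type()].
#' @param params Vessel-type parameter table, default [vessel_type_params()].
#' @return Numeric vector of wetted surface areas in m^2, strictly
#'   increasing in gross tonnage for each type.
#' @export
#' @examples
#' estimate_wsa_from_gt(50000, "container")
#' estimate_wsa_from_gt(c(1e3, 1e4, 1e5), "bulker")
estimate_wsa_from_gt <- function(gross_tonnage, vessel_type,
                                 params = vessel_type_params()) {
  .validate_params(params)
  type <- normalize_vessel_type(vessel_type)
  n <- max(length(gross_tonnage), length(type))
  gross_tonnage <- rep_len(gross_tonnage, n)
  type <- rep_len(type, n)
  if (any(type %in% .direct_types)) {
    rlang::abort(
      paste0("no gross-tonnage regression exists for type(s) ",
             paste(unique(type[type %in% .direct_types]), collapse = ", "),
             "; use compute_direct_wsa() on the hull dimensions instead."),
      class = "pppscore_unsupported_route"
    )
  }
  if (any(is.na(gross_tonnage)) || any(gross_tonnage <= 0)) {
    rlang::abort("gross_tonnage must be positive",
                 class = "pppscore_domain_error")
  }
  i <- match(type, params$type_code)
  params$m[i] * gross_tonnage^params$b[i]
}

#' Hull parameters for a direct wetted-surface-area calculation
#'
#' Bundles the hull-form quantities needed by [compute_direct_wsa()]:
#' waterline length, beam and draft in metres, the midship, block and
#' waterplane coefficients (dimensionless, in `(0, 1]`), and the transverse
#' bulbous-bow section area in m^2 (0 for the flat-bowed barges and tugs this
#' route is mostly used for).
#'
#' @param length_waterline,beam,draft Principal dimensions, metres (> 0).
#' @param midship_coeff,block_coeff,waterplane_coeff Form coefficients in
#'   `(0, 1]`.
#' @param bulb_transverse_area Transverse bulb area, m^2 (>= 0), default 0.
#' @return A list of class `ppp_hull`.
#' @export
#' @examples
#' hull_params(100, 30, 5, 0.99, 0.90, 0.92)
hull_params <- function(length_waterline, beam, draft, midship_coeff,
                        block_coeff, waterplane_coeff,
                        bulb_transverse_area = 0) {
  h <- list(length_waterline = length_waterline, beam = beam, draft = draft,
            midship_coeff = midship_coeff, block_coeff = block_coeff,
            waterplane_coeff = waterplane_coeff,
            bulb_transverse_area = bulb_transverse_area)
  .validate_hull(h)
  structure(h, class = "ppp_hull")
}

.hull_fields <- c("length_waterline", "beam", "draft", "midship_coeff",
                  "block_coeff", "waterplane_coeff", "bulb_transverse_area")

.validate_hull <- function(h) {
  missing <- .hull_fields[!vapply(.hull_fields, function(f) {
    !is.null(h[[f]]) && all(!is.na(h[[f]]))
  }, logical(1))]
  if (length(missing) > 0) {
    rlang::abort(
      paste0("hull parameters missing or NA: ",
             paste(missing, collapse = ", ")),
      class = "pppscore_validation_error"
    )
  }
  lengths_ok <- all(h$length_waterline > 0) && all(h$beam > 0) &&
    all(h$draft > 0)
  coefs <- c(h$midship_coeff, h$block_coeff, h$waterplane_coeff)
  if (!lengths_ok || any(coefs <= 0) || any(coefs > 1) ||
      any(h$bulb_transverse_area < 0)) {
    rlang::abort(
      paste0("invalid hull parameters: lengths must be > 0, form ",
             "coefficients in (0, 1], bulb_transverse_area >= 0"),
      class = "pppscore_validation_error"
    )
  }
  invisible(h)
}

#' Compute wetted surface area directly from hull dimensions
#'
#' Evaluates the flat-of-form wetted-surface approximation of Holtrop, used
#' for vessel classes (unmanned barges, tugs, articulated tug-barges) too
#' heterogeneous for a tonnage regression:
#'
#' \deqn{S = L(2T + B)\sqrt{C_m}\,(0.453 + 0.4425 C_b - 0.2862 C_m
#'   - 0.003467 B/T + 0.3696 C_{wp}) + 2.38\,A_{BT}/C_b}
#'
#' @param hull A [hull_params()] object, a list, or a data frame with the
#'   seven hull fields (vectorized over rows).
#' @return Numeric vector of wetted surface areas in m^2.
#' @export
#' @examples
#' compute_direct_wsa(hull_params(100, 30, 5, 0.99, 0.90, 0.92))
compute_direct_wsa <- function(hull) {
  .validate_hull(hull)
  L <- hull$length_waterline
  B <- hull$beam
  T <- hull$draft
  cm <- hull$midship_coeff
  cb <- hull$block_coeff
  cwp <- hull$waterplane_coeff
  abt <- hull$bulb_transverse_area
  L * (2 * T + B) * sqrt(cm) *
    (0.453 + 0.4425 * cb - 0.2862 * cm - 0.003467 * B / T + 0.3696 * cwp) +
    2.38 * abt / cb
}

#' Total wetted surface area
#'
#' Augments a wetted surface area by its niche-area fraction:
#' `TWSA = WSA * (1 + N_p)`. Niche areas (sea chests, rudders, thruster
#' tunnels) accumulate disproportionate biofouling, so including them gives
#' a more realistic biofouling proxy.
#'
#' @param wsa Wetted surface area, m^2 (> 0).
#' @param niche_proportion Niche fraction of WSA, in `[0, 1)`.
#' @return `wsa * (1 + niche_proportion)`, always `>= wsa`.
#' @export
#' @examples
#' compute_twsa(1000, 0.09)
compute_twsa <- function(wsa, niche_proportion) {
  if (any(is.na(wsa)) || any(wsa <= 0)) {
    rlang::abort("wsa must be positive", class = "pppscore_domain_error")
  }
  if (any(is.na(niche_proportion)) || any(niche_proportion < 0) ||
      any(niche_proportion >= 1)) {
    rlang::abort("niche_proportion must be in [0, 1)",
                 class = "pppscore_domain_error")
  }
  wsa * (1 + niche_proportion)
}

#' Total wetted surface area of a barge + tug unit
#'
#' ATBs and unmanned barges arrive as a two-hull unit with distinct niche
#' proportions (0.033 for the barge, 0.25 for the tug). By default each
#' proportion is applied to its own component,
#' `TWSA = barge_wsa * 1.033 + tug_wsa * 1.25`; `niche_mode = "summed"`
#' instead applies the summed proportion to the combined area,
#' `(barge_wsa + tug_wsa) * 1.283`.
#'
#' @param barge_wsa,tug_wsa Component wetted surface areas, m^2 (> 0); both
#'   components are required.
#' @param niche_mode `"per_component"` (default) or `"summed"`.
#' @return Combined total wetted surface area, m^2.
#' @export
#' @examples
#' compute_twsa_composite(1000, 100)
compute_twsa_composite <- function(barge_wsa, tug_wsa,
                                   niche_mode = c("per_component", "summed")) {
  niche_mode <- match.arg(niche_mode)
  if (any(is.na(barge_wsa)) || any(is.na(tug_wsa)) ||
      any(barge_wsa <= 0) || any(tug_wsa <= 0)) {
    rlang::abort(
      "both barge and tug wetted surface areas are required and must be > 0",
      class = "pppscore_domain_error"
    )
  }
  if (niche_mode == "per_component") {
    barge_wsa * (1 + .niche_barge) + tug_wsa * (1 + .niche_tug)
  } else {
    (barge_wsa + tug_wsa) * (1 + .niche_barge + .niche_tug)
  }
}

#' Fit a wetted-surface-area power law to observed data
#'
#' Least-squares fit of `log(WSA)` on `log(GT)`, reported on the power-law
#' scale as slope `m` and exponent `b` with the log-log r-squared. Intended
#' for jurisdictions refitting the packaged coefficients to their own fleet.
#'
#' @param gross_tonnage,wsa Paired positive observations (at least 3).
#' @return A list of class `ppp_wsa_fit` with elements `m`, `b`,
#'   `r_squared`, `n`.
#' @export
#' @examples
#' gt <- c(1e3, 1e4, 1e5)
#' refit_regression(gt, 15 * gt^0.6294)
refit_regression <- function(gross_tonnage, wsa) {
  if (length(gross_tonnage) != length(wsa)) {
    rlang::abort("gross_tonnage and wsa must have equal length",
                 class = "pppscore_validation_error")
  }
  ok <- !is.na(gross_tonnage) & !is.na(wsa)
  if (sum(ok) < 3 || any(gross_tonnage[ok] <= 0) || any(wsa[ok] <= 0)) {
    rlang::abort(
      "refit_regression needs at least 3 strictly positive (GT, WSA) pairs",
      class = "pppscore_validation_error"
    )
  }
  y <- log(wsa[ok])
  fit <- stats::lm(y ~ log(gross_tonnage[ok]))
  ## r^2 computed directly: summary.lm warns on noiseless data
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(m = unname(exp(stats::coef(fit)[1])),
         b = unname(stats::coef(fit)[2]),
         r_squared = r2,
         n = sum(ok)),
    class = "ppp_wsa_fit"
  )
}

#' @export
print.ppp_wsa_fit <- function(x, ...) {
  cat(sprintf("WSA power-law fit: WSA = %.4g * GT^%.4f  (r^2 = %.4f, n = %d)\n",
              x$m, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Resolve total wetted surface area for a table of arrivals
#'
#' Computes each arrival's TWSA: regression types via
#' [estimate_wsa_from_gt()] and [compute_twsa()]; `atb`/`barge_tug` arrivals
#' via a per-component route that accepts either a precomputed WSA
#' (`precomputed_wsa`, `tug_precomputed_wsa`) or full hull dimensions
#' (`hull_*`, `tug_*` columns) for each of the barge and tug components.
#' Missing data is never defaulted silently: unresolvable rows get `NA` and
#' are described in the `"problems"` attribute of the result.
#'
#' @param arrivals Arrivals tibble (see [read_arrivals()] for the schema).
#' @param params Vessel-type parameter table.
#' @param niche_mode Niche handling for barge+tug units, see
#'   [compute_twsa_composite()].
#' @return Numeric vector of TWSA (m^2), `NA` where unresolvable, with a
#'   `"problems"` attribute (tibble of `arrival_id`, `problem`).
#' @export
arrival_twsa <- function(arrivals, params = vessel_type_params(),
                         niche_mode = c("per_component", "summed")) {
  niche_mode <- match.arg(niche_mode)
  .validate_params(params)
  type <- normalize_vessel_type(arrivals$vessel_type)
  n <- nrow(arrivals)
  twsa <- rep(NA_real_, n)
  problems <- list()

  col <- function(name) {
    if (name %in% names(arrivals)) arrivals[[name]] else rep(NA_real_, n)
  }

  ## regression route
  reg <- type %in% .regression_types
  gt <- arrivals$gross_tonnage
  bad_gt <- reg & (is.na(gt) | gt <= 0)
  if (any(bad_gt)) {
    problems <- c(problems, list(tibble::tibble(
      arrival_id = as.character(arrivals$arrival_id[bad_gt]),
      problem = "missing or nonpositive gross_tonnage"
    )))
  }
  use <- reg & !bad_gt
  if (any(use)) {
    wsa <- estimate_wsa_from_gt(gt[use], type[use], params)
    np <- params$niche_proportion[match(type[use], params$type_code)]
    twsa[use] <- compute_twsa(wsa, np)
  }

  ## direct route, per component (barge, tug)
  direct <- type %in% .direct_types
  if (any(direct)) {
    component_wsa <- function(prefix, pre_col) {
      out <- col(pre_col)
      hull <- lapply(.hull_fields, function(f) col(paste0(prefix, f)))
      names(hull) <- .hull_fields
      hull$bulb_transverse_area[is.na(hull$bulb_transverse_area)] <- 0
      complete <- Reduce(`&`, lapply(hull[.hull_fields[1:6]],
                                     function(v) !is.na(v)))
      valid <- complete &
        hull$length_waterline > 0 & hull$beam > 0 & hull$draft > 0 &
        hull$midship_coeff > 0 & hull$midship_coeff <= 1 &
        hull$block_coeff > 0 & hull$block_coeff <= 1 &
        hull$waterplane_coeff > 0 & hull$waterplane_coeff <= 1 &
        hull$bulb_transverse_area >= 0
      valid[is.na(valid)] <- FALSE
      need <- direct & is.na(out) & valid
      if (any(need)) {
        h <- lapply(hull, function(v) v[need])
        out[need] <- compute_direct_wsa(h)
      }
      out
    }
    barge_wsa <- component_wsa("hull_", "precomputed_wsa")
    tug_wsa <- component_wsa("tug_", "tug_precomputed_wsa")
    ok <- direct & !is.na(barge_wsa) & barge_wsa > 0 &
      !is.na(tug_wsa) & tug_wsa > 0
    miss <- direct & !ok
    if (any(miss)) {
      problems <- c(problems, list(tibble::tibble(
        arrival_id = as.character(arrivals$arrival_id[miss]),
        problem = paste0("barge/tug WSA unresolvable (need precomputed WSA ",
                         "or full hull dimensions for both components)")
      )))
    }
    if (any(ok)) {
      twsa[ok] <- compute_twsa_composite(barge_wsa[ok], tug_wsa[ok],
                                         niche_mode)
    }
  }

  problems <- if (length(problems) > 0) {
    dplyr::bind_rows(problems)
  } else {
    tibble::tibble(arrival_id = character(), problem = character())
  }
  attr(twsa, "problems") <- problems
  twsa
}
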