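# Vessel-type parameter table and vessel-type vocabulary.

#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## type codes handled by the GT power-law regressions
.regression_types <- c("general", "passenger", "roro", "bulker", "container",
                       "tanker")
## type codes whose WSA must be computed directly per hull (barge + tug units)
.direct_types <- c("atb", "barge_tug")

## niche proportions for the two components of an ATB / unmanned-barge unit
.niche_barge <- 0.033
.niche_tug <- 0.25

#' Default vessel-type parameters
#'
#' Returns the packaged wetted-surface-area regression parameters and niche
#' proportions, one row per vessel type. For the six regression types WSA is
#' estimated as `m * GT^b`; `niche_proportion` is the fraction of WSA in
#' niche areas (sea chests, rudders, thruster tunnels). The `atb` and
#' `barge_tug` rows carry `NA` regression parameters because their WSA is
#' computed directly from hull dimensions (see [compute_direct_wsa()]); their
#' niche proportions are applied per component (0.033 barge, 0.25 tug).
#'
#' @return A tibble with columns `type_code`, `m`, `b`, `niche_proportion`.
#' @seealso [read_vessel_type_params()] to override from a config file.
#' @export
#' @examples
#' vessel_type_params()
vessel_type_params <- function() {
  tibble::tibble(
    type_code = c(.regression_types, .direct_types),
    m = c(20.02, 5.46, 25.04, 15, 10.66, 17.57, NA_real_, NA_real_),
    b = c(0.5728, 0.6951, 0.5309, 0.6294, 0.6501, 0.6105, NA_real_, NA_real_),
    niche_proportion = c(0.09, 0.27, 0.09, 0.07, 0.09, 0.08,
                         NA_real_, NA_real_)
  )
}

.validate_params <- function(params) {
  req <- c("type_code", "m", "b", "niche_proportion")
  missing <- setdiff(req, names(params))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("vessel-type parameter table is missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "pppscore_validation_error"
    )
  }
  reg <- params[params$type_code %in% .regression_types, ]
  bad <- !is.na(reg$m) & !is.na(reg$b) &
    (reg$m <= 0 | reg$b <= 0 | reg$b >= 1 |
       reg$niche_proportion < 0 | reg$niche_proportion >= 1)
  if (any(bad | is.na(reg$m) | is.na(reg$b))) {
    rlang::abort(
      paste0("invalid regression parameters for type(s): ",
             paste(reg$type_code[bad | is.na(reg$m)], collapse = ", "),
             " (need m > 0, 0 < b < 1, 0 <= niche_proportion < 1)"),
      class = "pppscore_validation_error"
    )
  }
  invisible(params)
}

#' Read or write a vessel-type parameter table
#'
#' The parameter table is shippable as plain-text CSV with columns
#' `type_code,m,b,niche_proportion` so a jurisdiction can version its own
#' regression coefficients. Types absent from the file fall back to the
#' packaged defaults.
#'
#' @param path Path to a CSV file.
#' @param params A parameter table as returned by [vessel_type_params()].
#' @return `read_vessel_type_params()` returns the merged parameter tibble;
#'   `write_vessel_type_params()` returns `path` invisibly.
#' @export
read_vessel_type_params <- function(path) {
  user <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  user$type_code <- normalize_vessel_type(user$type_code)
  defaults <- vessel_type_params()
  merged <- rbind(user[names(defaults)],
                  defaults[!defaults$type_code %in% user$type_code, ])
  merged <- merged[match(defaults$type_code, merged$type_code), ]
  .validate_params(merged)
  merged
}

#' @rdname read_vessel_type_params
#' @export
write_vessel_type_params <- function(params, path) {
  .validate_params(params)
  readr::write_csv(params, path)
  invisible(path)
}

## canonical aliases, keyed on the normalized (lower case, punctuation
## collapsed) input string
.type_alias_map <- function(extra = NULL) {
  map <- c(
    "general" = "general", "general cargo" = "general", "cargo" = "general",
    "gen cargo" = "general",
    "passenger" = "passenger", "cruise" = "passenger",
    "cruise ship" = "passenger",
    "roro" = "roro", "ro ro" = "roro", "auto carrier" = "roro",
    "vehicle carrier" = "roro", "vehicles carrier" = "roro", "pcc" = "roro",
    "bulker" = "bulker", "bulk" = "bulker", "bulk carrier" = "bulker",
    "container" = "container", "containership" = "container",
    "container ship" = "container",
    "tanker" = "tanker", "product tanker" = "tanker",
    "crude tanker" = "tanker",
    "atb" = "atb", "articulated tug barge" = "atb",
    "barge tug" = "barge_tug", "barge_tug" = "barge_tug",
    "unmanned barge" = "barge_tug", "unmanned barge tug" = "barge_tug",
    "barge" = "barge_tug"
  )
  if (!is.null(extra)) {
    names(extra) <- .normalize_type_string(names(extra))
    map[names(extra)] <- unname(extra)
  }
  map
}

.normalize_type_string <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[-+/_]", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Normalize vessel-type labels
#'
#' Maps free-text vessel-type strings (case-insensitive; `"RO-RO"`,
#' `"Auto Carrier"`, `"Barge+Tug"`, ...) onto the canonical type codes
#' `general, passenger, roro, bulker, container, tanker, atb, barge_tug`.
#' Unmapped strings are an error, never a guess.
#'
#' @param x Character vector of vessel-type labels.
#' @param extra_aliases Optional named character vector of additional
#'   aliases (`c("my label" = "tanker")`), merged over the defaults.
#' @return Character vector of canonical type codes.
#' @export
#' @examples
#' normalize_vessel_type(c("RO-RO", "roro", "Auto Carrier"))
normalize_vessel_type <- function(x, extra_aliases = NULL) {
  map <- .type_alias_map(extra_aliases)
  key <- .normalize_type_string(as.character(x))
  ## canonical codes pass through (barge_tug has an underscore)
  key[key == "barge tug"] <- "barge tug"
  out <- unname(map[key])
  if (anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    rlang::abort(
      paste0("unrecognized vessel type(s): ",
             paste(shQuote(bad), collapse = ", "),
             ". Known codes: ",
             paste(c(.regression_types, .direct_types), collapse = ", "),
             "; pass extra_aliases to extend the vocabulary."),
      class = "pppscore_validation_error"
    )
  }
  out
}
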