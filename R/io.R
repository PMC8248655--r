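# Reading and writing arrival tables and results.

.required_cols <- c("arrival_id", "vessel_id", "vessel_type",
                    "gross_tonnage", "bwd_volume", "port", "arrival_date",
                    "compliant")
.optional_cols <- function() {
  c("precomputed_wsa", "tug_precomputed_wsa",
    paste0("hull_", .hull_fields), paste0("tug_", .hull_fields))
}

#' Default column aliases for arrival tables
#'
#' Maps the canonical arrival-table column names onto the header variants
#' seen in ballast-management exports. Matching is case-insensitive with
#' punctuation collapsed to underscores. Extend or override by modifying
#' the returned list and passing it to [read_arrivals()].
#'
#' @return Named list: canonical column name -> character vector of
#'   accepted header spellings.
#' @export
arrival_aliases <- function() {
  list(
    arrival_id = c("arrival_id", "arrival", "arrival_no", "id"),
    vessel_id = c("vessel_id", "imo", "imo_number", "vessel", "mmsi"),
    vessel_type = c("vessel_type", "type", "ship_type", "vessel_class"),
    gross_tonnage = c("gross_tonnage", "gt", "gross_tons", "grt",
                      "gross_tonnes"),
    bwd_volume = c("bwd_volume", "bwd", "ballast_water_discharge",
                   "discharge_volume", "bw_discharge", "bwd_m3"),
    port = c("port", "arrival_port", "port_name", "destination_port"),
    arrival_date = c("arrival_date", "date", "date_of_arrival"),
    compliant = c("compliant", "compliance", "compliant_flag"),
    precomputed_wsa = c("precomputed_wsa", "wsa", "barge_wsa"),
    tug_precomputed_wsa = c("tug_precomputed_wsa", "tug_wsa")
  )
}

.normalize_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("_+", "_", gsub("[^a-z0-9]+", "_", x))
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[key %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Read and validate an arrival table
#'
#' Reads a delimited text file (comma- or, for `.tsv`/`.txt`, tab-separated;
#' lines starting with `#` are comments) of one row per vessel arrival,
#' resolves column names through the alias map, and validates every row.
#' Rows failing validation — unparseable date, unknown vessel type,
#' nonpositive tonnage for a regression-typed vessel, negative discharge,
#' missing barge/tug WSA route — are dropped with their reasons collected in
#' the `"validation"` attribute, never silently coerced. A missing
#' `bwd_volume` (as opposed to a reported zero) is treated as 0 with a
#' warning: no discharge report is read as no discharge. A missing
#' `compliant` flag defaults to `TRUE` (vessels are assumed compliant unless
#' flagged).
#'
#' @param path Path to the delimited file.
#' @param aliases Alias map, default [arrival_aliases()].
#' @param date_format Optional `strptime`-style date format; default parses
#'   ISO-8601 (`YYYY-MM-DD`).
#' @param params Vessel-type parameter table (used to know which types need
#'   a positive tonnage).
#' @param extra_type_aliases Passed to [normalize_vessel_type()].
#' @return Validated arrivals tibble with attribute `"validation"` (tibble
#'   of `row`, `arrival_id`, `problem` for dropped rows).
#' @export
read_arrivals <- function(path, aliases = arrival_aliases(),
                          date_format = NULL,
                          params = vessel_type_params(),
                          extra_type_aliases = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path),
                 class = "pppscore_validation_error")
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           trim_ws = TRUE, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))

  ## resolve headers through the alias map
  header <- .normalize_header(names(raw))
  canonical <- names(raw)
  for (canon in names(aliases)) {
    hit <- which(header %in% .normalize_header(aliases[[canon]]))
    if (length(hit) > 0) canonical[hit[1]] <- canon
  }
  other <- .normalize_header(canonical) %in% c(.required_cols, .optional_cols())
  canonical[other] <- .normalize_header(canonical[other])
  names(raw) <- canonical

  missing <- setdiff(.required_cols, names(raw))
  if ("compliant" %in% missing) {
    raw$compliant <- TRUE
    missing <- setdiff(missing, "compliant")
  }
  if (length(missing) > 0) {
    rlang::abort(
      paste0("arrival table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "pppscore_validation_error"
    )
  }

  n <- nrow(raw)
  problems <- list()
  note <- function(rows, why) {
    if (any(rows)) {
      problems[[length(problems) + 1]] <<- tibble::tibble(
        row = which(rows),
        arrival_id = as.character(raw$arrival_id[rows]),
        problem = why
      )
    }
    rows
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    arrival_id = as.character(raw$arrival_id),
    vessel_id = as.character(raw$vessel_id),
    vessel_type = as.character(raw$vessel_type),
    gross_tonnage = num(raw$gross_tonnage),
    bwd_volume = num(raw$bwd_volume),
    port = as.character(raw$port),
    arrival_date = if (is.null(date_format)) {
      suppressWarnings(readr::parse_date(as.character(raw$arrival_date)))
    } else {
      suppressWarnings(readr::parse_date(as.character(raw$arrival_date),
                                         format = date_format))
    },
    compliant = .parse_logical(raw$compliant)
  )
  for (c in .optional_cols()) {
    if (c %in% names(raw)) out[[c]] <- num(raw[[c]])
  }
  out$compliant[is.na(out$compliant)] <- TRUE
  if (anyNA(out$bwd_volume)) {
    rlang::warn("missing bwd_volume treated as 0 (no discharge reported)")
    out$bwd_volume[is.na(out$bwd_volume)] <- 0
  }

  ## per-row validation
  type <- rep(NA_character_, n)
  type_ok <- logical(n)
  for (i in seq_len(n)) {
    t <- tryCatch(normalize_vessel_type(out$vessel_type[i],
                                        extra_type_aliases),
                  error = function(e) NA_character_)
    type[i] <- t
    type_ok[i] <- !is.na(t)
  }
  bad <- note(!type_ok, "unrecognized vessel type")
  out$vessel_type[type_ok] <- type[type_ok]

  bad <- bad | note(is.na(out$arrival_date), "unparseable arrival_date")
  bad <- bad | note(!bad & out$bwd_volume < 0, "negative bwd_volume")
  reg <- type_ok & type %in% .regression_types
  bad <- bad | note(reg & (is.na(out$gross_tonnage) | out$gross_tonnage <= 0),
                    "missing or nonpositive gross_tonnage")

  direct <- type_ok & type %in% .direct_types & !bad
  if (any(direct)) {
    twsa <- arrival_twsa(out[direct, , drop = FALSE], params)
    unresolved <- logical(n)
    unresolved[which(direct)[is.na(twsa)]] <- TRUE
    bad <- bad | note(unresolved,
                      "barge/tug WSA unresolvable (no hull data or WSA)")
  }

  validation <- if (length(problems) > 0) {
    dplyr::bind_rows(problems)
  } else {
    tibble::tibble(row = integer(), arrival_id = character(),
                   problem = character())
  }
  if (nrow(validation) > 0) {
    rlang::warn(paste0(length(unique(validation$row)), " of ", n,
                       " row(s) dropped during validation; see the ",
                       "'validation' attribute"))
  }
  out <- out[!bad, ]
  attr(out, "validation") <- validation
  out
}

#' Write an arrival table
#'
#' Writes the canonical comma-separated, UTF-8, ISO-8601-dated arrivals
#' format. A table written by `write_arrivals()` and read back by
#' [read_arrivals()] round-trips all validated fields.
#'
#' @param arrivals Arrivals tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrivals <- function(arrivals, path) {
  readr::write_csv(arrivals, path, na = "")
  invisible(path)
}

## write a results table with provenance comment lines readable back via
## comment = "#"
.write_result <- function(x, path, provenance = character()) {
  if (length(provenance) > 0) {
    readr::write_lines(paste0("# ", provenance), path)
    readr::write_csv(x, path, na = "", append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(x, path, na = "")
  }
  invisible(path)
}

#' Read a previously written scored-arrivals or results table
#'
#' @param path Path to a CSV written by [run_pipeline()] or the CLI
#'   (provenance comment lines starting `#` are skipped).
#' @return A tibble.
#' @export
read_result <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
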