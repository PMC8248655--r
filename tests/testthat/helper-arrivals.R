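# Builders for small in-code fixtures.

toy_arrivals <- function(n = 1, vessel_type = "container",
                         gross_tonnage = 50000, bwd_volume = 0,
                         port = "Oakland", arrival_date = "2018-01-01",
                         vessel_id = NULL, arrival_id = NULL,
                         compliant = TRUE, ...) {
  tibble::tibble(
    arrival_id = if (is.null(arrival_id)) sprintf("T%03d", seq_len(n))
                 else rep_len(arrival_id, n),
    vessel_id = if (is.null(vessel_id)) sprintf("V%03d", seq_len(n))
                else rep_len(vessel_id, n),
    vessel_type = rep_len(vessel_type, n),
    gross_tonnage = rep_len(gross_tonnage, n),
    bwd_volume = rep_len(bwd_volume, n),
    port = rep_len(port, n),
    arrival_date = rep_len(as.Date(arrival_date), n),
    compliant = rep_len(compliant, n),
    ...
  )
}

## barge+tug arrival whose TWSA is exact by construction:
## twsa = precomputed_wsa * 1.033 + tug_precomputed_wsa * 1.25
barge_arrival <- function(twsa, tug_wsa = 100, ...) {
  toy_arrivals(n = 1, vessel_type = "barge_tug", gross_tonnage = 1000,
               precomputed_wsa = (twsa - 1.25 * tug_wsa) / 1.033,
               tug_precomputed_wsa = tug_wsa, ...)
}

## a hand-built scored table for prioritization / aggregation tests
make_scored <- function(ppp_score, bwd_volume = 0,
                        arrival_date = "2018-06-01", vessel_id = NULL,
                        port = "Oakland", vessel_type = "container",
                        compliant = TRUE, arrival_id = NULL) {
  n <- length(ppp_score)
  tibble::tibble(
    arrival_id = if (is.null(arrival_id)) sprintf("S%04d", seq_len(n))
                 else arrival_id,
    vessel_id = if (is.null(vessel_id)) sprintf("V%04d", seq_len(n))
                else rep_len(vessel_id, n),
    vessel_type = rep_len(vessel_type, n),
    port = rep_len(port, n),
    arrival_date = rep_len(as.Date(arrival_date), n),
    bwd_volume = rep_len(bwd_volume, n),
    compliant = rep_len(compliant, n),
    twsa = ppp_score * 1000,
    bw_component = rep_len(0, n),
    bf_component = ppp_score,
    ppp_score = ppp_score
  )
}

## a baseline object with known medians, for arithmetic checks
fixed_baseline <- function(med_bwd, med_twsa) {
  structure(
    list(med_bwd = med_bwd, med_twsa = med_twsa,
         window_start = as.Date("2015-01-01"),
         window_end = as.Date("2017-12-31"),
         n_arrivals = 1L, n_discharging = 1L,
         bwd_policy = "discharging", median_unit = "arrival",
         niche_mode = "per_component"),
    class = "ppp_baseline"
  )
}
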