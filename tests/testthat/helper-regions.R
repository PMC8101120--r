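# Shared fixtures, built in code.

iran_params <- function() {
  region_params("Iran",
                incidence = 3.11,
                prevalence = c(27.0, 24.6, 29.6),
                ibd_death = c(0.16, 0.06, 0.19),
                bg_death = c(463.97, 452.58, 477.04),
                initial_cases = 23812, start_year = 2017)
}

# Small population so demographic noise is visible at desk scale.
toy_params <- function(pop = 1e5, prev = 500, inc = 20, ibd_death = 5,
                       bg_death = 800) {
  region_params("toy",
                incidence = inc,
                prevalence = c(prev, prev * 0.9, prev * 1.1),
                ibd_death = c(ibd_death, ibd_death * 0.9, ibd_death * 1.1),
                bg_death = c(bg_death, bg_death * 0.9, bg_death * 1.1),
                initial_cases = round(pop * prev / 1e5), start_year = 2017)
}

# Table 2 of the source rate table: printed prevalent-case projections
# (thousands) used as reference values in the acceptance checks.
printed_projection <- function() {
  list(
    iran_det   = c(`2017` = 23.812, `2020` = 31.445, `2025` = 43.955,
                   `2030` = 56.207, `2035` = 68.207),
    iran_stoch_2035 = 69.166,
    det_2020 = c("High-income Asia-Pacific" = 104.918,
                 "East Asia" = 2835,
                 "Southeast Asia" = 119.716,
                 "North Africa and Middle East" = 222.746,
                 "South Asia (India)" = 549.418)
  )
}
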