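# shared builders for small deterministic fixtures

gaussian_spectrum <- function(mu, sigma, grid, amp = 1) {
  spectrum(grid, amp * exp(-((grid - mu) / sigma)^2 / 2))
}

# noiseless Naka-Rushton responses at given log irradiances
nr_responses <- function(log_i, r_max, log_k) {
  r_max / (1 + 10^(log_k - log_i))
}

# RI data frame for one wavelength
ri_frame <- function(wavelength, log_i, resp) {
  data.frame(wavelength_nm = wavelength, log_irradiance = log_i,
             response_uV = resp)
}

# a noiseless multi-wavelength RI table from per-wavelength LogK values
ri_table <- function(log_k_by_wl, r_max = 100, span = 2, n_levels = 8,
                     individual = "f1", condition = "control") {
  do.call(rbind, lapply(names(log_k_by_wl), function(w) {
    lk <- log_k_by_wl[[w]]
    li <- seq(lk - span, lk + span, length.out = n_levels)
    data.frame(individual = individual, condition = condition,
               wavelength_nm = as.numeric(w), log_irradiance = li,
               response_uV = nr_responses(li, r_max, lk))
  }))
}

noiseless_config <- function(...) {
  synthetic_config(log_sens_sigma = 0, response_sigma = 0, cq_sigma = 0, ...)
}
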