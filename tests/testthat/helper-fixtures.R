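# Published posterior-median rates of the motivating two-arm schizophrenia
# trial (per week), used as realistic plug-in inputs throughout the suite.
ami_rates <- function() transition_rates3(0.189, 0.052, 0.076, 0.024)
ris_rates <- function() transition_rates3(0.136, 0.047, 0.056, 0.009)

both_arms <- function() list(amisulpride = ami_rates(),
                             risperidone = ris_rates())

# Random valid rate sets for property-style tests.
random_rates <- function(max_rate = 2) {
  transition_rates3(stats::runif(1, 0, max_rate), stats::runif(1, 0, max_rate),
                    stats::runif(1, 0, max_rate), stats::runif(1, 0, max_rate))
}

# Frozen oracle values, computed independently with Matrix::expm on the
# generator and adaptive quadrature of the occupancy probabilities.
oracle <- list(
  ami_pi8 = c(p11 = 0.2549861, p12 = 0.4713147, p13 = 0.2736992,
              p21 = 0.1895230, p22 = 0.6066020, p23 = 0.2038750),
  ris_pi8_p12 = 0.4529500,
  ami_h = 0.2780953,
  ets_ami = c(3.973035, 2.795889, 1.231076),
  ets_ris = c(4.492837, 2.431933, 1.075230),
  or12 = 0.9287734, or13 = 0.8063561,
  or23 = 0.4654065, or21 = 0.9804478,
  rate_ratios = c(gamma12 = 0.7195767, gamma13 = 0.9038462,
                  gamma21 = 0.7368421, gamma23 = 0.3750000),
  pdwr_ami_8 = 0.1843867,
  split_ami_8 = c(from_nonresponse = 0.2065978, from_response = 0.0671013),
  mnar_or = 0.9117866, mar_or = 0.8113523
)
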