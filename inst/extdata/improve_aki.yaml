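# Canonical model inputs for the IMPROVE AKI implementation-strategy
# cost-effectiveness model. Probabilities and utilities are fractions;
# money is 2020 USD. 95% CIs come from trial data where available; other
# ranges are +/-25% of the base case. The AKI episode cost range is set to
# +/-25% of the base case (the literature estimate carries no usable
# interval).
model: aki-prevention-cea
currency_year: 2020
units: fraction
settings:
  discount_rate: 0.03
  horizon_years: 3
  wtp: 100000
  wtp_secondary: 50000
strategies:
  assistance:
    p_aki: {mean: 0.133, ci: [0.110, 0.156]}
    upfront_cost: {mean: 2.69, low: 2.02, high: 3.36}
  assistance_surveillance:
    p_aki: {mean: 0.114, ci: [0.095, 0.133]}
    upfront_cost: {mean: 3.36, low: 2.52, high: 4.20}
  collaborative:
    p_aki: {mean: 0.127, ci: [0.111, 0.144]}
    upfront_cost: {mean: 3.97, low: 2.98, high: 4.96}
  collaborative_surveillance:
    p_aki: {mean: 0.079, ci: [0.064, 0.095]}
    upfront_cost: {mean: 12.74, low: 9.56, high: 15.93}
thirty_day:
  aki:
    normal: {mean: 0.869, ci: [0.863, 0.874]}
    ckd: {mean: 0.036, ci: [0.033, 0.039]}
    esrd: {mean: 0.004, ci: [0.003, 0.005]}
    death: {mean: 0.091, ci: [0.087, 0.097]}
  no_aki:                      # printed row sums to 0.999; renormalized at load
    normal: {mean: 0.973, ci: [0.972, 0.974]}
    ckd: {mean: 0.012, ci: [0.011, 0.013]}
    esrd: {mean: 0.0, ci: [0.0, 0.0]}
    death: {mean: 0.014, ci: [0.014, 0.015]}
annual:                        # mean of the three observed yearly tables
  normal_post_aki:
    ckd: {mean: 0.028, ci: [0.021, 0.035]}
    esrd: {mean: 0.003, ci: [0.002, 0.004]}
    death: {mean: 0.123, ci: [0.092, 0.154]}
  normal_no_aki:
    ckd: {mean: 0.010, ci: [0.008, 0.013]}
    esrd: {mean: 0.0005, ci: [0.0004, 0.0006]}
    death: {mean: 0.067, ci: [0.050, 0.084]}
  ckd_post_aki:
    esrd: {mean: 0.047, ci: [0.035, 0.059]}
    death: {mean: 0.297, ci: [0.223, 0.371]}
  ckd_no_aki:
    esrd: {mean: 0.018, ci: [0.014, 0.023]}
    death: {mean: 0.273, ci: [0.205, 0.341]}
  esrd_post_aki:
    death: {mean: 0.345, ci: [0.259, 0.431]}
  esrd_no_aki:
    death: {mean: 0.275, ci: [0.206, 0.344]}
utilities:
  normal: {mean: 0.85, ci: [0.83, 0.87]}
  ckd: {mean: 0.80, ci: [0.70, 1.00]}
  esrd: {mean: 0.70, ci: [0.60, 0.80]}
costs:
  aki_episode: {mean: 14000, low: 10500, high: 17500}
  ckd_annual: {mean: 25322, low: 18992, high: 31653}
  esrd_annual: {mean: 78537, low: 58903, high: 98171}
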