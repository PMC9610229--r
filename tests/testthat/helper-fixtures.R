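# Shared builders for the test suite.

default_config <- function(length_mm = 40, wall_mm = 0.2, loading = NA_real_) {
  implant_config(length_mm = length_mm, wall_thickness_mm = wall_mm,
                 outer_diameter_mm = 2.5, drug_loading_mg = loading)
}

# Raw-transform spec for the five standard predictors except log10(CsE),
# matching the published functional form.
published_transforms <- function() {
  list(mw = "raw", cse = "logarithm", csp = "raw", pka = "raw", logp = "raw")
}

# log-uniform draws
runif_log <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))
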