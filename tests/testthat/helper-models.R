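# shared fixtures, computed once per test run
.pm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pm_cache)) {
    assign(key, force(expr), envir = .pm_cache)
  }
  get(key, envir = .pm_cache)
}

study_ion_table <- function() cached("ions", kiwi_ion_table())
study_responses <- function() cached("resp", kiwi_responses())
study_salts <- function() {
  cached("salts",
         design_to_salt_table(kiwi_design()[1:34, names(factor_groups())]))
}

# the six fitted additive-spline models (shared by several test files)
study_nf_models <- function() {
  cached("nf_models", {
    X <- study_ion_table()
    resp <- study_responses()
    out <- lapply(response_names(), function(r) {
      cfg <- nf_config(C1 = if (r == "SN") 0.8 else 0.868)
      asmod_fit(X, resp[[paste0(r, "_mean")]], cfg, output = r)
    })
    stats::setNames(out, response_names())
  })
}

# printed decimal places per ion column of the bundled treatment table
printed_digits <- function() {
  c(NH4 = 2, NO3 = 2, K = 2, Ca = 2, Mg = 2, PO4 = 2, SO4 = 2, Cl = 2,
    Fe = 2, BO3 = 2, Mn = 2, Zn = 3, Cu = 5, MoO2 = 4, Na = 2, Co = 5,
    I = 4, EDTA = 2)
}
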