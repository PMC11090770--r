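# Shared test helpers: small input bundles and random-parameter generators.

# base-case bundle, built once per test file load
fixture <- base_case_fixture()

# a bundle with every transition probability zero and a planned-exchange
# interval beyond the horizon: the cohort stays Patent forever
inert_inputs <- function(u_patent_annual = 0.8, horizon = 60) {
  inp <- base_case_fixture()
  inp$settings <- model_settings(
    horizon = horizon,
    reporting_horizons = unique(c(12, horizon)),
    discount_rate_annual = inp$settings$discount_rate_annual)
  zero <- param_value(0, family = "beta")
  inp$clinical$p_death <- zero
  for (nm in names(inp$clinical$by_strategy)) {
    inp$clinical$by_strategy[[nm]]$p_fail <- zero
    inp$clinical$by_strategy[[nm]]$p_uti <- zero
  }
  for (i in seq_along(inp$strategies)) {
    inp$strategies[[i]]$planned_exchange_interval <- as.integer(horizon + 12)
  }
  inp$utilities$u_patent <- param_value(u_patent_annual, family = "beta")
  inp
}

# random valid monthly probability set (p_fail + p_uti + p_death <= 1)
random_clinical <- function() {
  repeat {
    cl <- list(p_fail = runif(1, 0, 0.6), p_uti = runif(1, 0, 0.2),
               p_death = runif(1, 0, 0.3), p_uti_resolve = runif(1))
    if (cl$p_fail + cl$p_uti + cl$p_death <= 1) return(cl)
  }
}

# bundle whose uncertain parameters are all degenerate (low == base == high)
degenerate_inputs <- function() {
  inp <- base_case_fixture()
  for (path in names(flatten_params(inp))) {
    pv <- get_param(inp, path)
    inp <- set_param(inp, path, pv$base)
    # collapse the bounds onto the base
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    fixed <- param_value(pv$base, family = pv$family,
                         provenance = pv$provenance)
    inp <- replace_pv(inp, parts, fixed)
  }
  inp
}

replace_pv <- function(inputs, parts, pv) {
  strat_names <- vapply(inputs$strategies, function(s) s$name, "")
  if (parts[1] == "clinical" && length(parts) == 2) {
    inputs$clinical[[parts[2]]] <- pv
  } else if (parts[1] == "clinical") {
    inputs$clinical$by_strategy[[parts[2]]][[parts[3]]] <- pv
  } else if (parts[1] == "utilities") {
    inputs$utilities[[parts[2]]] <- pv
  } else if (parts[1] == "costs") {
    inputs$costs[[parts[2]]] <- pv
  } else if (parts[1] == "strategies") {
    inputs$strategies[[match(parts[2], strat_names)]][[parts[3]]] <- pv
  } else if (parts[1] == "settings") {
    inputs$settings[[parts[2]]] <- pv
  }
  inputs
}
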