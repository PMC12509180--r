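# Shared fixtures and independent oracles, all built in code.

# Independent normal-equations OLS solver (never calls lm).
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# A small simulated experiment with the network variance components.
sim_fixture <- function(n_sites = 6, family = "null", effect_pct = 0,
                        vc = variance_components(), seed = 101, ...) {
  simulate_experiment(build_design(n_sites, 3, seed = seed),
                      effect_scenario(family, effect_pct), vc,
                      seed = seed, ...)
}

# Full-factorial term labels in R's canonical order.
full_factorial <- "insecticide * fungicide * molluscicide"
rcb_random <- c("site_id", "site_id:block_id")

drop_term_fixed <- function(term) {
  terms <- attr(stats::terms(stats::reformulate(full_factorial)), "term.labels")
  paste(setdiff(terms, term), collapse = " + ")
}
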