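# small deterministic fixtures built in code

# single-level exponential truth used across tests
toy_exp_params <- function(var = 0.1) {
  mn_params("exponential", a = c(all = 1), b = c(all = 0.05),
            c = 4, d = 1, var = c(all = var))
}

# individual-form data frame on a curve with multiplicative lognormal noise
toy_dataset <- function(params = toy_exp_params(), doses = c(0, 5, 25),
                        n = 3, seed = 42, level = params$levels[1]) {
  generate_dataset(params, doses, n_per_group = n, seed = seed)
}

# independent per-observation lognormal log-likelihood (oracle; no reuse
# of package internals beyond the public curve formula)
brute_force_ll <- function(df, params) {
  sum(vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    m <- params$a[[r$covariate_level]] *
      switch(params$family,
             exponential = params$c - (params$c - 1) *
               exp(-params$b[[r$covariate_level]] * r$dose^params$d),
             hill = 1 + (params$c - 1) * r$dose^params$d /
               (params$b[[r$covariate_level]]^params$d + r$dose^params$d))
    v <- params$var[[r$covariate_level]]
    -0.5 * log(2 * pi * v) - (log(r$response) - log(m))^2 / (2 * v)
  }, 0))
}

# random valid parameter draw for property tests (c - 1 kept above ces)
random_params <- function(family, ces = 0.5) {
  a <- exp(stats::runif(1, -3, 2))
  d <- stats::runif(1, 0.25, 4)
  cc <- 1 + ces + exp(stats::runif(1, -1, 4))
  b <- if (family == "hill") exp(stats::runif(1, -2, 5))
       else exp(stats::runif(1, -8, 1))
  mn_params(family, a = c(all = a), b = c(all = b), c = cc, d = d,
            var = c(all = 0.1))
}
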