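# small cohort builders shared across tests

# single-sex cohort drawn from the shipped reference triples, n per age
make_ref_cohort <- function(sex = "boys", n_per_age = 300, seed = 1) {
  sp <- default_spec()
  sp <- sp[sp$sex == sex, ]
  sp$n <- n_per_age
  generate_cohort(sp, seed = seed)
}

# constant-parameter single-sex cohort (lambda, mu, sigma fixed across ages)
make_const_cohort <- function(lambda = 1, mu = 20, sigma = 0.2,
                              ages = 12:16, n_per_age = 300, seed = 1,
                              sex = "boys") {
  sp <- data.frame(sex = sex, age = ages, n = n_per_age,
                   L = lambda, M = mu, S = sigma,
                   height_median = 160, height_iqr = 10,
                   weight_median = 45, weight_iqr = 10)
  generate_cohort(generator_spec(sp), seed = seed)
}
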