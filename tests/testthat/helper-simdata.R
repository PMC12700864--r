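# direct simulation of the analysis table (bypassing surveys/methylation)
# for mixed-model and selection tests: the response follows
# y = b0 + beta_age*age + beta_bond*(z - mean z) + beta_group*(g - mean g)
#     + u[individual] + v[year] + eps
sim_lmm_data <- function(n = 200, n_ind = 100, n_year = 25,
                         beta_bond = -9.75, beta_group = 0.90,
                         beta_age = 0.74, b0 = 1.75,
                         sigma_id = 1.5, sigma_year = 0.5,
                         sigma_resid = 1.5, seed = 1) {
  set.seed(seed)
  id <- sample(sprintf("i%03d", seq_len(n_ind)), n, replace = TRUE)
  yr <- sample(seq_len(n_year) + 1999, n, replace = TRUE)
  z <- rbeta(n, 2.9, 4.4)          # bond strength: mean ~0.40, SD ~0.17
  g <- rgamma(n, shape = 7.7, scale = 0.52) # group size: mean ~4, SD ~1.44
  age <- runif(n, 0, 30)
  cv <- rgamma(n, shape = 4, scale = 0.25)  # uninformative extra predictor
  u <- setNames(rnorm(n_ind, 0, sigma_id), sprintf("i%03d", seq_len(n_ind)))
  v <- setNames(rnorm(n_year, 0, sigma_year),
                as.character(seq_len(n_year) + 1999))
  eps <- rnorm(n, 0, sigma_resid)
  y <- b0 + beta_age * age + beta_bond * (z - mean(z)) +
    beta_group * (g - mean(g)) + u[id] + v[as.character(yr)] + eps
  data.frame(epigenetic_age = unname(y), bond_strength_norm = z,
             mean_male_group_size = g, chronological_age = age,
             cv_bond = cv, individual_id = id, year_sampled = yr,
             stringsAsFactors = FALSE)
}

design3 <- function(d)
  cbind("(Intercept)" = 1,
        bond_strength_norm = d$bond_strength_norm,
        mean_male_group_size = d$mean_male_group_size,
        chronological_age = d$chronological_age)
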