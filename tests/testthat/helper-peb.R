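# shared fixtures: biological-variation parameter rows used across tests
# (CVs in percent, population mean on the original scale)
bv_rows <- list(
  albumin   = list(cv_i = 2.3,  cv_g = 6.0,  cv_a = 1.8, mu = 4.522),
  phosphate = list(cv_i = 9.5,  cv_g = 13.6, cv_a = 1.7, mu = 3.327),
  doc11     = list(cv_i = 50.0, cv_g = 33.5, cv_a = 5.3, mu = 31.91)
)

bv_row_params <- function(row) {
  bv_to_peb(bv_estimates(row$cv_i, row$cv_g, row$cv_a, row$mu))
}

# log-scale CV that yields a given working-scale variance
cv_for_var <- function(v) 100 * sqrt(exp(v) - 1)

# simulation config whose working-scale intraclass correlation is exactly b1
config_for_b1 <- function(b1, total_var = 0.04, ...) {
  simulation_config(mu_pop_original = 10,
                    cv_g_pct = cv_for_var(b1 * total_var),
                    cv_i_pct = cv_for_var((1 - b1) * total_var),
                    cv_a_pct = 0, ...)
}

# working-scale result pairs drawn straight from the hierarchical model
draw_pairs <- function(n_pairs, b1, sigma_pop = 1, mu = 0, seed = 1) {
  set.seed(seed)
  sg <- sqrt(b1) * sigma_pop
  si <- sqrt(1 - b1) * sigma_pop
  mu_i <- rnorm(n_pairs, mu, sg)
  data.frame(subject_id = sprintf("P%05d", seq_len(n_pairs)),
             x_prev = rnorm(n_pairs, mu_i, si),
             x_next = rnorm(n_pairs, mu_i, si))
}

albumin_lis_params <- function() {
  peb_parameters(3.181, 0.241, 0.66, scale = "boxcox", lambda = 0.890,
                 analyte = "albumin")
}
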