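# Independent oracles and small fixture factories shared across tests.

# Kinetic Monte-Carlo oracle for multi-pathway transfer: the donor decays at
# rate 1 and transfers to acceptor i at rate o_i = e_i / (1 - e_i); the
# efficiency is the fraction of excitations that leave via any transfer
# pathway. Independent of the odds-summation formula it checks.
kmc_efficiency <- function(e_list, n_trials = 1e5, rate_scale = 1) {
  t_decay <- stats::rexp(n_trials, rate = 1)
  t_transfer <- rep(Inf, n_trials)
  for (e in e_list) {
    o <- e / (1 - e) * rate_scale
    if (o > 0) t_transfer <- pmin(t_transfer, stats::rexp(n_trials, rate = o))
  }
  mean(t_transfer < t_decay)
}

# brute-force balanced two-way ANOVA from the cell-mean partition formulas
brute_anova <- function(df) {
  a_lev <- sort(unique(df$genotype)); b_lev <- sort(unique(df$uv))
  n <- nrow(df[df$genotype == a_lev[1] & df$uv == b_lev[1], ])
  gm <- mean(df$value)
  m_a <- tapply(df$value, df$genotype, mean)[a_lev]
  m_b <- tapply(df$value, df$uv, mean)[as.character(b_lev)]
  m_ab <- tapply(df$value, list(df$genotype, df$uv), mean)[a_lev, as.character(b_lev)]
  ss_a <- n * length(b_lev) * sum((m_a - gm)^2)
  ss_b <- n * length(a_lev) * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, length(b_lev))) -
                      outer(rep(1, length(a_lev)), m_b) + gm)^2)
  ss_tot <- sum((df$value - gm)^2)
  ss_res <- ss_tot - ss_a - ss_b - ss_ab
  df_res <- nrow(df) - length(a_lev) * length(b_lev)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_res = ss_res,
       ss_tot = ss_tot,
       f_a = (ss_a / (length(a_lev) - 1)) / (ss_res / df_res),
       f_b = (ss_b / (length(b_lev) - 1)) / (ss_res / df_res),
       f_ab = (ss_ab / ((length(a_lev) - 1) * (length(b_lev) - 1))) /
         (ss_res / df_res))
}

# a population whose donor-weighted mean efficiency is exactly `e`
single_path_state <- function(e) {
  population_state("NcCg", "WT", dimer_fraction = 0)
}
single_path_params <- function(e, beta = 0.05, alpha = 0.02) {
  fret_params(E_intra = e, E_inter = 0, beta_bleed = beta,
              alpha_direct = alpha)
}

# small, fast configs for tests
tiny_config <- function(state, params = fret_params(), seed = 1L, ...) {
  simulation_config(state, params, n_cells = 4, image_size = 64,
                    seed = seed, ...)
}
noiseless_config <- function(state, params = fret_params(), seed = 1L, ...) {
  simulation_config(state, params, noise_read_sd = 0, shot_noise = FALSE,
                    expression_cv = 0, seed = seed, ...)
}
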