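test_that("Forster law: half point, contact limit, sixth-power decay", {
  for (R0 in c(2, 5, 7.3)) {
    expect_identical(forster_efficiency(R0, R0), 0.5)
    expect_equal(forster_efficiency(2 * R0, R0), 1 / 65)
  }
  expect_gt(forster_efficiency(1e-6, 5), 1 - 1e-10)
  # strictly decreasing in r
  r <- seq(0.5, 15, by = 0.1)
  expect_true(all(diff(forster_efficiency(r, 5)) < 0))
  expect_error(forster_efficiency(0, 5), "positive")
  expect_error(forster_efficiency(3, -1), "positive")
})

test_that("pathway combination is rate-additive, commutative, dominated below 1", {
  expect_identical(combine_acceptors(c(0, 0)), 0)
  expect_equal(combine_acceptors(c(0.37, 0)), 0.37)
  expect_equal(combine_acceptors(c(0.5, 0.5)), 2 / 3)
  expect_identical(combine_acceptors(c(0.3, 1)), 1)
  expect_error(combine_acceptors(c(0.5, 1.2)), "0, 1")
  withr::with_seed(11, {
    for (k in 1:20) {
      e <- runif(sample(2:4, 1), 0, 0.95)
      comb <- combine_acceptors(e)
      expect_equal(comb, combine_acceptors(rev(e)))
      expect_gte(comb, max(e))
      expect_lt(comb, 1)
      # the probabilistic-OR alternative overcounts: it never falls below
      # the rate-additive value
      expect_gte(combine_acceptors(e, rule = "or"), comb - 1e-12)
    }
  })
})

test_that("pathway combination matches the kinetic Monte-Carlo oracle within 1%", {
  grid <- expand.grid(e1 = seq(0.1, 0.9, by = 0.2),
                      e2 = seq(0.1, 0.9, by = 0.2))
  withr::with_seed(21, {
    for (i in seq_len(nrow(grid))) {
      e <- c(grid$e1[i], grid$e2[i])
      mc <- kmc_efficiency(e, n_trials = 1e5)
      expect_equal(combine_acceptors(e), mc, tolerance = 0.01)
    }
  })
})

test_that("random assortment of dual homotags is binomial and sums to one", {
  a <- assort_2in1_dimers(0.5)
  expect_equal(a$prob, c(0.25, 0.5, 0.25))
  expect_equal(assort_2in1_dimers(1)$prob, c(1, 0, 0))
  expect_equal(assort_2in1_dimers(0.2)$prob, c(0.04, 0.32, 0.64))
  for (p in seq(0, 1, by = 0.05)) {
    probs <- assort_2in1_dimers(p)$prob
    expect_equal(sum(probs), 1)
  }
  # the mixed (FRET-competent) dimer is maximized at a 1:1 ratio
  gm <- vapply(seq(0, 1, by = 0.01),
               function(p) assort_2in1_dimers(p)$prob[2], 0)
  expect_equal(which.max(gm), 51L)
  expect_error(assort_2in1_dimers(1.1), "0, 1")
})

test_that("species mixtures encode the two-source model", {
  p <- fret_params(E_intra = 0.15, E_inter = 0.30)

  # fully monomerized dual-tag construct: intramolecular pathway only
  m0 <- species_mixture(population_state("NcCg", "WT", dimer_fraction = 0), p)
  expect_equal(nrow(m0), 1L)
  expect_equal(m0$weight, 1)
  expect_equal(m0$efficiency, p$E_intra)

  # dual-tag dimer: both pathways combined
  m1 <- species_mixture(population_state("NcCg", "WT", dimer_fraction = 1), p)
  expect_equal(m1$efficiency[m1$species == "NcCg_dimer"],
               combine_acceptors(c(p$E_intra, p$E_inter)))

  # co-expression at full dimerization: binomial weights, only GM transfers
  m2 <- species_mixture(
    population_state("TwoInOne", "WT", dimer_fraction = 1, p_gfp = 0.5), p)
  expect_equal(sort(m2$species), sort(c("GG_dimer", "GM_dimer", "MM_dimer")))
  w <- setNames(m2$weight, m2$species)
  expect_equal(unname(w[c("GG_dimer", "GM_dimer", "MM_dimer")]),
               c(0.25, 0.5, 0.25))
  expect_equal(m2$efficiency[m2$species == "GM_dimer"], p$E_inter)
  expect_true(all(m2$efficiency[m2$species != "GM_dimer"] == 0))

  # fully monomeric co-expression: no transfer anywhere
  m3 <- species_mixture(
    population_state("TwoInOne", "constitutive_monomer", dimer_fraction = 0), p)
  expect_true(all(m3$efficiency == 0))
  expect_equal(mean_efficiency(m3), 0)

  # weights always sum to one
  withr::with_seed(5, {
    for (k in 1:20) {
      st <- population_state(sample(c("NcCg", "TwoInOne"), 1), "WT",
                             dimer_fraction = runif(1),
                             p_gfp = runif(1))
      expect_equal(sum(species_mixture(st, p)$weight), 1, tolerance = 1e-12)
    }
  })
})

test_that("channel model: artifacts, monotonicity, donor post-transfer dimming", {
  # no transfer, no artifacts: dark FRET channel
  p0 <- fret_params(E_intra = 0, E_inter = 0, beta_bleed = 0,
                    alpha_direct = 0)
  mix0 <- species_mixture(population_state("NcCg", "WT", dimer_fraction = 0), p0)
  ch0 <- expected_channel_intensities(mix0, p0, 10)
  expect_equal(ch0$fret_488, 0)

  # bleed-through-only false positive: FRET/donor ratio equals beta exactly
  pb <- fret_params(E_intra = 0, E_inter = 0, beta_bleed = 0.07,
                    alpha_direct = 0)
  mixb <- species_mixture(population_state("TwoInOne", "WT",
                                           dimer_fraction = 0, p_gfp = 1), pb)
  chb <- expected_channel_intensities(mixb, pb, 10)
  expect_equal(chb$fret_488 / chb$donor_488, 0.07)

  # FRET channel rises and donor channel falls with mean efficiency
  p <- fret_params()
  states <- lapply(c(0.2, 0.5, 0.8), function(f) {
    species_mixture(population_state("NcCg", "WT", dimer_fraction = f), p)
  })
  ch <- lapply(states, expected_channel_intensities, params = p,
               donor_density = 10)
  fret <- vapply(ch, `[[`, 0, "fret_488")
  donor <- vapply(ch, `[[`, 0, "donor_488")
  ratio <- fret / donor
  expect_true(all(diff(fret) > 0))
  expect_true(all(diff(donor) < 0))
  expect_true(all(diff(ratio) > 0))
  expect_error(expected_channel_intensities(states[[1]], p, -1),
               "non-negative")
})

test_that("sensitized ratio orders conditions and never favours co-expression", {
  p <- fret_params()
  ratio_of <- function(construct, f) {
    expected_sensitized_ratio(
      species_mixture(population_state(construct, "WT", dimer_fraction = f), p),
      p)
  }
  fs <- seq(0, 1, by = 0.1)
  r_nccg <- vapply(fs, ratio_of, 0, construct = "NcCg")
  r_2in1 <- vapply(fs, ratio_of, 0, construct = "TwoInOne")
  # strictly decreasing in monomer fraction = increasing in dimer fraction
  expect_true(all(diff(r_nccg) > 0))
  expect_true(all(diff(r_2in1) > 0))
  # co-expression reports at most the dual-tag signal at equal parameters
  expect_true(all(r_2in1 <= r_nccg + 1e-12))
  # with no inter-monomer pathway the dual-tag ratio is flat in dimer fraction
  p_flat <- fret_params(E_intra = 0.15, E_inter = 0)
  r_flat <- vapply(fs, function(f) {
    expected_sensitized_ratio(
      species_mixture(population_state("NcCg", "WT", dimer_fraction = f),
                      p_flat), p_flat)
  }, 0)
  expect_equal(max(r_flat) - min(r_flat), 0, tolerance = 1e-12)
})

test_that("photobleach recovery: exact identity, partial-bleach physics, errors", {
  p <- single_path_params(0.2)
  mix <- species_mixture(single_path_state(0.2), p)
  expect_equal(mean_efficiency(mix), 0.2)
  expect_equal(expected_bleach_increase(mix, p, 1), 25)

  # no transfer, nothing to recover
  p0 <- single_path_params(0)
  mix0 <- species_mixture(single_path_state(0), p0)
  expect_equal(expected_bleach_increase(mix0, p0, 1), 0)
  expect_equal(expected_bleach_increase(mix0, p0, 0.4), 0)

  # exact identity 100 E/(1-E) for single-path species across a grid
  for (e in seq(0.05, 0.9, by = 0.05)) {
    pe <- single_path_params(e)
    expect_equal(
      expected_bleach_increase(species_mixture(single_path_state(e), pe), pe, 1),
      100 * e / (1 - e))
  }

  # partial bleach: rate scaled by (1 - c); checked against the kinetic
  # Monte-Carlo oracle run with the transfer rate halved
  e_half_formula <- (0.25 * 0.5) / (1 + 0.25 * 0.5) # odds 0.25 at half rate
  expect_equal(expected_bleach_increase(mix, p, 0.5),
               100 * (0.2 - e_half_formula) / (1 - 0.2))
  withr::with_seed(31, {
    e_half_mc <- kmc_efficiency(0.2, n_trials = 2e5, rate_scale = 0.5)
  })
  expect_equal(expected_bleach_increase(mix, p, 0.5),
               100 * (0.2 - e_half_mc) / (1 - 0.2), tolerance = 0.02)

  # recovery increases with efficiency and with completeness
  incs_e <- vapply(c(0.1, 0.2, 0.4), function(e) {
    pe <- single_path_params(e)
    expected_bleach_increase(species_mixture(single_path_state(e), pe), pe, 0.9)
  }, 0)
  expect_true(all(diff(incs_e) > 0))
  incs_c <- vapply(c(0.3, 0.6, 1), function(cc) {
    expected_bleach_increase(mix, p, cc)
  }, 0)
  expect_true(all(diff(incs_c) > 0))

  # saturated donor quenching has unbounded recovery
  p1 <- fret_params(E_intra = 1, E_inter = 0)
  mix1 <- species_mixture(population_state("NcCg", "WT", dimer_fraction = 0), p1)
  expect_error(expected_bleach_increase(mix1, p1, 1), "unbounded")
})

test_that("parameter and state constructors enforce their domains", {
  expect_error(fret_params(beta_bleed = 1), "beta_bleed")
  expect_error(fret_params(E_intra = 1.3))
  expect_error(fret_params(E_intra = 0.2, r_intra = 5), "not both")
  # distance-specified efficiency follows the Forster law
  p <- fret_params(r_intra = 5, r_inter = 5 * 2^(1 / 6), R0 = 5)
  expect_equal(p$E_intra, 0.5)
  expect_equal(p$E_inter, 1 / 3)
  expect_error(population_state("NcCg", "WT", dimer_fraction = 1.4))
  expect_error(population_state("NcCg", "constitutive_monomer",
                                dimer_fraction = 0.9), "0.2")
  # constitutive states ignore UV; WT does not
  s1 <- population_state("NcCg", "constitutive_dimer", uv = FALSE)
  s2 <- population_state("NcCg", "constitutive_dimer", uv = TRUE)
  expect_equal(s1$dimer_fraction, s2$dimer_fraction)
  m1 <- population_state("NcCg", "constitutive_monomer", uv = FALSE)
  m2 <- population_state("NcCg", "constitutive_monomer", uv = TRUE)
  expect_equal(m1$dimer_fraction, m2$dimer_fraction)
  expect_lte(m1$dimer_fraction, 0.05)
  w1 <- population_state("NcCg", "WT", uv = FALSE)
  w2 <- population_state("NcCg", "WT", uv = TRUE)
  expect_gt(w1$dimer_fraction, w2$dimer_fraction)
})
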