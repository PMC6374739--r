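make_table <- function(means, n = 5, sd = 0.1, seed = 1) {
  # means: named list like list(`WT.FALSE` = 0.6, ...)
  withr::with_seed(seed, {
    purrr::imap_dfr(means, function(m, key) {
      parts <- strsplit(key, "\\.")[[1]]
      tibble::tibble(experiment = seq_len(n), genotype = parts[1],
                     uv = parts[2], value = stats::rnorm(n, m, sd))
    })
  })
}

test_that("two-way ANOVA matches the brute-force partition oracle", {
  withr::with_seed(41, {
    for (k in 1:10) {
      df <- make_table(list(WT.no = runif(1), WT.yes = runif(1),
                            mut.no = runif(1), mut.yes = runif(1)),
                       n = 5, sd = runif(1, 0.05, 0.5), seed = k)
      fit <- two_way_anova(df)
      oracle <- brute_anova(df)
      tab <- fit$table
      get <- function(term, col) tab[[col]][tab$term == term]
      expect_equal(get("genotype", "sumsq"), oracle$ss_a, tolerance = 1e-9)
      expect_equal(get("uv", "sumsq"), oracle$ss_b, tolerance = 1e-9)
      expect_equal(get("genotype:uv", "sumsq"), oracle$ss_ab, tolerance = 1e-9)
      expect_equal(get("Residuals", "sumsq"), oracle$ss_res, tolerance = 1e-9)
      expect_equal(get("genotype", "statistic"), oracle$f_a, tolerance = 1e-9)
      expect_equal(get("uv", "statistic"), oracle$f_b, tolerance = 1e-9)
      expect_equal(get("genotype:uv", "statistic"), oracle$f_ab,
                   tolerance = 1e-9)
      # partition identity
      expect_equal(sum(tab$sumsq), oracle$ss_tot,
                   tolerance = 1e-9 * max(oracle$ss_tot, 1))
    }
  })
})

test_that("ANOVA handles degenerate and structured inputs", {
  # identical responses: zero total SS
  df0 <- make_table(list(WT.no = 1, WT.yes = 1, mut.no = 1, mut.yes = 1),
                    sd = 0)
  fit0 <- suppressWarnings(two_way_anova(df0)) # perfect-fit F warning
  expect_equal(sum(fit0$table$sumsq), 0, tolerance = 1e-20)

  # additive noiseless effects: interaction SS exactly zero
  dfa <- dplyr::bind_rows(
    tibble::tibble(experiment = 1:3, genotype = "WT", uv = "no", value = 1),
    tibble::tibble(experiment = 1:3, genotype = "WT", uv = "yes", value = 2),
    tibble::tibble(experiment = 1:3, genotype = "mut", uv = "no", value = 4),
    tibble::tibble(experiment = 1:3, genotype = "mut", uv = "yes", value = 5))
  # add tiny per-cell jitter so residual df > 0 without breaking additivity
  dfa$value <- dfa$value + rep(c(-0.01, 0, 0.01), 4)
  fita <- two_way_anova(dfa)
  expect_equal(fita$table$sumsq[fita$table$term == "genotype:uv"], 0,
               tolerance = 1e-12)

  # empty design cell is a named error
  dfm <- df0[df0$genotype != "WT" | df0$uv != "yes", ]
  expect_error(two_way_anova(dfm), "WT:yes")
  # single replicate per cell is rejected
  df1 <- make_table(list(WT.no = 1, WT.yes = 2, mut.no = 3, mut.yes = 4),
                    n = 1)
  expect_error(two_way_anova(df1), ">= 2 replicates")

  # unbalanced designs go through Type II and keep p-values in range
  dfu <- dplyr::bind_rows(df0, df0[df0$genotype == "WT" & df0$uv == "no", ][1:2, ])
  dfu$value <- dfu$value + stats::rnorm(nrow(dfu), 0, 0.1)
  fitu <- two_way_anova(dfu)
  expect_false(fitu$balanced)
  ps <- fitu$table$p.value
  expect_true(all(ps[!is.na(ps)] >= 0 & ps[!is.na(ps)] <= 1))
})

test_that("Sidak adjustment: closed form, order preservation, caps", {
  expect_equal(sidak_adjust(0, m = 6), 0)
  expect_equal(sidak_adjust(0.05, m = 1), 0.05)
  expect_equal(sidak_adjust(0.01, m = 6), 1 - 0.99^6)
  expect_equal(sidak_adjust(0.01, m = 6), 0.0585198506, tolerance = 1e-9)
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- sidak_adjust(p, m = 6)
  expect_true(all(diff(adj) > 0))
  expect_true(all(adj >= p))
  expect_lte(max(adj), 1)
})

test_that("post-hoc comparisons use pooled MSE t statistics and the m=6 family", {
  df <- make_table(list(WT.no = 0.60, WT.yes = 0.30,
                        dimer.no = 0.62, dimer.yes = 0.61,
                        monomer.no = 0.25, monomer.yes = 0.26),
                   n = 5, sd = 0.03, seed = 7)
  an <- two_way_anova(df)
  ph <- sidak_posthoc(an)
  expect_equal(nrow(ph), 6)
  expect_true(all(ph$p.adjusted >= ph$p.value))
  # hand-check one t statistic against the pooled formula
  cells <- dplyr::summarise(dplyr::group_by(an$data, genotype, uv),
                            m = mean(value), n = dplyr::n(), .groups = "drop")
  mse <- an$table$meansq[an$table$term == "Residuals"]
  a <- cells[cells$genotype == "WT" & cells$uv == "no", ]
  b <- cells[cells$genotype == "WT" & cells$uv == "yes", ]
  t_hand <- (a$m - b$m) / sqrt(mse * (1 / a$n + 1 / b$n))
  t_pkg <- ph$statistic[ph$genotype1 == "WT" & ph$genotype2 == "WT"]
  expect_equal(t_pkg, t_hand)
  # the WT UV contrast is significant; the mutants' are not
  wt <- ph$p.adjusted[ph$genotype1 == "WT" & ph$genotype2 == "WT"]
  expect_lt(wt, 0.05)
  other <- ph$p.adjusted[ph$genotype1 == ph$genotype2 & ph$genotype1 != "WT"]
  expect_true(all(other > 0.05))
  expect_error(sidak_posthoc(an, tibble::tibble(
    genotype1 = "WT", uv1 = "no", genotype2 = "nope", uv2 = "no")),
    "missing cell")
})

test_that("condition summaries: mean, SE, stars and letters", {
  # hand-computable SE
  df <- tibble::tibble(experiment = 1:3, genotype = "WT", uv = "no",
                       value = c(1, 2, 3))
  df <- dplyr::bind_rows(df,
    tibble::tibble(experiment = 1:3, genotype = "WT", uv = "yes",
                   value = c(4, 5, 6)),
    tibble::tibble(experiment = 1:3, genotype = "m", uv = "no",
                   value = c(1.1, 2.1, 3.1)),
    tibble::tibble(experiment = 1:3, genotype = "m", uv = "yes",
                   value = c(4.2, 5.2, 6.2)))
  s <- summarize_conditions(df)
  wt_no <- s$summary[s$summary$genotype == "WT" & s$summary$uv == "no", ]
  expect_equal(wt_no$mean, 2)
  expect_equal(wt_no$se, 1 / sqrt(3))
  expect_equal(wt_no$n, 3L)

  # identical values give SE 0
  dfe <- make_table(list(WT.no = 1, WT.yes = 1, m.no = 1, m.yes = 1), sd = 0)
  se <- suppressWarnings(summarize_conditions(dfe))$summary$se
  expect_true(all(se == 0))

  # clear separation produces a star for WT and distinct letters
  df2 <- make_table(list(WT.no = 0.60, WT.yes = 0.30,
                         dimer.no = 0.62, dimer.yes = 0.61),
                    n = 5, sd = 0.02, seed = 8)
  s2 <- summarize_conditions(df2)
  wt_star <- s2$summary$star[s2$summary$genotype == "WT"]
  dim_star <- s2$summary$star[s2$summary$genotype == "dimer"]
  expect_true(all(wt_star))
  expect_false(any(dim_star))
  letters_wt <- s2$summary$letter[s2$summary$genotype == "WT"]
  expect_false(letters_wt[1] == letters_wt[2])
  # conditions that do not differ share a letter
  letters_dim <- s2$summary$letter[s2$summary$genotype == "dimer"]
  expect_true(any(strsplit(letters_dim[1], "")[[1]] %in%
                    strsplit(letters_dim[2], "")[[1]]))
})
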