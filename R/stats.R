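#' Assemble a measurement table for experiment-level inference
#'
#' Validates and standardizes per-experiment responses (sensitized-emission
#' ratios or photobleaching percent increases) into the table the inference
#' functions consume: one row per experiment x condition, factors `genotype`
#' and `uv`.
#'
#' @param df A data frame with columns `experiment`, `genotype`, `uv` and
#'   `value` (plus any extras, kept).
#' @return A tibble with `genotype` and `uv` as factors and finite `value`.
#' @export
measurement_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("experiment", "genotype", "uv", "value") %in% names(df)))
  out <- tibble::as_tibble(df)
  out$genotype <- factor(out$genotype)
  out$uv <- factor(out$uv)
  if (any(!is.finite(out$value))) {
    stop("non-finite response values in the measurement table.", call. = FALSE)
  }
  counts <- dplyr::count(out, .data$genotype, .data$uv)
  full <- tidyr::expand_grid(genotype = levels(out$genotype),
                             uv = levels(out$uv))
  missing_cells <- dplyr::anti_join(
    full, dplyr::mutate(counts, genotype = as.character(.data$genotype),
                        uv = as.character(.data$uv)),
    by = c("genotype", "uv"))
  if (nrow(missing_cells) > 0) {
    stop("empty design cell(s): ",
         paste(missing_cells$genotype, missing_cells$uv, sep = ":",
               collapse = ", "), call. = FALSE)
  }
  if (any(counts$n < 2)) {
    stop("every genotype x uv cell needs >= 2 replicates for ANOVA.",
         call. = FALSE)
  }
  out
}

#' Two-way fixed-effects ANOVA (genotype x UV)
#'
#' Fits `value ~ genotype * uv` and partitions the sums of squares. Balanced
#' designs use the sequential decomposition (which the partition identity
#' makes unique); unbalanced designs use Type II sums of squares.
#'
#' @param table A [measurement_table()] (or a data frame accepted by it).
#' @return An object of class `fret_anova`: `$table` (term, df, sumsq,
#'   meansq, statistic, p.value), `$fit` (the underlying `lm`), `$data`,
#'   `$balanced`.
#' @export
two_way_anova <- function(table) {
  tab <- measurement_table(table)
  counts <- dplyr::count(tab, .data$genotype, .data$uv)
  balanced <- length(unique(counts$n)) == 1L
  fit <- stats::lm(value ~ genotype * uv, data = tab)
  if (balanced) {
    a <- stats::anova(fit)
    terms <- rownames(a)
    out <- tibble::tibble(
      term = c("genotype", "uv", "genotype:uv", "Residuals")[
        match(terms, c("genotype", "uv", "genotype:uv", "Residuals"))],
      df = a$Df, sumsq = a$`Sum Sq`, meansq = a$`Mean Sq`,
      statistic = a$`F value`, p.value = a$`Pr(>F)`
    )
  } else {
    a <- car::Anova(fit, type = 2)
    res <- stats::anova(fit)["Residuals", ]
    out <- tibble::tibble(
      term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
      meansq = a$`Sum Sq` / a$Df, statistic = a$`F value`,
      p.value = a$`Pr(>F)`
    )
  }
  structure(list(table = out, fit = fit, data = tab, balanced = balanced),
            class = "fret_anova")
}

#' @export
print.fret_anova <- function(x, ...) {
  cat(sprintf("<fret_anova> value ~ genotype * uv (%s design)\n",
              if (x$balanced) "balanced" else "unbalanced, Type II SS"))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @method tidy fret_anova
#' @export
tidy.fret_anova <- function(x, ...) x$table

#' @method glance fret_anova
#' @export
glance.fret_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 df.residual = x$fit$df.residual,
                 n = nrow(x$data), balanced = x$balanced)
}

#' Šídák adjustment of p-values
#'
#' For `m` comparisons, `p_adj = 1 - (1 - p)^m`: the exact familywise
#' correction under independence, slightly less conservative than Bonferroni.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values, capped at 1; order-preserving in `p`.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

# the standard comparison family: within-genotype +/-UV pairs plus
# between-genotype pairs at -UV
.default_comparisons <- function(tab) {
  gl <- levels(tab$genotype)
  ul <- levels(tab$uv)
  within <- tibble::tibble(genotype1 = gl, uv1 = ul[1],
                           genotype2 = gl, uv2 = ul[2])
  pairs <- utils::combn(gl, 2)
  between <- tibble::tibble(genotype1 = pairs[1, ], uv1 = ul[1],
                            genotype2 = pairs[2, ], uv2 = ul[1])
  dplyr::bind_rows(within, between)
}

#' Šídák post-hoc pairwise comparisons after a two-way ANOVA
#'
#' Each pair of design cells is compared with a t statistic pooled on the
#' ANOVA residual mean square (`t = (m1 - m2) / sqrt(MSE (1/n1 + 1/n2))`,
#' residual df), and raw p-values are Šídák-adjusted over the family. The
#' default family is the three within-genotype +/-UV pairs plus the three
#' between-genotype pairs without UV (m = 6), matching the contrasts
#' annotated in this kind of study.
#'
#' @param anova A `fret_anova` from [two_way_anova()].
#' @param comparisons Optional tibble with columns `genotype1`, `uv1`,
#'   `genotype2`, `uv2`; default as described.
#' @return A tibble: the comparison columns plus `estimate` (mean1 - mean2),
#'   `statistic`, `df`, `p.value`, `p.adjusted`.
#' @export
sidak_posthoc <- function(anova, comparisons = NULL) {
  stopifnot(inherits(anova, "fret_anova"))
  tab <- anova$data
  if (is.null(comparisons)) comparisons <- .default_comparisons(tab)
  comparisons <- tibble::as_tibble(comparisons)
  if (nrow(comparisons) == 0) {
    return(tibble::tibble(genotype1 = character(), uv1 = character(),
                          genotype2 = character(), uv2 = character(),
                          estimate = double(), statistic = double(),
                          df = double(), p.value = double(),
                          p.adjusted = double()))
  }
  cells <- tab |>
    dplyr::group_by(.data$genotype, .data$uv) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  cell_of <- function(g, u) {
    hit <- cells$genotype == g & cells$uv == u
    if (!any(hit)) {
      stop(sprintf("comparison references a missing cell: %s:%s.", g, u),
           call. = FALSE)
    }
    cells[hit, ]
  }
  resid_row <- anova$table[anova$table$term == "Residuals", ]
  mse <- resid_row$meansq
  df_res <- resid_row$df
  res <- purrr::pmap_dfr(comparisons, function(genotype1, uv1, genotype2, uv2, ...) {
    a <- cell_of(genotype1, uv1); b <- cell_of(genotype2, uv2)
    est <- a$mean - b$mean
    se <- sqrt(mse * (1 / a$n + 1 / b$n))
    tstat <- est / se
    tibble::tibble(genotype1 = as.character(genotype1), uv1 = as.character(uv1),
                   genotype2 = as.character(genotype2), uv2 = as.character(uv2),
                   estimate = est, statistic = tstat, df = df_res,
                   p.value = 2 * stats::pt(-abs(tstat), df_res))
  })
  res$p.adjusted <- sidak_adjust(res$p.value, m = nrow(res))
  res
}

# compact letter display: conditions sharing a letter are not significantly
# different (greedy insertion over the adjusted-p matrix)
.letter_groups <- function(names, pmat, alpha) {
  ord <- order(-attr(pmat, "means"))
  groups <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(pmat[i, groups[[g]]] > alpha, na.rm = TRUE)) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  letters_out <- rep("", length(names))
  for (g in seq_along(groups)) {
    letters_out[groups[[g]]] <- paste0(letters_out[groups[[g]]], letters[g])
  }
  stats::setNames(letters_out, names)
}

#' Summarize conditions as mean +/- SE with significance annotations
#'
#' Aggregates per-experiment responses into the standard figure form: group
#' mean, standard error across experiments, and significance annotations —
#' stars on the within-genotype +/-UV comparisons at `alpha_star`, and
#' compact letters over all pairwise cell comparisons at `alpha_letter`
#' (cells sharing a letter are not significantly different).
#'
#' @param table A [measurement_table()] (or data frame accepted by it).
#' @param alpha_star Threshold for the +/-UV stars (default 0.05).
#' @param alpha_letter Threshold for the letter display (default 0.01).
#' @return An object of class `fret_summary`: `$summary` tibble (`genotype`,
#'   `uv`, `mean`, `se`, `n`, `star`, `letter`), `$anova`, `$posthoc`
#'   (default family), `$posthoc_all` (all pairs, used for letters).
#' @export
summarize_conditions <- function(table, alpha_star = 0.05,
                                 alpha_letter = 0.01) {
  tab <- measurement_table(table)
  single <- dplyr::count(tab, .data$genotype, .data$uv)
  if (any(single$n < 2)) {
    warning("group(s) with a single experiment: SE reported as NA.",
            call. = FALSE)
  }
  an <- two_way_anova(tab)
  ph <- sidak_posthoc(an)
  cells <- tab |>
    dplyr::group_by(.data$genotype, .data$uv) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = ifelse(dplyr::n() >= 2,
                                 stats::sd(.data$value) / sqrt(dplyr::n()),
                                 NA_real_),
                     n = dplyr::n(), .groups = "drop")
  # all-pairs family for the letter display
  key <- paste(cells$genotype, cells$uv, sep = ":")
  all_pairs <- utils::combn(seq_len(nrow(cells)), 2)
  comp_all <- tibble::tibble(
    genotype1 = as.character(cells$genotype[all_pairs[1, ]]),
    uv1 = as.character(cells$uv[all_pairs[1, ]]),
    genotype2 = as.character(cells$genotype[all_pairs[2, ]]),
    uv2 = as.character(cells$uv[all_pairs[2, ]])
  )
  ph_all <- sidak_posthoc(an, comp_all)
  pmat <- matrix(NA_real_, nrow(cells), nrow(cells),
                 dimnames = list(key, key))
  for (k in seq_len(nrow(ph_all))) {
    i <- match(paste(ph_all$genotype1[k], ph_all$uv1[k], sep = ":"), key)
    j <- match(paste(ph_all$genotype2[k], ph_all$uv2[k], sep = ":"), key)
    pmat[i, j] <- pmat[j, i] <- ph_all$p.adjusted[k]
  }
  attr(pmat, "means") <- cells$mean
  letter <- .letter_groups(key, pmat, alpha_letter)
  uv_star <- ph |>
    dplyr::filter(.data$genotype1 == .data$genotype2) |>
    dplyr::mutate(star = .data$p.adjusted < alpha_star)
  cells$star <- vapply(seq_len(nrow(cells)), function(i) {
    hit <- uv_star$genotype1 == as.character(cells$genotype[i])
    any(hit) && any(uv_star$star[hit])
  }, TRUE)
  cells$letter <- letter[key]
  structure(list(summary = cells, anova = an, posthoc = ph,
                 posthoc_all = ph_all,
                 alpha_star = alpha_star, alpha_letter = alpha_letter),
            class = "fret_summary")
}

#' @export
print.fret_summary <- function(x, ...) {
  cat("<fret_summary> mean +/- SE across experiments\n")
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' @method tidy fret_summary
#' @export
tidy.fret_summary <- function(x, ...) x$summary

#' @method glance fret_summary
#' @export
glance.fret_summary <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x$summary),
    n_experiments = sum(x$summary$n),
    p_genotype = x$anova$table$p.value[x$anova$table$term == "genotype"],
    p_uv = x$anova$table$p.value[x$anova$table$term == "uv"],
    p_interaction = x$anova$table$p.value[x$anova$table$term == "genotype:uv"]
  )
}
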