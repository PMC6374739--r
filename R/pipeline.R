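#' Default study grid
#'
#' The full condition grid of the study design: constructs x genotypes x UV
#' states x experiments, with the standard protocol numbers (5 experiments,
#' 10 images per experiment, 20 regions per image, 5+5 bleach scans, ~100
#' periphery points).
#'
#' @param constructs,genotypes,uv Character/logical vectors of levels.
#' @param n_experiments,n_images Replication counts.
#' @return A tibble with one row per acquisition to simulate.
#' @export
study_grid <- function(constructs = c("NcCg", "TwoInOne"),
                       genotypes = c("WT", "constitutive_monomer",
                                     "constitutive_dimer"),
                       uv = c(FALSE, TRUE),
                       n_experiments = 5, n_images = 10) {
  tidyr::expand_grid(
    construct = constructs, genotype = genotypes, uv = uv,
    experiment = seq_len(n_experiments), image = seq_len(n_images)
  )
}

# deterministic per-acquisition seed derived from the base seed; arithmetic
# in doubles (exact below 2^53) so chained derivations cannot overflow
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 7919) %% 2147483563)
}

#' Simulate a study: render the full condition grid
#'
#' Renders one acquisition per row of the grid, either writing each to disk
#' as TIFF + sidecar (with a run manifest recording the resolved
#' configuration, seeds and file checksums) or returning the acquisitions in
#' memory.
#'
#' @param out_dir Output directory (created). Ignored when `write = FALSE`.
#' @param grid A [study_grid()] tibble; default the full standard grid.
#' @param seed Base integer seed; per-acquisition seeds derive from it
#'   deterministically.
#' @param params A [fret_params()].
#' @param config_args Named list of extra arguments passed to
#'   [simulation_config()] (e.g. `image_size`, `expression_level`).
#' @param write Write TIFFs to disk (`TRUE`, default) or return acquisitions
#'   in memory.
#' @param dry_run If `TRUE`, write only the manifest, no images.
#' @return When `write = TRUE`: the manifest (invisibly), a list with the
#'   resolved settings and a per-acquisition tibble (`files`). Otherwise a
#'   list with `grid` and `acquisitions`.
#' @export
simulate_study <- function(out_dir = NULL, grid = study_grid(), seed = 1L,
                           params = fret_params(), config_args = list(),
                           write = TRUE, dry_run = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  grid <- tibble::as_tibble(grid)
  grid$acq_seed <- .derive_seed(seed, seq_len(nrow(grid)))
  make_config <- function(row) {
    state <- population_state(construct = row$construct,
                              genotype = row$genotype, uv = row$uv)
    do.call(simulation_config,
            c(list(state = state, params = params, seed = row$acq_seed),
              config_args))
  }
  if (!write) {
    acqs <- purrr::map(seq_len(nrow(grid)), function(i) {
      render_acquisition(make_config(grid[i, ]))
    })
    return(list(grid = grid, acquisitions = acqs))
  }
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid$file <- sprintf("acq_%s_%s_%sUV_e%02d_i%02d",
                       grid$construct, grid$genotype,
                       ifelse(grid$uv, "p", "m"),
                       grid$experiment, grid$image)
  checksums <- character(nrow(grid))
  if (!dry_run) {
    for (i in seq_len(nrow(grid))) {
      acq <- render_acquisition(make_config(grid[i, ]))
      write_acquisition(acq, file.path(out_dir, grid$file[i]))
      checksums[i] <- unname(tools::md5sum(
        file.path(out_dir, paste0(grid$file[i], ".tif"))))
    }
  }
  grid$md5 <- checksums
  manifest <- list(
    type = "fretquant_simulation",
    seed = as.integer(seed),
    n_acquisitions = nrow(grid),
    params = params[c("E_intra", "E_inter", "R0", "beta_bleed",
                      "alpha_direct", "g_donor", "g_acceptor")],
    config_args = config_args,
    dry_run = dry_run,
    files = purrr::pmap(grid, function(construct, genotype, uv, experiment,
                                       image, acq_seed, file, md5, ...) {
      list(file = file, construct = construct, genotype = genotype,
           uv = uv, experiment = experiment, image = image,
           seed = acq_seed, md5 = md5)
    })
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, files = grid, out_dir = out_dir))
}

#' Quantify a simulated study directory
#'
#' Reads every acquisition listed in a simulation manifest, samples the
#' standard 20 random regions per image and writes/returns the per-region
#' table. Malformed acquisitions are reported and skipped; any failure makes
#' the function return with attribute `n_failed > 0`.
#'
#' @param in_dir Directory written by [simulate_study()].
#' @param n_regions,patch_side,min_signal Passed to
#'   [select_random_regions()].
#' @param seed Base seed for region sampling.
#' @param out_csv Optional path for the per-region CSV.
#' @return A tibble: grid columns plus one row per region, with attribute
#'   `n_failed`.
#' @export
quantify_study <- function(in_dir, n_regions = 20, patch_side = 16,
                           min_signal = NULL, seed = 1L, out_csv = NULL) {
  mf_path <- file.path(in_dir, "manifest.yaml")
  if (!file.exists(mf_path)) {
    stop("no inputs found: missing manifest.yaml in ", in_dir, call. = FALSE)
  }
  manifest <- yaml::read_yaml(mf_path)
  if (length(manifest$files) == 0 || isTRUE(manifest$dry_run)) {
    stop("no inputs found: manifest lists no rendered acquisitions.",
         call. = FALSE)
  }
  rows <- list()
  failures <- character(0)
  for (i in seq_along(manifest$files)) {
    fi <- manifest$files[[i]]
    res <- tryCatch({
      acq <- read_acquisition(file.path(in_dir, fi$file))
      regs <- select_random_regions(acq, n_regions = n_regions,
                                    patch_side = patch_side,
                                    min_signal = min_signal,
                                    seed = .derive_seed(seed, i))
      dplyr::mutate(regs, construct = fi$construct, genotype = fi$genotype,
                    uv = fi$uv, experiment = fi$experiment, image = fi$image,
                    .before = 1)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s: %s", fi$file, res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0) {
    stop("no inputs found: every acquisition failed to quantify.\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (length(failures) > 0) {
    warning(sprintf("%d acquisition(s) failed:\n%s", length(failures),
                    paste(failures, collapse = "\n")), call. = FALSE)
  }
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  attr(out, "n_failed") <- length(failures)
  out
}

#' Run the sensitized-emission readout for one condition, in memory
#'
#' Renders `n_experiments x n_images` acquisitions of one condition, samples
#' regions and aggregates the ratio — the standard protocol as a single call.
#'
#' @param state A [population_state()] for the condition.
#' @param params A [fret_params()].
#' @param n_experiments,n_images,n_regions Protocol numbers (defaults 5, 10,
#'   20).
#' @param seed Base seed.
#' @param config_args Extra [simulation_config()] arguments.
#' @param region_args Extra [select_random_regions()] arguments.
#' @return A `fret_ratio_result` (see [sensitized_emission_ratio()]).
#' @export
run_ratio_condition <- function(state, params = fret_params(),
                                n_experiments = 5, n_images = 10,
                                n_regions = 20, seed = 1L,
                                config_args = list(), region_args = list()) {
  regions <- purrr::map_dfr(seq_len(n_experiments), function(e) {
    purrr::map_dfr(seq_len(n_images), function(i) {
      s <- .derive_seed(seed, e * 1000L + i)
      cfg <- do.call(simulation_config,
                     c(list(state = state, params = params, seed = s),
                       config_args))
      acq <- render_acquisition(cfg)
      regs <- do.call(select_random_regions,
                      c(list(acq = acq, n_regions = n_regions,
                             seed = s + 1L), region_args))
      dplyr::mutate(regs, experiment = e, image = i, .before = 1)
    })
  })
  sensitized_emission_ratio(regions)
}

#' Run the photobleaching readout for one condition, in memory
#'
#' Renders `n_replicates` bleach series of one condition and quantifies each
#' by the periphery-profile percent increase; aggregates mean +/- SE across
#' replicates.
#'
#' @param state A [population_state()].
#' @param params A [fret_params()].
#' @param n_replicates Replicates (default 6; figures report n > 5).
#' @param n_points Periphery points per profile (default 100).
#' @param seed Base seed.
#' @param config_args Extra [simulation_config()] arguments.
#' @param method `"profile"` or `"mask"`, see [bleach_percent_increase()].
#' @return A list: `per_replicate` tibble (`replicate`, `percent_increase`,
#'   `control_percent_increase`, `I_pre`, `I_pb`), `summary` one-row tibble
#'   (means, SEs, n), `expected` (closed-form percent increase).
#' @export
run_bleach_condition <- function(state, params = fret_params(),
                                 n_replicates = 6, n_points = 100, seed = 1L,
                                 config_args = list(),
                                 method = c("profile", "mask")) {
  method <- match.arg(method)
  per <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- do.call(simulation_config,
                   c(list(state = state, params = params,
                          seed = .derive_seed(seed, r)),
                     config_args))
    series <- render_bleach_series(cfg)
    res <- bleach_percent_increase(series, method = method,
                                   n_points = n_points)
    dplyr::mutate(res$summary, replicate = r, .before = 1)
  })
  expected <- expected_bleach_increase(
    species_mixture(state, params), params,
    bleach_completeness = do.call(
      simulation_config,
      c(list(state = state, params = params), config_args))$bleach_completeness)
  n <- nrow(per)
  summary <- tibble::tibble(
    mean_percent_increase = mean(per$percent_increase),
    se = stats::sd(per$percent_increase) / sqrt(n),
    control_mean = mean(per$control_percent_increase),
    control_se = stats::sd(per$control_percent_increase) / sqrt(n),
    n_replicates = n, expected_percent_increase = expected
  )
  list(per_replicate = per, summary = summary, expected = expected)
}

#' Run a full study on the standard grid, in memory
#'
#' For every condition of the grid runs the requested readout(s) and returns
#' measurement tables ready for [summarize_conditions()].
#'
#' @param constructs,genotypes,uv Condition levels.
#' @param params A [fret_params()].
#' @param n_experiments,n_images,n_regions,n_bleach_replicates,n_points
#'   Protocol numbers.
#' @param seed Base seed.
#' @param readouts Character subset of `c("ratio", "bleach")`.
#' @param config_args Extra [simulation_config()] arguments.
#' @return A list with tibbles `ratio` and/or `bleach`: one row per
#'   experiment/replicate x condition with column `value`, plus a `summaries`
#'   list of `fret_summary` objects keyed `<construct>_<readout>`.
#' @export
run_study <- function(constructs = c("NcCg", "TwoInOne"),
                      genotypes = c("WT", "constitutive_monomer",
                                    "constitutive_dimer"),
                      uv = c(FALSE, TRUE),
                      params = fret_params(), n_experiments = 5,
                      n_images = 10, n_regions = 20,
                      n_bleach_replicates = 6, n_points = 100, seed = 1L,
                      readouts = c("ratio", "bleach"),
                      config_args = list()) {
  readouts <- match.arg(readouts, several.ok = TRUE)
  conditions <- tidyr::expand_grid(construct = constructs,
                                   genotype = genotypes, uv = uv)
  cond_seed <- function(i, offset) .derive_seed(seed + offset, i * 131L)
  out <- list()
  if ("ratio" %in% readouts) {
    out$ratio <- purrr::map_dfr(seq_len(nrow(conditions)), function(i) {
      st <- population_state(construct = conditions$construct[i],
                             genotype = conditions$genotype[i],
                             uv = conditions$uv[i])
      rr <- run_ratio_condition(st, params, n_experiments, n_images,
                                n_regions, seed = cond_seed(i, 0L),
                                config_args = config_args)
      dplyr::mutate(rr$per_experiment,
                    construct = conditions$construct[i],
                    genotype = conditions$genotype[i],
                    uv = conditions$uv[i], value = .data$ratio,
                    .before = 1)
    })
  }
  if ("bleach" %in% readouts) {
    out$bleach <- purrr::map_dfr(seq_len(nrow(conditions)), function(i) {
      st <- population_state(construct = conditions$construct[i],
                             genotype = conditions$genotype[i],
                             uv = conditions$uv[i])
      br <- run_bleach_condition(st, params, n_bleach_replicates, n_points,
                                 seed = cond_seed(i, 1L),
                                 config_args = config_args)
      dplyr::mutate(br$per_replicate,
                    construct = conditions$construct[i],
                    genotype = conditions$genotype[i],
                    uv = conditions$uv[i],
                    experiment = .data$replicate,
                    value = .data$percent_increase, .before = 1)
    })
  }
  out$summaries <- list()
  for (ct in constructs) {
    for (rd in readouts) {
      tab <- out[[rd]]
      tab <- tab[tab$construct == ct, ]
      out$summaries[[paste(ct, rd, sep = "_")]] <-
        summarize_conditions(tab)
    }
  }
  out
}

#' Write a report of condition summaries
#'
#' Emits the figure-style outputs for a study: one CSV of plot data per
#' summary (condition, mean, SE, annotations) plus a bar-chart PDF per
#' summary, and returns the plot-data tibble. Re-running on the same results
#' reproduces identical CSVs.
#'
#' @param summaries Named list of `fret_summary` objects (e.g.
#'   `run_study()$summaries`).
#' @param out_dir Output directory.
#' @param plots Also write PDF bar charts (default TRUE).
#' @return Invisibly, a tibble of all plot data with a `panel` column.
#' @export
report_study <- function(summaries, out_dir, plots = TRUE) {
  stopifnot(is.list(summaries), length(summaries) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_rows <- purrr::imap_dfr(summaries, function(s, nm) {
    stopifnot(inherits(s, "fret_summary"))
    df <- dplyr::mutate(s$summary, panel = nm, .before = 1)
    readr::write_csv(df, file.path(out_dir, paste0(nm, "_summary.csv")))
    readr::write_csv(s$posthoc,
                     file.path(out_dir, paste0(nm, "_posthoc.csv")))
    if (plots) {
      p <- autoplot(s) + ggplot2::ggtitle(nm)
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".pdf")), p,
                      width = 5, height = 4)
    }
    df
  })
  invisible(all_rows)
}
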