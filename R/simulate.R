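#' Configuration of a synthetic confocal acquisition
#'
#' Full generative description of one synthetic field of view: the molecular
#' state, transfer-model parameters, cell geometry, expression statistics,
#' noise model and the photobleaching protocol. Identical configurations
#' (including `seed`) render bit-identical images.
#'
#' Defaults emulate dim transient expression in leaf epidermis: fluorescence
#' concentrated in a 2--4 px periphery band per cell, a log-normal
#' cell-to-cell expression spread (transient-transformation variability),
#' Poisson shot noise and Gaussian read noise. The bleaching protocol is the
#' standard one: five pre-bleach scans, an acceptor bleach, five post-bleach
#' scans.
#'
#' @param state A [population_state()].
#' @param params A [fret_params()].
#' @param n_cells Number of cells to tessellate into the field (>= 1).
#' @param image_size Field size in pixels (square), >= 64.
#' @param expression_level Mean tagged molecules per periphery pixel (> 0).
#' @param expression_cv Coefficient of variation of expression across cells
#'   (>= 0); 0 makes all cells identical.
#' @param noise_read_sd Gaussian read-noise standard deviation, intensity
#'   units (DN).
#' @param shot_noise Logical; apply Poisson shot noise to the expected
#'   intensities.
#' @param bleach_completeness Fraction of acceptors destroyed inside the
#'   bleach region, `[0, 1]` (default 0.95; a 50 s full-power acceptor-line
#'   bleach is strong but rarely total).
#' @param n_pre_scans,n_post_scans Number of donor-channel scans before and
#'   after the bleach (default 5 and 5).
#' @param donor_fade Linear donor photobleaching per scan (fraction, default
#'   0: control peripheries are flat across scans).
#' @param nucleus Logical; add a nuclear spot of signal per cell (off by
#'   default: the constructs localize periphery-dominantly).
#' @param seed Integer seed; the single source of randomness for the
#'   acquisition.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(state = population_state(),
                              params = fret_params(),
                              n_cells = 6, image_size = 128,
                              expression_level = 15, expression_cv = 0.3,
                              noise_read_sd = 2, shot_noise = TRUE,
                              bleach_completeness = 0.95,
                              n_pre_scans = 5, n_post_scans = 5,
                              donor_fade = 0, nucleus = FALSE, seed = 1L) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "fret_params"),
            n_cells >= 1, image_size >= 64,
            expression_level > 0, expression_cv >= 0,
            noise_read_sd >= 0, is.logical(shot_noise),
            bleach_completeness >= 0, bleach_completeness <= 1,
            n_pre_scans >= 1, n_post_scans >= 1,
            donor_fade >= 0, donor_fade < 0.2,
            is.finite(seed))
  structure(
    list(state = state, params = params, n_cells = as.integer(n_cells),
         image_size = as.integer(image_size),
         expression_level = expression_level, expression_cv = expression_cv,
         noise_read_sd = noise_read_sd, shot_noise = shot_noise,
         bleach_completeness = bleach_completeness,
         n_pre_scans = as.integer(n_pre_scans),
         n_post_scans = as.integer(n_post_scans),
         donor_fade = donor_fade, nucleus = nucleus,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %dx%d px, %d cells, %s/%s/%sUV, seed %d\n",
    x$image_size, x$image_size, x$n_cells, x$state$construct,
    x$state$genotype, if (x$state$uv) "+" else "-", x$seed))
  invisible(x)
}

# Chebyshev dilation of a logical mask by 1 px (3x3 structuring element)
.dilate1 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-n, ]
  out[-n, ] <- out[-n, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -p]
  out[, -p] <- out[, -p] | m[, -1]
  out
}

#' Tessellate a field into cells and mark their periphery bands
#'
#' Places `n_cells` seed points with a minimum mutual spacing and assigns
#' every pixel to its nearest seed (a Voronoi tessellation, giving convex
#' polygonal cells as in an epidermal pavement idealization). The periphery
#' band is the set of pixels within 1 px (Chebyshev) of a cell--cell or
#' cell--field boundary, i.e. about 3 px wide. Each cell receives an
#' expression level drawn log-normally with mean `expression_level` and
#' coefficient of variation `expression_cv`.
#'
#' @param config A [simulation_config()].
#' @return A list with `labels` (integer matrix of cell ids), `periphery`
#'   (logical matrix), `expression` (numeric matrix, molecules per pixel:
#'   the cell's expression level on its periphery band, 0 elsewhere),
#'   `cell_expression` (numeric vector per cell) and `centers` (n x 2 matrix,
#'   row/col).
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$image_size
  k <- config$n_cells
  # each cell needs room for an interior beyond its ~3 px periphery band
  if (k > (n / 8)^2) {
    stop(sprintf("field too small to place %d cells in %dx%d px.", k, n, n),
         call. = FALSE)
  }
  min_d <- 0.45 * n / sqrt(k)
  withr::with_seed(config$seed, {
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < k) {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop(sprintf("could not place %d cells in a %dx%d field.", k, n, n),
             call. = FALSE)
      }
      cand <- stats::runif(2, min = 0.05 * n, max = 0.95 * n)
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - cand)^2))) >= min_d) {
        centers <- rbind(centers, cand)
      }
    }
    sdlog <- sqrt(log(1 + config$expression_cv^2))
    mulog <- log(config$expression_level) - sdlog^2 / 2
    expr_cell <- stats::rlnorm(k, meanlog = mulog, sdlog = sdlog)
    nuc_offset <- matrix(stats::runif(2 * k, -0.08 * n, 0.08 * n), k, 2)
  })
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- sapply(seq_len(k), function(i) {
    (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
  })
  labels <- matrix(max.col(-d2, ties.method = "first"), n, n)

  boundary <- matrix(FALSE, n, n)
  boundary[-1, ] <- boundary[-1, ] | (labels[-1, ] != labels[-n, ])
  boundary[-n, ] <- boundary[-n, ] | (labels[-n, ] != labels[-1, ])
  boundary[, -1] <- boundary[, -1] | (labels[, -1] != labels[, -n])
  boundary[, -n] <- boundary[, -n] | (labels[, -n] != labels[, -1])
  boundary[c(1, n), ] <- TRUE
  boundary[, c(1, n)] <- TRUE
  periphery <- .dilate1(boundary)

  expression <- matrix(0, n, n)
  expression[periphery] <- expr_cell[labels[periphery]]
  if (isTRUE(config$nucleus)) {
    nuc_r <- max(2, round(0.04 * n))
    for (i in seq_len(k)) {
      ctr <- centers[i, ] + nuc_offset[i, ]
      nuc <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= nuc_r^2
      nuc <- nuc & labels == i & !periphery
      expression[nuc] <- expr_cell[i]
    }
  }
  list(labels = labels, periphery = periphery, expression = expression,
       cell_expression = expr_cell, centers = centers)
}

# shot + read noise on an expected-intensity image, clipped at 0
.apply_noise <- function(expected, shot, read_sd) {
  out <- expected
  if (shot) out <- matrix(stats::rpois(length(out), lambda = out),
                          nrow(out), ncol(out))
  if (read_sd > 0) out <- out + matrix(stats::rnorm(length(out), 0, read_sd),
                                       nrow(out), ncol(out))
  pmax(out, 0)
}

#' Render one multi-channel acquisition
#'
#' Renders the three confocal channels of one field: `donor_488` (donor
#' excitation 488 nm, donor band 500--535 nm), `fret_488` (donor excitation,
#' acceptor band 590--645 nm: the FRET channel) and `acceptor_552` (acceptor
#' excitation 552 nm, acceptor band). Per-pixel expectations come from the
#' closed-form channel model applied to the cell expression map; Poisson shot
#' noise and Gaussian read noise are then applied per the configuration.
#' Ground-truth maps (cell labels, periphery, per-pixel mean efficiency) are
#' stored alongside.
#'
#' @param config A [simulation_config()].
#' @return An object of class `acquisition` with fields `donor_488`,
#'   `fret_488`, `acceptor_552` (numeric matrices), `channels` (metadata
#'   tibble), `truth` (list: `labels`, `periphery`, `efficiency`,
#'   `expression`, `expected` channel list, `mean_eff`) and `config`.
#' @export
render_acquisition <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- generate_cells(config)
  mix <- species_mixture(config$state, config$params)
  unit <- expected_channel_intensities(mix, config$params, donor_density = 1)
  expected <- list(
    donor_488 = cells$expression * unit$donor_488,
    fret_488 = cells$expression * unit$fret_488,
    acceptor_552 = cells$expression * unit$acceptor_552
  )
  withr::with_seed(config$seed + 1L, {
    donor <- .apply_noise(expected$donor_488, config$shot_noise,
                          config$noise_read_sd)
    fret <- .apply_noise(expected$fret_488, config$shot_noise,
                         config$noise_read_sd)
    acceptor <- .apply_noise(expected$acceptor_552, config$shot_noise,
                             config$noise_read_sd)
  })
  eff_map <- matrix(0, config$image_size, config$image_size)
  eff_map[cells$expression > 0] <- unit$mean_eff
  structure(
    list(
      donor_488 = donor, fret_488 = fret, acceptor_552 = acceptor,
      channels = channel_metadata(),
      truth = list(labels = cells$labels, periphery = cells$periphery,
                   efficiency = eff_map, expression = cells$expression,
                   expected = expected, mean_eff = unit$mean_eff),
      config = config
    ),
    class = "acquisition"
  )
}

#' Standard channel metadata table
#'
#' @return A tibble describing the three channels: excitation line (nm),
#'   collection band (nm) and gain tag.
#' @export
channel_metadata <- function() {
  tibble::tibble(
    channel = c("donor_488", "fret_488", "acceptor_552"),
    excitation_nm = c(488, 488, 552),
    band_low_nm = c(500, 590, 590),
    band_high_nm = c(535, 645, 645),
    gain = c("donor", "acceptor", "acceptor")
  )
}

#' @export
print.acquisition <- function(x, ...) {
  cat(sprintf("<acquisition> %dx%d px, 3 channels, mean efficiency %.4g\n",
              nrow(x$donor_488), ncol(x$donor_488), x$truth$mean_eff))
  invisible(x)
}

#' Render an acceptor-photobleaching time series
#'
#' Renders `n_pre_scans` donor-channel scans, applies an instantaneous
#' acceptor bleach of completeness `bleach_completeness` restricted to
#' `bleach_region`, then renders `n_post_scans` scans. Inside the bleached
#' region the expected donor intensity rises by the closed-form dequenching
#' amount; a disjoint control region is recorded for the no-bleach null.
#'
#' @param config A [simulation_config()].
#' @param bleach_region Optional rectangle `c(r0, c0, r1, c1)` (1-based,
#'   inclusive). By default a square window centred on the first cell's
#'   centroid, sized to about a quarter of the field.
#' @param control_region Optional rectangle like `bleach_region`; by default
#'   an equally sized window centred on the cell farthest from the bleach
#'   region. Must be disjoint from the bleach region.
#' @return An object of class `bleach_series`: `pre_stack`, `post_stack`
#'   (lists of matrices), `bleach_mask`, `control_mask` (logical matrices),
#'   `truth` (expected pre/post donor images, masks' expected percent
#'   increase, cell maps) and `config`.
#' @export
render_bleach_series <- function(config, bleach_region = NULL,
                                 control_region = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$image_size
  cells <- generate_cells(config)
  half <- round(n / 4)
  clamp <- function(v) pmin(pmax(round(v), 1), n)
  # full-size window around a centre, shifted (not cropped) into bounds, as
  # an operator frames a clearly visible cell
  rect_around <- function(ctr) {
    r0 <- min(max(round(ctr[1]) - half, 1), n - 2 * half)
    c0 <- min(max(round(ctr[2]) - half, 1), n - 2 * half)
    c(r0, c0, r0 + 2 * half, c0 + 2 * half)
  }
  bright <- cells$cell_expression >= stats::median(cells$cell_expression)
  if (is.null(bleach_region)) {
    bleach_region <- rect_around(cells$centers[which.max(cells$cell_expression), ])
  }
  bleach_region <- clamp(bleach_region)
  if (bleach_region[3] < bleach_region[1] || bleach_region[4] < bleach_region[2]) {
    stop("bleach region is empty.", call. = FALSE)
  }
  mask_from <- function(r) {
    m <- matrix(FALSE, n, n)
    m[r[1]:r[3], r[2]:r[4]] <- TRUE
    m
  }
  bleach_mask <- mask_from(bleach_region)
  if (is.null(control_region)) {
    bc <- c(mean(bleach_region[c(1, 3)]), mean(bleach_region[c(2, 4)]))
    d <- sqrt(rowSums((cells$centers - matrix(bc, nrow(cells$centers), 2,
                                              byrow = TRUE))^2))
    # farthest clearly expressing cell whose window, after removing any
    # bleached overlap, still frames enough periphery band to trace; dim
    # cells only as a last resort
    score <- d
    score[!bright] <- score[!bright] - 1e6
    best_band <- -1
    best_rect <- NULL
    for (i in order(score, decreasing = TRUE)) {
      rect <- rect_around(cells$centers[i, ])
      remainder <- mask_from(rect) & !bleach_mask
      band_px <- sum(remainder & cells$periphery)
      if (band_px > best_band) {
        best_band <- band_px
        best_rect <- rect
      }
      if (sum(remainder) >= 0.5 * sum(mask_from(rect)) && band_px >= 150) {
        best_rect <- rect
        break
      }
    }
    control_region <- best_rect
    if (is.null(control_region)) {
      stop("control region is empty or fully inside the bleach region.",
           call. = FALSE)
    }
  }
  control_region <- clamp(control_region)
  control_mask <- mask_from(control_region) & !bleach_mask
  if (!any(control_mask)) {
    stop("control region is empty or fully inside the bleach region.",
         call. = FALSE)
  }

  mix <- species_mixture(config$state, config$params)
  unit_pre <- expected_channel_intensities(mix, config$params, 1)
  mix_post <- .bleach_mix(mix, config$bleach_completeness)
  unit_post <- expected_channel_intensities(mix_post, config$params, 1)
  exp_pre <- cells$expression * unit_pre$donor_488
  exp_post <- exp_pre
  exp_post[bleach_mask] <- cells$expression[bleach_mask] * unit_post$donor_488

  render_scan <- function(expectation, fade_step) {
    .apply_noise(expectation * (1 - config$donor_fade * fade_step),
                 config$shot_noise, config$noise_read_sd)
  }
  withr::with_seed(config$seed + 2L, {
    pre_stack <- lapply(seq_len(config$n_pre_scans) - 1L,
                        function(k) render_scan(exp_pre, k))
    post_stack <- lapply(config$n_pre_scans + seq_len(config$n_post_scans) - 1L,
                         function(k) render_scan(exp_post, k))
  })
  structure(
    list(
      pre_stack = pre_stack, post_stack = post_stack,
      bleach_mask = bleach_mask, control_mask = control_mask,
      truth = list(
        expected_pre = exp_pre, expected_post = exp_post,
        labels = cells$labels, periphery = cells$periphery,
        expected_percent_increase = expected_bleach_increase(
          mix, config$params, config$bleach_completeness),
        mean_eff = unit_pre$mean_eff
      ),
      config = config
    ),
    class = "bleach_series"
  )
}

#' @export
print.bleach_series <- function(x, ...) {
  cat(sprintf(
    "<bleach_series> %d pre + %d post scans, %dx%d px, expected increase %.3g%%\n",
    length(x$pre_stack), length(x$post_stack),
    nrow(x$bleach_mask), ncol(x$bleach_mask),
    x$truth$expected_percent_increase))
  invisible(x)
}
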