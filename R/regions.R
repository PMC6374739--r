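#' Draw random square regions from an acquisition
#'
#' Implements the random-region sampling step of the sensitized-emission
#' readout: square patches are drawn uniformly among all candidate positions
#' whose donor-channel mean exceeds `min_signal` (excluding empty
#' background, where the ratio is undefined), with no two accepted regions
#' overlapping by more than half their area.
#'
#' @param acq An `acquisition`.
#' @param n_regions Number of regions to draw (default 20, the standard
#'   protocol).
#' @param patch_side Side of the square patch in pixels (default 16).
#' @param seed Integer seed making the draw reproducible.
#' @param min_signal Donor-channel mean threshold for a candidate position;
#'   `NULL` (default) uses the overall donor-channel mean, which sits above
#'   the background noise floor whenever the field contains signal.
#' @param max_overlap Maximum allowed pairwise area overlap fraction
#'   (default 0.5).
#' @return A tibble of class `region_sample`: `region`, `row0`, `col0`
#'   (top-left, 1-based), `side`, `mean_donor_488`, `mean_fret_488`,
#'   `mean_acceptor_552`.
#' @export
select_random_regions <- function(acq, n_regions = 20, patch_side = 16,
                                  seed = 1L, min_signal = NULL,
                                  max_overlap = 0.5) {
  stopifnot(inherits(acq, "acquisition"), n_regions >= 1, patch_side >= 2)
  n <- nrow(acq$donor_488); p <- ncol(acq$donor_488)
  if (patch_side > n || patch_side > p) {
    stop("patch does not fit in the image.", call. = FALSE)
  }
  if (is.null(min_signal)) min_signal <- mean(acq$donor_488)

  # patch means for every top-left position, via summed-area tables
  pm <- function(img) {
    sat <- apply(apply(img, 2, cumsum), 1, cumsum) # sat[j, i] after t()
    sat <- t(sat)
    sat <- rbind(0, cbind(0, sat))
    s <- patch_side
    i <- seq_len(n - s + 1); j <- seq_len(p - s + 1)
    (sat[i + s, j + s, drop = FALSE] - sat[i, j + s, drop = FALSE] -
        sat[i + s, j, drop = FALSE] + sat[i, j, drop = FALSE]) / s^2
  }
  donor_means <- pm(acq$donor_488)
  cand <- which(donor_means > min_signal, arr.ind = TRUE)
  if (nrow(cand) < n_regions) {
    stop(sprintf(
      "only %d candidate position(s) exceed min_signal = %.3g; %d needed.",
      nrow(cand), min_signal, n_regions), call. = FALSE)
  }

  overlap_frac <- function(a, b) {
    s <- patch_side
    dr <- max(0, min(a[1], b[1]) + s - max(a[1], b[1]))
    dc <- max(0, min(a[2], b[2]) + s - max(a[2], b[2]))
    (dr * dc) / s^2
  }
  accepted <- withr::with_seed(seed, {
    ord <- sample.int(nrow(cand))
    acc <- list()
    for (k in ord) {
      pos <- cand[k, ]
      if (all(vapply(acc, overlap_frac, 0, b = pos) <= max_overlap)) {
        acc[[length(acc) + 1L]] <- pos
        if (length(acc) == n_regions) break
      }
    }
    acc
  })
  if (length(accepted) < n_regions) {
    stop(sprintf(
      "only %d admissible region(s) found under the overlap rule; %d needed.",
      length(accepted), n_regions), call. = FALSE)
  }
  fret_means <- pm(acq$fret_488)
  acc_means <- pm(acq$acceptor_552)
  pos <- do.call(rbind, accepted)
  out <- tibble::tibble(
    region = seq_len(n_regions),
    row0 = pos[, 1], col0 = pos[, 2], side = patch_side,
    mean_donor_488 = donor_means[pos],
    mean_fret_488 = fret_means[pos],
    mean_acceptor_552 = acc_means[pos]
  )
  class(out) <- c("region_sample", class(out))
  out
}

#' Sensitized-emission FRET ratio over sampled regions
#'
#' The first FRET readout: each region's ratio is its mean FRET-channel
#' (acceptor emission under donor excitation) intensity divided by its mean
#' donor-channel intensity. Ratios aggregate region -> image mean ->
#' experiment mean, and the standard error is computed across experiments
#' (the declared replication unit), never across pooled regions.
#'
#' Regions with a non-positive donor mean are excluded with a warning (their
#' ratio is undefined); an all-excluded input is an error.
#'
#' @param regions A tibble of regions with columns `mean_fret_488`,
#'   `mean_donor_488` and (optionally) `experiment` and `image` ids; the
#'   output of [select_random_regions()], possibly row-bound over images and
#'   experiments. Missing `experiment`/`image` columns are treated as a
#'   single image in a single experiment.
#' @param pooled Logical; if `TRUE`, compute each image's ratio as the ratio
#'   of pooled means instead of the mean of per-region ratios (the
#'   alternative aggregation).
#' @return An object of class `fret_ratio_result` with elements `per_region`,
#'   `per_image`, `per_experiment` (tibbles) and `summary` (one-row tibble:
#'   `mean_ratio`, `se`, `n_experiments`, `n_images`, `n_regions`).
#' @export
sensitized_emission_ratio <- function(regions, pooled = FALSE) {
  stopifnot(is.data.frame(regions),
            all(c("mean_fret_488", "mean_donor_488") %in% names(regions)))
  df <- tibble::as_tibble(regions)
  if (!"experiment" %in% names(df)) df$experiment <- 1L
  if (!"image" %in% names(df)) df$image <- 1L
  bad <- df$mean_donor_488 <= 0
  if (any(bad)) {
    warning(sprintf("%d region(s) excluded: non-positive donor mean.",
                    sum(bad)), call. = FALSE)
    df <- df[!bad, ]
  }
  if (nrow(df) == 0) {
    stop("no regions left after excluding non-positive donor means.",
         call. = FALSE)
  }
  df$ratio <- df$mean_fret_488 / df$mean_donor_488
  per_image <- df |>
    dplyr::group_by(.data$experiment, .data$image) |>
    dplyr::summarise(
      ratio = if (pooled) {
        sum(.data$mean_fret_488) / sum(.data$mean_donor_488)
      } else {
        mean(.data$ratio)
      },
      n_regions = dplyr::n(), .groups = "drop"
    )
  per_experiment <- per_image |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(ratio = mean(.data$ratio),
                     n_images = dplyr::n(), .groups = "drop")
  n_exp <- nrow(per_experiment)
  summary <- tibble::tibble(
    mean_ratio = mean(per_experiment$ratio),
    se = if (n_exp >= 2) stats::sd(per_experiment$ratio) / sqrt(n_exp) else NA_real_,
    n_experiments = n_exp,
    n_images = nrow(per_image),
    n_regions = nrow(df)
  )
  structure(
    list(per_region = df, per_image = per_image,
         per_experiment = per_experiment, summary = summary,
         pooled = pooled),
    class = "fret_ratio_result"
  )
}

#' @export
print.fret_ratio_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<fret_ratio_result> mean ratio %.4g +/- %.3g SE (%d experiments, %d images, %d regions)\n",
    s$mean_ratio, s$se, s$n_experiments, s$n_images, s$n_regions))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy fret_ratio_result
#' @export
tidy.fret_ratio_result <- function(x, ...) {
  dplyr::select(x$per_region, dplyr::any_of(c(
    "experiment", "image", "region", "row0", "col0", "side",
    "mean_donor_488", "mean_fret_488", "mean_acceptor_552", "ratio")))
}

#' @method glance fret_ratio_result
#' @export
glance.fret_ratio_result <- function(x, ...) x$summary
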