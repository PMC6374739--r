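#' Trace a cell periphery and sample an intensity profile
#'
#' Reproduces the point-wise periphery measurement of the photobleaching
#' readout: the donor image inside `roi` is thresholded (Otsu), the largest
#' connected object is hole-filled and its outline extracted, the outline is
#' resampled to `n_points` equally spaced (arc length) ordered points, and
#' intensity is read at each point as the mean of its 3x3 neighbourhood.
#'
#' @param image Numeric matrix, the donor-channel image used for tracing.
#' @param roi Optional rectangle `c(r0, c0, r1, c1)` (1-based, inclusive)
#'   restricting the tracing; default the whole image.
#' @param n_points Number of profile points (default 100, the standard
#'   protocol; >= 10).
#' @param window Side of the square sampling neighbourhood (odd, default 3).
#' @param threshold Optional intensity threshold overriding Otsu, for images
#'   where automatic thresholding fails.
#' @param min_area Minimum object area in pixels for a trusted contour.
#' @return A tibble of class `periphery_profile` with columns `point`, `row`,
#'   `col` (profile coordinates, 1-based).
#' @export
trace_periphery <- function(image, roi = NULL, n_points = 100, window = 3,
                            threshold = NULL, min_area = 50) {
  stopifnot(is.matrix(image), n_points >= 10, window %% 2 == 1)
  if (is.null(roi)) roi <- c(1, 1, nrow(image), ncol(image))
  stopifnot(length(roi) == 4, roi[1] >= 1, roi[2] >= 1,
            roi[3] <= nrow(image), roi[4] <= ncol(image),
            roi[3] > roi[1], roi[4] > roi[2])
  sub <- image[roi[1]:roi[3], roi[2]:roi[4]]
  rng <- range(sub)
  if (diff(rng) <= 0) {
    stop("flat image in roi: no contour can be traced; ",
         "supply `threshold` or a different roi.", call. = FALSE)
  }
  norm <- (sub - rng[1]) / diff(rng)
  th0 <- if (is.null(threshold)) {
    EBImage::otsu(EBImage::Image(norm))
  } else {
    (threshold - rng[1]) / diff(rng)
  }
  # an informative threshold separates bright structure from background:
  # the foreground must stand clear of the background by more than the
  # overall spread, and a periphery band cannot cover most of the roi.
  # dim or partially framed cells may need a lower cut than Otsu's, so back
  # off before giving up; pure noise fails the contrast check at every cut.
  mask <- NULL
  for (th in th0 * c(1, 0.5, 0.25)) {
    cand_mask <- norm > th
    ok <- sum(cand_mask) >= min_area && mean(cand_mask) <= 0.5 &&
      mean(sub[cand_mask]) >= mean(sub[!cand_mask]) + 2 * stats::sd(sub)
    if (ok) {
      areas <- tabulate(as.integer(EBImage::bwlabel(EBImage::Image(cand_mask * 1))))
      if (max(areas) >= min_area) {
        mask <- cand_mask
        break
      }
    }
    if (!is.null(threshold)) break # an explicit threshold is not backed off
  }
  if (is.null(mask)) {
    stop("no closed contour found: the roi lacks contrasted structure; ",
         "supply `threshold` or a different roi.", call. = FALSE)
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(as.integer(lab))
  big <- which.max(areas)
  obj <- EBImage::fillHull(lab == big)
  oc <- EBImage::ocontour(EBImage::bwlabel(obj))
  contour <- oc[[which.max(vapply(oc, nrow, 0L))]] + 1 # EBImage is 0-based
  if (nrow(contour) < n_points / 4) {
    stop("no closed contour found: outline too short; ",
         "supply `threshold` or a different roi.", call. = FALSE)
  }
  # arc-length resampling of the closed outline to n_points ordered points
  closed <- rbind(contour, contour[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  target <- seq(0, total, length.out = n_points + 1)[seq_len(n_points)]
  idx <- findInterval(target, arc, rightmost.closed = TRUE)
  frac <- (target - arc[idx]) / pmax(seg[idx], .Machine$double.eps)
  pts <- closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
  # snap each point from the mask edge onto the local intensity ridge of the
  # band, as a manual operator places periphery points on the bright line
  snap <- function(r, c) {
    rs <- max(1, r - 1):min(nrow(sub), r + 1)
    cs <- max(1, c - 1):min(ncol(sub), c + 1)
    w <- sub[rs, cs, drop = FALSE]
    k <- which(w == max(w), arr.ind = TRUE)[1, ]
    c(rs[k[1]], cs[k[2]])
  }
  snapped <- t(mapply(function(r, c) snap(r, c),
                      round(pts[, 1]), round(pts[, 2])))
  out <- tibble::tibble(
    point = seq_len(n_points),
    row = snapped[, 1] + roi[1] - 1,
    col = snapped[, 2] + roi[2] - 1
  )
  attr(out, "window") <- window
  class(out) <- c("periphery_profile", class(out))
  out
}

# 3x3 box smoothing (edge-replicated); used only to steady the tracing
# reference so ridge snapping does not chase noise fluctuations
.box3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- m[c(1, seq_len(n), n), c(1, seq_len(p), p)]
  acc <- matrix(0, n, p)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[dr + seq_len(n), dc + seq_len(p)]
  }
  acc / 9
}

# mean intensity of the window x window neighbourhood at each profile point
.sample_profile <- function(image, profile, window = NULL) {
  if (is.null(window)) window <- attr(profile, "window") %||% 3
  h <- (window - 1) / 2
  n <- nrow(image); p <- ncol(image)
  vapply(seq_len(nrow(profile)), function(i) {
    r <- profile$row[i]; c <- profile$col[i]
    mean(image[max(1, r - h):min(n, r + h), max(1, c - h):min(p, c + h)])
  }, 0)
}

#' Sample pre- and post-bleach intensities along a traced periphery
#'
#' Traces the periphery on the scan-averaged pre-bleach image inside a region
#' and samples every pre and post scan at the identical point coordinates.
#'
#' @param series A `bleach_series`.
#' @param region `"bleach"` or `"control"`: which mask's bounding box to
#'   trace in.
#' @param n_points Number of profile points (default 100).
#' @param window Sampling neighbourhood side (default 3).
#' @param ... Further arguments passed to [trace_periphery()].
#' @return A tibble: `point`, `row`, `col`, `pre` (mean over pre scans),
#'   `post` (mean over post scans), plus per-scan columns `pre_1..`,
#'   `post_1..`.
#' @export
periphery_profile <- function(series, region = c("bleach", "control"),
                              n_points = 100, window = 3, ...) {
  stopifnot(inherits(series, "bleach_series"))
  region <- match.arg(region)
  mask <- if (region == "bleach") series$bleach_mask else series$control_mask
  idx <- which(mask, arr.ind = TRUE)
  # shrink the tracing roi so that ridge snapping (1 px) plus the sampling
  # neighbourhood stay inside the (un)bleached region
  pad <- 1 + (window - 1) / 2
  roi <- c(min(idx[, 1]) + pad, min(idx[, 2]) + pad,
           max(idx[, 1]) - pad, max(idx[, 2]) - pad)
  # trace on the time-average of all scans: averaging pre and post makes
  # ridge snapping symmetric in their noise, so point selection inflates
  # neither side of the pre/post comparison. Restrict to this region's
  # content so the outline cannot follow a cell in the other (possibly
  # window-overlapping) region; smooth so snapping follows the band, not
  # single-pixel noise. Intensities are still sampled from the raw scans.
  scans <- c(series$pre_stack, series$post_stack)
  mean_all <- Reduce(`+`, scans) / length(scans)
  masked <- .box3(mean_all)
  masked[!mask] <- 0
  prof <- trace_periphery(masked, roi = roi, n_points = n_points,
                          window = window, ...)
  # the traced outline may clip the other region where the two windows
  # overlap; keep only points inside this region's own mask
  inside <- mask[cbind(prof$row, prof$col)]
  if (sum(inside) < n_points / 2) {
    stop("fewer than half of the periphery points fall inside the ", region,
         " region; choose a different region geometry.", call. = FALSE)
  }
  prof <- prof[inside, ]
  pre_mat <- vapply(series$pre_stack, .sample_profile, numeric(nrow(prof)),
                    profile = prof, window = window)
  post_mat <- vapply(series$post_stack, .sample_profile, numeric(nrow(prof)),
                     profile = prof, window = window)
  colnames(pre_mat) <- paste0("pre_", seq_len(ncol(pre_mat)))
  colnames(post_mat) <- paste0("post_", seq_len(ncol(post_mat)))
  out <- dplyr::bind_cols(
    prof,
    tibble::tibble(pre = rowMeans(pre_mat), post = rowMeans(post_mat)),
    tibble::as_tibble(pre_mat), tibble::as_tibble(post_mat)
  )
  attr(out, "region") <- region
  attr(out, "window") <- window
  class(out) <- c("periphery_profile", class(out))
  out
}

#' Donor dequenching after acceptor photobleaching
#'
#' The second FRET readout: `I_pre` is the mean donor intensity over the
#' pre-bleach scans, `I_pb` over the post-bleach scans, and the statistic is
#' `100 * (I_pb - I_pre) / I_pre`. The same statistic on the unbleached
#' control region is reported alongside as the no-bleach null.
#'
#' @param series A `bleach_series`.
#' @param method `"profile"` (default): average over ~`n_points` traced
#'   periphery points, the point-wise protocol; or `"mask"`: average over all
#'   pixels of the bleach/control masks.
#' @param n_points Profile points when `method = "profile"`.
#' @param ... Further arguments passed to [periphery_profile()].
#' @return An object of class `bleach_result`: one-row tibble in `$summary`
#'   (`I_pre`, `I_pb`, `percent_increase`, `control_I_pre`, `control_I_pb`,
#'   `control_percent_increase`, `n_points`, `method`), plus the profiles
#'   when traced.
#' @export
bleach_percent_increase <- function(series, method = c("profile", "mask"),
                                    n_points = 100, ...) {
  stopifnot(inherits(series, "bleach_series"),
            length(series$pre_stack) >= 1, length(series$post_stack) >= 1)
  method <- match.arg(method)
  if (any(series$bleach_mask & series$control_mask)) {
    stop("bleach and control regions must be disjoint.", call. = FALSE)
  }
  if (method == "mask") {
    stack_mean <- function(stack, mask) {
      mean(vapply(stack, function(m) mean(m[mask]), 0))
    }
    i_pre <- stack_mean(series$pre_stack, series$bleach_mask)
    i_pb <- stack_mean(series$post_stack, series$bleach_mask)
    c_pre <- stack_mean(series$pre_stack, series$control_mask)
    c_pb <- stack_mean(series$post_stack, series$control_mask)
    profiles <- NULL
    npts <- sum(series$bleach_mask)
  } else {
    pb <- periphery_profile(series, "bleach", n_points = n_points, ...)
    # a control window may frame too little periphery to trace (the cell
    # sits at the field edge); its statistic then falls back to the mask
    # average, which needs no contour
    pc <- tryCatch(
      periphery_profile(series, "control", n_points = n_points, ...),
      error = function(e) {
        warning("control periphery not traceable (", conditionMessage(e),
                "); using the control-mask average instead.", call. = FALSE)
        NULL
      })
    i_pre <- mean(pb$pre); i_pb <- mean(pb$post)
    if (is.null(pc)) {
      c_pre <- mean(vapply(series$pre_stack,
                           function(m) mean(m[series$control_mask]), 0))
      c_pb <- mean(vapply(series$post_stack,
                          function(m) mean(m[series$control_mask]), 0))
    } else {
      c_pre <- mean(pc$pre); c_pb <- mean(pc$post)
    }
    profiles <- list(bleach = pb, control = pc)
    npts <- nrow(pb)
  }
  if (i_pre <= 0) {
    stop("pre-bleach intensity is non-positive: percent increase undefined.",
         call. = FALSE)
  }
  summary <- tibble::tibble(
    I_pre = i_pre, I_pb = i_pb,
    percent_increase = 100 * (i_pb - i_pre) / i_pre,
    control_I_pre = c_pre, control_I_pb = c_pb,
    control_percent_increase = 100 * (c_pb - c_pre) / c_pre,
    n_points = npts, method = method
  )
  structure(list(summary = summary, profiles = profiles, series = series),
            class = "bleach_result")
}

#' @export
print.bleach_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<bleach_result> +%.3g%% donor increase (control %+.3g%%), %d %s samples\n",
    s$percent_increase, s$control_percent_increase, s$n_points,
    if (s$method == "profile") "periphery-point" else "mask-pixel"))
  invisible(x)
}

#' @method tidy bleach_result
#' @export
tidy.bleach_result <- function(x, ...) {
  if (is.null(x$profiles)) return(x$summary)
  out <- dplyr::mutate(
    x$profiles$bleach[c("point", "row", "col", "pre", "post")],
    region = "bleach")
  if (!is.null(x$profiles$control)) {
    out <- dplyr::bind_rows(out, dplyr::mutate(
      x$profiles$control[c("point", "row", "col", "pre", "post")],
      region = "control"))
  }
  out
}

#' @method glance bleach_result
#' @export
glance.bleach_result <- function(x, ...) x$summary

`%||%` <- function(a, b) if (is.null(a)) b else a
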