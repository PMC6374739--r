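#' Quantize intensities to 16-bit detector numbers
#'
#' Confocal exports are 16-bit unsigned integers. Values are rounded and
#' clipped to `[0, 65535]`; clipping (saturation) is reported as a warning,
#' since saturated pixels bias intensity ratios.
#'
#' @param x Numeric matrix of intensities.
#' @return Integer-valued numeric matrix in `[0, 65535]`.
#' @export
quantize_dn <- function(x) {
  q <- round(x)
  n_clip <- sum(q < 0 | q > 65535)
  if (n_clip > 0) {
    warning(sprintf("%d pixel(s) clipped to the 16-bit range.", n_clip),
            call. = FALSE)
  }
  pmin(pmax(q, 0), 65535)
}

#' Quantize every channel or scan of an object
#'
#' Applies [quantize_dn()] to all image planes of an acquisition or bleach
#' series, yielding the in-memory equivalent of what [write_acquisition()] /
#' [write_bleach_series()] put on disk.
#'
#' @param x An `acquisition` or `bleach_series`.
#' @return The same object with quantized planes.
#' @export
quantize_images <- function(x) {
  if (inherits(x, "acquisition")) {
    for (ch in c("donor_488", "fret_488", "acceptor_552")) {
      x[[ch]] <- quantize_dn(x[[ch]])
    }
  } else if (inherits(x, "bleach_series")) {
    x$pre_stack <- lapply(x$pre_stack, quantize_dn)
    x$post_stack <- lapply(x$post_stack, quantize_dn)
  } else {
    stop("`x` must be an acquisition or bleach_series.", call. = FALSE)
  }
  x
}

.write_pages <- function(mats, path) {
  pages <- lapply(mats, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  invisible(path)
}

.read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p * 65535))
}

#' Write an acquisition as a multi-page TIFF with a sidecar
#'
#' One 16-bit multi-page TIFF holds the three channels (quantized via
#' [quantize_dn()]); ground-truth maps go to a companion `*_truth.tif`
#' (efficiency as 32-bit float, labels and periphery as 16-bit); channel
#' metadata, page mapping, the seed and scalar ground truth go to a YAML
#' sidecar. The channel-to-page mapping is carried by the sidecar, not by
#' page order.
#'
#' @param acq An `acquisition` from [render_acquisition()].
#' @param path Output path without extension (writes `<path>.tif`,
#'   `<path>_truth.tif`, `<path>.yaml`).
#' @param page_order Character permutation of the channel names controlling
#'   TIFF page order (metadata always records the true mapping).
#' @param truth Logical; also write ground-truth maps.
#' @return Invisibly, the quantized acquisition actually written.
#' @export
write_acquisition <- function(acq, path,
                              page_order = c("donor_488", "fret_488",
                                             "acceptor_552"),
                              truth = TRUE) {
  stopifnot(inherits(acq, "acquisition"),
            setequal(page_order, c("donor_488", "fret_488", "acceptor_552")))
  qacq <- quantize_images(acq)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img_path <- paste0(path, ".tif")
  .write_pages(qacq[page_order], img_path)
  meta <- list(
    type = "acquisition",
    image = basename(img_path),
    pages = as.list(stats::setNames(seq_along(page_order), page_order)),
    channels = lapply(seq_len(nrow(acq$channels)), function(i) {
      as.list(acq$channels[i, ])
    }),
    seed = acq$config$seed,
    truth = NULL
  )
  meta$condition <- list(
    construct = acq$config$state$construct,
    genotype = acq$config$state$genotype,
    uv = acq$config$state$uv,
    dimer_fraction = acq$config$state$dimer_fraction
  )
  if (isTRUE(truth)) {
    truth_path <- paste0(path, "_truth.tif")
    tiff::writeTIFF(
      list(acq$truth$efficiency,
           acq$truth$labels / 65535,
           (acq$truth$periphery * 1) / 65535),
      truth_path, bits.per.sample = 32L, compression = "deflate"
    )
    meta$truth <- list(image = basename(truth_path),
                       pages = list(efficiency = 1, labels = 2,
                                    periphery = 3),
                       mean_efficiency = acq$truth$mean_eff)
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(qacq)
}

#' Read an acquisition written by [write_acquisition()]
#'
#' Channels are mapped by the sidecar metadata, not by page order; missing
#' channels, dimension disagreements and unreadable metadata produce
#' descriptive errors.
#'
#' @param path Path without extension, as given to [write_acquisition()].
#' @return An `acquisition` with integer-DN channel matrices. Ground truth is
#'   restored when the truth companion exists.
#' @export
read_acquisition <- function(path) {
  yml <- paste0(path, ".yaml")
  if (!file.exists(yml)) {
    stop("metadata sidecar not found: ", yml, call. = FALSE)
  }
  meta <- tryCatch(yaml::read_yaml(yml), error = function(e) {
    stop("unreadable metadata sidecar: ", conditionMessage(e), call. = FALSE)
  })
  img_path <- file.path(dirname(path), meta$image)
  pages <- .read_pages(img_path)
  need <- c("donor_488", "fret_488", "acceptor_552")
  missing_ch <- setdiff(need, names(meta$pages))
  if (length(missing_ch) > 0) {
    stop("missing channel(s) in metadata: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  chans <- lapply(need, function(ch) {
    idx <- meta$pages[[ch]]
    if (idx > length(pages)) {
      stop("missing channel page for ", ch, " in ", img_path, call. = FALSE)
    }
    pages[[idx]]
  })
  names(chans) <- need
  dims <- vapply(chans, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L) {
    stop("channel dimension mismatch: ", paste(dims, collapse = " vs "),
         call. = FALSE)
  }
  truth <- NULL
  if (!is.null(meta$truth)) {
    tp <- file.path(dirname(path), meta$truth$image)
    if (file.exists(tp)) {
      tpages <- tiff::readTIFF(tp, all = TRUE)
      truth <- list(
        efficiency = tpages[[meta$truth$pages$efficiency]],
        labels = round(tpages[[meta$truth$pages$labels]] * 65535),
        periphery = round(tpages[[meta$truth$pages$periphery]] * 65535) > 0,
        mean_eff = meta$truth$mean_efficiency
      )
    }
  }
  structure(
    list(donor_488 = chans$donor_488, fret_488 = chans$fret_488,
         acceptor_552 = chans$acceptor_552,
         channels = channel_metadata(), truth = truth,
         meta = meta, config = NULL),
    class = "acquisition"
  )
}

#' Write a photobleaching series as TIFFs with a sidecar
#'
#' The donor-channel scans go to one multi-page TIFF (pre scans first, then
#' post scans); the bleach and control masks to single-page binary TIFFs; the
#' scan structure, masks and seed to a YAML sidecar.
#'
#' @param series A `bleach_series` from [render_bleach_series()].
#' @param path Output path without extension.
#' @return Invisibly, the quantized series actually written.
#' @export
write_bleach_series <- function(series, path) {
  stopifnot(inherits(series, "bleach_series"))
  qs <- quantize_images(series)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img_path <- paste0(path, ".tif")
  .write_pages(c(qs$pre_stack, qs$post_stack), img_path)
  bm <- paste0(path, "_bleach_mask.tif")
  cm <- paste0(path, "_control_mask.tif")
  tiff::writeTIFF(series$bleach_mask * 1, bm, bits.per.sample = 8L,
                  compression = "deflate")
  tiff::writeTIFF(series$control_mask * 1, cm, bits.per.sample = 8L,
                  compression = "deflate")
  meta <- list(
    type = "bleach_series",
    image = basename(img_path),
    n_pre = length(series$pre_stack),
    n_post = length(series$post_stack),
    bleach_mask = basename(bm),
    control_mask = basename(cm),
    channel = list(name = "donor_488", excitation_nm = 488,
                   band_low_nm = 500, band_high_nm = 535),
    bleach = list(excitation_nm = 552, duration_s = 50,
                  completeness = series$config$bleach_completeness),
    seed = series$config$seed,
    condition = list(construct = series$config$state$construct,
                     genotype = series$config$state$genotype,
                     uv = series$config$state$uv)
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(qs)
}

#' Read a photobleaching series written by [write_bleach_series()]
#'
#' @param path Path without extension, as given to [write_bleach_series()].
#' @return A `bleach_series` with integer-DN scan matrices and logical masks.
#' @export
read_bleach_series <- function(path) {
  yml <- paste0(path, ".yaml")
  if (!file.exists(yml)) {
    stop("metadata sidecar not found: ", yml, call. = FALSE)
  }
  meta <- yaml::read_yaml(yml)
  pages <- .read_pages(file.path(dirname(path), meta$image))
  if (length(pages) != meta$n_pre + meta$n_post) {
    stop(sprintf("expected %d scan pages, found %d.",
                 meta$n_pre + meta$n_post, length(pages)), call. = FALSE)
  }
  read_mask <- function(f) {
    tiff::readTIFF(file.path(dirname(path), f)) > 0.5
  }
  structure(
    list(pre_stack = pages[seq_len(meta$n_pre)],
         post_stack = pages[meta$n_pre + seq_len(meta$n_post)],
         bleach_mask = read_mask(meta$bleach_mask),
         control_mask = read_mask(meta$control_mask),
         truth = NULL, meta = meta, config = NULL),
    class = "bleach_series"
  )
}
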