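# Particle detection and tracking from grayscale image stacks, plus a
# synthetic stack renderer for testing.
#
# Image convention: frames are matrices indexed [row, col] with the origin
# at the top-left; x runs along columns (rightwards), y along rows
# (downwards), both in pixels. Conversion to the electrode-centered device
# axis is a downstream affine transform.

#' Grayscale image stack
#'
#' @param frames A 3-D array `[ny, nx, n_frames]` or list of equal-shape
#'   matrices; intensities finite and non-negative.
#' @param frame_interval Time between frames, s.
#' @param pixel_size Physical pixel size, m/px.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 0.05, pixel_size = 1e-6) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("frames must share one shape", call. = FALSE)
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param frame_interval,pixel_size See [image_stack()].
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path, frame_interval = 0.05, pixel_size = 1e-6) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  image_stack(pages, frame_interval, pixel_size)
}

#' Temporal median background
#'
#' Per-pixel median over time. With particles occupying any given pixel in
#' a minority of frames, the median is particle-free background.
#'
#' @param stack An `image_stack` with at least 3 frames.
#' @return Background frame (matrix).
#' @export
median_background <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (dim(stack$frames)[3] < 3)
    stop("temporal median needs at least 3 frames", call. = FALSE)
  apply(stack$frames, c(1, 2), stats::median)
}

# 8-connected component labelling by iterative minimum-label propagation.
# Masks here are small and blobs compact, so a handful of sweeps suffice.
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  work <- matrix(Inf, nr, nc)
  work[mask] <- lab[mask]
  repeat {
    nb <- work
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
      nb <- pmin(nb, shift(work, d[1], d[2]))
    nb[!mask] <- Inf
    if (all(nb[mask] == work[mask])) break
    work <- nb
  }
  ids <- sort(unique(work[mask]))
  lab[mask] <- match(work[mask], ids)
  lab
}

#' Detect particles in one frame
#'
#' Thresholds |frame - background|, labels 8-connected components, discards
#' components below the minimum area, and reports intensity-unweighted
#' centroids.
#'
#' @param frame,background Equal-shape matrices.
#' @param threshold Absolute intensity threshold.
#' @param min_area Minimum blob area in px^2 (default 4).
#' @return Data frame with columns `x`, `y` (centroid, px), `area` (px^2).
#' @export
detect_particles <- function(frame, background, threshold, min_area = 4) {
  stopifnot(is.matrix(frame), identical(dim(frame), dim(background)))
  mask <- abs(frame - background) > threshold
  lab <- label_components(mask)
  if (max(lab) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0)))
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  area <- tabulate(comp)
  xs <- tapply(idx[, "col"], comp, mean)
  ys <- tapply(idx[, "row"], comp, mean)
  out <- data.frame(x = as.numeric(xs), y = as.numeric(ys), area = area)
  out <- out[out$area >= min_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect particles across a stack
#'
#' @param stack An `image_stack`.
#' @param background Background frame (default: [median_background()]).
#' @param threshold,min_area See [detect_particles()].
#' @return Data frame with columns `frame`, `x`, `y`, `area`.
#' @export
detect_stack <- function(stack, background = NULL, threshold, min_area = 4) {
  stopifnot(inherits(stack, "image_stack"))
  background <- background %||% median_background(stack)
  nf <- dim(stack$frames)[3]
  out <- lapply(seq_len(nf), function(k) {
    d <- detect_particles(stack$frames[, , k], background, threshold, min_area)
    if (nrow(d)) cbind(frame = k, d) else NULL
  })
  out <- do.call(rbind, out)
  out %||% data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0))
}

#' Link detections into tracks
#'
#' Greedy nearest-neighbor frame-to-frame linking: between consecutive
#' frames, the closest remaining pair within `max_displacement` is linked
#' first, then the next, and so on. Unmatched detections start new tracks;
#' tracks end when unmatched.
#'
#' @param detections Data frame from [detect_stack()] (`frame`, `x`, `y`).
#' @param max_displacement Maximum linking distance per frame, px.
#' @param pixel_size m/px used for the metric columns (default 1e-6).
#' @param frame_interval s/frame used for the time column (default 0.05).
#' @return List of track data frames (`frame`, `t_s`, `x`, `y`, `x_m`,
#'   `y_m`), ordered by first appearance.
#' @export
link_tracks <- function(detections, max_displacement, pixel_size = 1e-6,
                        frame_interval = 0.05) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)))
  detections <- detections[order(detections$frame), , drop = FALSE]
  tracks <- list()          # each: list(rows = data.frame, open = TRUE/FALSE)
  active <- integer(0)      # indices into tracks still open
  for (fr in sort(unique(detections$frame))) {
    cur <- detections[detections$frame == fr, , drop = FALSE]
    prev_xy <- do.call(rbind, lapply(active, function(i) {
      r <- tracks[[i]]$rows
      c(r$x[nrow(r)], r$y[nrow(r)])
    }))
    assigned_trk <- integer(0)
    assigned_det <- integer(0)
    if (length(active) && nrow(cur)) {
      dmat <- outer(seq_len(nrow(prev_xy)), seq_len(nrow(cur)),
                    Vectorize(function(i, j)
                      sqrt((prev_xy[i, 1] - cur$x[j])^2 +
                           (prev_xy[i, 2] - cur$y[j])^2)))
      repeat {
        if (!length(dmat) || all(!is.finite(dmat)) ||
            min(dmat, na.rm = TRUE) > max_displacement) break
        hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        assigned_trk <- c(assigned_trk, active[hit[1]])
        assigned_det <- c(assigned_det, hit[2])
        dmat[hit[1], ] <- Inf
        dmat[, hit[2]] <- Inf
      }
    }
    for (k in seq_along(assigned_trk)) {
      i <- assigned_trk[k]
      tracks[[i]]$rows <- rbind(tracks[[i]]$rows,
                                cur[assigned_det[k],
                                    c("frame", "x", "y"), drop = FALSE])
    }
    # tracks not extended this frame are closed
    active <- assigned_trk
    new_det <- setdiff(seq_len(nrow(cur)), assigned_det)
    for (j in new_det) {
      tracks[[length(tracks) + 1]] <-
        list(rows = cur[j, c("frame", "x", "y"), drop = FALSE])
      active <- c(active, length(tracks))
    }
  }
  lapply(tracks, function(tr) {
    r <- tr$rows
    rownames(r) <- NULL
    r$t_s <- r$frame * frame_interval
    r$x_m <- r$x * pixel_size
    r$y_m <- r$y * pixel_size
    r
  })
}

#' Render a synthetic image stack
#'
#' Gaussian blobs following ground-truth pixel trajectories on a constant
#' background with additive Gaussian noise; reproducible by seed.
#'
#' @param tracks List of data frames (`frame`, `x`, `y`) in px giving each
#'   particle's ground-truth path.
#' @param dims `c(ny, nx)` frame shape in px.
#' @param n_frames Number of frames.
#' @param amplitude Blob peak intensity above background.
#' @param sigma Blob Gaussian width, px.
#' @param background_level Constant background intensity.
#' @param noise_sd Additive Gaussian noise sd.
#' @param frame_interval,pixel_size Stack metadata.
#' @param seed RNG seed.
#' @return An `image_stack`.
#' @export
render_stack <- function(tracks, dims = c(64, 64), n_frames,
                         amplitude = 1, sigma = 2, background_level = 0.1,
                         noise_sd = 0, frame_interval = 0.05,
                         pixel_size = 1e-6, seed = 1L) {
  if (missing(n_frames))
    n_frames <- max(vapply(tracks, function(tr) max(tr$frame), numeric(1)))
  xg <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  yg <- matrix(seq_len(dims[1]), dims[1], dims[2])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  frames <- array(0, dim = c(dims, n_frames))
  for (k in seq_len(n_frames)) {
    img <- matrix(background_level, dims[1], dims[2])
    for (tr in tracks) {
      row <- tr[tr$frame == k, , drop = FALSE]
      if (!nrow(row)) next
      img <- img + amplitude *
        exp(-((xg - row$x[1])^2 + (yg - row$y[1])^2) / (2 * sigma^2))
    }
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = noise_sd)
    frames[, , k] <- pmax(img, 0)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  image_stack(frames, frame_interval, pixel_size)
}

#' Write tracks to CSV
#'
#' All tracks in one table with a `track` id column.
#'
#' @param tracks List of track data frames (see [link_tracks()]).
#' @param path Output file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  tab <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(track = i, tracks[[i]])))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
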