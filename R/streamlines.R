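#' Streamline set container
#'
#' A list of polylines in world mm coordinates, optionally carrying
#' ground-truth bundle labels (used by the synthetic generator).
#'
#' @param streamlines list of n x 3 numeric matrices (n >= 2 rows each).
#' @param labels optional character vector, one label per streamline.
#' @export
streamline_set <- function(streamlines, labels = NULL) {
  if (!length(streamlines)) {
    return(structure(list(streamlines = list(), labels = character(0)),
                     class = "streamline_set"))
  }
  ok <- vapply(streamlines, function(m)
    is.matrix(m) && ncol(m) == 3L && nrow(m) >= 2L && all(is.finite(m)),
    logical(1))
  if (!all(ok)) stop("every streamline needs >= 2 finite 3-D points")
  if (!is.null(labels) && length(labels) != length(streamlines))
    stop("one label per streamline required")
  structure(list(streamlines = streamlines, labels = labels),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat("<streamline_set> ", length(x$streamlines), " streamlines\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Resample streamlines at a fixed arc-length step
#'
#' Linear interpolation along the cumulative arc length; both endpoints are
#' retained. Used before any streamline-mask intersection so that a
#' streamline cannot skip through a voxel between vertices.
#'
#' @param set a [streamline_set()].
#' @param step arc-length step in mm (default 0.5).
#' @return list with `points` (total x 3 matrix) and `fibre_id` (integer
#'   per point).
#' @export
resample_streamlines <- function(set, step = 0.5) {
  pts <- vector("list", length(set$streamlines))
  for (i in seq_along(set$streamlines)) {
    m <- set$streamlines[[i]]
    seg <- sqrt(rowSums(diff(m)^2))
    keep <- c(TRUE, seg > 1e-9)   # drop zero-length segments
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 2L) { pts[[i]] <- set$streamlines[[i]][1, , drop = FALSE]; next }
    seg <- seg[seg > 1e-9]
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    if (total <= 0) { pts[[i]] <- m[1, , drop = FALSE]; next }
    at <- unique(c(seq(0, total, by = step), total))
    pts[[i]] <- cbind(approx(s, m[, 1], xout = at)$y,
                      approx(s, m[, 2], xout = at)$y,
                      approx(s, m[, 3], xout = at)$y)
  }
  npts <- vapply(pts, nrow, integer(1))
  list(points = do.call(rbind, pts), fibre_id = rep(seq_along(pts), npts))
}

#' Fibre-to-VTA connectivity matrix
#'
#' A fibre and a patient are connected when any resampled point of the
#' streamline falls inside a voxel of the patient's bilateral VTA union.
#' Points are tested in each VTA's own (fine) grid.
#'
#' @param set a [streamline_set()].
#' @param vtas per-patient list of `left`/`right` `vta_result`s.
#' @param step resampling step in mm.
#' @return logical matrix fibres x patients; streamline labels (if any)
#'   attached as attribute `labels`.
#' @export
fibre_vta_connectivity <- function(set, vtas, step = 0.5) {
  rs <- resample_streamlines(set, step = step)
  nf <- length(set$streamlines)
  np <- length(vtas)
  conn <- matrix(FALSE, nf, np)
  for (p in seq_len(np)) {
    hit <- logical(nrow(rs$points))
    for (side in c("left", "right")) {
      vt <- vtas[[p]][[side]]
      if (is.null(vt) || !any(vt$mask$data)) next
      v <- sample_at(vt$mask, rs$points, outside = 0)
      hit <- hit | (!is.na(v) & v > 0)
    }
    if (any(hit)) conn[, p] <- tabulate(rs$fibre_id[hit], nbins = nf) > 0L
  }
  attr(conn, "labels") <- set$labels
  conn
}

#' Synthetic streamline set with planted bundles
#'
#' Two coherent bundles with known ground truth plus random-walk
#' distractors: an "SMA bundle" from the dorsolateral (sensorimotor) STN to
#' the dorsomedial SMA-like parcel, and a "PFC bundle" from the ventral
#' (limbic) STN to the frontal PFC-like parcel, split evenly between
#' hemispheres. When the planted `truth` is supplied, each bundle's STN
#' entry points are drawn from the subregion voxels nearest the matching
#' planted sphere, so that touching a bundle fibre specifically tags
#' stimulation of that site. Distractors are correlated random walks
#' confined to the atlas bounding box. Bundle membership is recorded in
#' the labels.
#'
#' @param atlas a `dbs_atlas`.
#' @param truth optional `ground_truth`; anchors the bundle entry zones at
#'   the planted sweet/sour spheres.
#' @param n_total total streamline count (default 20000).
#' @param n_positive,n_negative fibres per planted bundle (default 2.5% of
#'   the set each).
#' @param seed RNG seed.
#' @param point_jitter_sd transverse scatter of bundle paths, mm.
#' @param bundle_end_sd,bundle_ctrl_sd per-fibre scatter of the bundle
#'   endpoint and mid-course control point, mm; small values give a
#'   coherent tube.
#' @return a [streamline_set()] with labels `"sma_bundle"`, `"pfc_bundle"`,
#'   `"distractor"`.
#' @export
make_synthetic_streamlines <- function(atlas, truth = NULL, n_total = 20000L,
                                       n_positive = max(1L, round(0.025 * n_total)),
                                       n_negative = max(1L, round(0.025 * n_total)),
                                       seed = 1L, point_jitter_sd = 0.35,
                                       bundle_end_sd = 0.8,
                                       bundle_ctrl_sd = 0.8) {
  set.seed(seed)
  grid <- atlas$labels
  xyz <- voxel_centres(grid)
  lims <- apply(xyz, 2, range)
  bundle_paths <- function(n, start_mask_codes, target_fun, anchors, radius) {
    if (!is.null(anchors)) {
      # a coherent tube: every fibre of a side enters the STN at the
      # planted sphere centre, with sub-voxel scatter
      side_of <- sample(c("left", "right"), n, replace = TRUE)
      starts <- anchors[side_of, , drop = FALSE] +
        matrix(rnorm(3 * n, 0, 0.6), n, 3)
    } else {
      idx_pool <- which(as.vector(atlas$labels$data) %in% start_mask_codes)
      starts <- xyz[sample(idx_pool, n, replace = TRUE), , drop = FALSE] +
        matrix(rnorm(3 * n, 0, 0.3), n, 3)
    }
    lapply(seq_len(n), function(i) {
      s <- starts[i, ]
      side <- if (s[1] >= 0) "right" else "left"
      e <- target_fun(side) + rnorm(3, 0, bundle_end_sd)
      ctrl <- (s + e) / 2 + rnorm(3, 0, bundle_ctrl_sd)
      t <- seq(0, 1, length.out = 36L)
      path <- outer((1 - t)^2, s) + outer(2 * t * (1 - t), ctrl) +
        outer(t^2, e)
      path + matrix(rnorm(length(path), 0, point_jitter_sd), nrow(path), 3)
    })
  }
  sma <- bundle_paths(n_positive, c(11L, 21L),
                      function(side) atlas$geometry[[side]]$sma_centre,
                      anchors = if (!is.null(truth)) truth$sweet_centre,
                      radius = if (!is.null(truth)) truth$sweet_radius)
  pfc <- bundle_paths(n_negative, c(13L, 23L),
                      function(side) atlas$geometry[[side]]$pfc_centre,
                      anchors = if (!is.null(truth)) truth$sour_centre,
                      radius = if (!is.null(truth)) truth$sour_radius)

  n_dist <- n_total - n_positive - n_negative
  if (n_dist < 0L) stop("bundle sizes exceed n_total")
  n_steps <- 40L
  pos <- cbind(runif(n_dist, lims[1, 1] + 2, lims[2, 1] - 2),
               runif(n_dist, lims[1, 2] + 2, lims[2, 2] - 2),
               runif(n_dist, lims[1, 3] + 2, lims[2, 3] - 2))
  dirn <- matrix(rnorm(3 * n_dist), n_dist, 3)
  dirn <- dirn / sqrt(rowSums(dirn^2))
  walk <- array(NA_real_, dim = c(n_steps, n_dist, 3))
  walk[1, , ] <- pos
  for (t in 2:n_steps) {
    dirn <- dirn + matrix(rnorm(3 * n_dist, 0, 1.0), n_dist, 3)
    dirn <- dirn / sqrt(rowSums(dirn^2))
    pos <- pos + dirn
    for (ax in 1:3) pos[, ax] <- pmin(pmax(pos[, ax], lims[1, ax]), lims[2, ax])
    walk[t, , ] <- pos
  }
  distractors <- lapply(seq_len(n_dist), function(i) walk[, i, ])

  streamline_set(c(sma, pfc, distractors),
                 labels = c(rep("sma_bundle", n_positive),
                            rep("pfc_bundle", n_negative),
                            rep("distractor", n_dist)))
}

#' Write a streamline set to a TrackVis TRK file
#'
#' Standard TRK dialect: 1000-byte header with voxel size, dimensions and
#' the voxel-to-world affine of `reference`; coordinates are stored in the
#' TrackVis convention ((voxel index + 0.5) * voxel size) and converted
#' back to world mm on reading.
#'
#' @param set a [streamline_set()].
#' @param path output file.
#' @param reference [image3d] defining the voxel grid of the header.
#' @export
write_streamlines <- function(set, path, reference) {
  con <- file(path, "wb")
  on.exit(close(con))
  shp <- img_dim(reference)
  spacing <- img_spacing(reference)
  writeChar("TRACK", con, nchars = 5, eos = NULL); writeBin(raw(1), con)
  writeBin(as.integer(shp), con, size = 2)
  writeBin(as.numeric(spacing), con, size = 4)
  writeBin(numeric(3), con, size = 4)              # origin (unused)
  writeBin(0L, con, size = 2)                      # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                      # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(reference$affine)), con, size = 4)
  writeBin(raw(444), con)
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(raw(1), con)
  writeBin(raw(4), con)                            # pad2
  writeBin(numeric(6), con, size = 4)              # image orientation
  writeBin(raw(8), con)                            # pad1 + invert/swap flags
  writeBin(length(set$streamlines), con, size = 4)
  writeBin(2L, con, size = 4)                      # version
  writeBin(1000L, con, size = 4)                   # hdr_size
  for (m in set$streamlines) {
    vox <- world_to_voxel(reference, m)
    trk <- sweep(vox + 0.5, 2, spacing, `*`)
    writeBin(nrow(m), con, size = 4)
    writeBin(as.numeric(t(trk)), con, size = 4)
  }
  invisible(path)
}

#' @rdname write_streamlines
#' @return `read_streamlines` returns a [streamline_set()] with world-mm
#'   coordinates.
#' @export
read_streamlines <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    warning("empty streamline file: ", path)
    return(streamline_set(list()))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE); readBin(con, "raw", 1)
  if (!identical(magic, "TRACK")) stop("not a TRK file: ", path)
  readBin(con, "integer", 3, size = 2)             # dims
  spacing <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)             # origin
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  aff <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 8)
  n_count <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 2, size = 4)             # version, hdr_size
  if (max(abs(aff[4, ] - c(0, 0, 0, 1))) > 1e-4) aff <- diag(4)
  out <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    vals <- readBin(con, "numeric", np * (3 + n_scalars), size = 4)
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4)
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, spacing, `/`) - 0.5
    out[[i]] <- t(aff[1:3, 1:3] %*% t(vox)) +
      matrix(aff[1:3, 4], np, 3, byrow = TRUE)
  }
  streamline_set(out)
}
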