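#' Synthetic labelled atlas with bilateral STNs and cortical parcels
#'
#' Builds a toy template-space atlas for the synthetic study: two
#' ellipsoidal subthalamic nuclei placed mirror-symmetrically about the
#' midsagittal plane, each partitioned along its dorsolateral-to-
#' ventromedial long axis into sensorimotor, associative and limbic
#' subregions (default 50/30/20% of the axis), plus two pairs of spherical
#' grey-matter parcels used as network targets: a dorsomedial "SMA-like"
#' parcel and a frontal "PFC-like" parcel per side. Everything outside a
#' label is treated as white-matter background.
#'
#' The construction is fully deterministic; `seed` is accepted for
#' interface uniformity with the other generators but has no effect.
#'
#' @param grid_shape voxels per axis (>= 40 recommended).
#' @param voxel_size_mm isotropic voxel size (<= 1 mm recommended).
#' @param seed unused; the atlas is deterministic.
#' @param fractions sensorimotor/associative/limbic fractions of the STN
#'   long axis, summing to 1.
#' @param world_centre mm coordinate at the grid centre.
#' @param stn_lat lateral offset of the STN centres from the midline, mm.
#' @param semi_axes STN ellipsoid semi-axes: (long axis, and the two
#'   transverse axes), mm.
#' @return a `dbs_atlas`: `labels` ([image3d] of integer codes), `table`
#'   (code/name/side/type dictionary) and the STN geometry used.
#' @export
make_toy_atlas <- function(grid_shape = c(48L, 48L, 48L), voxel_size_mm = 1,
                           seed = NULL, fractions = c(0.5, 0.3, 0.2),
                           world_centre = c(0, -13, -6), stn_lat = 12,
                           semi_axes = c(5.5, 3, 4)) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 40L)) stop("atlas grid must be at least 40 voxels per axis")
  if (voxel_size_mm > 1) stop("atlas voxel size must be <= 1 mm")
  if (abs(sum(fractions) - 1) > 1e-8) stop("subregion fractions must sum to 1")
  grid <- make_grid(grid_shape, voxel_size_mm, centre = world_centre)
  xyz <- voxel_centres(grid)
  lab <- integer(nrow(xyz))

  sides <- list(right = +1, left = -1)
  geom <- list()
  for (s in names(sides)) {
    sgn <- sides[[s]]
    centre <- c(sgn * stn_lat, world_centre[2], world_centre[3])
    # long axis runs dorsolateral (lateral, dorsal) -> ventromedial;
    # the left-side frame is the exact midsagittal mirror of the right
    d <- c(-sgn * 0.45, -0.25, -1)
    d <- d / sqrt(sum(d^2))
    e2 <- c(sgn * 1, 0, -0.45) ; e2 <- e2 - sum(e2 * d) * d
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(d[2] * e2[3] - d[3] * e2[2],
            d[3] * e2[1] - d[1] * e2[3],
            d[1] * e2[2] - d[2] * e2[1])
    p <- sweep(xyz, 2, centre)
    q1 <- p %*% d; q2 <- p %*% e2; q3 <- p %*% e3
    inside <- (q1 / semi_axes[1])^2 + (q2 / semi_axes[2])^2 +
      (q3 / semi_axes[3])^2 <= 1
    if (any(inside)) {
      ext <- apply(abs(xyz[inside, , drop = FALSE] - matrix(centre,
        sum(inside), 3, byrow = TRUE)), 2, max)
      lim <- (grid_shape - 1) / 2 * voxel_size_mm
      if (any(abs(centre - world_centre) + ext > lim))
        stop("STN ellipsoid exceeds the atlas grid")
    }
    # fraction along the long axis, 0 at the dorsolateral tip
    f <- (q1 + semi_axes[1]) / (2 * semi_axes[1])
    base <- if (s == "right") 20L else 10L
    lab[inside & f < fractions[1]] <- base + 1L                    # sensorimotor
    lab[inside & f >= fractions[1] & f < fractions[1] + fractions[2]] <-
      base + 2L                                                    # associative
    lab[inside & f >= fractions[1] + fractions[2]] <- base + 3L    # limbic
    geom[[s]] <- list(centre = centre, axis = d, semi_axes = semi_axes)

    sma_c <- c(sgn * 6, -6, 12); pfc_c <- c(sgn * 9, 6, 0)
    lab[rowSums(sweep(xyz, 2, sma_c)^2) <= 16 & lab == 0L] <-
      if (s == "right") 32L else 31L
    lab[rowSums(sweep(xyz, 2, pfc_c)^2) <= 16 & lab == 0L] <-
      if (s == "right") 42L else 41L
    geom[[s]]$sma_centre <- sma_c
    geom[[s]]$pfc_centre <- pfc_c
  }

  table <- data.frame(
    code = c(1L, 2L, 11L, 12L, 13L, 21L, 22L, 23L, 31L, 32L, 41L, 42L, 0L),
    name = c("STN_L", "STN_R",
             "STN_L_sensorimotor", "STN_L_associative", "STN_L_limbic",
             "STN_R_sensorimotor", "STN_R_associative", "STN_R_limbic",
             "SMA_like_L", "SMA_like_R", "PFC_like_L", "PFC_like_R",
             "background_white"),
    side = c("left", "right", rep("left", 3), rep("right", 3),
             "left", "right", "left", "right", "both"),
    type = c(rep("stn", 8), rep("parcel", 4), "background"),
    stringsAsFactors = FALSE
  )
  structure(list(labels = img_like(grid, array(lab, dim = grid_shape)),
                 table = table, geometry = geom),
            class = "dbs_atlas")
}

#' @export
print.dbs_atlas <- function(x, ...) {
  cat("<dbs_atlas> ", paste(img_dim(x$labels), collapse = " x "),
      " voxels, ", sum(x$table$type != "background"), " foreground regions\n",
      sep = "")
  invisible(x)
}

#' Logical mask of an atlas region by name or code
#'
#' Aggregate regions (`STN_L`, `STN_R`) resolve to the union of their
#' subregions.
#'
#' @param atlas a `dbs_atlas`.
#' @param region region name (see `atlas$table$name`) or integer code.
#' @return logical array on the atlas grid.
#' @export
atlas_mask <- function(atlas, region) {
  tab <- atlas$table
  if (is.character(region)) {
    row <- tab[tab$name == region, ]
    if (nrow(row) != 1L) stop("unknown region: ", region)
    code <- row$code
  } else {
    code <- as.integer(region)
    if (!code %in% tab$code) stop("unknown region code: ", code)
  }
  if (code == 1L) return(atlas$labels$data %in% c(11L, 12L, 13L))
  if (code == 2L) return(atlas$labels$data %in% c(21L, 22L, 23L))
  array(atlas$labels$data == code, dim = img_dim(atlas$labels))
}

#' Names of the STN regions used in overlap analyses
#' @param atlas a `dbs_atlas`.
#' @export
stn_region_names <- function(atlas) {
  atlas$table$name[atlas$table$type == "stn"]
}
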