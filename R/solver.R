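#' Four-compartment conductivity model
#'
#' Conductivities (S/m) for the volume conductor: grey matter 0.33, white
#' matter 0.14, electrode contacts and insulated shaft sections as
#' near-ideal conductor/insulator limits.
#'
#' @param sigma_grey,sigma_white,sigma_contact,sigma_insulation S/m.
#' @export
conductivity_model <- function(sigma_grey = 0.33, sigma_white = 0.14,
                               sigma_contact = 1e8, sigma_insulation = 1e-8) {
  vals <- c(sigma_grey, sigma_white, sigma_contact, sigma_insulation)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all conductivities must be positive and finite")
  if (!(sigma_contact > sigma_grey && sigma_grey > sigma_insulation))
    stop("expected sigma_contact >> sigma_grey >> sigma_insulation")
  list(sigma_grey = sigma_grey, sigma_white = sigma_white,
       sigma_contact = sigma_contact, sigma_insulation = sigma_insulation)
}

#' Stimulation setting for one hemisphere
#'
#' Pulse width and frequency are carried as metadata; the quasi-static
#' field model is driven by amplitude alone.
#'
#' @param amplitude volts (> 0).
#' @param pulse_width microseconds.
#' @param frequency hertz; the cohort inclusion criterion requires
#'   high-frequency stimulation (>= `min_frequency`).
#' @param min_frequency inclusion threshold in Hz.
#' @export
stimulation_setting <- function(amplitude, pulse_width = 60,
                                frequency = 130, min_frequency = 90) {
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be non-negative")
  if (frequency < min_frequency)
    stop("frequency below the high-frequency inclusion threshold (",
         min_frequency, " Hz)")
  list(amplitude = amplitude, pulse_width = pulse_width, frequency = frequency)
}

#' Rasterise the four-compartment conductivity volume
#'
#' Every voxel of `grid` is assigned exactly one conductivity: grey matter
#' where the atlas carries a foreground (grey) label, white matter
#' elsewhere, overridden by the electrode geometry (insulated shaft, and
#' contact metal on the contacts). Atlas labels are looked up at the grid's
#' voxel centres in world coordinates, so the atlas and grid may differ in
#' resolution but must share the world space.
#'
#' @param lead a `lead_model`.
#' @param atlas a `dbs_atlas` (or `NULL` for an all-white background).
#' @param grid an [image3d] template defining shape and affine.
#' @param model a [conductivity_model()].
#' @return [image3d] of conductivities (S/m).
#' @export
rasterize_conductivity <- function(lead, atlas, grid,
                                   model = conductivity_model()) {
  shp <- img_dim(grid)
  if (is.null(atlas)) {
    grey <- array(FALSE, dim = shp)
  } else {
    lab <- sample_at(atlas$labels, voxel_centres(grid), outside = 0)
    grey <- array(lab > 0, dim = shp)
    if (!any(is.finite(lab)))
      stop("atlas and grid do not overlap in world space")
  }
  sig <- array(model$sigma_white, dim = shp)
  sig[grey] <- model$sigma_grey
  comp <- lead_compartments(lead, grid)
  sig[comp == 1L] <- model$sigma_insulation
  sig[comp >= 2L] <- model$sigma_contact
  img_like(grid, sig)
}

# Assemble the 7-point finite-difference operator for div(sigma grad phi) = 0
# with face conductances from harmonic means. Returns the off-diagonal edge
# list plus the diagonal, all over full-grid linear indices.
fd_stencil <- function(sigma, spacing) {
  shp <- dim(sigma)
  n <- prod(shp)
  idx <- array(seq_len(n), dim = shp)
  rows <- vector("list", 3L); cols <- vector("list", 3L); vals <- vector("list", 3L)
  diagv <- numeric(n)
  for (ax in 1:3) {
    if (shp[ax] < 2L) stop("grid must have at least 2 voxels per axis")
    sl1 <- lapply(shp, seq_len); sl1[[ax]] <- seq_len(shp[ax] - 1L)
    sl2 <- lapply(shp, seq_len); sl2[[ax]] <- 2:shp[ax]
    i1 <- as.vector(do.call(`[`, c(list(idx), sl1)))
    i2 <- as.vector(do.call(`[`, c(list(idx), sl2)))
    g <- 2 / (1 / sigma[i1] + 1 / sigma[i2]) / spacing[ax]^2
    rows[[ax]] <- i1; cols[[ax]] <- i2; vals[[ax]] <- -g
    diagv[i1] <- diagv[i1] + g
    diagv[i2] <- diagv[i2] + g
  }
  list(rows = unlist(rows), cols = unlist(cols), vals = unlist(vals),
       diagv = diagv, n = n, shape = shp)
}

# Add the open-boundary (radiation) term: the ghost value outside a boundary
# face is phi * r_b / r_g, exact for a potential decaying as 1/r from
# `centre`. Modifies the stencil diagonal in place and returns it.
fd_open_boundary <- function(st, grid, sigma, centre) {
  shp <- st$shape
  co <- arrayInd(seq_len(st$n), shp)
  xyz <- voxel_to_world(grid, co - 1L)
  spacing <- img_spacing(grid)
  for (ax in 1:3) {
    for (side in c(1L, shp[ax])) {
      sel <- which(co[, ax] == side)
      step <- grid$affine[1:3, ax] * (if (side == 1L) -1 else 1)
      rb <- sqrt(rowSums(sweep(xyz[sel, , drop = FALSE], 2, centre)^2))
      gx <- sweep(xyz[sel, , drop = FALSE], 2, step, `+`)
      rg <- sqrt(rowSums(sweep(gx, 2, centre)^2))
      coef <- pmax(0, 1 - rb / rg) * sigma[sel] / spacing[ax]^2
      st$diagv[sel] <- st$diagv[sel] + coef
    }
  }
  st
}

#' Solve the quasi-static potential around an active contact
#'
#' Finite-difference discretisation of the electrostatic conduction
#' equation `div(sigma grad phi) = 0` on the voxel grid of `sigma`, with a
#' Dirichlet condition `phi = amplitude` on the active-contact voxels
#' (monopolar, cathodic stimulation). The outer boundary is either grounded
#' (`phi = 0`, case-as-ground; the default) or open (a radiation condition
#' matching 1/r decay, for comparison against infinite-medium closed
#' forms). The linear operator is scaled by amplitude, so the unit-amplitude
#' problem is solved once and rescaled; zero amplitude returns a zero field.
#'
#' The symmetric system is Jacobi-scaled and factorised by sparse Cholesky;
#' the relative residual of the scaled system must not exceed `tol`.
#'
#' @param sigma [image3d] of conductivities (S/m).
#' @param lead a `lead_model`; its active contact defines the source.
#' @param setting a [stimulation_setting()].
#' @param boundary `"grounded"` or `"open"`.
#' @param tol relative residual tolerance.
#' @return [image3d] of potentials (V).
#' @export
solve_potential <- function(sigma, lead, setting,
                            boundary = c("grounded", "open"), tol = 1e-8) {
  boundary <- match.arg(boundary)
  shp <- img_dim(sigma)
  comp <- lead_compartments(lead, sigma)
  active <- as.vector(comp == 3L)
  if (!any(active)) stop("no active-contact voxels fall inside the grid")
  if (setting$amplitude == 0) return(img_like(sigma, array(0, dim = shp)))

  st <- fd_stencil(sigma$data, img_spacing(sigma))
  dir_mask <- active
  if (boundary == "grounded") {
    co <- arrayInd(seq_len(st$n), shp)
    on_bnd <- co[, 1] == 1L | co[, 1] == shp[1] |
              co[, 2] == 1L | co[, 2] == shp[2] |
              co[, 3] == 1L | co[, 3] == shp[3]
    dir_mask <- dir_mask | on_bnd
  } else {
    st <- fd_open_boundary(st, sigma, as.vector(sigma$data),
                           active_contact_centre(lead))
  }
  phi <- numeric(st$n)
  phi[active] <- 1  # unit problem; rescaled below

  unk <- which(!dir_mask)
  map <- integer(st$n)
  map[unk] <- seq_along(unk)
  keep <- !dir_mask[st$rows] & !dir_mask[st$cols]
  b <- numeric(length(unk))
  for (pair in list(cbind(st$rows, st$cols), cbind(st$cols, st$rows))) {
    kk <- which(!dir_mask[pair[, 1]] & dir_mask[pair[, 2]])
    if (length(kk)) {
      add <- rowsum(-st$vals[kk] * phi[pair[kk, 2]], map[pair[kk, 1]])
      at <- as.integer(rownames(add))
      b[at] <- b[at] + add[, 1]
    }
  }
  A <- Matrix::sparseMatrix(i = map[st$rows[keep]], j = map[st$cols[keep]],
                            x = st$vals[keep],
                            dims = c(length(unk), length(unk)),
                            symmetric = TRUE) +
    Matrix::Diagonal(x = st$diagv[unk])
  d <- sqrt(Matrix::diag(A))
  Dinv <- Matrix::Diagonal(x = 1 / d)
  As <- Matrix::forceSymmetric(Dinv %*% A %*% Dinv)
  bs <- as.numeric(Dinv %*% b)
  ch <- Matrix::Cholesky(As, LDL = FALSE, perm = TRUE)
  xs <- as.numeric(Matrix::solve(ch, bs))
  res <- sqrt(sum((as.numeric(As %*% xs) - bs)^2)) /
    max(sqrt(sum(bs^2)), .Machine$double.xmin)
  if (!is.finite(res) || res > tol)
    stop(sprintf(
      "potential solve did not reach tolerance %g (relative residual %g)",
      tol, res))
  phi[unk] <- xs / d
  img_like(sigma, array(phi * setting$amplitude, dim = shp))
}

#' Electric-field magnitude of a potential image
#'
#' Gradient by central differences in the interior and one-sided
#' differences at the edges, each axis divided by its voxel spacing;
#' returns the Euclidean magnitude in V/mm.
#'
#' @param phi [image3d] of potentials (V).
#' @return [image3d] of field magnitudes (V/mm).
#' @export
efield_magnitude <- function(phi) {
  shp <- img_dim(phi)
  if (any(shp < 2L)) stop("gradient undefined on a single-voxel axis")
  spacing <- img_spacing(phi)
  acc <- array(0, dim = shp)
  for (ax in 1:3) {
    n <- shp[ax]
    up <- lapply(shp, seq_len); lo <- lapply(shp, seq_len)
    up[[ax]] <- pmin(seq_len(n) + 1L, n)
    lo[[ax]] <- pmax(seq_len(n) - 1L, 1L)
    denom <- (pmin(seq_len(n) + 1L, n) - pmax(seq_len(n) - 1L, 1L)) * spacing[ax]
    g <- (do.call(`[`, c(list(phi$data), up)) -
          do.call(`[`, c(list(phi$data), lo)))
    g <- sweep(g, ax, denom, `/`)
    acc <- acc + g^2
  }
  img_like(phi, sqrt(acc))
}

#' Threshold a field magnitude into a binary VTA
#'
#' @param efield [image3d] of field magnitudes (V/mm).
#' @param threshold activation threshold in V/mm (default 0.2).
#' @param patient_id,hemisphere metadata carried on the result.
#' @return a `vta_result`: the field, the binary mask (same grid), the
#'   threshold and metadata.
#' @export
threshold_vta <- function(efield, threshold = 0.2, patient_id = NA_character_,
                          hemisphere = NA_character_) {
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")
  mask <- img_like(efield, efield$data >= threshold)
  structure(list(efield = efield, mask = mask, threshold = threshold,
                 patient_id = patient_id, hemisphere = hemisphere),
            class = "vta_result")
}

#' @export
print.vta_result <- function(x, ...) {
  cat("<vta_result> ", sum(x$mask$data), " active voxels (",
      signif(vta_volume(x), 4), " mm^3) at ", x$threshold, " V/mm\n", sep = "")
  invisible(x)
}

#' VTA volume in mm^3
#' @param vta a `vta_result`.
#' @export
vta_volume <- function(vta) sum(vta$mask$data) * voxel_volume(vta$mask)

#' Compute a hemisphere VTA on a lead-local grid
#'
#' Convenience wrapper running the whole chain: build a fine grid centred
#' on the active contact, rasterise conductivity from the atlas, solve the
#' potential, take the field magnitude, and threshold. The local grid keeps
#' each solve small; masks are later resampled onto the shared analysis
#' grid with [mask_on_grid()].
#'
#' @param lead a `lead_model`.
#' @param setting a [stimulation_setting()].
#' @param atlas a `dbs_atlas` or `NULL`.
#' @param model a [conductivity_model()].
#' @param resolution local grid voxel size in mm.
#' @param margin half-width of the local box around the active contact, mm.
#' @param threshold activation threshold in V/mm.
#' @param boundary passed to [solve_potential()].
#' @param patient_id metadata.
#' @return a `vta_result`.
#' @export
compute_vta <- function(lead, setting, atlas = NULL,
                        model = conductivity_model(), resolution = 0.5,
                        margin = 6, threshold = 0.2, boundary = "grounded",
                        patient_id = NA_character_) {
  centre <- active_contact_centre(lead)
  nvox <- 2L * ceiling(margin / resolution) + 1L
  grid <- make_grid(rep(nvox, 3L), spacing = resolution, centre = centre)
  sigma <- rasterize_conductivity(lead, atlas, grid, model)
  phi <- solve_potential(sigma, lead, setting, boundary = boundary)
  ef <- efield_magnitude(phi)
  threshold_vta(ef, threshold = threshold, patient_id = patient_id,
                hemisphere = lead$hemisphere)
}
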