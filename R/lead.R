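#' Default quadripolar lead geometry
#'
#' Geometry representative of the quadripolar leads used in STN-DBS
#' cohorts: four cylindrical contacts of 1.5 mm length separated by 0.5 mm
#' of insulation, 1.27 mm lead diameter. All values in mm and configurable.
#'
#' @param n_contacts number of contacts.
#' @param contact_length,contact_spacing,contact_radius geometry in mm.
#' @export
default_lead_spec <- function(n_contacts = 4L, contact_length = 1.5,
                              contact_spacing = 0.5, contact_radius = 0.635) {
  stopifnot(n_contacts >= 1L, contact_length > 0, contact_spacing >= 0,
            contact_radius > 0)
  list(n_contacts = as.integer(n_contacts), contact_length = contact_length,
       contact_spacing = contact_spacing, contact_radius = contact_radius)
}

#' Build a lead model from a tip position and trajectory
#'
#' Contact centres are placed from the tip upward along the normalised
#' trajectory direction: contact `k` (0-based) is centred at
#' `tip + (length/2 + k * (length + spacing)) * direction`.
#'
#' @param tip_point mm coordinates of the lead tip (start of contact 0).
#' @param direction trajectory direction (any nonzero length; normalised).
#' @param lead_spec geometry, see [default_lead_spec()].
#' @param hemisphere `"left"` or `"right"`.
#' @param active_contact_index 0-based index of the active contact.
#' @return a `lead_model` object.
#' @export
build_lead <- function(tip_point, direction, lead_spec = default_lead_spec(),
                       hemisphere = c("right", "left"),
                       active_contact_index = 0L) {
  hemisphere <- match.arg(hemisphere)
  tip_point <- as.numeric(tip_point)
  direction <- as.numeric(direction)
  stopifnot(length(tip_point) == 3L, length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("lead direction must be nonzero")
  u <- direction / nrm
  active_contact_index <- as.integer(active_contact_index)
  if (active_contact_index < 0L || active_contact_index >= lead_spec$n_contacts)
    stop("active_contact_index must address an existing contact")
  k <- seq_len(lead_spec$n_contacts) - 1L
  offs <- lead_spec$contact_length / 2 +
    k * (lead_spec$contact_length + lead_spec$contact_spacing)
  centres <- matrix(tip_point, lead_spec$n_contacts, 3L, byrow = TRUE) +
    outer(offs, u)
  structure(list(
    hemisphere = hemisphere,
    contact_centres = centres,
    trajectory_direction = u,
    contact_length = lead_spec$contact_length,
    contact_spacing = lead_spec$contact_spacing,
    contact_radius = lead_spec$contact_radius,
    active_contact_index = active_contact_index,
    tip_point = tip_point
  ), class = "lead_model")
}

#' @export
print.lead_model <- function(x, ...) {
  cat("<lead_model> ", x$hemisphere, " lead, ", nrow(x$contact_centres),
      " contacts, active contact ", x$active_contact_index, " at (",
      paste(signif(active_contact_centre(x), 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' World coordinates of the active contact centre
#' @param lead a `lead_model`.
#' @export
active_contact_centre <- function(lead) {
  lead$contact_centres[lead$active_contact_index + 1L, ]
}

# Classify voxel centres of `grid` against lead geometry.
# Returns integer array: 0 outside lead, 1 insulated shaft, 2 contact,
# 3 active contact.
lead_compartments <- function(lead, grid) {
  xyz <- voxel_centres(grid)
  p <- sweep(xyz, 2, lead$tip_point)
  t_ax <- p %*% lead$trajectory_direction
  rad2 <- rowSums(p^2) - t_ax^2
  shaft_len <- max(t_ax) + 1  # shaft runs from tip through the grid top
  in_shaft <- t_ax >= 0 & t_ax <= shaft_len & rad2 <= lead$contact_radius^2
  comp <- integer(nrow(xyz))
  comp[in_shaft] <- 1L
  pitch <- lead$contact_length + lead$contact_spacing
  for (k in seq_len(nrow(lead$contact_centres)) - 1L) {
    lo <- k * pitch
    hi <- lo + lead$contact_length
    # half-open axial span: voxel slabs tile the contact length exactly,
    # keeping the discrete source volume resolution-consistent
    on_contact <- in_shaft & t_ax >= lo & t_ax < hi
    comp[on_contact] <- if (k == lead$active_contact_index) 3L else 2L
  }
  array(comp, dim = img_dim(grid))
}

#' Write / read a lead model as a YAML sidecar
#' @param lead a `lead_model`.
#' @param path file path.
#' @export
write_lead <- function(lead, path) {
  yaml::write_yaml(list(
    hemisphere = lead$hemisphere,
    tip_point = as.numeric(lead$tip_point),
    trajectory_direction = as.numeric(lead$trajectory_direction),
    contact_length = lead$contact_length,
    contact_spacing = lead$contact_spacing,
    contact_radius = lead$contact_radius,
    n_contacts = nrow(lead$contact_centres),
    active_contact_index = lead$active_contact_index
  ), path)
  invisible(path)
}

#' @rdname write_lead
#' @export
read_lead <- function(path) {
  y <- yaml::read_yaml(path)
  build_lead(y$tip_point, y$trajectory_direction,
             default_lead_spec(y$n_contacts, y$contact_length,
                               y$contact_spacing, y$contact_radius),
             hemisphere = y$hemisphere,
             active_contact_index = y$active_contact_index)
}
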