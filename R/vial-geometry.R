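# Conical reaction-vial geometry. Coordinate convention: cone apex at the
# origin, symmetry axis along +z, lengths in mm. The fluid occupies
# { 0 <= z <= h, sqrt(x^2+y^2) <= z * tan(theta) } where h follows from the
# fill volume. The wall (polyethylene, 0.65 mm, 0.9 g/mL) and the air above
# the fluid are non-scoring absorbers: any particle energy crossing the
# fluid boundary counts as escaped.

#' Conical vial geometry
#'
#' A full cone of given height whose half-angle is set by the capacity:
#' capacity = (pi/3) h^3 tan^2(theta). Defaults give a 1 mL vial of height
#' 20 mm (tan(theta) = 0.3455, theta = 19.1 deg). Either the half-angle or
#' the capacity may be overridden; the other is derived.
#'
#' @param height_mm full interior cone height.
#' @param capacity_uL maximum fluid capacity; used to derive the half-angle
#'   when `half_angle_deg` is `NULL`.
#' @param half_angle_deg cone half-angle in degrees; overrides the
#'   capacity-derived value (capacity is then recomputed).
#' @param wall_thickness_mm,wall_density_g_mL,fluid_density_g_mL wall and
#'   fluid material parameters (defaults: 0.65 mm polyethylene at 0.9 g/mL,
#'   water at 1 g/mL).
#' @return an object of class `vial_geometry`.
#' @export
vial_geometry <- function(height_mm = 20, capacity_uL = 1000,
                          half_angle_deg = NULL,
                          wall_thickness_mm = 0.65, wall_density_g_mL = 0.9,
                          fluid_density_g_mL = 1.0) {
  stopifnot(height_mm > 0, wall_thickness_mm > 0)
  if (is.null(half_angle_deg)) {
    tan_theta <- sqrt(3 * capacity_uL / (pi * height_mm^3))  # uL == mm^3
    half_angle_deg <- atan(tan_theta) * 180 / pi
  } else {
    tan_theta <- tan(half_angle_deg * pi / 180)
    capacity_uL <- pi / 3 * height_mm^3 * tan_theta^2
  }
  structure(list(height_mm = height_mm, capacity_uL = capacity_uL,
                 half_angle_deg = half_angle_deg, tan_theta = tan_theta,
                 wall_thickness_mm = wall_thickness_mm,
                 wall_density_g_mL = wall_density_g_mL,
                 fluid_density_g_mL = fluid_density_g_mL),
            class = "vial_geometry")
}

#' @export
print.vial_geometry <- function(x, ...) {
  cat(sprintf(paste0("Conical vial: height %.3g mm, half-angle %.3g deg, ",
                     "capacity %.4g uL, wall %.3g mm\n"),
              x$height_mm, x$half_angle_deg, x$capacity_uL,
              x$wall_thickness_mm))
  invisible(x)
}

#' Fluid surface height for a fill volume
#'
#' Inverts the cone volume relation V = (pi/3) (h tan theta)^2 h.
#'
#' @param geometry a `vial_geometry`.
#' @param volume_uL fill volume, in (0, capacity].
#' @return height of the fluid surface above the apex, mm.
#' @export
fill_height <- function(geometry, volume_uL) {
  if (any(volume_uL <= 0) || any(volume_uL > geometry$capacity_uL + 1e-9))
    stop("volume_uL must lie in (0, capacity]")
  (3 * volume_uL / (pi * geometry$tan_theta^2))^(1 / 3)
}

#' Cone volume enclosed below a fluid height
#'
#' @param geometry a `vial_geometry`.
#' @param height_mm fluid height above the apex.
#' @return volume in uL.
#' @export
cone_volume <- function(geometry, height_mm) {
  pi / 3 * geometry$tan_theta^2 * height_mm^3
}

#' Fluid mass for a fill volume
#' @param geometry a `vial_geometry`.
#' @param volume_uL fill volume.
#' @return mass in kg.
#' @export
fluid_mass_kg <- function(geometry, volume_uL) {
  volume_uL * 1e-6 * geometry$fluid_density_g_mL
}

#' Is a point inside the fluid region?
#' @param geometry a `vial_geometry`.
#' @param volume_uL fill volume.
#' @param points n x 3 matrix of positions (mm).
#' @return logical vector.
#' @export
inside_fluid <- function(geometry, volume_uL, points) {
  points <- rbind(points)
  h <- fill_height(geometry, volume_uL)
  z <- points[, 3]
  r2 <- points[, 1]^2 + points[, 2]^2
  z >= 0 & z <= h & r2 <= (z * geometry$tan_theta)^2
}

#' Sample decay sites and emission directions in the fluid
#'
#' Positions are drawn uniformly over the fluid cone by inverse CDF
#' (z = h U^(1/3), radius r = z tan(theta) sqrt(U'), azimuth uniform);
#' directions are isotropic on the unit sphere. Reproducible under a fixed
#' seed.
#'
#' @param geometry a `vial_geometry`.
#' @param volume_uL fill volume.
#' @param n number of source points, >= 1.
#' @param seed optional integer seed.
#' @return list with `position` (n x 3, mm) and `direction` (n x 3, unit).
#' @export
sample_source <- function(geometry, volume_uL, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  h <- fill_height(geometry, volume_uL)
  z <- h * stats::runif(n)^(1 / 3)
  r <- z * geometry$tan_theta * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  position <- cbind(r * cos(phi), r * sin(phi), z)
  u <- stats::runif(n, -1, 1)              # cos(polar angle)
  psi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  direction <- cbind(s * cos(psi), s * sin(psi), u)
  list(position = position, direction = direction)
}

#' Ray distance to the fluid boundary
#'
#' Exact intersection of rays with the fluid surface: the lateral cone wall
#' r = z tan(theta) or the free surface plane z = h, whichever comes first.
#'
#' @param geometry a `vial_geometry`.
#' @param volume_uL fill volume.
#' @param point n x 3 matrix of start positions, strictly inside the fluid.
#' @param direction n x 3 matrix of unit direction vectors.
#' @return numeric vector of distances (mm), > 0.
#' @export
distance_to_boundary <- function(geometry, volume_uL, point, direction) {
  point <- rbind(point); direction <- rbind(direction)
  if (!all(inside_fluid(geometry, volume_uL, point)))
    stop("all start points must lie inside the fluid")
  h <- fill_height(geometry, volume_uL)
  c2 <- geometry$tan_theta^2
  px <- point[, 1]; py <- point[, 2]; pz <- point[, 3]
  dx <- direction[, 1]; dy <- direction[, 2]; dz <- direction[, 3]

  # lateral cone surface: |p_xy + t d_xy|^2 = c2 (pz + t dz)^2
  a <- dx^2 + dy^2 - c2 * dz^2
  b <- 2 * (px * dx + py * dy - c2 * pz * dz)
  cc <- px^2 + py^2 - c2 * pz^2          # < 0 inside
  disc <- b^2 - 4 * a * cc
  t_cone <- rep(Inf, length(a))
  quad <- abs(a) > 1e-14
  # quadratic case: the start point is inside (cc < 0), so exactly one root
  # bounds the forward ray on the physical nappe (z >= 0)
  sq <- sqrt(pmax(disc, 0))
  for (sgn in c(-1, 1)) {
    t <- (-b + sgn * sq) / (2 * a)
    ok <- quad & is.finite(t) & t > 1e-12 & (pz + t * dz) >= -1e-12
    t_cone[ok] <- pmin(t_cone[ok], t[ok])
  }
  lin <- !quad & abs(b) > 1e-14
  t <- -cc / b
  ok <- lin & t > 1e-12 & (pz + t * dz) >= -1e-12
  t_cone[ok] <- pmin(t_cone[ok], t[ok])

  # free fluid surface z = h
  t_top <- ifelse(dz > 1e-14, (h - pz) / dz, Inf)

  d <- pmin(t_cone, t_top)
  if (any(!is.finite(d)))
    stop("ray-boundary intersection failed (point on boundary?)")
  d
}

#' Monte Carlo fluid-volume estimate by rejection sampling
#'
#' Validation utility: samples the bounding box of the fluid region and
#' estimates the fluid volume as the acceptance fraction times the box
#' volume.
#'
#' @param geometry a `vial_geometry`.
#' @param volume_uL nominal fill volume.
#' @param n number of trial points.
#' @param seed optional integer seed.
#' @return estimated volume in uL.
#' @export
mc_fluid_volume <- function(geometry, volume_uL, n = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- fill_height(geometry, volume_uL)
  R <- h * geometry$tan_theta
  x <- stats::runif(n, -R, R); y <- stats::runif(n, -R, R)
  z <- stats::runif(n, 0, h)
  acc <- mean(x^2 + y^2 <= (z * geometry$tan_theta)^2)
  acc * (2 * R)^2 * h
}
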