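#' Euclidean interlandmark distance
#'
#' Straight-line distance in millimetres between two 3D landmarks, the
#' primitive from which all linear canal dimensions are built.
#'
#' @param a,b Numeric 3-vectors of coordinates in mm.
#' @return Distance in mm (non-negative, symmetric in its arguments).
#' @export
#' @examples
#' interlandmark_distance(c(0, 0, 0), c(3, 4, 0)) # 5
interlandmark_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || any(!is.finite(c(a, b)))) {
    abort_pelvi("Interlandmark distance needs two finite 3-vectors.",
                "invalid_landmark_error")
  }
  sqrt(sum((a - b)^2))
}

#' Canal plane shape index
#'
#' Shape of an obstetric plane as its anteroposterior dimension divided by
#' its mediolateral dimension (dimensionless; 1 means a round plane, below
#' 1 transversely wide, above 1 sagittally long).
#'
#' @param ap,ml Positive lengths in mm (vectorised).
#' @return `ap / ml`.
#' @export
shape_index <- function(ap, ml) {
  if (any(!is.finite(ap)) || any(!is.finite(ml)) || any(ap <= 0) || any(ml <= 0)) {
    abort_pelvi("Shape index requires strictly positive AP and ML dimensions.",
                "degenerate_geometry_error")
  }
  ap / ml
}

# Interior angles of a triangle from its three side lengths, law of cosines.
# Sides are named by the vertex they are OPPOSITE to. Returns degrees.
# The angular statistics are built on distances (not raw vectors) because the
# canal angles are defined on the spine/S5 "triangle" of interlandmark
# distances; the vector route exists only as an independent test oracle.
.triangle_angles <- function(a, b, c, rel_tol = 1e-6) {
  sides <- c(a, b, c)
  if (any(!is.finite(sides)) || any(sides <= 0)) {
    abort_pelvi("Triangle has a zero-length or non-finite side (coincident vertices).",
                "degenerate_geometry_error")
  }
  scale <- max(sides)
  slack <- c(a + b - c, b + c - a, c + a - b) / scale
  if (any(slack < -rel_tol)) {
    abort_pelvi("Side lengths violate the triangle inequality beyond tolerance.",
                "inconsistent_distances_error")
  }
  if (any(slack < rel_tol)) {
    abort_pelvi("Degenerate (collinear) triangle: an interior angle reaches 0 or 180 degrees.",
                "degenerate_geometry_error")
  }
  cosA <- (b^2 + c^2 - a^2) / (2 * b * c)
  cosB <- (a^2 + c^2 - b^2) / (2 * a * c)
  cosC <- (a^2 + b^2 - c^2) / (2 * a * b)
  deg <- function(x) acos(pmin(1, pmax(-1, x))) * 180 / pi
  c(A = deg(cosA), B = deg(cosB), C = deg(cosC))
}

# angles of the ischial-spine/S5 triangle from a coordinate matrix
# theta_a: vertex at the S5 apex; theta_b: vertex at the LEFT ischial spine
.spine_triangle_angles <- function(coords) {
  d_L  <- interlandmark_distance(coords["apex_S5", ], coords["ischial_spine_L", ])
  d_R  <- interlandmark_distance(coords["apex_S5", ], coords["ischial_spine_R", ])
  d_LR <- interlandmark_distance(coords["ischial_spine_L", ], coords["ischial_spine_R", ])
  # each vertex faces the side it does not touch: S5 faces d_LR, the left
  # spine faces d_R
  ang <- .triangle_angles(a = d_LR, b = d_L, c = d_R)
  c(theta_a = unname(ang["A"]), theta_b = unname(ang["C"]))
}

#' Ischial spine projection angle (theta_a)
#'
#' Angle at the apex of the fifth sacral vertebra subtended by the left and
#' right ischial spines, computed from the three interlandmark distances of
#' the spine/S5 triangle by the law of cosines. A smaller angle means more
#' medially projecting ischial spines (a more constricted midplane).
#'
#' @param landmarks Landmark tibble for a single configuration
#'   (one specimen/observer/replicate).
#' @return Angle in degrees, strictly between 0 and 180.
#' @export
ischial_spine_angle <- function(landmarks) {
  coords <- .config_matrix(validate_landmarks(landmarks))
  unname(.spine_triangle_angles(coords)["theta_a"])
}

#' S5 position angle (theta_b)
#'
#' Angle at the left ischial spine between the line to the S5 apex and the
#' line to the right ischial spine, from the same distance triangle as
#' [ischial_spine_angle()]. A larger angle indicates an S5 apex positioned
#' farther from the ischial spines (a roomier posterior canal). The left
#' spine is the vertex by definition; left/right asymmetry in the data is
#' therefore visible in this angle and is deliberately not symmetrised.
#'
#' @inheritParams ischial_spine_angle
#' @return Angle in degrees, strictly between 0 and 180.
#' @export
s5_position_angle <- function(landmarks) {
  coords <- .config_matrix(validate_landmarks(landmarks))
  unname(.spine_triangle_angles(coords)["theta_b"])
}

# Table of linear canal dimensions: measurement name -> landmark pair
.canal_dimension_pairs <- function() {
  tibble(
    measurement = c("IAP", "IML", "MAP", "MML", "OAP", "OML"),
    from = c("sacral_promontory", "max_iliopectineal_L", "between_S4_S5",
             "ischial_spine_L", "apex_S5", "ischial_tuberosity_L"),
    to   = c("dorsal_sup_pubic_symphysis", "max_iliopectineal_R",
             "dorsal_inf_pubic_symphysis", "ischial_spine_R",
             "dorsal_inf_pubic_symphysis", "ischial_tuberosity_R")
  )
}

#' Canal response names in report order
#'
#' The eleven responses of the regression report: six linear dimensions,
#' three plane shape indices, and the two canal angles.
#'
#' @return Character vector of length 11.
#' @export
canal_responses <- function() {
  c("IAP", "IML", "inlet_shape", "MAP", "MML", "midplane_shape",
    "OAP", "OML", "outlet_shape", "theta_a", "theta_b")
}

#' Compute canal measurements from landmarks
#'
#' Reduces each landmark configuration to the full set of pelvic canal
#' measurements: the six linear dimensions (inlet, midplane and outlet,
#' each anteroposterior and mediolateral, in mm), the three plane shape
#' indices (AP/ML), and the two angular statistics of the ischial-spine/S5
#' triangle, `theta_a` and `theta_b`, in degrees. All values are invariant
#' under rigid rotation and translation of the landmark set.
#'
#' @param landmarks Landmark tibble (long format; may hold many specimens,
#'   observers and replicates).
#' @return A tibble with one row per (specimen_id, observer_id,
#'   replicate_id) and columns `IAP`, `IML`, `MAP`, `MML`, `OAP`, `OML`,
#'   `inlet_shape`, `midplane_shape`, `outlet_shape`, `theta_a`, `theta_b`.
#' @export
#' @examples
#' cfg <- generator_config(n_male = 2, n_female = 2, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' lms <- simulate_landmarks(cohort, cfg)
#' canal_measurements(lms)
canal_measurements <- function(landmarks) {
  landmarks <- validate_landmarks(landmarks)
  pairs <- .canal_dimension_pairs()

  one_config <- function(df) {
    coords <- .config_matrix(df)
    dims <- setNames(
      map_dbl(seq_len(nrow(pairs)),
              function(i) interlandmark_distance(coords[pairs$from[i], ],
                                                 coords[pairs$to[i], ])),
      pairs$measurement
    )
    ang <- .spine_triangle_angles(coords)
    tibble(
      IAP = dims[["IAP"]], IML = dims[["IML"]],
      MAP = dims[["MAP"]], MML = dims[["MML"]],
      OAP = dims[["OAP"]], OML = dims[["OML"]],
      inlet_shape    = shape_index(dims[["IAP"]], dims[["IML"]]),
      midplane_shape = shape_index(dims[["MAP"]], dims[["MML"]]),
      outlet_shape   = shape_index(dims[["OAP"]], dims[["OML"]]),
      theta_a = ang[["theta_a"]], theta_b = ang[["theta_b"]]
    )
  }

  landmarks %>%
    group_by(specimen_id, observer_id, replicate_id) %>%
    dplyr::group_modify(~ one_config(.x)) %>%
    ungroup() %>%
    arrange(specimen_id, observer_id, replicate_id)
}
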