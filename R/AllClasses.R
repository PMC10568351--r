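## S4 containers for the water-network screening pipeline.
##
## Tabular slots use one row per atom/ring/plane so that all numerical work
## stays vectorised; accessors below are the supported interface.

setOldClass("data.frame")

#' TIP3P pair-potential parameters
#'
#' Parameters of the rigid three-site water pair potential used to decide
#' hydrogen bonding: partial charges on the O and H interaction sites, the
#' Lennard-Jones coefficients acting between the two oxygens, the Coulomb
#' conversion constant, and the pair-energy threshold below which two waters
#' are considered hydrogen bonded.
#'
#' @slot qO Partial charge on oxygen, e (default -0.834).
#' @slot qH Partial charge on each hydrogen, e (default +0.417).
#' @slot A Repulsive Lennard-Jones coefficient, kcal A^12 / mol (582000).
#' @slot C Attractive Lennard-Jones coefficient, kcal A^6 / mol (595).
#' @slot ke2 Coulomb conversion constant e^2, kcal A / (mol e^2) (332.0636,
#'   the CHARMM convention).
#' @slot hbondThreshold Hydrogen-bond energy criterion, kcal/mol (-2.25);
#'   a pair is bonded when its interaction energy is at or below this value.
#' @exportClass EnergyParameters
setClass("EnergyParameters",
  representation(qO = "numeric", qH = "numeric", A = "numeric",
                 C = "numeric", ke2 = "numeric",
                 hbondThreshold = "numeric"),
  prototype(qO = -0.834, qH = 0.417, A = 582000, C = 595,
            ke2 = 332.0636, hbondThreshold = -2.25))

setValidity("EnergyParameters", function(object) {
  msg <- character()
  if (abs(2 * object@qH + object@qO) > 1e-10)
    msg <- c(msg, "water must be neutral: 2*qH + qO == 0")
  if (object@A <= 0) msg <- c(msg, "A must be > 0")
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@ke2 <= 0) msg <- c(msg, "ke2 must be > 0")
  if (object@hbondThreshold >= 0)
    msg <- c(msg, "hbondThreshold must be negative")
  if (length(msg)) msg else TRUE
})

#' Gaussian shape-density parameters
#'
#' Atoms are represented as spherical Gaussians
#' \eqn{\rho_i(r) = p \exp(-\alpha_i |r - R_i|^2)} with a common amplitude
#' `p` and a per-element decay \eqn{\alpha_i} chosen so the Gaussian
#' reproduces the volume of a hard sphere with the element's van der Waals
#' radius.
#'
#' @slot p Gaussian amplitude (dimensionless, default 2*sqrt(2)).
#' @slot radii Named numeric vector of van der Waals radii, Angstrom.
#' @slot normalization Either "hodgkin" (2*Oab/(Oaa+Obb), default) or
#'   "minmax" (Oab/max(Oaa,Obb)).
#' @slot representation Either "centroids" (the four group centroids as O
#'   pseudo-atoms, default) or "members" (all member-ring O atoms).
#' @exportClass ShapeParameters
setClass("ShapeParameters",
  representation(p = "numeric", radii = "numeric",
                 normalization = "character",
                 representation = "character"),
  prototype(
    p = 2 * sqrt(2),
    radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
              P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98),
    normalization = "hodgkin",
    representation = "centroids"))

setValidity("ShapeParameters", function(object) {
  msg <- character()
  if (object@p <= 0) msg <- c(msg, "p must be > 0")
  if (any(object@radii <= 0)) msg <- c(msg, "all radii must be > 0")
  if (!object@normalization %in% c("hodgkin", "minmax"))
    msg <- c(msg, "normalization must be 'hodgkin' or 'minmax'")
  if (!object@representation %in% c("centroids", "members"))
    msg <- c(msg, "representation must be 'centroids' or 'members'")
  if (length(msg)) msg else TRUE
})

#' Binding-site definition
#'
#' A sphere (center + radius) inside which water rings are retained.
#'
#' @slot center Numeric 3-vector, Angstrom.
#' @slot radius Sphere radius, Angstrom (default 20).
#' @exportClass SiteDefinition
setClass("SiteDefinition",
  representation(center = "numeric", radius = "numeric"),
  prototype(center = c(0, 0, 0), radius = 20))

setValidity("SiteDefinition", function(object) {
  msg <- character()
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite 3-vector")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "radius must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Explicit-water snapshots
#'
#' A set of frames, each holding rigid three-site waters. The `waters` table
#' has one row per water with columns `frame`, `mol`, `ox,oy,oz`,
#' `h1x,h1y,h1z`, `h2x,h2y,h2z` (coordinates in Angstrom).
#'
#' @slot waters data.frame as described above.
#' @slot boxes List (one per frame) of periodic box 3-vectors or `NULL`.
#' @slot frameIds Integer vector of frame identifiers, in input order.
#' @exportClass WaterFrames
setClass("WaterFrames",
  representation(waters = "data.frame", boxes = "list",
                 frameIds = "integer"))

.waterCols <- c("frame", "mol", "ox", "oy", "oz",
                "h1x", "h1y", "h1z", "h2x", "h2y", "h2z")

setValidity("WaterFrames", function(object) {
  w <- object@waters
  msg <- character()
  if (!all(.waterCols %in% names(w)))
    return(paste("waters must have columns:",
                 paste(.waterCols, collapse = ", ")))
  if (nrow(w)) {
    if (anyDuplicated(w[, c("frame", "mol")]))
      msg <- c(msg, "(mol, frame) pairs must be unique")
    d1 <- sqrt((w$h1x - w$ox)^2 + (w$h1y - w$oy)^2 + (w$h1z - w$oz)^2)
    d2 <- sqrt((w$h2x - w$ox)^2 + (w$h2y - w$oy)^2 + (w$h2z - w$oz)^2)
    if (any(d1 <= 0.5 | d1 >= 1.5 | d2 <= 0.5 | d2 >= 1.5))
      msg <- c(msg, "O-H distances must lie in (0.5, 1.5) Angstrom")
    if (!all(w$frame %in% object@frameIds))
      msg <- c(msg, "every water's frame must appear in frameIds")
  }
  if (length(msg)) msg else TRUE
})

#' Detected four-membered water rings
#'
#' One row per ring: `ring` (id), `frame`, member water ids `m1..m4` in
#' canonical cyclic order, and the 12 oxygen coordinates `o1x..o4z`.
#'
#' @slot rings data.frame as described above.
#' @slot nFrames Number of frames the detection ran over (for occupancy).
#' @exportClass RingSet
setClass("RingSet",
  representation(rings = "data.frame", nFrames = "integer"))

setValidity("RingSet", function(object) {
  r <- object@rings
  need <- c("ring", "frame", paste0("m", 1:4), .ringCoordCols)
  if (!all(need %in% names(r)))
    return(paste("rings must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    mem <- as.matrix(r[, paste0("m", 1:4)])
    if (any(apply(mem, 1L, anyDuplicated) > 0))
      return("each ring must have 4 distinct members")
    if (anyDuplicated(r$ring)) return("ring ids must be unique")
  }
  TRUE
})

#' Grouped water networks
#'
#' Final clusters of recurrent rings. `groups` has one row per group
#' (`group`, `nRings`, `occupancy`, centroid coordinates `c1x..c4z`);
#' `oxygens` one row per member-ring oxygen (`group`, `ring`, `slot`,
#' `x,y,z`) where `slot` in 1..4 indexes the oxygen cluster the atom was
#' assigned to; `planes` one best-fit plane per member ring (`group`,
#' `ring`, unit normal `nx,ny,nz`, plane point `px,py,pz`).
#'
#' @slot groups data.frame, one row per group.
#' @slot oxygens data.frame, one row per member oxygen.
#' @slot planes data.frame, one row per member ring.
#' @slot totalFrames Number of frames underlying the detection.
#' @exportClass TwnGroups
setClass("TwnGroups",
  representation(groups = "data.frame", oxygens = "data.frame",
                 planes = "data.frame", totalFrames = "integer"))

.centroidCols <- as.vector(t(outer(paste0("c", 1:4), c("x", "y", "z"),
                                   paste0)))

setValidity("TwnGroups", function(object) {
  g <- object@groups
  need <- c("group", "nRings", "occupancy", .centroidCols)
  if (!all(need %in% names(g)))
    return(paste("groups must have columns:", paste(need, collapse = ", ")))
  if (nrow(g) && any(g$nRings < 1L))
    return("every group must have at least one member ring")
  if (nrow(g) && any(g$occupancy <= 0))
    return("occupancy must be positive")
  TRUE
})

#' Docked fragment poses
#'
#' `atoms` has one row per atom: `frag` (pose id), `element` (normalized
#' symbol), `x,y,z` (Angstrom) and `hydrogen` (logical flag; hydrogens are
#' retained on input but excluded from centroid and shape calculations).
#'
#' @slot atoms data.frame as described above.
#' @slot source Character, provenance of each pose (named by frag id).
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(atoms = "data.frame", source = "character"))

setValidity("FragmentSet", function(object) {
  a <- object@atoms
  need <- c("frag", "element", "x", "y", "z", "hydrogen")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    heavy <- tapply(!a$hydrogen, a$frag, any)
    if (!all(heavy))
      return("every fragment must contain at least one heavy atom")
  }
  TRUE
})

#' Fragment-screening results
#'
#' One row per (fragment, group) pair with the shape similarity, average
#' orthogonal plane distance and the inclusive pass flag
#' `passed == (shape >= sMin & dist <= dMax)`.
#'
#' @slot records data.frame with columns `frag`, `group`,
#'   `shape_similarity`, `avg_distance`, `passed`.
#' @slot sMin Shape-similarity threshold (default 0.6).
#' @slot dMax Average-distance threshold, Angstrom (default 0.5).
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(records = "data.frame", sMin = "numeric", dMax = "numeric"))

setValidity("ScreenResult", function(object) {
  r <- object@records
  need <- c("frag", "group", "shape_similarity", "avg_distance", "passed")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    ok <- r$passed == (r$shape_similarity >= object@sMin &
                       r$avg_distance <= object@dMax)
    if (!all(ok)) return("passed flags inconsistent with thresholds")
  }
  TRUE
})
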