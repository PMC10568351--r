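#' Create TIP3P pair-potential parameters
#'
#' Defaults are the rigid TIP3P values: charges -0.834e (O) and +0.417e (H),
#' Lennard-Jones coefficients A = 582000 kcal A^12/mol and
#' C = 595 kcal A^6/mol acting between the oxygens, Coulomb constant
#' e^2 = 332.0636 kcal A/(mol e^2), and a hydrogen-bond criterion of
#' -2.25 kcal/mol (the minimum of the water pair-energy distribution).
#'
#' @param qO,qH Partial charges, e.
#' @param A,C Lennard-Jones coefficients.
#' @param ke2 Coulomb conversion constant.
#' @param hbondThreshold Hydrogen-bond energy criterion, kcal/mol.
#' @return An [EnergyParameters-class] object.
#' @examples
#' energyParameters()
#' @export
energyParameters <- function(qO = -0.834, qH = 0.417, A = 582000, C = 595,
                             ke2 = 332.0636, hbondThreshold = -2.25) {
  ## slots set explicitly: an argument named `C` would partially match
  ## the `Class` formal of methods::new()
  obj <- methods::new("EnergyParameters")
  obj@qO <- qO; obj@qH <- qH; obj@A <- A; obj@C <- C
  obj@ke2 <- ke2; obj@hbondThreshold <- hbondThreshold
  methods::validObject(obj)
  obj
}

#' Create Gaussian shape-density parameters
#'
#' @param p Gaussian amplitude (default `2*sqrt(2)`).
#' @param radii Named vector of van der Waals radii (Angstrom); merged over
#'   the built-in table.
#' @param normalization "hodgkin" (default) or "minmax" overlap
#'   normalization.
#' @param representation "centroids" (default; the four group centroids as
#'   oxygen pseudo-atoms) or "members" (all member-ring oxygens).
#' @return A [ShapeParameters-class] object.
#' @examples
#' shapeParameters()
#' @export
shapeParameters <- function(p = 2 * sqrt(2), radii = NULL,
                            normalization = c("hodgkin", "minmax"),
                            representation = c("centroids", "members")) {
  obj <- methods::new("ShapeParameters", p = p,
                      normalization = match.arg(normalization),
                      representation = match.arg(representation))
  if (!is.null(radii)) {
    stopifnot(!is.null(names(radii)))
    r <- obj@radii
    r[names(radii)] <- radii
    obj@radii <- r
    methods::validObject(obj)
  }
  obj
}

#' Gaussian decay factor for a van der Waals radius
#'
#' Chooses \eqn{\alpha = \pi (3 p / (4 \pi r^3))^{2/3}} so that a Gaussian
#' of amplitude `p` encloses the same volume as a hard sphere of radius `r`
#' (the usual Gaussian-shape convention in molecular shape comparison).
#'
#' @param r van der Waals radius, Angstrom (vectorised).
#' @param p Gaussian amplitude.
#' @return Decay factor(s), 1/Angstrom^2.
#' @examples
#' alphaFromRadius(1.52)
#' @export
alphaFromRadius <- function(r, p = 2 * sqrt(2)) {
  pi * (3 * p / (4 * pi * r^3))^(2 / 3)
}

#' Define a spherical binding-site region
#'
#' @param center Numeric 3-vector (Angstrom).
#' @param radius Sphere radius (Angstrom, default 20): large enough to
#'   cover a full kinase binding site around an anchor such as the DFG
#'   motif.
#' @return A [SiteDefinition-class] object.
#' @examples
#' siteDefinition(c(0, 0, 0), 20)
#' @export
siteDefinition <- function(center, radius = 20) {
  methods::new("SiteDefinition", center = as.numeric(center),
               radius = radius)
}

#' Assemble a WaterFrames object from a water table
#'
#' @param waters data.frame with columns `frame`, `mol`, `ox,oy,oz`,
#'   `h1x,h1y,h1z`, `h2x,h2y,h2z`.
#' @param boxes Optional list of per-frame box 3-vectors.
#' @param frameIds Optional explicit frame ids (defaults to the frames
#'   present in `waters`, in order of first appearance).
#' @return A [WaterFrames-class] object.
#' @export
waterFrames <- function(waters, boxes = NULL, frameIds = NULL) {
  if (is.null(frameIds)) frameIds <- unique(waters$frame)
  frameIds <- as.integer(frameIds)
  if (is.null(boxes)) boxes <- vector("list", length(frameIds))
  methods::new("WaterFrames", waters = as.data.frame(waters),
               boxes = boxes, frameIds = frameIds)
}

#' Assemble a FragmentSet from an atom table
#'
#' @param atoms data.frame with columns `frag`, `element`, `x`, `y`, `z`
#'   and optionally `hydrogen` (derived from `element` if absent).
#' @param source Optional named character vector of pose provenance.
#' @return A [FragmentSet-class] object.
#' @export
fragmentSet <- function(atoms, source = character()) {
  atoms <- as.data.frame(atoms)
  atoms$element <- normalizeElement(atoms$element)
  if (is.null(atoms$hydrogen)) atoms$hydrogen <- atoms$element == "H"
  methods::new("FragmentSet", atoms = atoms, source = source)
}

#' Normalize an element symbol ("CL" -> "Cl", " c" -> "C")
#' @keywords internal
normalizeElement <- function(el) {
  el <- trimws(as.character(el))
  bad <- !grepl("^[A-Za-z]{1,2}$", el)
  if (any(bad))
    stop("unparseable element symbol(s): ",
         paste(unique(el[bad]), collapse = ", "))
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 3)))
}
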