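## Accessors and show() methods.

#' @describeIn twnscreen-generics Number of frames in a `WaterFrames` set.
#' @export
setMethod("nFrames", "WaterFrames", function(x, ...) length(x@frameIds))

#' @describeIn twnscreen-generics Frame identifiers of a `WaterFrames` set.
#' @export
setMethod("frameIds", "WaterFrames", function(x, ...) x@frameIds)

#' @describeIn twnscreen-generics Water table; optionally one frame only.
#' @param frame Optional frame id to subset to.
#' @export
setMethod("waters", "WaterFrames", function(x, frame = NULL, ...) {
  if (is.null(frame)) x@waters else x@waters[x@waters$frame == frame, ,
                                             drop = FALSE]
})

#' @describeIn twnscreen-generics Number of frames a `RingSet` was built from.
#' @export
setMethod("nFrames", "RingSet", function(x, ...) x@nFrames)

#' @describeIn twnscreen-generics Ring table of a `RingSet`.
#' @export
setMethod("rings", "RingSet", function(x, ...) x@rings)

#' @describeIn twnscreen-generics Number of rings in a `RingSet`.
#' @export
setMethod("nRings", "RingSet", function(x, ...) nrow(x@rings))

#' @describeIn twnscreen-generics Number of final groups.
#' @export
setMethod("nGroups", "TwnGroups", function(x, ...) nrow(x@groups))

#' @describeIn twnscreen-generics Per-group summary table.
#' @export
setMethod("groups", "TwnGroups", function(x, ...) x@groups)

#' @describeIn twnscreen-generics 4 x 3 centroid matrix of one group.
#' @param group Group identifier.
#' @export
setMethod("groupCentroids", "TwnGroups", function(x, group, ...) {
  row <- x@groups[x@groups$group == group, , drop = FALSE]
  if (!nrow(row)) stop("no such group: ", group)
  matrix(as.numeric(row[1, .centroidCols]), 4L, 3L, byrow = TRUE,
         dimnames = list(paste0("c", 1:4), c("x", "y", "z")))
})

#' @describeIn twnscreen-generics Per-ring best-fit plane table.
#' @export
setMethod("groupPlanes", "TwnGroups", function(x, group = NULL, ...) {
  if (is.null(group)) x@planes else
    x@planes[x@planes$group == group, , drop = FALSE]
})

#' @describeIn twnscreen-generics Member-oxygen table.
#' @export
setMethod("groupOxygens", "TwnGroups", function(x, group = NULL, ...) {
  if (is.null(group)) x@oxygens else
    x@oxygens[x@oxygens$group == group, , drop = FALSE]
})

#' @describeIn twnscreen-generics Per-group occupancy (members / frames).
#' @export
setMethod("occupancy", "TwnGroups", function(x, ...) {
  stats::setNames(x@groups$occupancy, x@groups$group)
})

#' @describeIn twnscreen-generics Fragment identifiers.
#' @export
setMethod("fragIds", "FragmentSet", function(x, ...) unique(x@atoms$frag))

#' @describeIn twnscreen-generics Atom table; optionally one fragment,
#'   optionally heavy atoms only.
#' @param frag Optional fragment id.
#' @param heavyOnly Drop hydrogens (default FALSE).
#' @export
setMethod("fragAtoms", "FragmentSet",
          function(x, frag = NULL, heavyOnly = FALSE, ...) {
  a <- x@atoms
  if (!is.null(frag)) a <- a[a$frag == frag, , drop = FALSE]
  if (heavyOnly) a <- a[!a$hydrogen, , drop = FALSE]
  a
})

#' @describeIn twnscreen-generics Per-pair screening table.
#' @export
setMethod("screenRecords", "ScreenResult", function(x, ...) x@records)

#' @describeIn twnscreen-generics Site center 3-vector.
#' @export
setMethod("siteCenter", "SiteDefinition", function(x, ...) x@center)

#' @describeIn twnscreen-generics Site radius.
#' @export
setMethod("siteRadius", "SiteDefinition", function(x, ...) x@radius)

setMethod("show", "WaterFrames", function(object) {
  cat(sprintf("WaterFrames: %d frame(s), %d water(s) total\n",
              length(object@frameIds), nrow(object@waters)))
})

setMethod("show", "RingSet", function(object) {
  cat(sprintf("RingSet: %d four-membered ring(s) over %d frame(s)\n",
              nrow(object@rings), object@nFrames))
})

setMethod("show", "TwnGroups", function(object) {
  cat(sprintf(
    "TwnGroups: %d group(s), %d member ring(s), %d frame(s) analysed\n",
    nrow(object@groups), sum(object@groups$nRings), object@totalFrames))
  if (nrow(object@groups)) {
    cat("  members per group:",
        paste(object@groups$nRings, collapse = ", "), "\n")
  }
})

setMethod("show", "FragmentSet", function(object) {
  ids <- unique(object@atoms$frag)
  cat(sprintf("FragmentSet: %d pose(s), %d atom(s) (%d heavy)\n",
              length(ids), nrow(object@atoms), sum(!object@atoms$hydrogen)))
})

setMethod("show", "ScreenResult", function(object) {
  r <- object@records
  cat(sprintf(
    "ScreenResult: %d (fragment, group) pair(s); S >= %g, D <= %g; %d passed\n",
    nrow(r), object@sMin, object@dMax, sum(r$passed)))
})

setMethod("show", "SiteDefinition", function(object) {
  cat(sprintf("SiteDefinition: center (%.3f, %.3f, %.3f), radius %.1f A\n",
              object@center[1], object@center[2], object@center[3],
              object@radius))
})

setMethod("show", "EnergyParameters", function(object) {
  cat(sprintf(
    "EnergyParameters: qO %+.3fe qH %+.3fe A %g C %g ke2 %.4f threshold %.2f kcal/mol\n",
    object@qO, object@qH, object@A, object@C, object@ke2,
    object@hbondThreshold))
})

setMethod("show", "ShapeParameters", function(object) {
  cat(sprintf(
    "ShapeParameters: p %.4f, %d element radii, %s normalization, %s representation\n",
    object@p, length(object@radii), object@normalization,
    object@representation))
})
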