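## Superposition-free fragment scoring against grouped water networks:
## Gaussian shape-density similarity and average orthogonal plane distance.

## Resolve the pseudo-atom representation of a grouped network:
## 4 x 3 centroid matrix (default) or all member-ring oxygens.
.twnPoints <- function(twn, group = NULL, representation = "centroids") {
  if (is.matrix(twn) || is.data.frame(twn)) {
    m <- as.matrix(twn)
    stopifnot(ncol(m) == 3L)
    return(m)
  }
  stopifnot(methods::is(twn, "TwnGroups"))
  if (is.null(group)) {
    if (nrow(twn@groups) != 1L)
      stop("specify `group` when the TwnGroups object holds several groups")
    group <- twn@groups$group[1L]
  }
  if (representation == "members") {
    ox <- groupOxygens(twn, group = group)
    if (!nrow(ox)) stop("no such group: ", group)
    as.matrix(ox[, c("x", "y", "z")])
  } else {
    groupCentroids(twn, group = group)
  }
}

## Resolve fragment heavy-atom coordinates + element symbols.
.fragPoints <- function(fragment, frag = NULL, fragElements = NULL) {
  if (is.matrix(fragment) || is.data.frame(fragment)) {
    m <- as.matrix(fragment)
    stopifnot(ncol(m) == 3L)
    el <- if (is.null(fragElements)) rep("C", nrow(m))
          else normalizeElement(rep_len(fragElements, nrow(m)))
    return(list(xyz = m, el = el))
  }
  stopifnot(methods::is(fragment, "FragmentSet"))
  if (is.null(frag)) {
    ids <- fragIds(fragment)
    if (length(ids) != 1L)
      stop("specify `frag` when the FragmentSet holds several poses")
    frag <- ids[1L]
  }
  a <- fragAtoms(fragment, frag = frag, heavyOnly = TRUE)
  if (!nrow(a)) stop("fragment ", frag, " has no heavy atoms")
  list(xyz = as.matrix(a[, c("x", "y", "z")]), el = a$element)
}

.alphaFor <- function(el, params) {
  r <- params@radii[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]),
                                         collapse = ", "),
            "; using the carbon radius")
    r[is.na(r)] <- params@radii[["C"]]
  }
  alphaFromRadius(unname(r), p = params@p)
}

## Analytic overlap of two Gaussian mixtures with common amplitude p:
## sum_ij p^2 (pi/(ai+aj))^{3/2} exp(-ai aj |Ri-Rj|^2/(ai+aj)).
.gaussianOverlap <- function(xa, aa, xb, ab, p) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  asum <- outer(aa, ab, "+")
  sum(p^2 * (pi / asum)^1.5 * exp(-outer(aa, ab) * d2 / asum))
}

#' Gaussian shape-density similarity between a grouped network and a
#' fragment pose
#'
#' Each atom is a spherical Gaussian \eqn{\rho_i(r) = p\,
#' \exp(-\alpha_i |r - R_i|^2)}; the overlap of two atom sets is the sum of
#' the closed-form integrals \eqn{\int \rho_i \rho_j \, dV} over all cross
#' pairs, and the similarity is the Hodgkin index
#' \eqn{2 O_{AB} / (O_{AA} + O_{BB})} (bounded in \[0, 1\]). No rotation or
#' translation is applied to either set: both are compared in the shared
#' laboratory frame so that the location of the water network is part of
#' the score. The grouped network is represented by its four cluster
#' centroids as oxygen pseudo-atoms (or all member oxygens, see
#' [shapeParameters()]); the fragment by its heavy atoms.
#'
#' @param twn A [TwnGroups-class] object or a numeric matrix of pseudo-atom
#'   coordinates (treated as oxygens).
#' @param fragment A [FragmentSet-class] object or a numeric coordinate
#'   matrix (elements via `fragElements`, default carbon).
#' @param params [ShapeParameters-class].
#' @param group,frag Identifiers when the containers hold several
#'   groups/poses.
#' @param fragElements Element symbols when `fragment` is a bare matrix.
#' @return Similarity in \[0, 1\].
#' @examples
#' pts <- rbind(c(0,0,0), c(2.8,0,0), c(2.8,2.8,0), c(0,2.8,0))
#' shapeSimilarity(pts, pts, fragElements = "O")  # identity: 1
#' @export
shapeSimilarity <- function(twn, fragment, params = shapeParameters(),
                            group = NULL, frag = NULL,
                            fragElements = NULL) {
  tp <- .twnPoints(twn, group = group,
                   representation = params@representation)
  fp <- .fragPoints(fragment, frag = frag, fragElements = fragElements)
  if (!nrow(tp) || !nrow(fp$xyz)) stop("empty point set")
  aT <- .alphaFor(rep("O", nrow(tp)), params)
  aF <- .alphaFor(fp$el, params)
  oab <- .gaussianOverlap(tp, aT, fp$xyz, aF, params@p)
  oaa <- .gaussianOverlap(tp, aT, tp, aT, params@p)
  obb <- .gaussianOverlap(fp$xyz, aF, fp$xyz, aF, params@p)
  if (params@normalization == "minmax") oab / max(oaa, obb)
  else 2 * oab / (oaa + obb)
}

#' Heavy-atom centroid of a fragment pose
#'
#' @inheritParams shapeSimilarity
#' @return Numeric 3-vector, Angstrom.
#' @export
fragmentCentroid <- function(fragment, frag = NULL) {
  fp <- .fragPoints(fragment, frag = frag)
  colMeans(fp$xyz)
}

#' Average orthogonal distance from a point to a group's ring planes
#'
#' Mean over the group's member-ring best-fit planes of the unsigned
#' orthogonal distance \eqn{|n \cdot (c - p_0)|} from the fragment centroid
#' `c` to each plane. Averaging makes the score independent of how many
#' rings a group accumulated.
#'
#' @param twn A [TwnGroups-class] object.
#' @param centroid Numeric 3-vector (typically [fragmentCentroid()]).
#' @param group Group id when several groups are present.
#' @return Mean distance, Angstrom (non-negative).
#' @export
avgPlaneDistance <- function(twn, centroid, group = NULL) {
  stopifnot(methods::is(twn, "TwnGroups"))
  if (is.null(group)) {
    if (nrow(twn@groups) != 1L)
      stop("specify `group` when the TwnGroups object holds several groups")
    group <- twn@groups$group[1L]
  }
  pl <- groupPlanes(twn, group = group)
  if (!nrow(pl)) stop("group ", group, " has no planes")
  dx <- centroid[1] - pl$px
  dy <- centroid[2] - pl$py
  dz <- centroid[3] - pl$pz
  mean(abs(pl$nx * dx + pl$ny * dy + pl$nz * dz))
}

#' Screen fragment poses against grouped water networks
#'
#' Scores every (fragment, group) pair by shape similarity and average
#' plane distance; a pair passes when `shape >= sMin` and `dist <= dMax`
#' (both inclusive). A pose counts as screened when it passes against at
#' least one group (see [screenSummary()]). When the bounding boxes of the
#' poses and the networks are more than ~20 Angstrom apart a warning is
#' emitted, since both scores presume a shared laboratory frame.
#'
#' @param fragments A [FragmentSet-class] object.
#' @param twn A [TwnGroups-class] object.
#' @param sMin Shape-similarity threshold (default 0.6).
#' @param dMax Distance threshold, Angstrom (default 0.5).
#' @param params [ShapeParameters-class].
#' @return A [ScreenResult-class] object.
#' @export
screenFragments <- function(fragments, twn, sMin = 0.6, dMax = 0.5,
                            params = shapeParameters()) {
  stopifnot(methods::is(fragments, "FragmentSet"),
            methods::is(twn, "TwnGroups"))
  .frameSanityWarning(fragments, twn)
  ids <- fragIds(fragments)
  gids <- twn@groups$group
  rows <- list()
  for (f in ids) {
    ctr <- fragmentCentroid(fragments, frag = f)
    for (g in gids) {
      s <- shapeSimilarity(twn, fragments, params = params, group = g,
                           frag = f)
      d <- avgPlaneDistance(twn, ctr, group = g)
      rows[[length(rows) + 1L]] <- data.frame(
        frag = f, group = g, shape_similarity = s, avg_distance = d)
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frag = character(), group = integer(),
               shape_similarity = numeric(), avg_distance = numeric())
  rec$passed <- rec$shape_similarity >= sMin & rec$avg_distance <= dMax
  methods::new("ScreenResult", records = rec, sMin = sMin, dMax = dMax)
}

.frameSanityWarning <- function(fragments, twn) {
  a <- fragAtoms(fragments, heavyOnly = TRUE)
  if (!nrow(a) || !nrow(twn@groups)) return(invisible())
  fc <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  cen <- twn@groups[, .centroidCols]
  tc <- c(mean(rowMeans(cen[, c("c1x", "c2x", "c3x", "c4x")])),
          mean(rowMeans(cen[, c("c1y", "c2y", "c3y", "c4y")])),
          mean(rowMeans(cen[, c("c1z", "c2z", "c3z", "c4z")])))
  if (sqrt(sum((fc - tc)^2)) > 20)
    warning("fragment poses and grouped networks are > 20 Angstrom ",
            "apart; both scores assume a shared laboratory frame")
  invisible()
}

#' Per-fragment screening summary
#'
#' @param result A [ScreenResult-class] object.
#' @return data.frame with one row per fragment: `frag`, `screened` (passed
#'   against at least one group), `nPassed`, `bestShape`, `bestDistance`.
#' @export
screenSummary <- function(result) {
  r <- screenRecords(result)
  ids <- unique(r$frag)
  out <- do.call(rbind, lapply(ids, function(f) {
    sub <- r[r$frag == f, , drop = FALSE]
    data.frame(frag = f, screened = any(sub$passed),
               nPassed = sum(sub$passed),
               bestShape = max(sub$shape_similarity),
               bestDistance = min(sub$avg_distance))
  }))
  if (is.null(out))
    out <- data.frame(frag = character(), screened = logical(),
                      nPassed = integer(), bestShape = numeric(),
                      bestDistance = numeric())
  rownames(out) <- NULL
  out
}

#' Screened-fragment counts over a threshold grid
#'
#' For every combination of shape and distance thresholds, counts the
#' fragments that pass against at least one group. The default grid spans
#' shape similarity \{0.5, 0.6, 0.7\} and average distance
#' \{0.3, 0.5, 1.0\} Angstrom.
#'
#' @param result A [ScreenResult-class] object (its per-pair scores are
#'   re-thresholded; the stored pass flags are not used).
#' @param sGrid Shape-similarity thresholds.
#' @param dGrid Distance thresholds, Angstrom.
#' @return data.frame with columns `sMin`, `dMax`, `nScreened`,
#'   `pctScreened` (percentage of all fragments).
#' @export
thresholdSweep <- function(result, sGrid = c(0.5, 0.6, 0.7),
                           dGrid = c(0.3, 0.5, 1.0)) {
  r <- screenRecords(result)
  nf <- length(unique(r$frag))
  out <- expand.grid(sMin = sGrid, dMax = dGrid,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$sMin, out$dMax), , drop = FALSE]
  out$nScreened <- vapply(seq_len(nrow(out)), function(k) {
    pass <- r$shape_similarity >= out$sMin[k] &
      r$avg_distance <= out$dMax[k]
    length(unique(r$frag[pass]))
  }, integer(1))
  out$pctScreened <- if (nf) 100 * out$nScreened / nf else 0
  rownames(out) <- NULL
  out
}
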