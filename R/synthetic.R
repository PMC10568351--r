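## Seeded synthetic fixtures: frames with planted four-membered water
## rings plus uniform noise waters, and fragment poses at controlled
## offsets. Not a physical water simulator: geometries are constructed to
## satisfy the hydrogen-bond energy criterion, nothing more.

.OH_BOND <- 0.9572      # TIP3P O-H bond length, Angstrom
.HOH_ANGLE <- 104.52 * pi / 180  # TIP3P H-O-H angle

#' A planted ring site
#'
#' Describes one recurring four-membered water ring: a square of oxygens
#' of half-diagonal `ringRadius` (so the O-O edge is `ringRadius * sqrt(2)`,
#' about 2.8 Angstrom at the default) in the plane perpendicular to
#' `normal`, re-planted every frame with isotropic Gaussian jitter.
#'
#' @slot center Ring center, Angstrom.
#' @slot ringRadius Center-to-corner distance, Angstrom (default 1.98).
#' @slot normal Unit plane normal.
#' @slot jitterSigma Per-oxygen isotropic jitter, Angstrom.
#' @slot occupancyProb Probability a frame contains the ring.
#' @exportClass PlantedSite
setClass("PlantedSite",
  representation(center = "numeric", ringRadius = "numeric",
                 normal = "numeric", jitterSigma = "numeric",
                 occupancyProb = "numeric"),
  prototype(center = c(0, 0, 0), ringRadius = 1.98, normal = c(0, 0, 1),
            jitterSigma = 0, occupancyProb = 1))

setValidity("PlantedSite", function(object) {
  msg <- character()
  if (length(object@center) != 3L) msg <- c(msg, "center must be a 3-vector")
  if (object@ringRadius <= 0) msg <- c(msg, "ringRadius must be > 0")
  if (abs(vnorm(object@normal) - 1) > 1e-6)
    msg <- c(msg, "normal must be a unit vector")
  if (object@jitterSigma < 0) msg <- c(msg, "jitterSigma must be >= 0")
  if (object@occupancyProb < 0 || object@occupancyProb > 1)
    msg <- c(msg, "occupancyProb must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlantedSite", function(object) {
  cat(sprintf(
    "PlantedSite: center (%.2f, %.2f, %.2f), edge %.2f A, jitter %.2f A, occupancy %.2f\n",
    object@center[1], object@center[2], object@center[3],
    object@ringRadius * sqrt(2), object@jitterSigma,
    object@occupancyProb))
})

#' Create a planted ring site
#'
#' @param center Ring center (3-vector, Angstrom).
#' @param ringRadius Center-to-corner distance (default 1.98, giving an
#'   O-O edge of about 2.8 Angstrom, well inside the hydrogen-bond well).
#' @param normal Plane normal (normalised internally).
#' @param jitterSigma Isotropic per-oxygen jitter, Angstrom (default 0).
#' @param occupancyProb Per-frame inclusion probability (default 1).
#' @return A [PlantedSite-class] object.
#' @export
plantedSite <- function(center, ringRadius = 1.98, normal = c(0, 0, 1),
                        jitterSigma = 0, occupancyProb = 1) {
  normal <- as.numeric(normal) / vnorm(as.numeric(normal))
  methods::new("PlantedSite", center = as.numeric(center),
               ringRadius = ringRadius, normal = normal,
               jitterSigma = jitterSigma, occupancyProb = occupancyProb)
}

## Ideal (jitter-free) oxygen corners of a site, 4 x 3.
.siteCorners <- function(site) {
  u <- orthoUnit(site@normal)
  v <- pracmaCross(site@normal, u)
  ang <- (0:3) * pi / 2
  t(vapply(ang, function(a) {
    site@center + site@ringRadius * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}

## Build the water rows for a ring given its 4 oxygen positions (ordered
## counter-clockwise about `normal`): each water donates H1 toward the
## next oxygen (near-linear hydrogen bond) and holds its free H in the
## ring plane rotated away from the ring interior by the rigid H-O-H
## angle — the orientation that minimises the consecutive pair energies
## for a square ring (about -6.3 kcal/mol per edge at a 2.8 A edge).
.ringWaterRows <- function(opts, normal, frame, molIds) {
  rows <- vector("list", 4L)
  for (i in 1:4) {
    o <- opts[i, ]
    acc <- opts[i %% 4L + 1L, ]
    u <- (acc - o) / vnorm(acc - o)
    h1 <- o + .OH_BOND * u
    h2 <- o + .OH_BOND * rotateAbout(u, normal, -.HOH_ANGLE)
    rows[[i]] <- data.frame(frame = frame, mol = molIds[i],
                            ox = o[1], oy = o[2], oz = o[3],
                            h1x = h1[1], h1y = h1[2], h1z = h1[3],
                            h2x = h2[1], h2y = h2[2], h2z = h2[3])
  }
  do.call(rbind, rows)
}

#' Generate the four waters of a planted ring
#'
#' Oxygens sit at the corners of the site square (with Gaussian jitter when
#' `jitterSigma > 0`); each water donates one hydrogen toward the next
#' oxygen around the ring, making every consecutive pair a near-linear
#' hydrogen bond, and holds its second hydrogen out of plane at the rigid
#' water angle. At zero jitter all four consecutive pair energies are below
#' the -2.25 kcal/mol criterion.
#'
#' @param site A [PlantedSite-class] object.
#' @param seed Optional integer seed (jitter only).
#' @param frame Frame id to stamp on the waters (default 0).
#' @param molIds Four molecule ids (default 1:4).
#' @return data.frame of four waters in the standard water-table layout.
#' @export
makeRingWaters <- function(site, seed = NULL, frame = 0L, molIds = 1:4) {
  gen <- function() {
    opts <- .siteCorners(site)
    if (site@jitterSigma > 0)
      opts <- opts + matrix(stats::rnorm(12L, sd = site@jitterSigma),
                            4L, 3L)
    .ringWaterRows(opts, site@normal, frame, molIds)
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

#' Generate synthetic water frames
#'
#' Each frame contains every planted site's ring with its occupancy
#' probability, plus `nNoiseWaters` randomly oriented waters placed
#' uniformly in the box and rejected within 4 Angstrom of any ideal planted
#' oxygen (so noise does not perturb the planted networks). Fully
#' deterministic given the seed.
#'
#' @param sites List of [PlantedSite-class] objects.
#' @param nFrames Number of frames.
#' @param nNoiseWaters Noise waters per frame.
#' @param box Either a 3-vector of box lengths (box spans 0..box, Angstrom)
#'   or `NULL` to span the planted oxygens padded by 8 Angstrom.
#' @param seed Integer seed.
#' @return A [WaterFrames-class] object with frame ids `0:(nFrames-1)`.
#' @examples
#' wf <- makeFrames(list(plantedSite(c(0, 0, 0))), nFrames = 2,
#'                  nNoiseWaters = 5, seed = 7)
#' nFrames(wf)
#' @export
makeFrames <- function(sites, nFrames, nNoiseWaters = 0, box = NULL,
                       seed = 1L) {
  stopifnot(nFrames >= 1L)
  corners <- if (length(sites))
    do.call(rbind, lapply(sites, .siteCorners)) else
    matrix(numeric(), 0L, 3L)
  if (is.null(box)) {
    if (!nrow(corners))
      stop("provide `box` when there are no planted sites")
    lo <- apply(corners, 2L, min) - 8
    hi <- apply(corners, 2L, max) + 8
  } else {
    lo <- c(0, 0, 0); hi <- as.numeric(box)
  }
  withSeed(seed, {
    frames <- vector("list", nFrames)
    for (f in seq_len(nFrames) - 1L) {
      molNext <- 1L
      rows <- list()
      for (s in seq_along(sites)) {
        site <- sites[[s]]
        if (stats::runif(1) > site@occupancyProb) next
        opts <- .siteCorners(site)
        if (site@jitterSigma > 0)
          opts <- opts + matrix(stats::rnorm(12L, sd = site@jitterSigma),
                                4L, 3L)
        rows[[length(rows) + 1L]] <-
          .ringWaterRows(opts, site@normal, f, molNext + 0:3)
        molNext <- molNext + 4L
      }
      if (nNoiseWaters > 0) {
        placed <- 0L
        tries <- 0L
        while (placed < nNoiseWaters) {
          tries <- tries + 1L
          if (tries > 1000L * nNoiseWaters)
            stop("could not place noise waters; box too crowded")
          o <- lo + stats::runif(3L) * (hi - lo)
          if (nrow(corners) &&
              min(sqrt(colSums((t(corners) - o)^2))) < 4) next
          d1 <- stats::rnorm(3L); d1 <- d1 / vnorm(d1)
          ax <- orthoUnit(d1)
          ax <- rotateAbout(ax, d1, stats::runif(1L, 0, 2 * pi))
          d2 <- rotateAbout(d1, ax, .HOH_ANGLE)
          h1 <- o + .OH_BOND * d1
          h2 <- o + .OH_BOND * d2
          placed <- placed + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            frame = f, mol = molNext,
            ox = o[1], oy = o[2], oz = o[3],
            h1x = h1[1], h1y = h1[2], h1z = h1[3],
            h2x = h2[1], h2y = h2[2], h2z = h2[3])
          molNext <- molNext + 1L
        }
      }
      frames[[f + 1L]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    frames <- frames[!vapply(frames, is.null, logical(1))]
    waters <- do.call(rbind, frames)
    waterFrames(waters, frameIds = seq_len(nFrames) - 1L)
  })
}

#' Generate a fragment pose at a controlled offset
#'
#' With a [TwnGroups-class] target and `nAtoms = 4`, the atoms are placed
#' exactly on the four group centroids displaced by `offset` (the on-site
#' pass construction). Otherwise `nAtoms` atoms are scattered uniformly in
#' a disc of the ring footprint radius in the target plane and recentered
#' so the heavy-atom centroid equals the target point plus `offset`.
#'
#' @param target A 3-vector, or a [TwnGroups-class] (with `group` when it
#'   holds several groups).
#' @param offset Centroid displacement 3-vector, Angstrom (default 0).
#' @param nAtoms Number of atoms (default 4).
#' @param seed Optional integer seed (disc scatter only).
#' @param elements Element symbol(s) for the atoms (default "C"; use "O"
#'   to reproduce the exact-identity shape case against group centroids).
#' @param group Group id when `target` is a multi-group object.
#' @param fragId Pose identifier (default "frag1").
#' @return A [FragmentSet-class] with one pose.
#' @export
makeFragmentAt <- function(target, offset = c(0, 0, 0), nAtoms = 4L,
                           seed = NULL, elements = "C", group = NULL,
                           fragId = "frag1") {
  stopifnot(nAtoms >= 1L)
  offset <- as.numeric(offset)
  if (methods::is(target, "TwnGroups")) {
    cents <- .twnPoints(target, group = group)
    anchor <- colMeans(cents)
    pl <- ringPlane(cents)
    normal <- pl$normal
  } else {
    cents <- NULL
    anchor <- as.numeric(target)
    normal <- c(0, 0, 1)
  }
  gen <- function() {
    if (!is.null(cents) && nAtoms == 4L) {
      xyz <- sweep(cents, 2L, offset, "+")
    } else {
      u <- orthoUnit(normal)
      v <- pracmaCross(normal, u)
      rr <- 1.98 * sqrt(stats::runif(nAtoms))
      th <- stats::runif(nAtoms, 0, 2 * pi)
      xyz <- t(vapply(seq_len(nAtoms), function(i) {
        anchor + rr[i] * (cos(th[i]) * u + sin(th[i]) * v)
      }, numeric(3)))
      xyz <- sweep(xyz, 2L, colMeans(xyz) - anchor - offset, "-")
    }
    atoms <- data.frame(frag = fragId,
                        element = rep_len(elements, nAtoms),
                        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
    fragmentSet(atoms, source = stats::setNames("synthetic", fragId))
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

#' Demonstration planted sites
#'
#' Five well-separated ring sites (centers about 8 Angstrom apart, varied
#' plane orientations) with 0.1 Angstrom jitter: the default end-to-end
#' fixture for the grouping and screening pipeline.
#'
#' @param jitterSigma Per-oxygen jitter, Angstrom (default 0.1).
#' @param occupancyProb Per-frame inclusion probability (default 1).
#' @return List of five [PlantedSite-class] objects.
#' @export
demoSites <- function(jitterSigma = 0.1, occupancyProb = 1) {
  centers <- list(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0),
                  c(-8, 0, 4), c(0, -8, 4))
  normals <- list(c(0, 0, 1), c(0, 1, 1), c(1, 0, 1),
                  c(1, 1, 1), c(0, 0, 1))
  lapply(seq_along(centers), function(i) {
    plantedSite(centers[[i]], normal = normals[[i]],
                jitterSigma = jitterSigma,
                occupancyProb = occupancyProb)
  })
}
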