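## Two-stage grouping of recurrent rings: grid-based primary grouping,
## DBSCAN cluster centers, and centroid-distance secondary grouping.

#' 3D grid index over ring oxygens
#'
#' Half-open cubic cells of side `spacing`; the cell of a point p is
#' `floor((p - origin)/spacing)` componentwise. The origin is the
#' componentwise minimum of all oxygen coordinates snapped down to a
#' multiple of the spacing.
#'
#' @slot origin Numeric 3-vector, Angstrom.
#' @slot spacing Cell side, Angstrom.
#' @slot entries data.frame with one row per registered oxygen: `row`
#'   (ring-table row), `ring` (ring id), `slot` (oxygen index 1..4) and
#'   integer cell coordinates `cx`, `cy`, `cz`.
#' @exportClass GridIndex
setClass("GridIndex",
  representation(origin = "numeric", spacing = "numeric",
                 entries = "data.frame"))

setMethod("show", "GridIndex", function(object) {
  cat(sprintf(
    "GridIndex: spacing %.2f A, origin (%.2f, %.2f, %.2f), %d oxygen(s) in %d cell(s)\n",
    object@spacing, object@origin[1], object@origin[2], object@origin[3],
    nrow(object@entries),
    nrow(unique(object@entries[, c("cx", "cy", "cz")]))))
})

#' Primary ring groups
#'
#' Connected components of the grid-neighbourhood link relation, with the
#' oxygen-to-cluster correspondence propagated so each member ring
#' contributes exactly one oxygen per cluster.
#'
#' @slot members data.frame: `ring`, `group`, and `s1..s4` giving the
#'   cluster slot of the ring's 1st..4th oxygen.
#' @slot centers data.frame: `group`, `slot`, `x,y,z` cluster centers
#'   (filled by [clusterCenters()]).
#' @slot ringSet The underlying [RingSet-class].
#' @exportClass PrimaryGroups
setClass("PrimaryGroups",
  representation(members = "data.frame", centers = "data.frame",
                 ringSet = "RingSet"))

setMethod("show", "PrimaryGroups", function(object) {
  cat(sprintf("PrimaryGroups: %d group(s) over %d ring(s)\n",
              length(unique(object@members$group)),
              nrow(object@members)))
})

#' Build the oxygen grid index
#'
#' @param ringSet A [RingSet-class] object.
#' @param spacing Grid spacing, Angstrom (default 0.5).
#' @return A [GridIndex-class] object.
#' @export
buildGrid <- function(ringSet, spacing = 0.5) {
  r <- ringSet@rings
  if (!nrow(r)) stop("cannot build a grid from an empty ring set")
  pts <- .allOxygens(r)
  origin <- floor(apply(pts[, c("x", "y", "z")], 2L, min) / spacing) *
    spacing
  cells <- floor(sweep(as.matrix(pts[, c("x", "y", "z")]), 2L, origin) /
                 spacing)
  entries <- data.frame(row = pts$row, ring = pts$ring, slot = pts$slot,
                        cx = as.integer(cells[, 1L]),
                        cy = as.integer(cells[, 2L]),
                        cz = as.integer(cells[, 3L]))
  methods::new("GridIndex", origin = as.numeric(origin), spacing = spacing,
               entries = entries)
}

## Long-format oxygen table of a ring data.frame: row, ring, slot, x, y, z.
.allOxygens <- function(r) {
  n <- nrow(r)
  data.frame(row = rep(seq_len(n), 4L),
             ring = rep(r$ring, 4L),
             slot = rep(1:4, each = n),
             x = c(r$o1x, r$o2x, r$o3x, r$o4x),
             y = c(r$o1y, r$o2y, r$o3y, r$o4y),
             z = c(r$o1z, r$o2z, r$o3z, r$o4z))
}

## Per-ring 4x3 coordinate and cell matrices, as lists indexed by row.
.ringMatrices <- function(r, grid) {
  n <- nrow(r)
  coords <- array(0, c(n, 4L, 3L))
  coords[, , 1L] <- cbind(r$o1x, r$o2x, r$o3x, r$o4x)
  coords[, , 2L] <- cbind(r$o1y, r$o2y, r$o3y, r$o4y)
  coords[, , 3L] <- cbind(r$o1z, r$o2z, r$o3z, r$o4z)
  cells <- floor(sweep(coords, 3L, grid@origin) / grid@spacing)
  list(coords = coords, cells = cells)
}

## Simple union-find.
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Primary grouping of rings on the oxygen grid
#'
#' Two rings are directly linked when a one-to-one correspondence between
#' their four oxygens exists such that every matched pair lies within each
#' other's extended zone (the own grid cell expanded by one cell per axis,
#' i.e. the 3x3x3 cell neighbourhood). Groups are the connected components
#' of this relation; the minimum-total-distance feasible correspondence is
#' propagated along a spanning forest so each ring contributes one oxygen
#' to each of the four clusters.
#'
#' @param ringSet A [RingSet-class] object.
#' @param grid Optional [GridIndex-class] built from `ringSet` (built on
#'   the fly if omitted).
#' @param spacing Grid spacing used when `grid` is missing.
#' @return A [PrimaryGroups-class] object (centers not yet computed).
#' @export
primaryGrouping <- function(ringSet, grid = NULL, spacing = 0.5) {
  r <- ringSet@rings
  if (!nrow(r)) stop("cannot group an empty ring set")
  r <- r[order(r$ring), , drop = FALSE]
  if (is.null(grid))
    grid <- buildGrid(methods::new("RingSet", rings = r,
                                   nFrames = ringSet@nFrames), spacing)
  n <- nrow(r)
  rm <- .ringMatrices(r, grid)

  ## Hash cells -> ring rows for candidate generation.
  cellKey <- function(cx, cy, cz) paste(cx, cy, cz, sep = "_")
  h <- new.env(hash = TRUE, size = 4L * n)
  for (i in seq_len(n)) for (s in 1:4) {
    k <- cellKey(rm$cells[i, s, 1L], rm$cells[i, s, 2L],
                 rm$cells[i, s, 3L])
    h[[k]] <- c(h[[k]], i)
  }
  neighOffsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

  parent <- seq_len(n)
  links <- list()
  for (i in seq_len(n)) {
    cand <- integer()
    for (s in 1:4) {
      cc <- rm$cells[i, s, ]
      for (o in seq_len(27L)) {
        k <- cellKey(cc[1L] + neighOffsets[o, 1L],
                     cc[2L] + neighOffsets[o, 2L],
                     cc[3L] + neighOffsets[o, 3L])
        v <- h[[k]]
        if (!is.null(v)) cand <- c(cand, v)
      }
    }
    cand <- sort(unique(cand[cand > i]))
    for (j in cand) {
      ri <- .ufFind(parent, i)
      rj <- .ufFind(parent, j)
      if (ri == rj) next
      match <- .ringLinkMatch(rm, i, j)
      if (is.null(match)) next
      parent[max(ri, rj)] <- min(ri, rj)
      links[[length(links) + 1L]] <- list(i = i, j = j, perm = match)
    }
  }

  comp <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
  comp <- match(comp, sort(unique(comp)))

  slots <- .propagateSlots(n, comp, links)
  members <- data.frame(ring = r$ring, group = comp,
                        s1 = slots[, 1L], s2 = slots[, 2L],
                        s3 = slots[, 3L], s4 = slots[, 4L])
  methods::new("PrimaryGroups", members = members,
               centers = data.frame(group = integer(), slot = integer(),
                                    x = numeric(), y = numeric(),
                                    z = numeric()),
               ringSet = methods::new("RingSet", rings = r,
                                      nFrames = ringSet@nFrames))
}

## Feasible minimum-distance correspondence between rings at rows i and j,
## or NULL when no permutation keeps all four oxygen pairs within one grid
## cell of each other on every axis.
.ringLinkMatch <- function(rm, i, j) {
  ok <- matrix(FALSE, 4L, 4L)
  for (a in 1:4) for (b in 1:4) {
    ok[a, b] <- all(abs(rm$cells[i, a, ] - rm$cells[j, b, ]) <= 1L)
  }
  feas <- which(vapply(seq_len(24L), function(k) {
    all(ok[cbind(1:4, .perm4[k, ])])
  }, logical(1)))
  if (!length(feas)) return(NULL)
  d <- matrix(0, 4L, 4L)
  for (a in 1:4)
    d[a, ] <- sqrt(rowSums(sweep(rm$coords[j, , ], 2L,
                                 rm$coords[i, a, ])^2))
  tot <- vapply(feas, function(k) sum(d[cbind(1:4, .perm4[k, ])]),
                numeric(1))
  .perm4[feas[which.min(tot)], ]
}

## Propagate oxygen->cluster-slot assignments along the link forest.
## Returns an n x 4 matrix: row i, column a = cluster slot of ring i's
## a-th oxygen. The smallest-row ring of each component anchors slots 1:4.
.propagateSlots <- function(n, comp, links) {
  adj <- vector("list", n)
  for (L in links) {
    adj[[L$i]] <- c(adj[[L$i]], list(L))
    adj[[L$j]] <- c(adj[[L$j]], list(L))
  }
  slots <- matrix(NA_integer_, n, 4L)
  for (g in unique(comp)) {
    rows <- which(comp == g)
    root <- min(rows)
    slots[root, ] <- 1:4
    queue <- root
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (L in adj[[cur]]) {
        other <- if (L$i == cur) L$j else L$i
        if (!is.na(slots[other, 1L])) next
        if (L$i == cur) {
          ## perm maps i's oxygen a -> j's oxygen perm[a]
          slots[other, L$perm] <- slots[cur, ]
        } else {
          slots[other, ] <- slots[cur, L$perm]
        }
        queue <- c(queue, other)
      }
    }
  }
  slots
}

#' Density-based clustering (DBSCAN)
#'
#' Plain DBSCAN on a point matrix with Euclidean distances. Written for the
#' small per-cluster point sets that arise here (hundreds of points).
#'
#' @param x Numeric matrix, one point per row.
#' @param eps Neighbourhood radius.
#' @param minPts Minimum neighbourhood size (including the point itself)
#'   for a core point.
#' @return Integer cluster labels, 0 for noise, clusters numbered in order
#'   of first appearance.
#' @export
dbscanLabels <- function(x, eps, minPts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!n) return(integer())
  d <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      nxt <- integer()
      for (q in frontier) {
        if (!core[q]) next
        cand <- nb[[q]]
        cand <- cand[labels[cand] == 0L]
        if (length(cand)) {
          labels[cand] <- cl
          nxt <- c(nxt, cand)
        }
      }
      frontier <- nxt
    }
  }
  labels
}

#' Cluster centers of the four oxygen clouds of each primary group
#'
#' Runs DBSCAN on each oxygen cluster of each primary group; the center is
#' the mean of the largest DBSCAN cluster (ties broken toward the cluster
#' appearing first). If DBSCAN labels every point noise, the plain mean of
#' the set is used and a warning is recorded.
#'
#' @param primary A [PrimaryGroups-class] object.
#' @param eps DBSCAN neighbourhood radius, Angstrom (default 1.0).
#' @param minSamples DBSCAN core-point minimum (default 1).
#' @return The [PrimaryGroups-class] object with its `centers` slot filled.
#' @export
clusterCenters <- function(primary, eps = 1.0, minSamples = 1L) {
  ox <- .groupOxygenTable(primary)
  keys <- unique(ox[, c("group", "cslot")])
  keys <- keys[order(keys$group, keys$cslot), , drop = FALSE]
  centers <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- ox$group == keys$group[k] & ox$cslot == keys$cslot[k]
    pts <- as.matrix(ox[sel, c("x", "y", "z"), drop = FALSE])
    c(keys$group[k], keys$cslot[k], .dbscanCenter(pts, eps, minSamples))
  })
  centers <- as.data.frame(do.call(rbind, centers))
  names(centers) <- c("group", "slot", "x", "y", "z")
  primary@centers <- centers
  primary
}

.dbscanCenter <- function(pts, eps, minPts) {
  labels <- dbscanLabels(pts, eps, minPts)
  if (all(labels == 0L)) {
    warning("DBSCAN labelled all points noise; using the plain mean")
    return(colMeans(pts))
  }
  sizes <- table(labels[labels > 0L])
  big <- as.integer(names(sizes)[which.max(sizes)])
  colMeans(pts[labels == big, , drop = FALSE])
}

## Long oxygen table of a PrimaryGroups object with cluster slots:
## columns group, ring, row, oslot (position in ring), cslot (cluster), xyz.
.groupOxygenTable <- function(primary) {
  r <- primary@ringSet@rings
  m <- primary@members
  n <- nrow(r)
  sl <- as.matrix(m[, paste0("s", 1:4)])
  data.frame(group = rep(m$group, 4L),
             ring = rep(m$ring, 4L),
             row = rep(seq_len(n), 4L),
             oslot = rep(1:4, each = n),
             cslot = as.vector(sl),
             x = c(r$o1x, r$o2x, r$o3x, r$o4x),
             y = c(r$o1y, r$o2y, r$o3y, r$o4y),
             z = c(r$o1z, r$o2z, r$o3z, r$o4z))
}

#' Best-fit plane through four points
#'
#' Total-least-squares plane: the normal is the singular vector of the
#' smallest singular value of the centered point matrix; the plane point is
#' the centroid. The normal sign is fixed to a positive z component (ties
#' resolved toward positive y, then x).
#'
#' @param pts 4 x 3 numeric matrix.
#' @return List with `normal` (unit 3-vector) and `point` (3-vector).
#' @examples
#' ringPlane(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
#' @export
ringPlane <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(nrow(pts) == 4L, ncol(pts) == 3L)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2L, ctr)
  sv <- svd(X)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop("degenerate geometry: points are collinear or coincident")
  normal <- sv$v[, 3L]
  tol <- 1e-12
  flip <- if (abs(normal[3L]) > tol) normal[3L] < 0
          else if (abs(normal[2L]) > tol) normal[2L] < 0
          else normal[1L] < 0
  if (flip) normal <- -normal
  list(normal = normal, point = ctr)
}

#' Secondary grouping: merge primary groups by cluster-center distance
#'
#' Two primary groups are linked when a one-to-one assignment of their four
#' cluster centers exists with every matched pair at most `radius` apart
#' (minimum-cost assignment over the 4x4 distance matrix, then the largest
#' matched distance is compared). Final groups are connected components of
#' this relation (single-linkage transitive closure). Merged groups pool
#' their oxygen clouds slot-wise and re-derive centers with DBSCAN; one
#' best-fit plane is stored per member ring from that ring's four oxygens.
#'
#' @param primary A [PrimaryGroups-class] with centers computed (see
#'   [clusterCenters()]; computed on the fly if absent).
#' @param radius Center-distance merge criterion, Angstrom (default 1.0,
#'   inclusive).
#' @param eps,minSamples DBSCAN parameters for re-derived centers.
#' @return A [TwnGroups-class] object.
#' @export
secondaryGrouping <- function(primary, radius = 1.0, eps = 1.0,
                              minSamples = 1L) {
  if (!nrow(primary@centers))
    primary <- clusterCenters(primary, eps = eps, minSamples = minSamples)
  cen <- primary@centers
  gids <- sort(unique(primary@members$group))
  k <- length(gids)
  cmat <- lapply(gids, function(g) {
    cc <- cen[cen$group == g, , drop = FALSE]
    as.matrix(cc[order(cc$slot), c("x", "y", "z")])
  })

  parent <- seq_len(k)
  links <- list()
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    asg <- assignPoints4(cmat[[i]], cmat[[j]])
    if (asg$maxDist > radius) next
    ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
    links[[length(links) + 1L]] <- list(i = i, j = j, perm = asg$perm)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_len(k), function(i) .ufFind(parent, i), integer(1))
  comp <- match(comp, sort(unique(comp)))

  ## Re-map primary cluster slots onto the slots of each component's
  ## anchor primary group (smallest index).
  slotMap <- .propagateSlots(k, comp, links)

  ox <- .groupOxygenTable(primary)
  pidx <- match(ox$group, gids)
  ox$final <- comp[pidx]
  ox$fslot <- slotMap[cbind(pidx, ox$cslot)]

  r <- primary@ringSet@rings
  total <- primary@ringSet@nFrames
  finals <- sort(unique(ox$final))
  grows <- list(); orows <- list(); prows <- list()
  for (fi in seq_along(finals)) {
    g <- finals[fi]
    sub <- ox[ox$final == g, , drop = FALSE]
    cents <- matrix(0, 4L, 3L)
    for (s in 1:4) {
      pts <- as.matrix(sub[sub$fslot == s, c("x", "y", "z"),
                           drop = FALSE])
      cents[s, ] <- .dbscanCenter(pts, eps, minSamples)
    }
    ringsIn <- sort(unique(sub$ring))
    planes <- lapply(ringsIn, function(rg) {
      pr <- sub[sub$ring == rg, , drop = FALSE]
      pr <- pr[order(pr$fslot), , drop = FALSE]
      ringPlane(as.matrix(pr[, c("x", "y", "z")]))
    })
    grows[[fi]] <- data.frame(
      group = fi, nRings = length(ringsIn),
      occupancy = length(ringsIn) / total,
      c1x = cents[1, 1], c1y = cents[1, 2], c1z = cents[1, 3],
      c2x = cents[2, 1], c2y = cents[2, 2], c2z = cents[2, 3],
      c3x = cents[3, 1], c3y = cents[3, 2], c3z = cents[3, 3],
      c4x = cents[4, 1], c4y = cents[4, 2], c4z = cents[4, 3])
    orows[[fi]] <- data.frame(group = fi, ring = sub$ring,
                              slot = sub$fslot, x = sub$x, y = sub$y,
                              z = sub$z)
    prows[[fi]] <- data.frame(
      group = fi, ring = ringsIn,
      nx = vapply(planes, function(p) p$normal[1], numeric(1)),
      ny = vapply(planes, function(p) p$normal[2], numeric(1)),
      nz = vapply(planes, function(p) p$normal[3], numeric(1)),
      px = vapply(planes, function(p) p$point[1], numeric(1)),
      py = vapply(planes, function(p) p$point[2], numeric(1)),
      pz = vapply(planes, function(p) p$point[3], numeric(1)))
  }
  methods::new("TwnGroups",
               groups = do.call(rbind, grows),
               oxygens = do.call(rbind, orows),
               planes = do.call(rbind, prows),
               totalFrames = as.integer(total))
}

#' Group recurrent rings into final water-network clusters
#'
#' Convenience wrapper: grid construction, primary grouping, DBSCAN cluster
#' centers and secondary grouping in one call.
#'
#' @param ringSet A [RingSet-class] object.
#' @param spacing Grid spacing, Angstrom (default 0.5).
#' @param secondaryRadius Center-distance merge criterion, Angstrom
#'   (default 1.0).
#' @param eps,minSamples DBSCAN parameters (defaults 1.0 Angstrom, 1).
#' @return A [TwnGroups-class] object.
#' @examples
#' site <- plantedSite(center = c(0, 0, 0))
#' wf <- makeFrames(list(site), nFrames = 5, nNoiseWaters = 0, seed = 1)
#' groupRings(detectRings(wf))
#' @export
groupRings <- function(ringSet, spacing = 0.5, secondaryRadius = 1.0,
                       eps = 1.0, minSamples = 1L) {
  pg <- primaryGrouping(ringSet, spacing = spacing)
  pg <- clusterCenters(pg, eps = eps, minSamples = minSamples)
  secondaryGrouping(pg, radius = secondaryRadius, eps = eps,
                    minSamples = minSamples)
}
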