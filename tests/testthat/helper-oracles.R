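## Independent oracles and random-geometry helpers. Oracles are written
## as literal transcriptions (explicit loops, no shared code with the
## package internals) so they stay independent of the paths they check.

## Literal term-by-term pair energy: nine charge-charge terms plus one
## oxygen-oxygen Lennard-Jones term.
oraclePairEnergy <- function(a, b, qO = -0.834, qH = 0.417, A = 582000,
                             C = 595, ke2 = 332.0636) {
  q <- c(qO, qH, qH)
  v <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      r <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2 +
                (a[i, 3] - b[j, 3])^2)
      v <- v + q[i] * q[j] * ke2 / r
    }
  }
  roo <- sqrt(sum((a[1, ] - b[1, ])^2))
  v + A / roo^12 - C / roo^6
}

## A random rigid water: O at `center`, O-H 0.9572 A, H-O-H 104.52 deg,
## uniformly random orientation.
randomWater <- function(center) {
  d1 <- stats::rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
  ref <- if (abs(d1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * d1) * d1; p <- p / sqrt(sum(p^2))
  phi <- stats::runif(1, 0, 2 * pi)
  q <- cos(phi) * p + sin(phi) * cross3(d1, p)
  th <- 104.52 * pi / 180
  d2 <- cos(th) * d1 + sin(th) * q
  rbind(center, center + 0.9572 * d1, center + 0.9572 * d2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## A WaterFrames object with n random waters in a box of side L (frame 0).
randomFrame <- function(n, L = 8) {
  rows <- lapply(seq_len(n), function(i) {
    w <- randomWater(stats::runif(3, 0, L))
    data.frame(frame = 0L, mol = i,
               ox = w[1, 1], oy = w[1, 2], oz = w[1, 3],
               h1x = w[2, 1], h1y = w[2, 2], h1z = w[2, 3],
               h2x = w[3, 1], h2y = w[3, 2], h2z = w[3, 3])
  })
  waterFrames(do.call(rbind, rows))
}

waterMatrix <- function(w, k) {
  rbind(c(w$ox[k], w$oy[k], w$oz[k]),
        c(w$h1x[k], w$h1y[k], w$h1z[k]),
        c(w$h2x[k], w$h2y[k], w$h2z[k]))
}

## Exhaustive ring oracle: every 4-subset of waters, the three cyclic
## pairings of each, kept when all four consecutive pairs have oracle
## energy at or below the threshold. Returns a sorted key per ring
## (canonical start at smallest id, smaller neighbour second).
oracleRings <- function(frames, threshold = -2.25) {
  w <- waters(frames)
  n <- nrow(w)
  if (n < 4) return(character())
  mats <- lapply(seq_len(n), function(k) waterMatrix(w, k))
  bonded <- function(i, j) oraclePairEnergy(mats[[i]], mats[[j]]) <= threshold
  keys <- character()
  pairings <- list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4))
  for (sub in utils::combn(n, 4, simplify = FALSE)) {
    for (p in pairings) {
      cyc <- sub[p]
      ok <- TRUE
      for (e in 1:4) {
        if (!bonded(cyc[e], cyc[e %% 4 + 1])) { ok <- FALSE; break }
      }
      if (!ok) next
      ids <- w$mol[cyc]
      s <- which.min(ids)
      prv <- ids[(s - 2) %% 4 + 1]; nxt <- ids[s %% 4 + 1]
      ord <- if (nxt <= prv) (s - 1 + 0:3) %% 4 + 1 else (s - 1 - 0:3) %% 4 + 1
      keys <- c(keys, paste(ids[ord], collapse = "_"))
    }
  }
  sort(unique(keys))
}

ringKeys <- function(ringSet) {
  r <- rings(ringSet)
  if (!nrow(r)) return(character())
  sort(paste(r$m1, r$m2, r$m3, r$m4, sep = "_"))
}

## Brute-force pairwise primary-grouping oracle: all ring pairs, all 24
## permutations, linked when some permutation keeps every matched oxygen
## pair within one grid cell per axis; partition = transitive closure.
oraclePrimaryPartition <- function(ringSet, spacing = 0.5) {
  r <- rings(ringSet)
  r <- r[order(r$ring), , drop = FALSE]
  n <- nrow(r)
  coord <- function(k) matrix(as.numeric(
    r[k, c("o1x", "o1y", "o1z", "o2x", "o2y", "o2z",
           "o3x", "o3y", "o3z", "o4x", "o4y", "o4z")]), 4, 3,
    byrow = TRUE)
  allpts <- do.call(rbind, lapply(seq_len(n), coord))
  origin <- floor(apply(allpts, 2, min) / spacing) * spacing
  cellOf <- function(m) floor(sweep(m, 2, origin) / spacing)
  cells <- lapply(seq_len(n), function(k) cellOf(coord(k)))
  perms <- asplit(perms4(), 1)
  linked <- function(i, j) {
    for (p in perms) {
      ok <- TRUE
      for (a in 1:4) {
        if (any(abs(cells[[i]][a, ] - cells[[j]][p[a], ]) > 1)) {
          ok <- FALSE; break
        }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (comp[i] != comp[j] && linked(i, j)) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

perms4 <- function() {
  out <- matrix(NA_integer_, 24, 4)
  k <- 1
  for (a in 1:4) for (b in setdiff(1:4, a)) for (d in setdiff(1:4, c(a, b))) {
    out[k, ] <- c(a, b, d, setdiff(1:4, c(a, b, d)))
    k <- k + 1
  }
  out
}

## Canonical partition signature: groups as sorted member-id strings.
partitionSignature <- function(ids, groupOf) {
  unname(sort(vapply(split(ids, groupOf), function(m)
    paste(sort(m), collapse = ","), character(1))))
}

## 1D Gauss product integral by midpoint quadrature (the 3D integral of a
## product of two spherical Gaussians factorises over axes).
quad1d <- function(ai, aj, xi, xj, lo, hi, h = 5e-4) {
  x <- seq(lo + h / 2, hi - h / 2, by = h)
  sum(exp(-ai * (x - xi)^2 - aj * (x - xj)^2)) * h
}
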