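#' Evaluate an expression with a private, seeded RNG stream
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## All 24 permutations of 1:4, one per row (fixed order, no RNG).
.perm4 <- local({
  p <- matrix(NA_integer_, 24L, 4L)
  k <- 1L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (d in setdiff(1:4, c(a, b))) {
    p[k, ] <- c(a, b, d, setdiff(1:4, c(a, b, d)))
    k <- k + 1L
  }
  p
})

#' Optimal assignment between two sets of four 3D points
#'
#' Exhaustive minimum-cost bipartite assignment on the 4 x 4 Euclidean
#' distance matrix (24 permutations; exact).
#'
#' @param a,b 4 x 3 numeric matrices.
#' @return List with `perm` (index into rows of `b` for each row of `a`),
#'   `dists` (the four matched distances) and `maxDist`.
#' @keywords internal
assignPoints4 <- function(a, b) {
  d <- matrix(0, 4L, 4L)
  for (i in 1:4) d[i, ] <- sqrt(colSums((t(b) - a[i, ])^2))
  cost <- .perm4
  total <- d[cbind(rep(1:4, each = 24L), as.vector(cost))]
  dim(total) <- c(24L, 4L)
  sums <- rowSums(total)
  k <- which.min(sums)
  list(perm = .perm4[k, ], dists = total[k, ], maxDist = max(total[k, ]))
}

#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' Unit vector orthogonal to `v` (deterministic choice)
#' @keywords internal
orthoUnit <- function(v) {
  v <- v / vnorm(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * v) * v
  u / vnorm(u)
}

#' Rotation of vector `x` about unit axis `k` by angle `theta` (Rodrigues)
#' @keywords internal
rotateAbout <- function(x, k, theta) {
  k <- k / vnorm(k)
  x * cos(theta) + pracmaCross(k, x) * sin(theta) +
    k * sum(k * x) * (1 - cos(theta))
}

#' @keywords internal
pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Column names used for the 12 ring oxygen coordinates
#' @keywords internal
.ringCoordCols <- as.vector(t(outer(paste0("o", 1:4), c("x", "y", "z"),
                                    paste0)))

#' Extract the 4 x 3 oxygen-coordinate matrix of one ring row
#' @keywords internal
ringCoords <- function(ringRow) {
  matrix(as.numeric(ringRow[.ringCoordCols]), nrow = 4L, ncol = 3L,
         byrow = TRUE)
}
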