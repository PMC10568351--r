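#' Hydrogen-bond graph of one frame
#'
#' Nodes are water molecule ids; an undirected edge carries the pair
#' interaction energy and is present only when that energy is at or below
#' the hydrogen-bond threshold.
#'
#' @slot frame Frame identifier.
#' @slot nodes Water molecule ids present in the frame.
#' @slot edges data.frame with columns `a`, `b` (mol ids, a < b) and
#'   `energy` (kcal/mol).
#' @exportClass HBondGraph
setClass("HBondGraph",
  representation(frame = "integer", nodes = "integer",
                 edges = "data.frame"))

setMethod("show", "HBondGraph", function(object) {
  cat(sprintf("HBondGraph: frame %d, %d node(s), %d edge(s)\n",
              object@frame, length(object@nodes), nrow(object@edges)))
})

#' Water-water pair interaction energy
#'
#' Rigid three-site pair potential: the Coulomb sum over all nine
#' site-site charge pairs plus a single Lennard-Jones term acting between
#' the two oxygens,
#' \deqn{v(a,b) = \sum_{i \in a}\sum_{j \in b} \frac{q_i q_j e^2}{r_{ij}}
#'   + \frac{A}{r_{oo}^{12}} - \frac{C}{r_{oo}^6}.}
#' Symmetric in its arguments.
#'
#' @param a,b Water geometries: 3 x 3 numeric matrices with rows O, H1, H2
#'   (coordinates in Angstrom).
#' @param params [EnergyParameters-class].
#' @return Interaction energy, kcal/mol.
#' @examples
#' a <- rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.24, 0.927, 0))
#' b <- a + c(2.8, 0, 0)  # translated copy
#' pairEnergy(a, b)
#' @export
pairEnergy <- function(a, b, params = energyParameters()) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == c(3L, 3L)), all(dim(b) == c(3L, 3L)))
  roo <- sqrt(sum((a[1, ] - b[1, ])^2))
  if (roo < 0.1)
    stop("degenerate geometry: O-O distance below 0.1 Angstrom")
  q <- c(params@qO, params@qH, params@qH)
  coul <- 0
  for (i in 1:3) for (j in 1:3) {
    rij <- sqrt(sum((a[i, ] - b[j, ])^2))
    coul <- coul + q[i] * q[j] / rij
  }
  params@ke2 * coul + params@A / roo^12 - params@C / roo^6
}

## Vectorised pair energies for index pairs (ii, jj) into a water table.
## w: data.frame with the standard water columns. Returns kcal/mol.
.pairEnergiesIdx <- function(w, ii, jj, params) {
  sx <- cbind(w$ox, w$h1x, w$h2x)
  sy <- cbind(w$oy, w$h1y, w$h2y)
  sz <- cbind(w$oz, w$h1z, w$h2z)
  q <- c(params@qO, params@qH, params@qH)
  coul <- numeric(length(ii))
  for (i in 1:3) for (j in 1:3) {
    rij <- sqrt((sx[ii, i] - sx[jj, j])^2 +
                (sy[ii, i] - sy[jj, j])^2 +
                (sz[ii, i] - sz[jj, j])^2)
    coul <- coul + q[i] * q[j] / rij
  }
  roo <- sqrt((sx[ii, 1] - sx[jj, 1])^2 +
              (sy[ii, 1] - sy[jj, 1])^2 +
              (sz[ii, 1] - sz[jj, 1])^2)
  params@ke2 * coul + params@A / roo^12 - params@C / roo^6
}

#' Build the hydrogen-bond graph of one frame
#'
#' Evaluates the pair potential for every water pair whose O-O distance is
#' within `cutoff` and keeps an edge when the energy is at or below the
#' hydrogen-bond threshold (inclusive). The default 4.5 Angstrom cutoff is
#' a lossless neighbour-list optimization: the orientation-optimal rigid
#' three-site pair energy falls above -2.25 kcal/mol once the oxygens are
#' more than about 4.1 Angstrom apart, so no qualifying pair is ever
#' skipped (see the package vignette for the numerical bound). Set
#' `cutoff = Inf` for an exhaustive all-pairs evaluation.
#'
#' @param frames A [WaterFrames-class] object.
#' @param frame Frame id to analyse (default: the first frame).
#' @param params [EnergyParameters-class].
#' @param cutoff O-O neighbour cutoff, Angstrom (default 4.5).
#' @return An [HBondGraph-class] object.
#' @export
buildHBondGraph <- function(frames, frame = NULL,
                            params = energyParameters(), cutoff = 4.5) {
  if (is.null(frame)) frame <- frames@frameIds[1]
  w <- waters(frames, frame = frame)
  if (!nrow(w)) stop("frame ", frame, " has no waters")
  n <- nrow(w)
  edges <- data.frame(a = integer(), b = integer(), energy = numeric())
  if (n >= 2L) {
    if (is.finite(cutoff)) {
      d <- as.matrix(stats::dist(cbind(w$ox, w$oy, w$oz)))
      keep <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    } else {
      keep <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    }
    if (nrow(keep)) {
      ii <- keep[, 1L]; jj <- keep[, 2L]
      v <- .pairEnergiesIdx(w, ii, jj, params)
      sel <- v <= params@hbondThreshold
      if (any(sel)) {
        a <- w$mol[ii[sel]]; b <- w$mol[jj[sel]]
        swap <- a > b
        tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        edges <- data.frame(a = a, b = b, energy = v[sel])
        edges <- edges[order(edges$a, edges$b), , drop = FALSE]
        rownames(edges) <- NULL
      }
    }
  }
  methods::new("HBondGraph", frame = as.integer(frame),
               nodes = as.integer(w$mol), edges = edges)
}
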