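## Four-membered ring enumeration and site filtering.

#' Canonical cyclic order of a 4-cycle
#'
#' Rotates/reflects the member tuple so it starts at the smallest id and its
#' second element is the smaller of the start's two ring neighbours; makes
#' the tuple unique per (vertex set, cyclic pairing).
#'
#' @param v Integer 4-vector in cyclic order.
#' @return Integer 4-vector in canonical cyclic order.
#' @keywords internal
canonicalCycle <- function(v) {
  s <- which.min(v)
  prv <- v[(s - 2L) %% 4L + 1L]
  nxt <- v[s %% 4L + 1L]
  if (nxt <= prv) idx <- (s - 1L + 0:3) %% 4L + 1L
  else idx <- (s - 1L - 0:3) %% 4L + 1L
  v[idx]
}

#' Enumerate simple 4-cycles of a hydrogen-bond graph
#'
#' Returns every simple cycle of exactly four waters, each (vertex set,
#' cyclic pairing) once in canonical order. Chords are permitted: a fully
#' connected 4-clique yields its three distinct cyclic pairings. No
#' planarity filter is applied.
#'
#' @param graph An [HBondGraph-class] object.
#' @param frames The [WaterFrames-class] the graph was built from (supplies
#'   oxygen coordinates).
#' @return data.frame with one row per ring: `frame`, `m1..m4` (mol ids in
#'   canonical cyclic order), `o1x..o4z` (oxygen coordinates, Angstrom).
#' @export
enumerateRings <- function(graph, frames) {
  nodes <- graph@nodes
  n <- length(nodes)
  empty <- function() {
    out <- data.frame(frame = integer(), m1 = integer(), m2 = integer(),
                      m3 = integer(), m4 = integer())
    for (cc in .ringCoordCols) out[[cc]] <- numeric()
    out
  }
  if (n < 4L || !nrow(graph@edges)) return(empty())
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- matrix(FALSE, n, n)
  ea <- idx[as.character(graph@edges$a)]
  eb <- idx[as.character(graph@edges$b)]
  adj[cbind(ea, eb)] <- TRUE
  adj[cbind(eb, ea)] <- TRUE

  ## A 4-cycle i-j-k-l is found from either diagonal pair {i,k}: collect
  ## over all vertex pairs the 2-subsets of their common neighbours, then
  ## de-duplicate canonically.
  seen <- new.env(hash = TRUE)
  out <- list()
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    cn <- which(adj[i, ] & adj[k, ])
    if (length(cn) < 2L) next
    for (ji in seq_len(length(cn) - 1L)) for (li in (ji + 1L):length(cn)) {
      cyc <- canonicalCycle(c(nodes[i], nodes[cn[ji]],
                              nodes[k], nodes[cn[li]]))
      key <- paste(cyc, collapse = "_")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- cyc
    }
  }
  if (!length(out)) return(empty())
  mem <- do.call(rbind, out)
  mem <- mem[order(mem[, 1L], mem[, 2L], mem[, 3L], mem[, 4L]), ,
             drop = FALSE]
  w <- waters(frames, frame = graph@frame)
  om <- as.matrix(w[, c("ox", "oy", "oz")])
  rownames(om) <- w$mol
  res <- data.frame(frame = rep(graph@frame, nrow(mem)),
                    m1 = mem[, 1L], m2 = mem[, 2L],
                    m3 = mem[, 3L], m4 = mem[, 4L])
  for (j in 1:4) {
    xyz <- om[as.character(mem[, j]), , drop = FALSE]
    res[[paste0("o", j, "x")]] <- xyz[, 1L]
    res[[paste0("o", j, "y")]] <- xyz[, 2L]
    res[[paste0("o", j, "z")]] <- xyz[, 3L]
  }
  rownames(res) <- NULL
  res
}

#' Detect four-membered water rings across frames
#'
#' Runs the hydrogen-bond graph construction and 4-cycle enumeration on
#' every frame, optionally restricted to a binding site, and assigns
#' sequential ring ids.
#'
#' @param frames A [WaterFrames-class] object.
#' @param params [EnergyParameters-class].
#' @param cutoff O-O neighbour cutoff, Angstrom (default 4.5).
#' @param site Optional [SiteDefinition-class]; rings whose oxygen centroid
#'   falls outside are dropped.
#' @return A [RingSet-class] object.
#' @examples
#' site <- plantedSite(center = c(0, 0, 0))
#' wf <- makeFrames(list(site), nFrames = 3, nNoiseWaters = 0, seed = 1)
#' detectRings(wf)
#' @export
detectRings <- function(frames, params = energyParameters(), cutoff = 4.5,
                        site = NULL) {
  res <- vector("list", length(frames@frameIds))
  for (i in seq_along(frames@frameIds)) {
    f <- frames@frameIds[i]
    w <- waters(frames, frame = f)
    if (!nrow(w)) next
    g <- buildHBondGraph(frames, frame = f, params = params,
                         cutoff = cutoff)
    res[[i]] <- enumerateRings(g, frames)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  rs <- if (length(res)) do.call(rbind, res) else enumerateRings(
    methods::new("HBondGraph", frame = 0L, nodes = integer(),
                 edges = data.frame(a = integer(), b = integer(),
                                    energy = numeric())),
    frames)
  rs <- cbind(ring = seq_len(nrow(rs)), rs)
  out <- methods::new("RingSet", rings = as.data.frame(rs),
                      nFrames = length(frames@frameIds))
  if (!is.null(site)) out <- filterSite(out, site)
  out
}

#' Restrict rings to a binding site
#'
#' Keeps rings whose oxygen-coordinate centroid lies within the site radius
#' of the site center (inclusive boundary).
#'
#' @param ringSet A [RingSet-class] object.
#' @param site A [SiteDefinition-class] object.
#' @return A filtered [RingSet-class].
#' @export
filterSite <- function(ringSet, site) {
  r <- ringSet@rings
  if (!nrow(r)) return(ringSet)
  cx <- (r$o1x + r$o2x + r$o3x + r$o4x) / 4
  cy <- (r$o1y + r$o2y + r$o3y + r$o4y) / 4
  cz <- (r$o1z + r$o2z + r$o3z + r$o4z) / 4
  d <- sqrt((cx - site@center[1])^2 + (cy - site@center[2])^2 +
            (cz - site@center[3])^2)
  keep <- d <= site@radius
  methods::new("RingSet", rings = r[keep, , drop = FALSE],
               nFrames = ringSet@nFrames)
}

#' Locate a site center from protein residues
#'
#' Reads a protein PDB and returns the geometric mean of the C-alpha atoms
#' of the selected residues (falling back to all atoms of the selection if
#' no C-alpha is present) as a [SiteDefinition-class]. Typical use: anchor
#' the analysis sphere on a conserved motif such as a kinase DFG region.
#'
#' @param pdbPath Path to a protein PDB file.
#' @param resno Integer vector of residue numbers to select.
#' @param chain Optional chain identifier(s).
#' @param radius Site radius, Angstrom (default 20).
#' @return A [SiteDefinition-class] object.
#' @export
siteCenterFromResidues <- function(pdbPath, resno, chain = NULL,
                                   radius = 20) {
  pdb <- bio3d::read.pdb(pdbPath, verbose = FALSE)
  at <- pdb$atom
  sel <- at$resno %in% resno
  if (!is.null(chain)) sel <- sel & at$chain %in% chain
  if (!any(sel)) {
    avail <- unique(paste0(at$chain, ":", at$resno))
    stop("residue selection matched nothing; available residues: ",
         paste(utils::head(avail, 50L), collapse = ", "),
         if (length(avail) > 50L) ", ..." else "")
  }
  ca <- sel & at$elety == "CA"
  use <- if (any(ca)) ca else sel
  center <- colMeans(at[use, c("x", "y", "z")])
  siteDefinition(center, radius = radius)
}
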