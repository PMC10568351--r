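## Tabular and JSON interchange: screening CSV, ring table, group sidecar.

#' Write the per-pair screening table as CSV
#'
#' Columns `frag_id`, `group_id`, `shape_similarity`, `avg_distance`,
#' `passed`; one row per (fragment, group) pair, header-only when the
#' result is empty.
#'
#' @param result A [ScreenResult-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeScreenTable <- function(result, path) {
  stopifnot(methods::is(result, "ScreenResult"))
  r <- screenRecords(result)
  out <- data.frame(frag_id = r$frag, group_id = r$group,
                    shape_similarity = r$shape_similarity,
                    avg_distance = r$avg_distance, passed = r$passed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the detected-ring table as CSV
#'
#' The interchange format between detection and grouping: `ring_id`,
#' `frame_id`, the four member molecule ids and the twelve oxygen
#' coordinates.
#'
#' @param ringSet A [RingSet-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeRingTable <- function(ringSet, path) {
  r <- ringSet@rings
  out <- cbind(data.frame(ring_id = r$ring, frame_id = r$frame,
                          m1 = r$m1, m2 = r$m2, m3 = r$m3, m4 = r$m4),
               r[, .ringCoordCols])
  attr(out, "nFrames") <- ringSet@nFrames
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ring table written by [writeRingTable()]
#'
#' @param path CSV file path.
#' @param nFrames Number of frames the detection ran over (stored in the
#'   pipeline sidecar; needed for occupancy).
#' @return A [RingSet-class] object.
#' @export
readRingTable <- function(path, nFrames) {
  d <- utils::read.csv(path)
  names(d)[names(d) == "ring_id"] <- "ring"
  names(d)[names(d) == "frame_id"] <- "frame"
  methods::new("RingSet", rings = d, nFrames = as.integer(nFrames))
}

#' Write the grouped-network JSON sidecar
#'
#' Full-fidelity description of a [TwnGroups-class] object: per group the
#' member count, occupancy and four centroids; per member ring its
#' best-fit plane (unit normal + point) and its four slot-assigned
#' oxygens.
#'
#' @param twn A [TwnGroups-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGroupsJSON <- function(twn, path) {
  stopifnot(methods::is(twn, "TwnGroups"))
  payload <- list(
    total_frames = twn@totalFrames,
    groups = lapply(seq_len(nrow(twn@groups)), function(k) {
      g <- twn@groups$group[k]
      list(group_id = g,
           n_rings = twn@groups$nRings[k],
           occupancy = twn@groups$occupancy[k],
           centroids = unname(split(groupCentroids(twn, g),
                                    rep(1:4, 3))),
           planes = {
             pl <- groupPlanes(twn, group = g)
             lapply(seq_len(nrow(pl)), function(j) list(
               ring_id = pl$ring[j],
               normal = c(pl$nx[j], pl$ny[j], pl$nz[j]),
               point = c(pl$px[j], pl$py[j], pl$pz[j])))
           },
           oxygens = {
             ox <- groupOxygens(twn, group = g)
             lapply(seq_len(nrow(ox)), function(j) list(
               ring_id = ox$ring[j], slot = ox$slot[j],
               xyz = c(ox$x[j], ox$y[j], ox$z[j])))
           })
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a grouped-network JSON sidecar
#'
#' @param path JSON file written by [writeGroupsJSON()].
#' @return A [TwnGroups-class] object.
#' @export
readGroupsJSON <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  grows <- list(); orows <- list(); prows <- list()
  for (g in p$groups) {
    ce <- do.call(rbind, lapply(g$centroids, unlist))
    grows[[length(grows) + 1L]] <- data.frame(
      group = g$group_id, nRings = g$n_rings, occupancy = g$occupancy,
      c1x = ce[1, 1], c1y = ce[1, 2], c1z = ce[1, 3],
      c2x = ce[2, 1], c2y = ce[2, 2], c2z = ce[2, 3],
      c3x = ce[3, 1], c3y = ce[3, 2], c3z = ce[3, 3],
      c4x = ce[4, 1], c4y = ce[4, 2], c4z = ce[4, 3])
    for (pl in g$planes)
      prows[[length(prows) + 1L]] <- data.frame(
        group = g$group_id, ring = pl$ring_id,
        nx = pl$normal[[1]], ny = pl$normal[[2]], nz = pl$normal[[3]],
        px = pl$point[[1]], py = pl$point[[2]], pz = pl$point[[3]])
    for (oxe in g$oxygens)
      orows[[length(orows) + 1L]] <- data.frame(
        group = g$group_id, ring = oxe$ring_id, slot = oxe$slot,
        x = oxe$xyz[[1]], y = oxe$xyz[[2]], z = oxe$xyz[[3]])
  }
  methods::new("TwnGroups",
               groups = do.call(rbind, grows),
               oxygens = do.call(rbind, orows),
               planes = do.call(rbind, prows),
               totalFrames = as.integer(p$total_frames))
}
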