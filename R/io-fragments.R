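## Fragment pose input (SDF via ChemmineR, PDB via bio3d) and output.

#' Read fragment poses from SDF or PDB
#'
#' Multi-record SDF input yields one pose per record (parsed with
#' ChemmineR); PDB input yields a single pose of all its atoms. Element
#' symbols are normalised; explicit hydrogens are retained but flagged so
#' downstream scoring can exclude them. A record whose coordinates are all
#' zero in z (a 2D block) is kept with a warning; a record with no usable
#' coordinates is reported and skipped while the remaining records are
#' still returned.
#'
#' @param path An .sdf (multi-record) or .pdb file.
#' @return A [FragmentSet-class] object.
#' @export
readFragments <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file")
  if (grepl("\\.pdb$", path, ignore.case = TRUE))
    return(.readFragmentsPDB(path))
  .readFragmentsSDF(path)
}

## Literal fixed-column V2000 atom-block parse of one raw SDF record:
## the fallback for atoms-only records (e.g. single-atom pseudo-fragments
## with an empty bond block) that ChemmineR's container cannot represent.
.parseV2000Atoms <- function(recLines) {
  if (length(recLines) < 4L) return(NULL)
  nAtoms <- suppressWarnings(as.integer(substr(recLines[4L], 1, 3)))
  if (is.na(nAtoms) || nAtoms < 1L ||
      length(recLines) < 4L + nAtoms) return(NULL)
  al <- recLines[5:(4L + nAtoms)]
  x <- suppressWarnings(as.numeric(substr(al, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(al, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(al, 21, 30)))
  el <- trimws(substr(al, 32, 34))
  if (anyNA(c(x, y, z)) || any(!nzchar(el))) return(NULL)
  data.frame(element = el, x = x, y = y, z = z)
}

.readFragmentsSDF <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (!length(sdfs)) stop("no SDF records parsed from '", path, "'")
  raw <- readLines(path, warn = FALSE)
  recEnds <- c(0L, which(trimws(raw) == "$$$$"))
  atomsList <- list(); src <- character(); bad <- character()
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    id <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
    if (!nzchar(id)) id <- sprintf("record%03d", i)
    id <- make.unique(c(names(src), id))[length(src) + 1L]
    ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
    if (is.null(ab) || !nrow(ab) || ncol(ab) < 3L ||
        anyNA(ab[, 1:3])) {
      fallback <- if (i < length(recEnds))
        .parseV2000Atoms(raw[(recEnds[i] + 1L):recEnds[i + 1L]]) else NULL
      if (is.null(fallback)) {
        bad <- c(bad, sprintf("record %d (%s): no 3D coordinates", i, id))
        next
      }
      ab <- cbind(fallback$x, fallback$y, fallback$z)
      rownames(ab) <- paste0(fallback$element, "_", seq_len(nrow(ab)))
    }
    el <- sub("_.*$", "", rownames(ab))
    if (all(ab[, 3L] == 0))
      warning("record ", i, " (", id, ") looks 2D (all z = 0); retained")
    atomsList[[length(atomsList) + 1L]] <- data.frame(
      frag = id, element = el, x = ab[, 1L], y = ab[, 2L], z = ab[, 3L])
    src[id] <- path
  }
  if (length(bad))
    warning(length(bad), " record(s) skipped: ",
            paste(bad, collapse = "; "))
  if (!length(atomsList))
    stop("no usable fragment records in '", path, "'")
  fragmentSet(do.call(rbind, atomsList), source = src)
}

.readFragmentsPDB <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!nrow(at)) stop("no atoms parsed from '", path, "'")
  el <- at$elesy
  miss <- is.na(el) | !nzchar(trimws(el))
  el[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  fragmentSet(data.frame(frag = id, element = el,
                         x = at$x, y = at$y, z = at$z),
              source = stats::setNames(path, id))
}

#' Write fragment poses as a multi-record V2000 SDF file
#'
#' Atoms only (no bond block): sufficient for shape and centroid scoring,
#' and round-trips through [readFragments()].
#'
#' @param fragments A [FragmentSet-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFragmentsSDF <- function(fragments, path) {
  stopifnot(methods::is(fragments, "FragmentSet"))
  out <- character()
  for (id in fragIds(fragments)) {
    a <- fragAtoms(fragments, frag = id)
    out <- c(out,
      id, "  twnscreen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              a$x, a$y, a$z, a$element),
      "M  END", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}
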