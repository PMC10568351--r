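## PDB input/output for water frames and grouped-network pseudo-atoms.
##
## Frames may arrive as one multi-MODEL file or as one file per frame with
## varying water counts per block, which is why MODEL blocks are parsed
## record-wise here rather than through a fixed-shape trajectory container.

.waterResnames <- c("HOH", "SOL", "WAT", "TIP3")

## Parse one PDB block (character vector of lines) into a water table.
## Returns list(waters = data.frame or NULL, dropped = count,
## reasons = character).
.parseWaterBlock <- function(lines, frame, residueNames) {
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec))
    return(list(waters = NULL, dropped = 0L, reasons = character()))
  resn <- trimws(substr(rec, 18, 21))
  sel <- resn %in% residueNames
  rec <- rec[sel]
  if (!length(rec))
    return(list(waters = NULL, dropped = 0L, reasons = character()))
  name <- trimws(substr(rec, 13, 16))
  chain <- substr(rec, 22, 22)
  resno <- suppressWarnings(as.integer(substr(rec, 23, 26)))
  icode <- substr(rec, 27, 27)
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  elem <- trimws(substr(rec, 77, 78))
  ## Element: explicit column if present, else first letter of the atom
  ## name after stripping digits (handles OW/HW1/OH2/1H style names).
  guess <- toupper(substr(gsub("[0-9 ]", "", name), 1, 1))
  elem <- ifelse(elem %in% c("O", "H"), elem, guess)
  key <- paste(chain, resno, icode, sep = "|")
  rows <- list(); dropped <- 0L; reasons <- character()
  for (k in unique(key)) {
    i <- which(key == k)
    oi <- i[elem[i] == "O"]
    hi <- i[elem[i] == "H"]
    if (length(oi) != 1L || length(hi) != 2L) {
      dropped <- dropped + 1L
      reasons <- c(reasons, sprintf(
        "residue %s: %d O and %d H records (need 1 and 2)",
        k, length(oi), length(hi)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frame = frame, mol = resno[oi],
      ox = x[oi], oy = y[oi], oz = z[oi],
      h1x = x[hi[1]], h1y = y[hi[1]], h1z = z[hi[1]],
      h2x = x[hi[2]], h2y = y[hi[2]], h2z = z[hi[2]])
  }
  w <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(w) && anyDuplicated(w$mol)) w$mol <- seq_len(nrow(w))
  list(waters = w, dropped = dropped, reasons = reasons)
}

.parseBox <- function(lines) {
  cl <- lines[startsWith(lines, "CRYST1")]
  if (!length(cl)) return(NULL)
  as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
               substr(cl[1], 25, 33)))
}

#' Read explicit-water frames from PDB input
#'
#' Accepts either a single PDB file whose MODEL blocks are successive
#' snapshots, or a directory of per-frame PDB files (taken in lexicographic
#' order). Waters are identified by residue name (default whitelist HOH,
#' SOL, WAT, TIP3); a residue that does not contribute exactly one O and
#' two H records is skipped with a warning reporting the drop count and
#' reasons. Frame ids are assigned in encounter order starting at 0. A
#' CRYST1 record, when present, is stored as the frame's periodic box (no
#' wrapping is applied; see the package vignette).
#'
#' @param path A PDB file or a directory of PDB files.
#' @param format "auto" (default: directory implies `pdb_files`),
#'   "pdb_models" or "pdb_files".
#' @param residueNames Water residue-name whitelist.
#' @return A [WaterFrames-class] object.
#' @export
readWaterFrames <- function(path, format = c("auto", "pdb_models",
                                             "pdb_files"),
                            residueNames = .waterResnames) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file or directory")
  isDir <- dir.exists(path)
  if (format == "auto") format <- if (isDir) "pdb_files" else "pdb_models"
  files <- if (format == "pdb_files") {
    if (!isDir) path else {
      f <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
      if (!length(f)) stop("no .pdb files found in '", path, "'")
      f
    }
  } else path

  frames <- list(); boxes <- list(); frame <- 0L
  droppedTotal <- 0L; reasonsAll <- character()
  for (fp in files) {
    lines <- tryCatch(readLines(fp, warn = FALSE), error = function(e)
      stop("cannot read '", fp, "': ", conditionMessage(e)))
    box <- .parseBox(lines)
    starts <- which(startsWith(lines, "MODEL"))
    blocks <- if (length(starts) && format == "pdb_models") {
      ends <- c(starts[-1L] - 1L, length(lines))
      lapply(seq_along(starts), function(i) lines[starts[i]:ends[i]])
    } else list(lines)
    for (bl in blocks) {
      parsed <- .parseWaterBlock(bl, frame, residueNames)
      droppedTotal <- droppedTotal + parsed$dropped
      reasonsAll <- c(reasonsAll, parsed$reasons)
      frames[[frame + 1L]] <- parsed$waters
      boxes[[frame + 1L]] <- box
      frame <- frame + 1L
    }
  }
  if (droppedTotal > 0L)
    warning(droppedTotal, " incomplete water(s) skipped: ",
            paste(utils::head(reasonsAll, 5L), collapse = "; "),
            if (length(reasonsAll) > 5L) "; ..." else "")
  waters <- do.call(rbind, frames[!vapply(frames, is.null, logical(1))])
  if (is.null(waters) || !nrow(waters))
    stop("no waters parsed from '", path, "'")
  waterFrames(waters, boxes = boxes, frameIds = seq_len(frame) - 1L)
}

.pdbAtomLine <- function(serial, name, resn, resno, xyz, occ, b, elem) {
  sprintf("HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name, resn, "A", resno %% 10000L,
          xyz[1], xyz[2], xyz[3], occ, b, elem)
}

#' Write water frames as a multi-MODEL PDB file
#'
#' One MODEL block per frame; each water is three HETATM records (O, H1,
#' H2) of residue HOH with the molecule id as residue number. Coordinates
#' are written at standard PDB precision (3 decimals).
#'
#' @param frames A [WaterFrames-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeWaterFramesPDB <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  out <- character()
  for (i in seq_along(frames@frameIds)) {
    f <- frames@frameIds[i]
    box <- frames@boxes[[i]]
    if (!is.null(box))
      out <- c(out, sprintf(
        "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
        box[1], box[2], box[3]))
    out <- c(out, sprintf("MODEL %8d", i))
    w <- waters(frames, frame = f)
    serial <- 1L
    for (k in seq_len(nrow(w))) {
      out <- c(out,
        .pdbAtomLine(serial, "O", "HOH", w$mol[k],
                     c(w$ox[k], w$oy[k], w$oz[k]), 1, 0, "O"),
        .pdbAtomLine(serial + 1L, "H1", "HOH", w$mol[k],
                     c(w$h1x[k], w$h1y[k], w$h1z[k]), 1, 0, "H"),
        .pdbAtomLine(serial + 2L, "H2", "HOH", w$mol[k],
                     c(w$h2x[k], w$h2y[k], w$h2z[k]), 1, 0, "H"))
      serial <- serial + 3L
    }
    out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con)
  invisible(path)
}

#' Write grouped networks as an oxygen-only pseudo-atom PDB
#'
#' One residue per group: every member-ring oxygen as a HETATM record of
#' residue TWN, followed by the four cluster centroids as residue CEN. The
#' occupancy column carries the group size normalised by the largest
#' group, so density is visible when the file is coloured by occupancy.
#'
#' @param twn A non-empty [TwnGroups-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeGroupedTwnPDB <- function(twn, path) {
  stopifnot(methods::is(twn, "TwnGroups"))
  if (!nrow(twn@groups)) stop("no groups to write")
  biggest <- max(twn@groups$nRings)
  out <- character()
  serial <- 1L
  for (k in seq_len(nrow(twn@groups))) {
    g <- twn@groups$group[k]
    occ <- twn@groups$nRings[k] / biggest
    ox <- groupOxygens(twn, group = g)
    for (j in seq_len(nrow(ox))) {
      out <- c(out, .pdbAtomLine(serial, "O", "TWN", g,
                                 c(ox$x[j], ox$y[j], ox$z[j]), occ, 0,
                                 "O"))
      serial <- serial + 1L
    }
    cents <- groupCentroids(twn, group = g)
    for (s in 1:4) {
      out <- c(out, .pdbAtomLine(serial, "O", "CEN", g, cents[s, ], occ,
                                 0, "O"))
      serial <- serial + 1L
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
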