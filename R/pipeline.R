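## End-to-end pipeline: configuration, gridbox (detect + group), analysis
## (screen), automation (both), and synthetic fixture generation. The
## command-line front end in exec/twnscreen is a thin wrapper over these.

.defaultConfig <- function() {
  list(
    paths = list(frames = NULL, fragments = NULL, protein = NULL,
                 outdir = "twnscreen_out"),
    site = list(center = NULL, resno = NULL, chain = NULL, radius = 20),
    energy = list(threshold = -2.25, cutoff = 4.5, ke2 = 332.0636),
    grouping = list(spacing = 0.5, secondary_radius = 1.0,
                    dbscan_eps = 1.0, dbscan_min_samples = 1),
    screening = list(s_min = 0.6, d_max = 0.5),
    synth = list(n_frames = 50, n_noise = 30, jitter = 0.1,
                 occupancy = 1.0),
    seed = 1L)
}

#' Assemble a pipeline run configuration
#'
#' Defaults (site radius 20 A; energy threshold -2.25 kcal/mol, neighbour
#' cutoff 4.5 A, Coulomb constant 332.0636; grid spacing 0.5 A, secondary
#' radius 1.0 A, DBSCAN eps 1.0 A / min samples 1; screening thresholds
#' S >= 0.6, D <= 0.5 A) are overridden first by a YAML config file, then
#' by the `overrides` list (flags win over file values).
#'
#' @param file Optional YAML configuration file.
#' @param overrides Optional nested list of overrides, e.g.
#'   `list(screening = list(s_min = 0.7))`.
#' @return A nested configuration list of class `twnRunConfig`.
#' @export
runConfig <- function(file = NULL, overrides = list()) {
  cfg <- .defaultConfig()
  merge2 <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge2(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- merge2(cfg, yaml::read_yaml(file))
  }
  cfg <- merge2(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "twnRunConfig")
}

.logOpen <- function(cfg, fresh = FALSE) {
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$paths$outdir, "run.log")
  if (fresh && file.exists(logPath)) unlink(logPath)
  logPath
}

.logLine <- function(logPath, ...) {
  msg <- paste0(...)
  cat(msg, "\n", sep = "", file = logPath, append = TRUE)
  message(msg)
}

.echoConfig <- function(cfg, logPath) {
  .logLine(logPath, "config:")
  flat <- function(x, prefix = "") {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) flat(v, paste0(prefix, nm, "."))
      else .logLine(logPath, "  ", prefix, nm, ": ",
                    if (is.null(v)) "(unset)" else
                      paste(format(v), collapse = ", "))
    }
  }
  flat(unclass(cfg))
}

.resolveSite <- function(cfg) {
  if (!is.null(cfg$site$center))
    return(siteDefinition(as.numeric(unlist(cfg$site$center)),
                          radius = cfg$site$radius))
  if (!is.null(cfg$site$resno)) {
    if (is.null(cfg$paths$protein))
      stop("site.resno given but paths.protein is unset")
    return(siteCenterFromResidues(cfg$paths$protein,
                                  resno = unlist(cfg$site$resno),
                                  chain = cfg$site$chain,
                                  radius = cfg$site$radius))
  }
  NULL
}

.energyFromConfig <- function(cfg) {
  energyParameters(ke2 = cfg$energy$ke2,
                   hbondThreshold = cfg$energy$threshold)
}

#' Gridbox stage: detect rings and form grouped networks
#'
#' Reads the water frames, detects four-membered rings inside the binding
#' site, groups them, and writes the grouped-network PDB
#' (`grouped_twn.pdb`), the JSON sidecar (`groups.json`), the ring table
#' (`rings.csv`) and a run log with the water/ring/group counts.
#'
#' @param config A `twnRunConfig` list (see [runConfig()]).
#' @return The [TwnGroups-class] result, invisibly.
#' @export
runGridbox <- function(config) {
  logPath <- .logOpen(config)
  .logLine(logPath, "stage: gridbox")
  .echoConfig(config, logPath)
  if (is.null(config$paths$frames))
    stop(errorCondition("paths.frames is unset", class = "twnInputError"))
  frames <- readWaterFrames(config$paths$frames)
  .logLine(logPath, "frames: ", nFrames(frames), "; waters: ",
           nrow(waters(frames)))
  params <- .energyFromConfig(config)
  site <- .resolveSite(config)
  ringsAll <- detectRings(frames, params = params,
                          cutoff = config$energy$cutoff, site = site)
  .logLine(logPath, "rings detected (site-filtered): ", nRings(ringsAll))
  if (!nRings(ringsAll))
    stop(errorCondition(
      paste0("no rings detected (threshold ", config$energy$threshold,
             " kcal/mol, cutoff ", config$energy$cutoff, " A, site ",
             if (is.null(site)) "none" else
               paste0("center ", paste(round(siteCenter(site), 2),
                                       collapse = "/"),
                      " radius ", siteRadius(site), " A"), ")"),
      class = "twnEmptyResult"))
  pg <- primaryGrouping(ringsAll, spacing = config$grouping$spacing)
  .logLine(logPath, "primary groups: ", length(unique(pg@members$group)))
  pg <- clusterCenters(pg, eps = config$grouping$dbscan_eps,
                       minSamples = config$grouping$dbscan_min_samples)
  twn <- secondaryGrouping(pg, radius = config$grouping$secondary_radius,
                           eps = config$grouping$dbscan_eps,
                           minSamples = config$grouping$dbscan_min_samples)
  .logLine(logPath, "final grouped networks: ", nGroups(twn))
  outdir <- config$paths$outdir
  writeRingTable(ringsAll, file.path(outdir, "rings.csv"))
  writeGroupedTwnPDB(twn, file.path(outdir, "grouped_twn.pdb"))
  writeGroupsJSON(twn, file.path(outdir, "groups.json"))
  .logLine(logPath, "gridbox outputs written to ", outdir)
  invisible(twn)
}

#' Analysis stage: screen fragments against grouped networks
#'
#' Loads the grouped-network sidecar written by [runGridbox()] and the
#' fragment poses, scores every (fragment, group) pair, and writes the
#' per-pair table (`screen_pairs.csv`), the per-fragment summary with the
#' thresholds echoed as comment metadata (`screen_summary.csv`) and the
#' threshold-sweep table (`threshold_sweep.csv`).
#'
#' @param config A `twnRunConfig` list (see [runConfig()]).
#' @return The [ScreenResult-class], invisibly.
#' @export
runAnalysis <- function(config) {
  logPath <- .logOpen(config)
  .logLine(logPath, "stage: analysis")
  sidecar <- file.path(config$paths$outdir, "groups.json")
  if (!file.exists(sidecar))
    stop(errorCondition(
      paste0("grouped-network sidecar not found at ", sidecar,
             "; run the gridbox stage first"),
      class = "twnInputError"))
  if (is.null(config$paths$fragments))
    stop(errorCondition("paths.fragments is unset",
                        class = "twnInputError"))
  twn <- readGroupsJSON(sidecar)
  frags <- readFragments(config$paths$fragments)
  .logLine(logPath, "groups: ", nGroups(twn), "; fragments: ",
           length(fragIds(frags)))
  res <- screenFragments(frags, twn, sMin = config$screening$s_min,
                         dMax = config$screening$d_max)
  outdir <- config$paths$outdir
  writeScreenTable(res, file.path(outdir, "screen_pairs.csv"))
  summ <- screenSummary(res)
  sfile <- file.path(outdir, "screen_summary.csv")
  writeLines(c(sprintf("# s_min: %g", config$screening$s_min),
               sprintf("# d_max: %g", config$screening$d_max)), sfile)
  suppressWarnings(utils::write.table(
    summ, sfile, append = TRUE, sep = ",", row.names = FALSE,
    quote = FALSE))
  sweep <- thresholdSweep(res)
  utils::write.csv(sweep, file.path(outdir, "threshold_sweep.csv"),
                   row.names = FALSE, quote = FALSE)
  .logLine(logPath, "fragments screened: ", sum(summ$screened), " of ",
           nrow(summ))
  .logLine(logPath, "analysis outputs written to ", outdir)
  invisible(res)
}

#' Synth stage: write the bundled synthetic demonstration fixture
#'
#' Generates frames from the five demonstration ring sites (see
#' [demoSites()]) and a fragment file containing, per site, one on-site
#' pose (atoms on the ideal ring corners) and one decoy displaced 4
#' Angstrom along the ring normal, plus two disc-scattered poses. Writes
#' `frames.pdb` and `fragments.sdf` into the output directory.
#'
#' @param config A `twnRunConfig` list; `synth$n_frames`, `synth$n_noise`,
#'   `synth$jitter`, `synth$occupancy` and `seed` control the fixture.
#' @return List with the paths written, invisibly.
#' @export
runSynth <- function(config) {
  logPath <- .logOpen(config)
  .logLine(logPath, "stage: synth")
  sites <- demoSites(jitterSigma = config$synth$jitter,
                     occupancyProb = config$synth$occupancy)
  wf <- makeFrames(sites, nFrames = config$synth$n_frames,
                   nNoiseWaters = config$synth$n_noise,
                   seed = config$seed)
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  framesPath <- file.path(outdir, "frames.pdb")
  writeWaterFramesPDB(wf, framesPath)
  atoms <- list()
  for (i in seq_along(sites)) {
    corners <- .siteCorners(sites[[i]])
    atoms[[length(atoms) + 1L]] <- data.frame(
      frag = sprintf("onsite_%d", i), element = "O",
      x = corners[, 1], y = corners[, 2], z = corners[, 3])
    dec <- sweep(corners, 2L, 4 * sites[[i]]@normal, "+")
    atoms[[length(atoms) + 1L]] <- data.frame(
      frag = sprintf("decoy_%d", i), element = "C",
      x = dec[, 1], y = dec[, 2], z = dec[, 3])
  }
  scat <- lapply(1:2, function(k) {
    fs <- makeFragmentAt(sites[[k]]@center, nAtoms = 6L,
                         seed = config$seed + k,
                         fragId = sprintf("scatter_%d", k))
    fragAtoms(fs)[, c("frag", "element", "x", "y", "z")]
  })
  frags <- fragmentSet(do.call(rbind, c(atoms, scat)))
  fragsPath <- file.path(outdir, "fragments.sdf")
  writeFragmentsSDF(frags, fragsPath)
  .logLine(logPath, "fixture: ", nFrames(wf), " frame(s), ",
           length(fragIds(frags)), " fragment pose(s)")
  invisible(list(frames = framesPath, fragments = fragsPath))
}

#' Automation stage: fixture (optional), gridbox and analysis end to end
#'
#' Runs [runSynth()] when `demo = TRUE` (pointing the frame and fragment
#' paths at the generated fixture), then [runGridbox()] and
#' [runAnalysis()], sharing one log file in the output directory.
#'
#' @param config A `twnRunConfig` list (see [runConfig()]).
#' @param demo Generate and use the bundled synthetic fixture.
#' @param dryRun Print the resolved configuration and planned stages
#'   without computing.
#' @return The [ScreenResult-class], invisibly (`NULL` on a dry run).
#' @export
runAutomation <- function(config, demo = FALSE, dryRun = FALSE) {
  if (dryRun) {
    logPath <- .logOpen(config, fresh = TRUE)
    .logLine(logPath, "dry run: stages ",
             if (demo) "synth, " else "", "gridbox, analysis")
    .echoConfig(config, logPath)
    return(invisible(NULL))
  }
  .logOpen(config, fresh = TRUE)
  if (demo) {
    paths <- runSynth(config)
    config$paths$frames <- paths$frames
    config$paths$fragments <- paths$fragments
    if (is.null(config$site$center) && is.null(config$site$resno))
      config$site$center <- c(0, 0, 2)
  }
  runGridbox(config)
  runAnalysis(config)
}
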