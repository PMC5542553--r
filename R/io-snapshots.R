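## Snapshot-series persistence: a plain-text directory store (JSON manifest +
## CSV tables, numbers written with 17 significant digits so doubles
## round-trip exactly), plus per-frame XYZ and legacy-ASCII VTK exports.

.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.writeTable <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- .fmtNum(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a snapshot series to a directory store
#'
#' Layout: `meta.json` (scenario, ledger, parameters, domain),
#' `frames.csv` (per-frame times and summary metrics),
#' `events.csv`, and one `agents_NNNNNN.csv` per frame. Everything is plain
#' text; writing, reading and re-writing produces byte-identical files.
#'
#' @param series a [SnapshotSeries-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeSnapshotSeries <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paramList <- lapply(stats::setNames(names(.PARAM_KEYS), names(.PARAM_KEYS)),
                      function(k) slot(series@params, .PARAM_KEYS[[k]]))
  domList <- lapply(stats::setNames(names(.DOMAIN_KEYS), names(.DOMAIN_KEYS)),
                    function(k) slot(series@domain, .DOMAIN_KEYS[[k]]))
  meta <- list(scenario = series@scenarioName,
               nFrames = length(series@frames),
               ledger = series@ledger,
               parameters = paramList, domain = domList)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "meta.json"))
  fr <- do.call(rbind, lapply(seq_along(series@frames), function(i) {
    f <- series@frames[[i]]
    m <- f$metrics
    data.frame(frame = i, time = f$time, Tstar = f$Tstar, Tss = f$Tss,
               meanHeight = m$meanHeight, maxHeight = m$maxHeight,
               roughness = m$roughness, porosity = m$porosity,
               bacteria = m$bacteria, EPS = m$EPS, inert = m$inert,
               activeLayer = m$activeLayer, nAgents = m$nAgents,
               totalMass = m$totalMass, volumeFrac = m$volumeFrac,
               pressure = m$pressure, phase = m$phase)
  }))
  .writeTable(fr, file.path(dir, "frames.csv"))
  .writeTable(series@events, file.path(dir, "events.csv"))
  for (i in seq_along(series@frames)) {
    .writeTable(series@frames[[i]]$agents,
                file.path(dir, sprintf("agents_%06d.csv", i)))
  }
  invisible(dir)
}

#' Read a snapshot series from a directory store
#'
#' @param dir directory written by [writeSnapshotSeries()]
#' @return a [SnapshotSeries-class]
#' @export
readSnapshotSeries <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("not a snapshot store (missing meta.json): ", dir)
  meta <- jsonlite::fromJSON(metaPath, simplifyVector = TRUE)
  pargs <- list()
  for (k in names(meta$parameters)) pargs[[.PARAM_KEYS[[k]]]] <- meta$parameters[[k]]
  params <- do.call(bfParams, pargs)
  dargs <- list()
  for (k in names(meta$domain)) dargs[[.DOMAIN_KEYS[[k]]]] <- meta$domain[[k]]
  domain <- do.call(bfDomain, dargs)
  fr <- utils::read.csv(file.path(dir, "frames.csv"),
                        stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(type = "character"))
  if (nrow(events) == 0) events <- .emptyRunEvents()
  frames <- lapply(seq_len(nrow(fr)), function(i) {
    a <- utils::read.csv(file.path(dir, sprintf("agents_%06d.csv", i)),
                         stringsAsFactors = FALSE)
    if (nrow(a) && !file.exists(file.path(dir, sprintf("agents_%06d.csv", i))))
      stop("missing agents table for frame ", i)
    m <- as.list(fr[i, !(names(fr) %in% c("frame", "time", "Tstar", "Tss"))])
    list(time = fr$time[i], Tstar = fr$Tstar[i], Tss = fr$Tss[i],
         agents = a, metrics = m)
  })
  methods::new("SnapshotSeries", frames = frames, events = events,
               ledger = meta$ledger, params = params, domain = domain,
               scenarioName = meta$scenario)
}

#' Export a snapshot series as XYZ frames
#'
#' Extended XYZ: per frame, a count line, a comment with the time stamp,
#' then one `group x y z radius id` row per agent. Readable by OVITO/VMD.
#'
#' @param series a [SnapshotSeries-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeXYZ <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in series@frames) {
    a <- f$agents
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("time=%.17g", f$time), con)
    if (nrow(a))
      writeLines(sprintf("%s %.8g %.8g %.8g %.8g %d",
                         a$group, a$x, a$y, a$z, a$radius, a$id), con)
  }
  invisible(path)
}

#' Export a solute field as a legacy-ASCII VTK structured-points file
#'
#' Scalars live at voxel centres; dimensions equal the grid size.
#'
#' @param field 3-D concentration array (or a [SoluteFields-class] plus
#'   `solute` name)
#' @param domain a [BfDomain-class]
#' @param path output file
#' @param solute field name when a [SoluteFields-class] is given
#' @param name scalar name written to the file
#' @return `path`, invisibly
#' @export
writeSoluteVTK <- function(field, domain, path, solute = "S_S",
                           name = solute) {
  if (is(field, "SoluteFields")) {
    domain <- field@domain
    field <- field@fields[[solute]]
  }
  d <- dim(field)
  hx <- domain@Lx / domain@Nx
  hy <- domain@Ly / domain@Ny
  hz <- domain@Lz / domain@Nz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "biofilmDEM solute field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", hx / 2, hy / 2, hz / 2),
               sprintf("SPACING %g %g %g", hx, hy, hz),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.8g", as.vector(field)), con)
  invisible(path)
}
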