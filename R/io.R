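# Readers and writers: dwell CSVs with JSON sidecars, XYZ polymer
# trajectories, TIFF kymographs with a YAML manifest, and run manifests.
# Every writer's output round-trips through its reader.

#' Write / read dwell samples as CSV with a JSON sidecar
#'
#' The CSV has columns `id` and `dwell_seconds`; provenance (label, frame
#' time, generating rates, seed, package version) goes into
#' `<path>.json`.
#'
#' @param sample a [DwellSample-class].
#' @param path CSV path.
#' @param rates optional generating [KineticRates-class] recorded in the
#'   sidecar.
#' @param seed optional seed recorded in the sidecar.
#' @param model optional model tag recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
writeDwellCsv <- function(sample, path, rates = NULL, seed = NULL,
                          model = NULL) {
  df <- data.frame(id = seq_along(sample@times),
                   dwell_seconds = sample@times)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(label = sample@label, frameTime = sample@frameTime,
               seed = seed, model = model,
               package = as.character(packageVersion("ParBspread")))
  if (!is.null(rates))
    side$rates <- list(kCtp = rates@kCtp, kOff = rates@kOff,
                       kBl = rates@kBl)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null", digits = NA)
  invisible(path)
}

#' @rdname writeDwellCsv
#' @return `readDwellCsv`: a [DwellSample-class].
#' @export
readDwellCsv <- function(path) {
  df <- read.csv(path)
  if (!all(c("id", "dwell_seconds") %in% names(df)))
    stop("expected columns id, dwell_seconds in ", path, call. = FALSE)
  label <- ""
  ft <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    if (!is.null(side$label)) label <- side$label
    if (is.numeric(side$frameTime) && !is.na(side$frameTime))
      ft <- as.numeric(side$frameTime)
  }
  dwellSample(df$dwell_seconds, label = label, frameTime = ft)
}

#' Write / read polymer trajectories as XYZ
#'
#' One XYZ record per sampled frame; the atom-name column carries the bead
#' role (`P` plain, `S` parS, `R` roadblock).
#'
#' @param trajectory nBeads x 3 x nFrames array (sigma units).
#' @param roles character vector of bead roles.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeXyz <- function(trajectory, roles, path) {
  codes <- c(plain = "P", parS = "S", roadblock = "R")[roles]
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(trajectory)[1]
  for (f in seq_len(dim(trajectory)[3])) {
    xyz <- trajectory[, , f]
    writeLines(c(as.character(n), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", codes, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname writeXyz
#' @return `readXyz`: list with `trajectory` (array) and `roles`.
#' @export
readXyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  rec <- n + 2
  nFrames <- length(lines) %/% rec
  traj <- array(NA_real_, c(n, 3, nFrames))
  roles <- NULL
  for (f in seq_len(nFrames)) {
    body <- lines[((f - 1) * rec + 3):((f - 1) * rec + 2 + n)]
    parts <- do.call(rbind, strsplit(body, " ", fixed = TRUE))
    if (f == 1)
      roles <- c(P = "plain", S = "parS", R = "roadblock")[parts[, 1]]
    traj[, , f] <- apply(parts[, 2:4], 2, as.numeric)
  }
  list(trajectory = traj, roles = unname(roles))
}

#' Write / read kymographs as TIFF plus a YAML manifest
#'
#' Each channel goes to `<base>_<channel>.tif` (32-bit float, scaled to
#' `[0, 1]`; the scale factor is recorded in the manifest
#' `<base>.yaml` together with the calibration).
#'
#' @param k a [Kymograph-class].
#' @param dir output directory (created if needed).
#' @param base file base name.
#' @return the manifest path, invisibly.
#' @export
writeKymographTiff <- function(k, dir, base = "kymo") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scales <- list()
  files <- list()
  for (nm in names(k@channels)) {
    m <- k@channels[[nm]]
    hi <- max(m, 1e-12)
    fn <- sprintf("%s_%s.tif", base, nm)
    tiff::writeTIFF(m / hi, file.path(dir, fn), bits.per.sample = 32L)
    scales[[nm]] <- hi
    files[[nm]] <- fn
  }
  manifest <- list(channels = files, scales = scales,
                   nmPerPixel = k@nmPerPixel, secPerFrame = k@secPerFrame)
  mp <- file.path(dir, paste0(base, ".yaml"))
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}

#' @rdname writeKymographTiff
#' @param manifestPath path to the YAML manifest written by
#'   `writeKymographTiff`.
#' @return `readKymographTiff`: a [Kymograph-class].
#' @export
readKymographTiff <- function(manifestPath) {
  man <- yaml::read_yaml(manifestPath)
  dir <- dirname(manifestPath)
  ch <- lapply(names(man$channels), function(nm) {
    m <- tiff::readTIFF(file.path(dir, man$channels[[nm]]))
    m * man$scales[[nm]]
  })
  names(ch) <- names(man$channels)
  kymograph(ch, man$nmPerPixel, man$secPerFrame)
}

#' Write a run manifest
#'
#' JSON manifest recording the configuration, seeds and package version of
#' a run; deliberately timestamp-free so identical runs produce identical
#' manifests.
#'
#' @param path output JSON path.
#' @param config named list of run parameters (must include any seeds).
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, config) {
  jsonlite::write_json(
    list(package = "ParBspread",
         version = as.character(packageVersion("ParBspread")),
         config = config),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
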