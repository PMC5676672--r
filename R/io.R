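## Matrix and configuration I/O. Two matrix formats round-trip exactly:
## a CSV with a commented metadata header (portable, ~15 significant
## digits) and a raw little-endian binary container with a JSON sidecar
## (bit-identical).

.CSV_KEYS <- c("fast_dt_ns", "slow_fs_hz", "axis_type", "range_axis_m")

#' Write an EchoMatrix
#'
#' \code{format = "csv"} writes a plain-text file whose first lines are
#' \code{# key: value} metadata (fast-time step, slow-time rate, axis
#' type, range axis) followed by the sample rows; values survive a round
#' trip to about 15 significant digits. \code{format = "binary"} writes
#' the samples as little-endian doubles in column-major order next to a
#' \code{<path>.json} metadata sidecar; the round trip is bit-identical.
#'
#' @param m an \linkS4class{EchoMatrix}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"binary"}.
#' @return \code{path}, invisibly.
#' @export
writeEchoMatrix <- function(m, path, format = c("csv", "binary")) {
  format <- match.arg(format)
  if (format == "csv") {
    hdr <- c(
      "# bioradar_echo_matrix: v1",
      sprintf("# fast_dt_ns: %.17g", m@fastDtNs),
      sprintf("# slow_fs_hz: %.17g", m@slowFsHz),
      sprintf("# axis_type: %s", m@axisType),
      paste0("# range_axis_m: ",
             paste(sprintf("%.17g", m@rangeAxisM), collapse = " "))
    )
    writeLines(hdr, path)
    data.table::fwrite(data.table::as.data.table(m@data), path,
                       append = TRUE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    ## numeric metadata live in the double stream itself so the round trip
    ## is bit-identical: [fast_dt_ns, slow_fs_hz, range axis, samples]
    writeBin(c(m@fastDtNs, m@slowFsHz, m@rangeAxisM, as.numeric(m@data)),
             con, size = 8L, endian = "little")
    meta <- list(format = "bioradar_echo_matrix_bin", version = 1L,
                 nrow = nrow(m@data), ncol = ncol(m@data),
                 storage = "double_le_header_axis_then_column_major",
                 axis_type = m@axisType)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an EchoMatrix
#'
#' @param path file written by \code{\link{writeEchoMatrix}} (for
#'   \code{"binary"}, the data file; the \code{.json} sidecar must sit
#'   next to it).
#' @param format \code{"csv"} or \code{"binary"}.
#' @return An \linkS4class{EchoMatrix}.
#' @export
readEchoMatrix <- function(path, format = c("csv", "binary")) {
  format <- match.arg(format)
  if (format == "csv") {
    hdr <- readLines(path, n = 5L)
    if (!length(hdr) || !startsWith(hdr[1L], "# bioradar_echo_matrix"))
      stop("not a bioradar echo-matrix CSV: ", path, call. = FALSE)
    meta <- list()
    for (line in hdr[-1L]) {
      kv <- regmatches(line, regexec("^# ([a-z_]+): (.*)$", line))[[1L]]
      if (length(kv) == 3L) meta[[kv[2L]]] <- kv[3L]
    }
    missing <- setdiff(.CSV_KEYS, names(meta))
    if (length(missing))
      stop("echo-matrix CSV header missing key(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    data <- as.matrix(data.table::fread(path, skip = 5L, header = FALSE))
    dimnames(data) <- NULL
    axis <- as.numeric(strsplit(meta$range_axis_m, " ", fixed = TRUE)[[1L]])
    if (length(axis) != nrow(data))
      stop(sprintf("range axis length %d does not match %d data rows",
                   length(axis), nrow(data)), call. = FALSE)
    echoMatrix(data, fastDtNs = as.numeric(meta$fast_dt_ns),
               slowFsHz = as.numeric(meta$slow_fs_hz),
               rangeAxisM = axis, axisType = meta$axis_type)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("missing metadata sidecar: ", sidecar, call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    need <- c("nrow", "ncol", "axis_type")
    missing <- setdiff(need, names(meta))
    if (length(missing))
      stop("sidecar missing key(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    n <- 2L + meta$nrow + meta$nrow * meta$ncol
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, what = "numeric", n = n, size = 8L, endian = "little")
    if (length(v) != n)
      stop(sprintf("binary file holds %d doubles, sidecar promises %d",
                   length(v), n), call. = FALSE)
    axis <- v[3:(2L + meta$nrow)]
    echoMatrix(matrix(v[-seq_len(2L + meta$nrow)], meta$nrow, meta$ncol),
               fastDtNs = v[1L], slowFsHz = v[2L],
               rangeAxisM = axis, axisType = meta$axis_type)
  }
}

.targetToList <- function(t) {
  list(range_m = t@rangeM, angle_deg = t@angleDeg,
       resp_freq_hz = t@respFreqHz, resp_amp = t@respAmp,
       body_thickness_m = t@bodyThicknessM, phase_rad = t@phaseRad)
}

.listToTarget <- function(l) {
  targetSpec(rangeM = l$range_m,
             angleDeg = if (is.null(l$angle_deg)) 0 else l$angle_deg,
             respFreqHz = if (is.null(l$resp_freq_hz)) 0.25 else l$resp_freq_hz,
             respAmp = if (is.null(l$resp_amp)) 1 else l$resp_amp,
             bodyThicknessM = if (is.null(l$body_thickness_m)) 0.4
                              else l$body_thickness_m,
             phaseRad = if (is.null(l$phase_rad)) 0 else l$phase_rad)
}

.runConfigToList <- function(cfg) {
  sc <- cfg@scene
  list(
    scene = list(
      targets = lapply(sc@targets, .targetToList),
      n_fast = sc@nFast, fast_window_ns = sc@fastWindowNs,
      slow_fs_hz = sc@slowFsHz, duration_s = sc@durationS,
      wall_range_m = sc@wallRangeM, wall_amp = sc@wallAmp,
      noise_sigma = sc@noiseSigma,
      shadow_half_angle_deg = sc@shadowHalfAngleDeg,
      shadow_atten = sc@shadowAtten, trail_length_m = sc@trailLengthM,
      trail_amp_frac = sc@trailAmpFrac, trail_gap_m = sc@trailGapM,
      seed = sc@seed),
    preprocess = list(
      n_range_bins = cfg@preprocess@nRangeBins,
      clutter_window = cfg@preprocess@clutterWindow,
      lp_cutoff_hz = cfg@preprocess@lpCutoffHz,
      lp_order = cfg@preprocess@lpOrder),
    autocorr = list(
      estimator = cfg@autocorr@estimator,
      max_lag = if (is.na(cfg@autocorr@maxLag)) NULL else cfg@autocorr@maxLag,
      normalize = cfg@autocorr@normalize),
    wavelet = list(
      wavelet_name = cfg@wavelet@waveletName,
      n_levels = cfg@wavelet@nLevels,
      window_len = if (is.na(cfg@wavelet@windowLen)) NULL
                   else cfg@wavelet@windowLen,
      energy_mode = cfg@wavelet@energyMode,
      window_combine = cfg@wavelet@windowCombine),
    detection = list(
      blind_range_m = cfg@detection@blindRangeM, pit_k = cfg@detection@pitK,
      min_pit_width_m = cfg@detection@minPitWidthM,
      max_pit_width_m = cfg@detection@maxPitWidthM,
      ghost_window_m = cfg@detection@ghostWindowM)
  )
}

.get <- function(l, key, default) if (is.null(l[[key]])) default else l[[key]]

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to the package defaults; the assembled
#' \linkS4class{RunConfig} is validated for cross-field consistency
#' before it is returned.
#'
#' @param path YAML file with (optional) sections \code{scene},
#'   \code{preprocess}, \code{autocorr}, \code{wavelet}, \code{detection}.
#' @return A validated \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  s <- .get(y, "scene", list())
  d <- sceneConfig()   # defaults
  scene <- sceneConfig(
    targets = lapply(.get(s, "targets", list()), .listToTarget),
    nFast = .get(s, "n_fast", d@nFast),
    fastWindowNs = .get(s, "fast_window_ns", d@fastWindowNs),
    slowFsHz = .get(s, "slow_fs_hz", d@slowFsHz),
    durationS = .get(s, "duration_s", d@durationS),
    wallRangeM = unlist(.get(s, "wall_range_m", d@wallRangeM)),
    wallAmp = .get(s, "wall_amp", d@wallAmp),
    noiseSigma = .get(s, "noise_sigma", d@noiseSigma),
    shadowHalfAngleDeg = .get(s, "shadow_half_angle_deg", d@shadowHalfAngleDeg),
    shadowAtten = .get(s, "shadow_atten", d@shadowAtten),
    trailLengthM = .get(s, "trail_length_m", d@trailLengthM),
    trailAmpFrac = .get(s, "trail_amp_frac", d@trailAmpFrac),
    trailGapM = .get(s, "trail_gap_m", d@trailGapM),
    seed = .get(s, "seed", d@seed))
  p <- .get(y, "preprocess", list())
  a <- .get(y, "autocorr", list())
  w <- .get(y, "wavelet", list())
  dt <- .get(y, "detection", list())
  pd <- preprocessParams(); ad <- autocorrParams()
  wd <- waveletParams(); dd <- detectionParams()
  cfg <- runConfig(
    scene = scene,
    preprocess = preprocessParams(
      nRangeBins = .get(p, "n_range_bins", pd@nRangeBins),
      clutterWindow = .get(p, "clutter_window", pd@clutterWindow),
      lpCutoffHz = .get(p, "lp_cutoff_hz", pd@lpCutoffHz),
      lpOrder = .get(p, "lp_order", pd@lpOrder)),
    autocorr = autocorrParams(
      estimator = .get(a, "estimator", ad@estimator),
      maxLag = .get(a, "max_lag", ad@maxLag),
      normalize = .get(a, "normalize", ad@normalize)),
    wavelet = waveletParams(
      waveletName = .get(w, "wavelet_name", wd@waveletName),
      nLevels = .get(w, "n_levels", wd@nLevels),
      windowLen = .get(w, "window_len", wd@windowLen),
      energyMode = .get(w, "energy_mode", wd@energyMode),
      windowCombine = .get(w, "window_combine", wd@windowCombine)),
    detection = detectionParams(
      blindRangeM = .get(dt, "blind_range_m", dd@blindRangeM),
      pitK = .get(dt, "pit_k", dd@pitK),
      minPitWidthM = .get(dt, "min_pit_width_m", dd@minPitWidthM),
      maxPitWidthM = .get(dt, "max_pit_width_m", dd@maxPitWidthM),
      ghostWindowM = .get(dt, "ghost_window_m", dd@ghostWindowM)))
  validObject(cfg)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg a \linkS4class{RunConfig}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(.runConfigToList(cfg), path)
  invisible(path)
}
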