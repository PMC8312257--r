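# Harmonization: align every stream to the time-domain DerivedTime grid,
# build the combined data table with explicit missingness, and persist the
# compact per-stream store.

.STORE_VERSION <- 1L

#' Build the unified DerivedTime grid
#'
#' The time-domain stream (highest rate) owns the grid. The grid runs in
#' exact 1000/fs ms steps on the time-domain phase, extended before/after
#' the time-domain span so that every sample of every stream has a grid
#' point within half a step.
#'
#' @param seriesList named list of [DerivedTimeSeries-class]; the grid
#'   owner is "td" when present, otherwise the highest-rate stream (with a
#'   warning).
#' @return List: `tRef`, `step` (ms), `k0` (index offset of the first grid
#'   point), `times` (numeric vector of grid times), `fs`.
#' @export
buildUnifiedGrid <- function(seriesList) {
  seriesList <- seriesList[vapply(seriesList, length, integer(1)) > 0]
  if (!length(seriesList)) stop("no non-empty streams", call. = FALSE)
  if ("td" %in% names(seriesList)) {
    owner <- seriesList[["td"]]
  } else {
    rates <- vapply(seriesList, streamFs, numeric(1))
    owner <- seriesList[[which.max(rates)]]
    warning("no time-domain stream; using highest-rate stream ('",
            names(seriesList)[which.max(rates)], "') as grid owner")
  }
  tRef <- owner@tRef
  step <- 1000 / owner@fs
  ks <- unlist(lapply(seriesList, function(s) {
    rng <- range(s@derivedTime)
    roundHalfDown((rng - tRef) / step)
  }))
  k0 <- min(ks)
  k1 <- max(ks)
  list(tRef = tRef, step = step, k0 = k0,
       times = tRef + (k0:k1) * step, fs = owner@fs)
}

#' Align one stream's samples onto the unified grid
#'
#' Each sample is assigned to the nearest grid time (ties toward the
#' earlier point); unassigned rows stay missing. Two samples of one
#' stream competing for a single grid point is an error — it cannot occur
#' while the stream's rate does not exceed the grid rate.
#'
#' @param series A [DerivedTimeSeries-class].
#' @param grid from [buildUnifiedGrid()].
#' @param streamName for error messages.
#' @return Numeric matrix (grid rows x stream channels) with NA where the
#'   stream has no sample.
#' @export
alignStreamToGrid <- function(series, grid, streamName = "stream") {
  nGrid <- length(grid$times)
  out <- matrix(NA_real_, nGrid, ncol(series@samples))
  colnames(out) <- colnames(series@samples)
  if (!length(series@derivedTime)) return(out)
  k <- roundHalfDown((series@derivedTime - grid$tRef) / grid$step)
  idx <- k - grid$k0 + 1
  if (anyDuplicated(idx)) {
    d <- idx[duplicated(idx)][1]
    stop(sprintf(
      "alignment error: stream '%s' has two samples nearest grid time %.3f",
      streamName, grid$times[d]), call. = FALSE)
  }
  if (any(idx < 1 | idx > nGrid))
    stop("alignment error: sample outside grid for stream ", streamName,
         call. = FALSE)
  out[idx, ] <- series@samples
  out
}

#' Create the combined data table
#'
#' All requested streams aligned onto the unified DerivedTime grid, one
#' row per grid point. Wherever a stream lacks a value for a grid time,
#' the entry is NA; columns that would be entirely NA are dropped. Column
#' names: `TD_ch1..`, `Accel_X/Y/Z`, `Power_Band1..`, prefix from the
#' stream name otherwise. A `localTime` column (POSIXct, shifted by the
#' session's UTC offset) is added when metadata carries one.
#'
#' @param store An [RCSStore-class] (or named list of
#'   [DerivedTimeSeries-class]).
#' @param include character vector of stream names to include; default all.
#' @return data.frame with `DerivedTime` (unix ms) plus data columns;
#'   attributes `tRef`, `step`, `fs`, `k0` describe the grid.
#' @export
createCombinedTable <- function(store, include = NULL) {
  seriesList <- if (is(store, "RCSStore")) store@streams else store
  if (is.null(include)) include <- names(seriesList)
  unknown <- setdiff(include, names(seriesList))
  if (length(unknown))
    stop("configuration error: unknown stream(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  seriesList <- seriesList[include]
  seriesList <- seriesList[vapply(seriesList, length, integer(1)) > 0]
  grid <- buildUnifiedGrid(seriesList)
  tab <- data.frame(DerivedTime = grid$times)
  prefixes <- c(td = "TD_", accel = "Accel_", power = "Power_",
                fft = "FFT_", adaptive = "Adaptive_")
  for (nm in names(seriesList)) {
    m <- alignStreamToGrid(seriesList[[nm]], grid, nm)
    cn <- colnames(m)
    if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(m)))
    pre <- if (nm %in% names(prefixes)) prefixes[[nm]] else paste0(nm, "_")
    colnames(m) <- paste0(pre, cn)
    tab <- cbind(tab, as.data.frame(m))
  }
  allNa <- vapply(tab, function(x) all(is.na(x)), logical(1))
  tab <- tab[, !allNa, drop = FALSE]
  meta <- if (is(store, "RCSStore")) store@metadata else list()
  if (!is.null(meta$utcOffset)) {
    tab$localTime <- as.POSIXct((tab$DerivedTime +
                                   meta$utcOffset * 60000) / 1000,
                                origin = "1970-01-01", tz = "UTC")
    tab <- tab[, c("DerivedTime", "localTime",
                   setdiff(names(tab), c("DerivedTime", "localTime"))),
               drop = FALSE]
  }
  attr(tab, "tRef") <- grid$tRef
  attr(tab, "step") <- grid$step
  attr(tab, "fs") <- grid$fs
  attr(tab, "k0") <- grid$k0
  tab
}

#' Process a session folder into a store
#'
#' Convenience composition: [loadSession()], then [reconstructStream()]
#' for every stream present.
#'
#' @param folder session folder path.
#' @param method short-gap handling, see [reconstructStream()].
#' @param constants A [ClockConstants-class].
#' @return An [RCSStore-class].
#' @export
processSession <- function(folder, method = "default",
                           constants = clockConstants()) {
  sess <- loadSession(folder)
  streams <- list()
  for (nm in names(sess$streams)) {
    s <- tryCatch(reconstructStream(sess$streams[[nm]], method, constants),
                  warning = function(w) NULL)
    if (!is.null(s) && length(s) > 0) streams[[nm]] <- s
  }
  new("RCSStore", streams = streams, settings = sess$settings,
      events = sess$events,
      metadata = c(sess$metadata, list(loadReport = sess$loadReport)))
}

# -- persistence -------------------------------------------------------------

.seriesToFrame <- function(s) {
  df <- data.frame(derivedTime = s@derivedTime,
                   provenance = s@provenance)
  sm <- as.data.frame(s@samples)
  if (is.null(colnames(s@samples)))
    names(sm) <- paste0("ch", seq_len(ncol(sm)))
  cbind(df, sm)
}

#' Persist / reload a session store
#'
#' Each stream's numeric block is written as a compressed columnar
#' Parquet file (small on disk despite gaps, fast to reload); settings,
#' events, chunk tables and metadata go to a JSON sidecar with a store
#' version. The round trip is lossless: integers to the bit, floats to
#' full double precision.
#'
#' @param folder store directory (created if needed).
#' @param store An [RCSStore-class].
#' @return `saveStore`: the folder, invisibly. `loadStore`: the store.
#' @export
saveStore <- function(folder, store) {
  if (!dir.exists(folder) &&
      !dir.create(folder, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create ", folder, call. = FALSE)
  meta <- list(storeVersion = .STORE_VERSION,
               streams = list(), metadata = store@metadata[
                 setdiff(names(store@metadata), "loadReport")],
               events = store@events,
               settings = list(
                 td = store@settings$td,
                 stim = store@settings$stim,
                 fftConfig = if (!is.null(store@settings$fftConfig)) list(
                   size = store@settings$fftConfig@size,
                   interval = store@settings$fftConfig@interval,
                   windowLoad = store@settings$fftConfig@windowLoad,
                   fs = store@settings$fftConfig@fs),
                 powerBands = lapply(store@settings$powerBands, function(b)
                   list(fLo = b@fLo, fHi = b@fHi, gainG = b@gainG,
                        tdChannel = b@tdChannel))))
  for (nm in names(store@streams)) {
    s <- store@streams[[nm]]
    arrow::write_parquet(.seriesToFrame(s),
                         file.path(folder, paste0(nm, ".parquet")))
    meta$streams[[nm]] <- list(fs = s@fs, tRef = s@tRef,
                               chunks = s@chunks,
                               rejectionLog = s@rejectionLog)
  }
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, dataframe = "columns",
                                           POSIXt = "epoch", null = "null")),
             file.path(folder, "store.json"))
  invisible(folder)
}

#' @rdname saveStore
#' @export
loadStore <- function(folder) {
  metaPath <- file.path(folder, "store.json")
  if (!file.exists(metaPath))
    stop("I/O error: not a store (store.json missing): ", folder,
         call. = FALSE)
  meta <- tryCatch(
    jsonlite::fromJSON(paste(readLines(metaPath, warn = FALSE),
                             collapse = "\n"), simplifyVector = TRUE),
    error = function(e) stop("corruption error: unreadable store.json: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(meta$storeVersion) || meta$storeVersion != .STORE_VERSION)
    stop("version mismatch: store version ",
         meta$storeVersion %||% "<missing>", " != ", .STORE_VERSION,
         call. = FALSE)
  streams <- list()
  for (nm in names(meta$streams)) {
    p <- file.path(folder, paste0(nm, ".parquet"))
    df <- tryCatch(as.data.frame(arrow::read_parquet(p)),
                   error = function(e)
                     stop("corruption error: cannot read ", p, ": ",
                          conditionMessage(e), call. = FALSE))
    sm <- meta$streams[[nm]]
    chans <- setdiff(names(df), c("derivedTime", "provenance"))
    mat <- as.matrix(df[, chans, drop = FALSE])
    chunks <- as.data.frame(sm$chunks)
    rej <- as.data.frame(sm$rejectionLog)
    if (!nrow(rej)) rej <- data.frame(index = integer(0),
                                      rule = character(0))
    streams[[nm]] <- new("DerivedTimeSeries",
                         derivedTime = df$derivedTime, samples = mat,
                         fs = sm$fs, tRef = sm$tRef, chunks = chunks,
                         provenance = as.integer(df$provenance),
                         rejectionLog = rej)
  }
  settings <- list(
    td = as.data.frame(meta$settings$td),
    stim = if (!is.null(meta$settings$stim))
      as.data.frame(meta$settings$stim) else NULL,
    fftConfig = if (!is.null(meta$settings$fftConfig))
      fftConfig(meta$settings$fftConfig$size,
                meta$settings$fftConfig$interval,
                meta$settings$fftConfig$windowLoad,
                meta$settings$fftConfig$fs) else NULL,
    powerBands = if (!is.null(meta$settings$powerBands) &&
                     length(meta$settings$powerBands))
      lapply(seq_len(nrow(as.data.frame(meta$settings$powerBands))),
             function(i) {
               b <- as.data.frame(meta$settings$powerBands)[i, ]
               powerBand(b$fLo, b$fHi, b$gainG, b$tdChannel)
             }) else list())
  events <- as.data.frame(meta$events)
  if (!nrow(events)) events <- data.frame(time = numeric(0),
                                          type = character(0),
                                          payload = character(0))
  new("RCSStore", streams = streams, settings = settings, events = events,
      metadata = as.list(meta$metadata))
}
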