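#' Write a session of labeled segments to a portable container
#'
#' Sessions are stored as a single plain-text JSON file holding the
#' sampling rate, subject/session identifiers and each segment as a
#' row-major channels x samples array with its label.  Numbers are written
#' at full precision so a write/read round trip reproduces the data
#' exactly.
#'
#' @param segments a [SessionContainer-class] or a list of
#'   [SignalEpoch-class] objects.
#' @param path output file path (conventionally `.json`).
#' @param subject,session identifiers stored in the container (ignored if
#'   `segments` is already a `SessionContainer`).
#' @return `path`, invisibly.
#' @seealso [readSession()]
#' @export
writeSession <- function(segments, path, subject = "synthetic", session = "1") {
  if (is(segments, "SessionContainer")) {
    sc <- segments
  } else {
    fs <- segments[[1L]]@fs
    sc <- new("SessionContainer", segments = segments, fs = fs,
              subject = as.character(subject), session = as.character(session))
  }
  obj <- list(
    format = "stentropy-session",
    version = 1L,
    fs = sc@fs,
    subject = sc@subject,
    session = sc@session,
    segments = lapply(sc@segments, function(s)
      list(label = if (is.na(s@label)) NULL else s@label,
           t0 = s@t0, data = s@data))
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a session container
#'
#' Reads a portable session file written by [writeSession()].  Labels can
#' be overridden (or supplied, when the file has none) through `labelMap`,
#' a numeric vector with one emotion code per segment in storage order.
#'
#' @param path session file path.
#' @param labelMap optional numeric label vector, one entry per segment.
#' @param fs sampling rate to assume if the file lacks one (default 200).
#' @param expectedSegments if not `NA`, warn when the file holds a
#'   different number of segments (15 for a standard SEED-style session).
#' @return A [SessionContainer-class].
#' @export
readSession <- function(path, labelMap = NULL, fs = 200,
                        expectedSegments = NA) {
  if (!file.exists(path)) stop("cannot read session file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$format, "stentropy-session"))
    stop("not a session container: ", path)
  fs <- if (!is.null(obj$fs)) obj$fs else fs
  segs <- obj$segments
  if (!is.na(expectedSegments) && length(segs) != expectedSegments)
    warning("expected ", expectedSegments, " segments, found ", length(segs))
  if (!is.null(labelMap) && length(labelMap) != length(segs))
    stop("labelMap has ", length(labelMap), " entries for ",
         length(segs), " segments")
  out <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    lab <- if (!is.null(labelMap)) labelMap[i]
           else if (!is.null(s$label)) s$label
           else stop("segment ", i, " carries no label; supply labelMap")
    dat <- s$data
    if (!is.matrix(dat)) dat <- matrix(dat, nrow = 1L)
    out[[i]] <- signalEpoch(dat, fs = fs, label = lab,
                            t0 = if (is.null(s$t0)) 0 else s$t0)
  }
  new("SessionContainer", segments = out, fs = fs,
      subject = as.character(obj$subject %||% "unknown"),
      session = as.character(obj$session %||% "1"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash of an extraction configuration
#'
#' MD5 digest of the canonical JSON encoding of all configuration fields;
#' any change to any field changes the hash.  Stored in reports so results
#' can be traced back to the configuration that produced them.
#'
#' @param cfg an [extractionConfig()].
#' @return Character MD5 hash.
#' @export
configHash <- function(cfg) {
  stopifnot(is(cfg, "ExtractionConfig"))
  obj <- list(epochLen = cfg@epochLen, fmin = cfg@fmin, fmax = cfg@fmax,
              width = cfg@width, bands = cfg@bands, windowK = cfg@windowK,
              nCSP = cfg@nCSP)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write an evaluation report
#'
#' JSON serialization of a [CVReport-class]: task, band, window, per-fold
#' accuracies, mean, std, seed, classifier and (optionally) the hash of
#' the configuration that produced the features.
#'
#' @param report a [CVReport-class].
#' @param path output path.
#' @param cfg optional [extractionConfig()] whose [configHash()] is stored.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, cfg = NULL) {
  stopifnot(is(report, "CVReport"))
  obj <- list(task = report@task, band = report@band, window = report@window,
              folds = report@folds, mean = report@accMean, std = report@accSd,
              seed = report@seed, classifier = report@classifier,
              details = report@details,
              configHash = if (is.null(cfg)) NULL else configHash(cfg))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CVReport", task = obj$task,
      band = if (is.null(obj$band)) NA_character_ else obj$band,
      window = if (is.null(obj$window)) NA_integer_ else as.integer(obj$window),
      folds = as.numeric(obj$folds), accMean = obj$mean, accSd = obj$std,
      seed = obj$seed, classifier = obj$classifier,
      details = as.list(obj$details))
}

#' Write / read a feature table as CSV
#'
#' Plain CSV with columns `epoch_id`, `band`, `window`, `f1..fK`, `label`.
#'
#' @param ft a [FeatureTable-class].
#' @param path CSV path.
#' @return `writeFeatureTable`: `path` invisibly; `readFeatureTable`: the
#'   [FeatureTable-class].
#' @export
writeFeatureTable <- function(ft, path) {
  stopifnot(is(ft, "FeatureTable"))
  X <- ft@X
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  df <- data.frame(epoch_id = seq_len(nrow(X)), band = ft@band,
                   window = ft@window, X, label = ft@y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  new("FeatureTable", X = as.matrix(df[, fcols, drop = FALSE]),
      y = as.numeric(df$label), band = as.character(df$band[1L]),
      window = as.integer(df$window[1L]))
}
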