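# Sequence I/O in three plain-text dialects:
#   csv-long : header frame,joint,x,y,z ; one row per joint per frame
#   csv-wide : header frame,j00_x,j00_y,j00_z,...,j16_z
#   jsonl    : first line a metadata object, then one frame object per line
# The csv dialects carry metadata in an optional JSON sidecar <path>.json.
# Numbers are written with 17 significant digits so round-trips are
# bit-for-bit exact.

.DIALECTS <- c("csv-wide", "csv-long", "jsonl")

.fmt <- function(x) sprintf("%.17g", x)

.read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
}

.meta_or <- function(meta, key, default) {
  v <- meta[[key]]
  if (is.null(v) || length(v) != 1L || is.na(v)) default else v
}

# Interpolate NA runs of length <= max_gap per coordinate column; runs at
# either end or longer than max_gap are errors.
.fill_gaps <- function(mat, max_gap = 5L) {
  for (jc in seq_len(ncol(mat))) {
    v <- mat[, jc]
    if (!anyNA(v)) next
    na <- is.na(v)
    r <- rle(na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      joint <- (jc - 1L) %/% 3L
      if (starts[k] == 1L || ends[k] == nrow(mat)) {
        stop(sprintf("cannot interpolate joint %d: gap touches sequence boundary (frames %d-%d)",
                     joint, starts[k] - 1L, ends[k] - 1L), call. = FALSE)
      }
      if (r$lengths[k] > max_gap) {
        stop(sprintf("joint %d invalid for %d consecutive frames (%d-%d); gaps longer than %d frames are not interpolated",
                     joint, r$lengths[k], starts[k] - 1L, ends[k] - 1L, max_gap),
             call. = FALSE)
      }
    }
    mat[, jc] <- stats::approx(which(!na), v[!na], xout = seq_along(v))$y
  }
  mat
}

.check_cells <- function(mat) {
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing coordinate: frame %d, joint %d",
                 idx[1] - 1L, (idx[2] - 1L) %/% 3L), call. = FALSE)
  }
  invisible(mat)
}

.check_frame_ids <- function(ids) {
  if (any(diff(ids) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  invisible(ids)
}

#' Read a skeleton sequence from disk
#'
#' Supported dialects: `"csv-wide"` (one row per frame, 51 coordinate
#' columns `j00_x`..`j16_z`), `"csv-long"` (header `frame,joint,x,y,z`, one
#' row per joint per frame) and `"jsonl"` (a metadata line followed by one
#' frame object per line). Frame and joint indices in files are 0-based.
#' Metadata (`person`, `exercise`, `position`, `label`, `fps`) is read from
#' a `<path>.json` sidecar for the csv dialects and from the first line for
#' jsonl.
#'
#' A frame with a missing coordinate is a hard error naming the 0-based
#' frame and joint, unless `interpolate_gaps = TRUE`, in which case a joint
#' missing for at most 5 consecutive frames is filled by linear
#' interpolation (longer gaps remain an error).
#'
#' @param path File to read.
#' @param dialect One of `"csv-wide"`, `"csv-long"`, `"jsonl"`.
#' @param fps Frame rate to use when no sidecar/metadata value is present.
#' @param interpolate_gaps Fill short tracking gaps by linear interpolation?
#' @return A [skeleton_sequence()].
#' @seealso [save_sequence()]
#' @export
load_sequence <- function(path, dialect = c("csv-wide", "csv-long", "jsonl"),
                          fps = 30, interpolate_gaps = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  meta <- list()
  if (dialect == "csv-wide") {
    df <- utils::read.csv(path, check.names = FALSE)
    want <- c("frame", .wide_colnames())
    if (!identical(names(df), want)) {
      stop("csv-wide header must be frame,j00_x,j00_y,j00_z,...,j16_z",
           call. = FALSE)
    }
    .check_frame_ids(df$frame)
    mat <- as.matrix(df[, -1L, drop = FALSE])
    if (interpolate_gaps) mat <- .fill_gaps(mat)
    .check_cells(mat)
    coords <- .unflatten_coords(mat)
    meta <- .read_sidecar(path)
  } else if (dialect == "csv-long") {
    df <- utils::read.csv(path)
    if (!identical(names(df), c("frame", "joint", "x", "y", "z"))) {
      stop("csv-long header must be frame,joint,x,y,z", call. = FALSE)
    }
    ids <- unique(df$frame)
    .check_frame_ids(ids)
    n <- length(ids)
    mat <- matrix(NA_real_, n, 3L * .K)
    for (r in seq_len(nrow(df))) {
      i <- match(df$frame[r], ids)
      j <- df$joint[r]
      if (j < 0L || j >= .K) {
        stop(sprintf("joint index %d out of range in frame %d", j, df$frame[r]),
             call. = FALSE)
      }
      mat[i, 3L * j + 1:3] <- c(df$x[r], df$y[r], df$z[r])
    }
    if (interpolate_gaps) mat <- .fill_gaps(mat)
    .check_cells(mat)
    coords <- .unflatten_coords(mat)
    meta <- .read_sidecar(path)
  } else {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("jsonl file must have a metadata line and frames",
                                 call. = FALSE)
    meta <- jsonlite::fromJSON(lines[1L], simplifyVector = TRUE)
    frames <- lapply(lines[-1L], jsonlite::fromJSON, simplifyVector = TRUE)
    ids <- vapply(frames, function(f) as.numeric(f$frame), numeric(1))
    .check_frame_ids(ids)
    mat <- do.call(rbind, lapply(frames, function(f) {
      cm <- f$coords
      if (is.null(dim(cm)) || nrow(cm) != .K || ncol(cm) != 3L) {
        stop(sprintf("frame %d: coords must be 17 x 3", f$frame), call. = FALSE)
      }
      as.vector(t(cm))
    }))
    if (interpolate_gaps) mat <- .fill_gaps(mat)
    .check_cells(mat)
    coords <- .unflatten_coords(mat)
  }
  skeleton_sequence(
    coords,
    fps = .meta_or(meta, "fps", fps),
    person = .meta_or(meta, "person", NA_character_),
    exercise = .meta_or(meta, "exercise", NA_character_),
    position = .meta_or(meta, "position", NA_character_),
    label = .meta_or(meta, "label", NA_character_)
  )
}

#' Write a skeleton sequence to disk
#'
#' Inverse of [load_sequence()]: for the csv dialects, metadata (including
#' `fps`) is written to a `<path>.json` sidecar; for jsonl it is embedded
#' as the first line. Coordinates are written with 17 significant digits,
#' so `load_sequence(save_sequence(x))` reproduces `x` bit-for-bit.
#'
#' @param seq A valid [skeleton_sequence()].
#' @param path Output file.
#' @param dialect One of `"csv-wide"`, `"csv-long"`, `"jsonl"`.
#' @return `path`, invisibly.
#' @export
save_sequence <- function(seq, path, dialect = c("csv-wide", "csv-long", "jsonl")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(seq, "skeleton_sequence"))
  n <- nframes(seq)
  mat <- .flatten_coords(seq$coords)
  meta <- c(seq$meta, list(fps = seq$fps))
  if (dialect == "csv-wide") {
    lines <- c(paste(c("frame", .wide_colnames()), collapse = ","),
               vapply(seq_len(n), function(i) {
                 paste(c(i - 1L, .fmt(mat[i, ])), collapse = ",")
               }, character(1)))
    writeLines(lines, path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null", na = "null")
  } else if (dialect == "csv-long") {
    rows <- character(n * .K)
    k <- 1L
    for (i in seq_len(n)) {
      for (j in seq_len(.K)) {
        rows[k] <- paste(c(i - 1L, j - 1L, .fmt(mat[i, 3L * (j - 1L) + 1:3])),
                         collapse = ",")
        k <- k + 1L
      }
    }
    writeLines(c("frame,joint,x,y,z", rows), path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null", na = "null")
  } else {
    head <- jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null", na = "null")
    body <- vapply(seq_len(n), function(i) {
      triples <- matrix(.fmt(mat[i, ]), ncol = 3L, byrow = TRUE)
      sprintf('{"frame": %d, "coords": [%s]}', i - 1L,
              paste(sprintf("[%s, %s, %s]", triples[, 1], triples[, 2],
                            triples[, 3]), collapse = ", "))
    }, character(1))
    writeLines(c(as.character(head), body), path)
  }
  invisible(path)
}
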