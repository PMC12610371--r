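# Standard 17-joint skeleton model, sequence container, joint-layout
# mapping, and anthropometric normalization.

.JOINTS <- c(
  "pelvis", "spine_navel", "spine_chest", "neck", "head",
  "l_shoulder", "l_elbow", "l_wrist",
  "r_shoulder", "r_elbow", "r_wrist",
  "l_hip", "l_knee", "l_ankle",
  "r_hip", "r_knee", "r_ankle"
)

.K <- 17L

# 16-edge tree over the standard joints, 1-based internal indices.
.EDGES <- matrix(c(
  1, 2,   # pelvis - spine_navel
  2, 3,   # spine_navel - spine_chest
  3, 4,   # spine_chest - neck
  4, 5,   # neck - head
  3, 6,   # spine_chest - l_shoulder
  6, 7,   # l_shoulder - l_elbow
  7, 8,   # l_elbow - l_wrist
  3, 9,   # spine_chest - r_shoulder
  9, 10,  # r_shoulder - r_elbow
  10, 11, # r_elbow - r_wrist
  1, 12,  # pelvis - l_hip
  12, 13, # l_hip - l_knee
  13, 14, # l_knee - l_ankle
  1, 15,  # pelvis - r_hip
  15, 16, # r_hip - r_knee
  16, 17  # r_knee - r_ankle
), ncol = 2, byrow = TRUE)

#' Standard joint names
#'
#' The 17 standard joint names, in index order (0-based index `i` in file
#' formats corresponds to element `i + 1` of this vector). The table is a
#' package convention for the standardized skeletal model.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' standard_joints()
standard_joints <- function() .JOINTS

#' Standard skeleton edge set
#'
#' The 16-edge tree connecting the 17 standard joints, used as the bone set
#' whose total length defines the skeleton scale during normalization.
#'
#' @param zero_based Return 0-based joint indices (the convention used in
#'   file formats and documentation)? Default `TRUE`.
#' @return A 16 x 2 integer matrix; each row is one bone.
#' @export
standard_edges <- function(zero_based = TRUE) {
  e <- .EDGES
  if (zero_based) e <- e - 1L
  storage.mode(e) <- "integer"
  colnames(e) <- c("from", "to")
  e
}

.check_frame <- function(coords, what = "frame") {
  if (!is.matrix(coords) || !is.numeric(coords) ||
      nrow(coords) != .K || ncol(coords) != 3L) {
    stop(sprintf("%s must be a numeric %d x 3 matrix", what, .K), call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1L, all))
    stop(sprintf("%s has non-finite coordinates at joint(s) %s",
                 what, paste(bad - 1L, collapse = ", ")), call. = FALSE)
  }
  invisible(coords)
}

#' Skeleton sequence container
#'
#' An ordered series of standardized skeleton frames with a frame rate and
#' recording metadata. Coordinates are stored as an `N x 17 x 3` array
#' (frame, joint, coordinate).
#'
#' @param coords An `N x 17 x 3` numeric array, or a list of `17 x 3` frame
#'   matrices. At least two frames are required.
#' @param fps Frames per second (positive scalar).
#' @param person,exercise,position,label Optional metadata strings.
#'   `position` is typically `"sitting"` or `"standing"`; `label` one of
#'   `"good"`, `"intermediate"`, `"bad"`, `"reference"` or `"unlabeled"`.
#' @return An object of class `"skeleton_sequence"` with elements `coords`,
#'   `fps` and `meta`.
#' @export
#' @examples
#' pose <- matrix(rnorm(51), 17, 3)
#' seq <- skeleton_sequence(array(rep(pose, 5), c(17, 3, 5)) |>
#'   aperm(c(3, 1, 2)), fps = 30)
#' nframes(seq)
skeleton_sequence <- function(coords, fps = 30,
                              person = NA_character_,
                              exercise = NA_character_,
                              position = NA_character_,
                              label = NA_character_) {
  if (is.list(coords)) {
    lapply(seq_along(coords), function(i) {
      .check_frame(coords[[i]], sprintf("frame %d", i - 1L))
    })
    coords <- aperm(array(unlist(coords), c(.K, 3L, length(coords))), c(3L, 1L, 2L))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L ||
      dim(coords)[2] != .K || dim(coords)[3] != 3L) {
    stop("coords must be an N x 17 x 3 array or a list of 17 x 3 matrices",
         call. = FALSE)
  }
  if (dim(coords)[1] < 2L) stop("a skeleton sequence needs at least 2 frames",
                                call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a positive number", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1L, all))
    stop(sprintf("non-finite coordinates in frame(s) %s",
                 paste(bad - 1L, collapse = ", ")), call. = FALSE)
  }
  dimnames(coords) <- list(NULL, .JOINTS, c("x", "y", "z"))
  structure(
    list(coords = coords, fps = as.numeric(fps),
         meta = list(person = person, exercise = exercise,
                     position = position, label = label)),
    class = "skeleton_sequence"
  )
}

#' Number of frames in a skeleton sequence
#' @param seq A [skeleton_sequence()].
#' @return Integer frame count.
#' @export
nframes <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  dim(seq$coords)[1]
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<skeleton_sequence> %d frames x %d joints @ %g fps\n",
              nframes(x), .K, x$fps))
  tags <- m[!is.na(unlist(m))]
  if (length(tags)) {
    cat("  ", paste(sprintf("%s=%s", names(tags), unlist(tags)),
                    collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract one frame
#' @param seq A [skeleton_sequence()].
#' @param i Frame index, 0-based (the convention used across file formats).
#' @return A `17 x 3` coordinate matrix.
#' @export
get_frame <- function(seq, i) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  n <- nframes(seq)
  if (i < 0L || i >= n) stop(sprintf("frame %d out of range [0, %d]", i, n - 1L),
                             call. = FALSE)
  f <- seq$coords[i + 1L, , ]
  dimnames(f) <- list(.JOINTS, c("x", "y", "z"))
  f
}

# Flatten an N x 17 x 3 array to N x 51 with column order
# j00_x, j00_y, j00_z, ..., j16_z (the csv-wide column order).
.flatten_coords <- function(coords) {
  n <- dim(coords)[1]
  t(matrix(aperm(coords, c(3L, 2L, 1L)), nrow = 3L * .K, ncol = n))
}

.unflatten_coords <- function(mat) {
  n <- nrow(mat)
  aperm(array(t(mat), c(3L, .K, n)), c(3L, 2L, 1L))
}

.wide_colnames <- function() {
  as.vector(t(outer(sprintf("j%02d", 0:(.K - 1L)), c("x", "y", "z"),
                    paste, sep = "_")))
}

#' Normalize a single skeleton frame
#'
#' Translates the pelvis (standard joint 0) to the origin and rescales so
#' that the total bone length over the 16-edge standard skeleton tree
#' equals 1. This removes global position and body size, making frames of
#' different people directly comparable; the operation is idempotent and
#' invariant under uniform scaling and translation of the input. No
#' rotational alignment is applied unless `align_rotation = TRUE`, which
#' additionally yaw-rotates the skeleton about the vertical (y) axis so the
#' shoulder axis lies in the x-y plane. Rotation is opt-in because the
#' pose dissimilarity is normally computed in the shared sensor frame.
#'
#' @param frame A `17 x 3` numeric coordinate matrix.
#' @param align_rotation Apply the optional yaw alignment? Default `FALSE`.
#' @return The normalized `17 x 3` matrix.
#' @export
#' @examples
#' f <- matrix(rnorm(51), 17, 3)
#' g <- normalize_frame(f)
#' sum(sqrt(rowSums((g[standard_edges()[, 1] + 1, ] -
#'                   g[standard_edges()[, 2] + 1, ])^2)))  # 1
normalize_frame <- function(frame, align_rotation = FALSE) {
  .check_frame(frame)
  out <- sweep(frame, 2L, frame[1L, ], `-`)
  bl <- sum(sqrt(rowSums((out[.EDGES[, 1], ] - out[.EDGES[, 2], ])^2)))
  if (bl < 1e-12) {
    stop("degenerate frame: all joints coincide (zero skeleton size)",
         call. = FALSE)
  }
  out <- out / bl
  if (align_rotation) {
    ax <- out[6L, ] - out[9L, ]           # l_shoulder - r_shoulder
    r <- sqrt(ax[1]^2 + ax[3]^2)
    if (r > 1e-9) {
      ct <- ax[1] / r; st <- -ax[3] / r   # rotate about y so axis z-comp = 0
      rot <- matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3L, 3L)
      out <- out %*% rot
    }
  }
  dimnames(out) <- list(.JOINTS, c("x", "y", "z"))
  out
}

#' Normalize every frame of a sequence
#'
#' Applies [normalize_frame()] to each frame; metadata and frame rate are
#' preserved. Errors in individual frames are reported with the 0-based
#' frame index.
#'
#' @inheritParams normalize_frame
#' @param seq A [skeleton_sequence()].
#' @return A normalized [skeleton_sequence()].
#' @export
normalize_sequence <- function(seq, align_rotation = FALSE) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  co <- seq$coords
  n <- dim(co)[1]
  if (align_rotation) {
    # rotation path: per-frame (rarely used)
    for (i in seq_len(n)) {
      co[i, , ] <- tryCatch(normalize_frame(seq$coords[i, , ], TRUE),
                            error = function(e) {
                              stop(sprintf("frame %d: %s", i - 1L,
                                           conditionMessage(e)), call. = FALSE)
                            })
    }
  } else {
    # vectorized: translate pelvis to origin, divide by per-frame bone sum
    co <- co - co[, rep(1L, .K), ]
    d <- co[, .EDGES[, 1], , drop = FALSE] - co[, .EDGES[, 2], , drop = FALSE]
    bl <- rowSums(sqrt(apply(d^2, c(1L, 2L), sum)))
    if (any(bl < 1e-12)) {
      stop(sprintf("frame %d: degenerate frame: all joints coincide (zero skeleton size)",
                   which(bl < 1e-12)[1] - 1L), call. = FALSE)
    }
    co <- co / bl
  }
  out <- seq
  out$coords <- co
  dimnames(out$coords) <- list(NULL, .JOINTS, c("x", "y", "z"))
  out
}

#' Joint-layout mapping to the standard 17-joint model
#'
#' A table-driven projection from a raw sensor/pose-network joint layout to
#' the standard 17-joint model. Each standard joint is produced either by
#' copying one source joint or as the midpoint of two source joints.
#'
#' @param source_layout Name of the source layout (e.g. `"kinect25"`).
#' @param table A list of 17 elements; element `i` gives the 0-based source
#'   joint index (length 1) or pair of indices (length 2, midpoint rule)
#'   producing standard joint `i - 1`.
#' @return An object of class `"joint_mapping"`.
#' @seealso [kinect25_mapping()], [mediapipe33_mapping()], [map_to_standard()]
#' @export
joint_mapping <- function(source_layout, table) {
  if (!is.list(table) || length(table) != .K) {
    stop("mapping table must be a list of 17 entries (one per standard joint)",
         call. = FALSE)
  }
  for (i in seq_along(table)) {
    src <- table[[i]]
    if (!is.numeric(src) || !(length(src) %in% 1:2) || any(src != floor(src)) ||
        any(src < 0)) {
      stop(sprintf("entry %d: each standard joint maps to one or two nonnegative source indices",
                   i - 1L), call. = FALSE)
    }
    table[[i]] <- as.integer(src)
  }
  structure(list(source_layout = source_layout, table = table),
            class = "joint_mapping")
}

#' Built-in Kinect-v2-style 25-joint mapping
#'
#' Maps the 25-joint Kinect v2 layout (SpineBase, SpineMid, Neck, Head,
#' ShoulderLeft, ..., SpineShoulder, hand tips and thumbs) onto the
#' standard 17-joint model by direct index selection.
#'
#' @return A [joint_mapping()].
#' @export
kinect25_mapping <- function() {
  joint_mapping("kinect25", list(
    0L,   # pelvis       <- SpineBase
    1L,   # spine_navel  <- SpineMid
    20L,  # spine_chest  <- SpineShoulder
    2L,   # neck         <- Neck
    3L,   # head         <- Head
    4L,   # l_shoulder   <- ShoulderLeft
    5L,   # l_elbow      <- ElbowLeft
    6L,   # l_wrist      <- WristLeft
    8L,   # r_shoulder   <- ShoulderRight
    9L,   # r_elbow      <- ElbowRight
    10L,  # r_wrist      <- WristRight
    12L,  # l_hip        <- HipLeft
    13L,  # l_knee       <- KneeLeft
    14L,  # l_ankle      <- AnkleLeft
    16L,  # r_hip        <- HipRight
    17L,  # r_knee       <- KneeRight
    18L   # r_ankle      <- AnkleRight
  ))
}

#' Built-in pose-network-style 33-landmark mapping
#'
#' Maps a 33-landmark full-body pose-network layout (BlazePose-style) onto
#' the standard 17-joint model. Trunk joints absent from the landmark set
#' (pelvis, spine, neck) are synthesized as midpoints of hip/shoulder
#' landmarks; this is an approximation, documented as such.
#'
#' @return A [joint_mapping()].
#' @export
mediapipe33_mapping <- function() {
  joint_mapping("mediapipe33", list(
    c(23L, 24L),  # pelvis       <- mid(hips)
    c(12L, 23L),  # spine_navel  <- mid(r_shoulder, l_hip) ~ mid-spine
    c(11L, 12L),  # spine_chest  <- mid(shoulders)
    c(9L, 10L),   # neck         <- mid(mouth corners) ~ below head
    0L,           # head         <- nose
    11L,          # l_shoulder
    13L,          # l_elbow
    15L,          # l_wrist
    12L,          # r_shoulder
    14L,          # r_elbow
    16L,          # r_wrist
    23L,          # l_hip
    25L,          # l_knee
    27L,          # l_ankle
    24L,          # r_hip
    26L,          # r_knee
    28L           # r_ankle
  ))
}

#' Project a raw-layout frame onto the standard 17-joint model
#'
#' @param raw_coords A `J x 3` numeric matrix of source-layout joint
#'   coordinates.
#' @param mapping A [joint_mapping()] covering all 17 standard joints.
#' @return A `17 x 3` standard frame matrix.
#' @export
#' @examples
#' raw <- matrix(rnorm(25 * 3), 25, 3)
#' std <- map_to_standard(raw, kinect25_mapping())
map_to_standard <- function(raw_coords, mapping) {
  stopifnot(inherits(mapping, "joint_mapping"))
  if (!is.matrix(raw_coords) || !is.numeric(raw_coords) || ncol(raw_coords) != 3L) {
    stop("raw_coords must be a numeric J x 3 matrix", call. = FALSE)
  }
  jmax <- nrow(raw_coords)
  out <- matrix(NA_real_, .K, 3L, dimnames = list(.JOINTS, c("x", "y", "z")))
  for (i in seq_len(.K)) {
    src <- mapping$table[[i]]
    if (any(src >= jmax)) {
      stop(sprintf("mapping for standard joint %d references source joint %d, but input has only %d joints",
                   i - 1L, max(src), jmax), call. = FALSE)
    }
    out[i, ] <- if (length(src) == 1L) raw_coords[src + 1L, ]
                else (raw_coords[src[1] + 1L, ] + raw_coords[src[2] + 1L, ]) / 2
  }
  out
}
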