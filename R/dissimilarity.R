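# Motion-dependent pose dissimilarity: attention weights derived from the
# instructor's motion, the weighted Euclidean distance between two frames,
# and the per-record motion intensity.

#' Attention weights from an instructor sequence
#'
#' For each of the 51 coordinates (17 joints x 3 axes), computes the
#' population standard deviation sigma_pm of that coordinate across the
#' instructor's frames, then normalizes:
#' \deqn{w_{pm} = \sigma_{pm} / \sum_{p}\sum_{m} \sigma_{pm}.}
#' The weights concentrate the pose distance on the coordinates the
#' exercise actually moves; coordinates the instructor never moves get
#' weight exactly 0. Weights are always derived from the instructor's
#' recording, never the patient's.
#'
#' The population (1/N) standard deviation is used; the 1/N vs 1/(N-1)
#' choice cancels in the normalization.
#'
#' @param instructor_seq A normalized [skeleton_sequence()] with at least
#'   two frames.
#' @return An object of class `"weight_set"`: list with `w` and `sigma`,
#'   both `17 x 3` matrices. `sum(w)` is 1.
#' @export
#' @examples
#' seq <- generate_instructor(exercise_template("standing"))
#' W <- attention_weights(normalize_sequence(seq))
#' sum(W$w)
attention_weights <- function(instructor_seq) {
  stopifnot(inherits(instructor_seq, "skeleton_sequence"))
  co <- instructor_seq$coords
  n <- dim(co)[1]
  mu <- colMeans(co, dims = 1L)                     # 17 x 3
  sigma <- sqrt(colMeans(sweep(co, c(2L, 3L), mu)^2, dims = 1L))
  tot <- sum(sigma)
  if (tot <= 0) stop("no motion in reference: all coordinate standard deviations are zero",
                     call. = FALSE)
  w <- sigma / tot
  dimnames(w) <- dimnames(sigma) <- list(.JOINTS, c("x", "y", "z"))
  structure(list(w = w, sigma = sigma), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  nz <- sum(x$w > 0)
  top <- utils::head(order(x$w, decreasing = TRUE), 3L)
  lab <- sprintf("%s_%s", .JOINTS[(top - 1L) %% .K + 1L],
                 c("x", "y", "z")[(top - 1L) %/% .K + 1L])
  cat(sprintf("<weight_set> %d/51 nonzero weights; top: %s\n", nz,
              paste(sprintf("%s=%.3f", lab, x$w[top]), collapse = ", ")))
  invisible(x)
}

#' Write / read an attention weight table
#'
#' Serializes a [weight_set][attention_weights()] to CSV with columns
#' `joint,coord,sigma,weight` (0-based joint index) for inspection, and
#' reads it back.
#'
#' @param W A weight set.
#' @param path CSV file path.
#' @return `write_weights`: `path`, invisibly. `read_weights`: a weight set.
#' @export
write_weights <- function(W, path) {
  stopifnot(inherits(W, "weight_set"))
  df <- data.frame(
    joint = rep(0:(.K - 1L), each = 3L),
    coord = rep(c("x", "y", "z"), .K),
    sigma = as.vector(t(W$sigma)),
    weight = as.vector(t(W$w))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(identical(names(df), c("joint", "coord", "sigma", "weight")),
            nrow(df) == 3L * .K)
  ord <- order(df$joint, match(df$coord, c("x", "y", "z")))
  df <- df[ord, ]
  shape <- function(v) matrix(v, .K, 3L, byrow = TRUE,
                              dimnames = list(.JOINTS, c("x", "y", "z")))
  structure(list(w = shape(df$weight), sigma = shape(df$sigma)),
            class = "weight_set")
}

#' Weighted pose distance between two skeleton frames
#'
#' The motion-dependent dissimilarity between an instructor frame and a
#' patient frame:
#' \deqn{d(S^{(I)}, S^{(P)}) = \sqrt{\frac{1}{K} \sum_{p=0}^{K-1}
#'   \sum_{m \in \{x,y,z\}} w_{pm} \left(S^{(I)}_{pm} - S^{(P)}_{pm}\right)^2},}
#' with K = 17 joints. The square root makes it a weighted Euclidean
#' seminorm; `squared = TRUE` returns the root-free variant (the two are
#' monotone-equivalent for alignment purposes).
#'
#' @param frame_a,frame_b `17 x 3` normalized coordinate matrices.
#' @param W A [weight_set][attention_weights()].
#' @param squared Skip the square root? Default `FALSE`.
#' @return Nonnegative scalar distance.
#' @export
skeleton_distance <- function(frame_a, frame_b, W, squared = FALSE) {
  .check_frame(frame_a, "frame_a")
  .check_frame(frame_b, "frame_b")
  stopifnot(inherits(W, "weight_set"))
  d2 <- sum(W$w * (frame_a - frame_b)^2) / .K
  if (squared) d2 else sqrt(d2)
}

# All pairwise weighted distances between frames of two sequences:
# returns an Na x Nb matrix. Shared by the DP aligner and the
# brute-force oracle so both see identical arithmetic.
.pair_distances <- function(coords_a, coords_b, W, squared = FALSE) {
  A <- .flatten_coords(coords_a)
  B <- .flatten_coords(coords_b)
  wv <- as.vector(t(W$w))
  na <- nrow(A)
  # column-wise differences rather than a cross-product expansion: exact
  # zeros for identical frames, no cancellation error
  D <- matrix(0, na, nrow(B))
  for (j in seq_len(nrow(B))) {
    diff <- A - rep(B[j, ], each = na)
    D[, j] <- as.vector((diff * diff) %*% wv) / .K
  }
  if (squared) D else sqrt(D)
}

#' Motion intensity of a record
#'
#' The average interframe squared displacement of a single record:
#' \deqn{E = \frac{1}{N K} \sum_{i=1}^{N-1} \sum_{p}\sum_{m}
#'   \left(S_{i,pm} - S_{i-1,pm}\right)^2,}
#' where N is the record's own frame count and K = 17. This is an
#' unweighted, root-free quantity; it summarizes how vigorously a record
#' moves and correlates with execution quality when degradation attenuates
#' movement amplitude. It is invariant under time reversal.
#'
#' @param seq A normalized [skeleton_sequence()] with N >= 2 frames.
#' @return Nonnegative scalar intensity.
#' @export
intensity <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  co <- seq$coords
  n <- dim(co)[1]
  d <- co[-1L, , , drop = FALSE] - co[-n, , , drop = FALSE]
  sum(d^2) / (n * .K)
}
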