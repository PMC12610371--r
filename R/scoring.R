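# Decomposition of an alignment into the posture component DP and the
# dynamics component DT, the anthropometric correction, and the balanced
# combination of the two.

#' Posture component of an alignment
#'
#' The minimum aligned pair distance `M_anthro` is attributed to the
#' anthropometric discrepancy between the two bodies (after normalization,
#' a residual constant offset reflects body proportions rather than
#' performance); the posture dissimilarity is the mean excess over it:
#' \deqn{D_P = \frac{1}{N_b} \sum_i (d_i - M),\qquad M = \min_i d_i.}
#' Subtracting `M` makes `DP` exactly invariant to a constant offset added
#' to every pair distance.
#'
#' @param ar An [alignment_result][align_sequences()].
#' @return List with `DP` and `M_anthro`.
#' @export
#' @examples
#' # pair distances 0.2, 0.5, 0.8 -> M = 0.2, DP = (0 + 0.3 + 0.6)/3
posture_component <- function(ar) {
  stopifnot(inherits(ar, "alignment_result"))
  d <- ar$pair_distances
  if (length(d) == 0L) stop("empty alignment", call. = FALSE)
  m <- min(d)
  list(DP = sum(d - m) / length(d), M_anthro = m)
}

#' Dynamics component of an alignment
#'
#' Measures tempo/rhythm mismatch as the mean absolute change of the
#' matched-frame index offset along the alignment path:
#' \deqn{D_T = \frac{1}{N_b} \sum_{i\ge 1}
#'   \left| (b_i - r_i) - (b_{i-1} - r_{i-1}) \right|,}
#' which equals the total variation of the shift sequence divided by the
#' base length. A constant time delay inside the window therefore carries
#' no dynamics penalty.
#'
#' @param ar An [alignment_result][align_sequences()].
#' @return Nonnegative scalar `DT`.
#' @export
dynamics_component <- function(ar) {
  stopifnot(inherits(ar, "alignment_result"))
  if (ar$n_base < 2L) stop("dynamics component needs at least 2 aligned pairs",
                           call. = FALSE)
  off <- ar$base_frames - ar$ref_frames   # = -shifts
  sum(abs(diff(off))) / ar$n_base
}

#' Dynamics component with an intensity penalty
#'
#' Augments [dynamics_component()] with a penalty for under-vigorous
#' execution: `DT + beta * (E_max - E_r)`, where `E_r` is the patient
#' record's [intensity()] and `E_max` the maximum intensity in the
#' dataset. With `beta = 0` (the default elsewhere in the package) this
#' reduces to the plain dynamics component.
#'
#' @param ar An [alignment_result][align_sequences()].
#' @param E_r Patient record intensity (`0 <= E_r <= E_max`).
#' @param E_max Maximum intensity in the dataset.
#' @param beta Nonnegative penalty coefficient.
#' @return Nonnegative scalar.
#' @export
dynamics_with_intensity <- function(ar, E_r, E_max, beta) {
  stopifnot(is.numeric(E_r), is.numeric(E_max), is.numeric(beta), beta >= 0,
            E_r >= 0)
  if (E_r > E_max) stop("E_r exceeds E_max", call. = FALSE)
  dynamics_component(ar) + beta * (E_max - E_r)
}

#' Combine posture and dynamics into one distance
#'
#' Linear combination `D = DP + alpha * DT`.
#'
#' @param DP,DT Posture and dynamics components (vectorized).
#' @param alpha Nonnegative balancing coefficient.
#' @return Combined distance.
#' @seealso [project_score()] for the angle parameterization
#'   (`alpha = tan(phi)` induces the same record ordering).
#' @export
combine_score <- function(DP, DT, alpha) {
  stopifnot(is.numeric(alpha), all(alpha >= 0))
  DP + alpha * DT
}

#' Project a record onto the balancing axis
#'
#' `D = DP * cos(phi) + DT * sin(phi)`, the projection of the record's
#' (DP, DT) point onto the axis through the origin at angle `phi` (in
#' degrees, `0 <= phi < 90`). For `cos(phi) > 0` this induces the same
#' ordering of records as [combine_score()] with `alpha = tan(phi)`.
#'
#' @param DP,DT Posture and dynamics components (vectorized).
#' @param phi_degrees Angle in degrees, in `[0, 90)`.
#' @return Projected distance.
#' @export
project_score <- function(DP, DT, phi_degrees) {
  stopifnot(is.numeric(phi_degrees), length(phi_degrees) == 1L)
  if (phi_degrees < 0 || phi_degrees >= 90) {
    stop("phi must lie in [0, 90) degrees", call. = FALSE)
  }
  DP * cospi(phi_degrees / 180) + DT * sinpi(phi_degrees / 180)
}

#' Compare a patient record against an instructor record
#'
#' Runs the full pipeline for one pair of recordings: normalize both
#' sequences, derive attention weights from the instructor, pick the
#' shorter recording as the alignment base, align, and decompose the
#' aligned dissimilarity into the posture component `DP` (with the
#' anthropometric offset `M_anthro` removed) and the dynamics component
#' `DT`. Combination into a single number is deferred until a balancing
#' angle/coefficient is chosen (see [project_score()], [optimize_phi()]).
#'
#' @param instructor_seq,patient_seq [skeleton_sequence()] objects (raw or
#'   already normalized).
#' @param params An [alignment_params()].
#' @param normalize Normalize both sequences first? Default `TRUE`.
#' @param squared Use the root-free pose distance? Default `FALSE`.
#' @param legacy_uncorrected If `TRUE`, compute the historical uncorrected
#'   form (no anthropometric subtraction and the raw total variation of
#'   the offsets for the dynamics term). Default `FALSE`; the corrected
#'   form is canonical.
#' @return An object of class `"score_decomposition"`: `DP`, `DT`,
#'   `M_anthro`, base length `n_base`, the `alignment`, and the weight set.
#' @export
#' @examples
#' ins <- generate_instructor(exercise_template("standing"))
#' sc <- compare_records(ins, ins)
#' c(sc$DP, sc$DT)  # 0 0
compare_records <- function(instructor_seq, patient_seq,
                            params = alignment_params(),
                            normalize = TRUE, squared = FALSE,
                            legacy_uncorrected = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (normalize) {
    instructor_seq <- stage("normalize instructor", normalize_sequence(instructor_seq))
    patient_seq <- stage("normalize patient", normalize_sequence(patient_seq))
  }
  W <- stage("attention weights", attention_weights(instructor_seq))
  cb <- choose_base(instructor_seq, patient_seq)
  ar <- stage("align", align_sequences(cb$base, cb$ref, W, params, squared = squared))
  if (legacy_uncorrected) {
    d <- ar$pair_distances
    DP <- sum(d) / length(d)
    M <- 0
    DT <- sum(abs(diff(ar$base_frames - ar$ref_frames)))
  } else {
    pc <- stage("posture component", posture_component(ar))
    DP <- pc$DP
    M <- pc$M_anthro
    DT <- stage("dynamics component", dynamics_component(ar))
  }
  structure(
    list(DP = DP, DT = DT, M_anthro = M, n_base = ar$n_base,
         loss = ar$loss, alignment = ar, weights = W,
         base_is_instructor = !cb$swapped,
         instructor_meta = instructor_seq$meta, patient_meta = patient_seq$meta),
    class = "score_decomposition"
  )
}

#' @export
print.score_decomposition <- function(x, ...) {
  cat(sprintf("<score_decomposition> DP = %.6g, DT = %.6g, M_anthro = %.6g (Nb = %d)\n",
              x$DP, x$DT, x$M_anthro, x$n_base))
  invisible(x)
}

#' Scale scores per exercise group for joint display
#'
#' For plotting records of different exercises (e.g. sitting and standing)
#' in one DP-DT plane, each exercise group's axes are divided by that
#' group's standard deviation of the patient points. The instructor's
#' reference record sits at the origin of each group's plane by
#' construction (its self-distance decomposition is (0, 0)), and stays
#' there after scaling, so groups share a common origin.
#'
#' @param scores A data frame with at least columns `DP`, `DT` and a
#'   grouping column.
#' @param group Name of the grouping column. Default `"position"`.
#' @return `scores` with added columns `DP_scaled`, `DT_scaled`.
#' @export
scale_scores <- function(scores, group = "position") {
  stopifnot(is.data.frame(scores), all(c("DP", "DT", group) %in% names(scores)))
  scores$DP_scaled <- NA_real_
  scores$DT_scaled <- NA_real_
  for (g in unique(scores[[group]])) {
    sel <- scores[[group]] == g
    sdp <- stats::sd(scores$DP[sel])
    sdt <- stats::sd(scores$DT[sel])
    scores$DP_scaled[sel] <- scores$DP[sel] / ifelse(sdp > 0, sdp, 1)
    scores$DT_scaled[sel] <- scores$DT[sel] / ifelse(sdt > 0, sdt, 1)
  }
  scores
}

#' Plot the DP-DT score plane
#'
#' Scatter of patient records in the posture/dynamics plane, with the
#' instructor reference at the origin. Following the display convention
#' for this decomposition, the ordinate (DT) is multiplied by 10 for
#' legibility — a plotting-only convention, never applied in scoring. If
#' `file` ends in `.svg` or `.png` the plot is written there.
#'
#' @param scores Data frame with columns `DP`, `DT`, `label` and
#'   optionally `position`.
#' @param dt_scale Ordinate magnification. Default 10.
#' @param phi Optional balancing angle (degrees); if given, the balancing
#'   axis is drawn.
#' @param file Optional output path (`.svg` or `.png`).
#' @param scale_by_group Divide each position group's axes by its standard
#'   deviation before plotting? Default `TRUE` when a `position` column is
#'   present.
#' @return The plotted data frame, invisibly.
#' @export
plot_score_plane <- function(scores, dt_scale = 10, phi = NULL, file = NULL,
                             scale_by_group = "position" %in% names(scores)) {
  stopifnot(is.data.frame(scores), all(c("DP", "DT", "label") %in% names(scores)))
  df <- scores
  if (scale_by_group) {
    df <- scale_scores(df)
    x <- df$DP_scaled; y <- df$DT_scaled * dt_scale
  } else {
    x <- df$DP; y <- df$DT * dt_scale
  }
  if (!is.null(file)) {
    ext <- tolower(sub(".*\\.", "", file))
    switch(ext,
           svg = grDevices::svg(file, width = 7, height = 6),
           png = grDevices::png(file, width = 900, height = 780, res = 130),
           stop("file must end in .svg or .png", call. = FALSE))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- c(good = "forestgreen", intermediate = "royalblue", bad = "firebrick",
            reference = "purple")
  pchs <- c(sitting = 16, standing = 17)
  pch <- if ("position" %in% names(df)) pchs[df$position] else 16
  graphics::plot(x, y, col = cols[df$label], pch = pch,
                 xlab = "DP (posture)", ylab = sprintf("DT x %g (dynamics)", dt_scale),
                 main = "Posture-dynamics score plane")
  graphics::points(0, 0, pch = 8, col = "purple", cex = 1.5)
  if (!is.null(phi)) {
    graphics::abline(0, tanpi(phi / 180) * dt_scale, col = "steelblue", lty = 2)
  }
  graphics::legend("topright", bty = "n",
                   legend = names(cols), col = cols, pch = 15)
  invisible(df)
}
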