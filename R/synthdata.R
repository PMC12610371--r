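# Synthetic rehabilitation-study generator. Emulates the study design the
# scoring pipeline targets: one instructor reference per exercise position
# plus, per participant, three renditions at graded accuracy levels
# (good / intermediate / bad) that differ in movement amplitude, tempo,
# start delay, pose noise and anthropometry.

.STANDING_POSE <- matrix(c(
  #  x,     y,     z
   0.00, 1.00, 0.00,   # pelvis
   0.00, 1.15, 0.00,   # spine_navel
   0.00, 1.30, 0.00,   # spine_chest
   0.00, 1.45, 0.00,   # neck
   0.00, 1.58, 0.00,   # head
   0.20, 1.40, 0.00,   # l_shoulder
   0.26, 1.12, 0.00,   # l_elbow
   0.28, 0.86, 0.00,   # l_wrist
  -0.20, 1.40, 0.00,   # r_shoulder
  -0.26, 1.12, 0.00,   # r_elbow
  -0.28, 0.86, 0.00,   # r_wrist
   0.12, 0.95, 0.00,   # l_hip
   0.13, 0.52, 0.00,   # l_knee
   0.13, 0.10, 0.00,   # l_ankle
  -0.12, 0.95, 0.00,   # r_hip
  -0.13, 0.52, 0.00,   # r_knee
  -0.13, 0.10, 0.00    # r_ankle
), ncol = 3, byrow = TRUE)

.SITTING_POSE <- local({
  p <- .STANDING_POSE
  p[, 2] <- p[, 2] - 0.35                 # lowered trunk
  p[12:17, 2] <- c(0.62, 0.60, 0.18, 0.62, 0.60, 0.18)
  p[12:17, 3] <- c(0.05, 0.42, 0.45, 0.05, 0.42, 0.45)  # knees forward
  p
})

#' Harmonic motion template
#'
#' A surrogate exercise: a fixed base pose plus a set of harmonic
#' displacement terms, each moving one coordinate of one joint as
#' `amplitude * sin(2 pi frequency t + phase)`.
#'
#' @param base_pose `17 x 3` matrix of resting joint coordinates.
#' @param moves Data frame with columns `joint` (0-based standard index),
#'   `coord` (`"x"`, `"y"` or `"z"`), `amplitude`, `frequency` (Hz),
#'   `phase` (radians). At least one amplitude must be nonzero.
#' @param duration Exercise duration in seconds.
#' @param fps Frames per second. `duration * fps` must be at least 10.
#' @return An object of class `"motion_template"`.
#' @seealso [exercise_template()] for the two shipped surrogates.
#' @export
motion_template <- function(base_pose, moves, duration = 8, fps = 10) {
  .check_frame(base_pose, "base_pose")
  stopifnot(is.data.frame(moves),
            all(c("joint", "coord", "amplitude", "frequency", "phase")
                %in% names(moves)))
  if (nrow(moves) == 0L || all(moves$amplitude == 0)) {
    stop("template must contain at least one nonzero-amplitude term",
         call. = FALSE)
  }
  if (any(moves$joint < 0 | moves$joint >= .K) ||
      !all(moves$coord %in% c("x", "y", "z"))) {
    stop("moves reference an invalid joint or coordinate", call. = FALSE)
  }
  if (duration * fps < 10) stop("template must span at least 10 frames",
                                call. = FALSE)
  structure(list(base_pose = base_pose, moves = moves,
                 duration = duration, fps = fps),
            class = "motion_template")
}

#' Shipped exercise surrogates
#'
#' Two generic harmonic exercises: a standing bilateral arm raise (wrists
#' and elbows oscillate vertically and slightly laterally) and a sitting
#' forward reach (arms and chest oscillate along z). Amplitudes are in
#' the raw pose units of the built-in base poses (total bone length about
#' 3.1, so roughly a third of the amplitude survives normalization).
#'
#' @param position `"standing"` or `"sitting"`.
#' @return A [motion_template()].
#' @export
exercise_template <- function(position = c("standing", "sitting")) {
  position <- match.arg(position)
  if (position == "standing") {
    moves <- data.frame(
      joint = c(7L, 10L, 6L, 9L, 7L, 10L),
      coord = c("y", "y", "y", "y", "x", "x"),
      amplitude = c(0.30, 0.30, 0.15, 0.15, 0.08, -0.08),
      frequency = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
      phase = c(0, 0, 0, 0, pi / 2, pi / 2)
    )
    motion_template(.STANDING_POSE, moves, duration = 8, fps = 10)
  } else {
    moves <- data.frame(
      joint = c(7L, 10L, 6L, 9L, 2L),
      coord = c("z", "z", "z", "z", "z"),
      amplitude = c(0.28, 0.28, 0.14, 0.14, 0.05),
      frequency = c(0.4, 0.4, 0.4, 0.4, 0.4),
      phase = c(0, 0, 0, 0, 0)
    )
    motion_template(.SITTING_POSE, moves, duration = 8, fps = 10)
  }
}

#' Impairment profile
#'
#' Degradation parameters for one synthetic rendition: amplitude
#' attenuation about the mean pose, tempo change, start delay, additive
#' pose noise, and an anthropometric rescale (undone by normalization
#' downstream, which is precisely what the anthropometric correction is
#' meant to absorb).
#'
#' @param amplitude_factor In `(0, 1]`: 1 keeps the instructor's movement
#'   amplitude, smaller values attenuate it.
#' @param tempo_factor Positive: 1 keeps the pace; smaller is slower
#'   (longer recording).
#' @param start_delay Nonnegative integer; the first pose is held this
#'   many extra frames.
#' @param pose_noise_sd Standard deviation of i.i.d. Gaussian coordinate
#'   noise, in normalized units.
#' @param anthropometric_scale Positive uniform body-size factor.
#' @param level Label: `"good"`, `"intermediate"`, `"bad"` or custom.
#' @return An object of class `"impairment_profile"`.
#' @export
impairment_profile <- function(amplitude_factor = 1, tempo_factor = 1,
                               start_delay = 0L, pose_noise_sd = 0,
                               anthropometric_scale = 1,
                               level = "unlabeled") {
  stopifnot(amplitude_factor > 0, amplitude_factor <= 1,
            tempo_factor > 0, start_delay >= 0,
            start_delay == floor(start_delay),
            pose_noise_sd >= 0, anthropometric_scale > 0)
  structure(list(amplitude_factor = amplitude_factor,
                 tempo_factor = tempo_factor,
                 start_delay = as.integer(start_delay),
                 pose_noise_sd = pose_noise_sd,
                 anthropometric_scale = anthropometric_scale,
                 level = level),
            class = "impairment_profile")
}

#' Shipped three-level impairment presets
#'
#' Reads the versioned preset configuration from the package's
#' `extdata/impairment_presets.json`. The presets satisfy the
#' monotone-degradation regime: amplitude factors decrease and noise
#' levels increase from `"good"` to `"bad"`, so mean motion intensity is
#' ordered good > intermediate > bad and the score pipeline can recover
#' the accuracy ranking.
#'
#' @return A list with `levels` (named list of [impairment_profile()]
#'   objects), per-level `jitter` ranges, and the participant
#'   `anthropometric_scale_range`.
#' @export
impairment_presets <- function() {
  cfg <- jsonlite::read_json(
    system.file("extdata", "impairment_presets.json", package = "hsbtw",
                mustWork = TRUE),
    simplifyVector = TRUE)
  levels <- lapply(names(cfg$levels), function(nm) {
    lv <- cfg$levels[[nm]]
    impairment_profile(lv$amplitude_factor, lv$tempo_factor, lv$start_delay,
                       lv$pose_noise_sd, 1, level = nm)
  })
  names(levels) <- names(cfg$levels)
  jitter <- lapply(cfg$levels, function(lv) {
    list(amplitude = lv$amplitude_jitter, tempo = lv$tempo_jitter,
         delay = lv$start_delay_range)
  })
  list(levels = levels, jitter = jitter,
       anthropometric_scale_range = cfg$anthropometric_scale_range,
       version = cfg$version)
}

#' Generate an instructor reference recording
#'
#' Samples the template's harmonic motion noise-free at the template's
#' frame rate. The output is deterministic: the same template always
#' yields the same sequence (the `seed` argument is accepted for API
#' symmetry with [degrade()] but no randomness is involved).
#'
#' @param template A [motion_template()].
#' @param seed Ignored (the reference is noise-free).
#' @param position Stored in the sequence metadata.
#' @return A [skeleton_sequence()] labeled `"reference"`.
#' @export
generate_instructor <- function(template, seed = NULL, position = NA_character_) {
  stopifnot(inherits(template, "motion_template"))
  n <- round(template$duration * template$fps)
  t <- (seq_len(n) - 1L) / template$fps
  coords <- aperm(array(template$base_pose, c(.K, 3L, n)), c(3L, 1L, 2L))
  ci <- c(x = 1L, y = 2L, z = 3L)
  for (r in seq_len(nrow(template$moves))) {
    mv <- template$moves[r, ]
    coords[, mv$joint + 1L, ci[[mv$coord]]] <-
      coords[, mv$joint + 1L, ci[[mv$coord]]] +
      mv$amplitude * sin(2 * pi * mv$frequency * t + mv$phase)
  }
  skeleton_sequence(coords, fps = template$fps, person = "instructor",
                    position = position, label = "reference")
}

#' Degrade a reference recording into a simulated patient rendition
#'
#' Applies, in this fixed order: (1) uniform anthropometric rescale about
#' the pelvis; (2) tempo resampling by linear interpolation of each joint
#' trajectory (`tempo_factor < 1` slows the motion down, lengthening the
#' recording); (3) a start delay, holding the first pose for
#' `start_delay` extra frames; (4) amplitude attenuation of every
#' coordinate about its temporal mean; (5) i.i.d. Gaussian pose noise.
#' Each step exercises one stage of the scoring pipeline: the rescale is
#' absorbed by normalization and the anthropometric correction, the tempo
#' change by base selection and the shift path, the delay by the shift
#' window.
#'
#' @param instructor_seq The reference [skeleton_sequence()].
#' @param profile An [impairment_profile()].
#' @param seed Optional integer seed for the noise draw.
#' @param window Declared alignment window; a warning is issued when the
#'   start delay exceeds `window / 2` (such a recording cannot be aligned
#'   loss-free).
#' @return A degraded [skeleton_sequence()] labeled with the profile level.
#' @export
degrade <- function(instructor_seq, profile, seed = NULL, window = 60L) {
  stopifnot(inherits(instructor_seq, "skeleton_sequence"),
            inherits(profile, "impairment_profile"))
  if (!is.null(seed)) set.seed(seed)
  if (profile$start_delay > window / 2) {
    warning(sprintf("start delay %d exceeds half the declared window (%d); alignment will be lossy",
                    profile$start_delay, as.integer(window)))
  }
  co <- instructor_seq$coords
  n <- dim(co)[1]
  # (1) anthropometric rescale about the pelvis
  if (profile$anthropometric_scale != 1) {
    pelvis <- co[, rep(1L, .K), ]
    co <- pelvis + profile$anthropometric_scale * (co - pelvis)
  }
  # (2) tempo resampling
  if (profile$tempo_factor != 1) {
    m <- max(2L, as.integer(round(n / profile$tempo_factor)))
    src <- seq(0, n - 1L, length.out = m)
    flat <- .flatten_coords(co)
    flat <- apply(flat, 2L, function(v) stats::approx(0:(n - 1L), v, xout = src)$y)
    co <- .unflatten_coords(flat)
  }
  # (3) start delay: hold the first pose
  if (profile$start_delay > 0L) {
    co <- .unflatten_coords(rbind(
      matrix(rep(.flatten_coords(co)[1L, ], profile$start_delay),
             nrow = profile$start_delay, byrow = TRUE),
      .flatten_coords(co)))
  }
  # (4) amplitude attenuation about the temporal mean pose
  if (profile$amplitude_factor != 1) {
    mu <- colMeans(co, dims = 1L)
    co <- sweep(co, c(2L, 3L), mu) * profile$amplitude_factor +
      aperm(array(mu, c(.K, 3L, dim(co)[1])), c(3L, 1L, 2L))
  }
  # (5) pose noise
  if (profile$pose_noise_sd > 0) {
    co <- co + array(stats::rnorm(length(co), 0, profile$pose_noise_sd), dim(co))
  }
  skeleton_sequence(co, fps = instructor_seq$fps,
                    person = instructor_seq$meta$person,
                    exercise = instructor_seq$meta$exercise,
                    position = instructor_seq$meta$position,
                    label = profile$level)
}

#' Generate a synthetic rehabilitation study
#'
#' Builds the full study design the scoring pipeline assumes: per
#' position, one instructor reference plus, for each participant, three
#' renditions at the preset accuracy levels with participant-specific
#' random anthropometry and per-record jitter of the profile parameters.
#' With 22 participants and both positions this yields 2 references and
#' 132 labeled patient records. Identical seeds give identical studies.
#'
#' @param n_participants Number of participants. Default 22.
#' @param positions Character vector of exercise positions.
#' @param presets Preset structure from [impairment_presets()].
#' @param seed Integer seed driving every random draw.
#' @param dir If non-`NULL`, the study is also written there: one
#'   csv-wide file (plus JSON sidecar) per record and a `manifest.json`
#'   with the per-record generation parameters.
#' @param instructor_repeat Also generate a noise-free near-identical
#'   instructor repeat per position (small good-level jitter), mirroring
#'   a reference-repeatability check? Default `FALSE`.
#' @return An object of class `"hsbtw_study"`: `instructors` (named by
#'   position), `records` (list of sequences), and `manifest` (data
#'   frame of generation parameters).
#' @export
generate_study <- function(n_participants = 22L,
                           positions = c("sitting", "standing"),
                           presets = impairment_presets(),
                           seed = 1L, dir = NULL,
                           instructor_repeat = FALSE) {
  set.seed(seed)
  instructors <- lapply(positions, function(pos) {
    ins <- generate_instructor(exercise_template(pos), position = pos)
    ins$meta$exercise <- pos
    ins
  })
  names(instructors) <- positions
  records <- list()
  manifest <- list()
  for (k in seq_len(n_participants)) {
    person <- sprintf("P%02d", k)
    anthro <- stats::runif(1, presets$anthropometric_scale_range[1],
                           presets$anthropometric_scale_range[2])
    for (pos in positions) {
      for (lv in names(presets$levels)) {
        base <- presets$levels[[lv]]
        jit <- presets$jitter[[lv]]
        prof <- impairment_profile(
          amplitude_factor = min(1, base$amplitude_factor *
                                   stats::runif(1, jit$amplitude[1], jit$amplitude[2])),
          tempo_factor = base$tempo_factor *
            stats::runif(1, jit$tempo[1], jit$tempo[2]),
          start_delay = sample(jit$delay[1]:jit$delay[2], 1L),
          pose_noise_sd = base$pose_noise_sd,
          anthropometric_scale = anthro,
          level = lv
        )
        rec <- degrade(instructors[[pos]], prof)
        rec$meta$person <- person
        rec$meta$exercise <- pos
        rec$meta$person_record_id <- sprintf("%s_%s_%s", person, pos, lv)
        records[[length(records) + 1L]] <- rec
        manifest[[length(manifest) + 1L]] <- data.frame(
          record_id = rec$meta$person_record_id, person = person,
          position = pos, label = lv,
          amplitude_factor = prof$amplitude_factor,
          tempo_factor = prof$tempo_factor,
          start_delay = prof$start_delay,
          pose_noise_sd = prof$pose_noise_sd,
          anthropometric_scale = prof$anthropometric_scale,
          n_frames = nframes(rec)
        )
      }
    }
  }
  if (instructor_repeat) {
    for (pos in positions) {
      prof <- impairment_profile(amplitude_factor = 0.995, tempo_factor = 1,
                                 start_delay = 1L, pose_noise_sd = 0,
                                 anthropometric_scale = 1,
                                 level = "reference")
      rep_rec <- degrade(instructors[[pos]], prof)
      rep_rec$meta$person <- "instructor_repeat"
      rep_rec$meta$exercise <- pos
      rep_rec$meta$person_record_id <- sprintf("instructor_repeat_%s", pos)
      records[[length(records) + 1L]] <- rep_rec
    }
  }
  study <- structure(
    list(instructors = instructors, records = records,
         manifest = do.call(rbind, manifest), seed = seed),
    class = "hsbtw_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.hsbtw_study <- function(x, ...) {
  cat(sprintf("<hsbtw_study> %d instructor reference(s), %d patient records (seed %s)\n",
              length(x$instructors), length(x$records), format(x$seed)))
  invisible(x)
}

#' Write a study to a directory
#'
#' One csv-wide file (with JSON metadata sidecar) per instructor and
#' record, plus `manifest.json` carrying the per-record generation
#' parameters (for parameter-recovery tests).
#'
#' @param study An `"hsbtw_study"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "hsbtw_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pos in names(study$instructors)) {
    save_sequence(study$instructors[[pos]],
                  file.path(dir, sprintf("instructor_%s.csv", pos)), "csv-wide")
  }
  for (rec in study$records) {
    save_sequence(rec, file.path(dir, paste0(rec$meta$person_record_id, ".csv")),
                  "csv-wide")
  }
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a study directory
#'
#' Inverse of [write_study()].
#'
#' @param dir Directory produced by [write_study()] /
#'   [generate_study()]`(dir = ...)`.
#' @return An `"hsbtw_study"`.
#' @export
load_study <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  ins_files <- list.files(dir, pattern = "^instructor_.*\\.csv$",
                          full.names = TRUE)
  instructors <- lapply(ins_files, load_sequence, dialect = "csv-wide")
  names(instructors) <- sub("^instructor_(.*)\\.csv$", "\\1", basename(ins_files))
  records <- lapply(seq_len(nrow(mf)), function(i) {
    rec <- load_sequence(file.path(dir, paste0(mf$record_id[i], ".csv")),
                         dialect = "csv-wide")
    rec$meta$person_record_id <- mf$record_id[i]
    rec
  })
  structure(list(instructors = instructors, records = records,
                 manifest = mf, seed = NA_integer_),
            class = "hsbtw_study")
}
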