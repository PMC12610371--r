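# Shared fixture builders. Everything is generated in code; no data files.

# A random non-degenerate skeleton frame.
random_frame <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(17 * 3), 17, 3)
}

# A random sequence of normalized-ish frames (valid, finite, N >= 2).
random_sequence <- function(n = 5, seed = NULL, fps = 30, ...) {
  if (!is.null(seed)) set.seed(seed)
  co <- array(rnorm(n * 17 * 3), c(n, 17, 3))
  skeleton_sequence(co, fps = fps, ...)
}

# A smooth deterministic motion: base pose plus a sine on a few joints.
# Useful when tests need motion that is neither static nor random.
smooth_sequence <- function(n = 40, fps = 10, amplitude = 0.3, freq = 0.5,
                            joints = c(8, 11), coord = 2) {
  tmpl <- exercise_template("standing")
  co <- aperm(array(tmpl$base_pose, c(17, 3, n)), c(3, 1, 2))
  t <- (seq_len(n) - 1) / fps
  for (j in joints) {
    co[, j, coord] <- co[, j, coord] + amplitude * sin(2 * pi * freq * t)
  }
  skeleton_sequence(co, fps = fps)
}

# Uniform weights over all 51 coordinates.
uniform_weights <- function() {
  w <- matrix(1 / 51, 17, 3)
  structure(list(w = w, sigma = w), class = "weight_set")
}

# Small random alignment instance for DP-vs-oracle checks.
random_instance <- function(seed) {
  set.seed(seed)
  nb <- sample(2:8, 1)
  nr <- sample(nb:12, 1)
  w <- sample(c(0, 2, 4), 1)
  q <- sample(c(0, 0.01, 0.1, 1), 1)
  list(
    base = random_sequence(nb),
    ref = random_sequence(nr),
    W = uniform_weights(),
    params = alignment_params(w, q)
  )
}
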