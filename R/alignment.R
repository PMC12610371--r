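# Shift-window temporal alignment. Each frame i of the base (shorter)
# sequence is matched to frame i + v_i of the reference sequence, with the
# integer shift v_i restricted to a symmetric window {-w/2, ..., w/2}.
# The shift sequence minimizes
#   J(V) = sum_i d(base_i, ref_{i+v_i}) + sum_{i>=1} gamma(v_{i-1}, v_i),
# where gamma is a quadratic smoothness penalty on shift increments and
# transitions that would cross matched frames (v_i < v_{i-1} - 1) are
# excluded outright. The minimization is a dynamic program over the chain
# of per-frame shift states, linear in the base length; an exhaustive
# enumeration oracle with identical arithmetic and tie-breaking is
# provided for testing.

#' Alignment parameters
#'
#' @param window Shift window width `w` (even, nonnegative integer).
#'   Admissible per-frame shifts are `-w/2, ..., w/2`; the window absorbs
#'   start/end delays between the two recordings. Default 60 frames
#'   (about 2 s at 30 fps).
#' @param smoothness Quadratic penalty coefficient `q` applied to squared
#'   shift increments, in units of the (normalized) pose distance.
#'   Default 0.01, chosen so that one unit shift step costs about as much
#'   as one typical frame of pose mismatch (0.01-0.05 in normalized
#'   units); much larger values freeze the shift path and leave the
#'   dynamics component with no signal.
#' @return An object of class `"alignment_params"`.
#' @export
alignment_params <- function(window = 60L, smoothness = 0.01) {
  if (!is.numeric(window) || length(window) != 1L || window < 0 ||
      window != floor(window) || window %% 2 != 0) {
    stop("window must be an even nonnegative integer", call. = FALSE)
  }
  if (!is.numeric(smoothness) || length(smoothness) != 1L || smoothness < 0) {
    stop("smoothness must be a nonnegative number", call. = FALSE)
  }
  structure(list(window = as.integer(window), smoothness = as.numeric(smoothness)),
            class = "alignment_params")
}

#' Choose base and reference sequence
#'
#' The shorter of the two sequences becomes the base (every base frame is
#' matched); the longer becomes the reference. On equal lengths the first
#' argument is the base (documented tie-break).
#'
#' @param seq_a,seq_b Two [skeleton_sequence()] objects.
#' @return A list with `base`, `ref`, and `swapped` (`TRUE` if `seq_b` is
#'   the base).
#' @export
choose_base <- function(seq_a, seq_b) {
  stopifnot(inherits(seq_a, "skeleton_sequence"),
            inherits(seq_b, "skeleton_sequence"))
  if (nframes(seq_a) <= nframes(seq_b)) {
    list(base = seq_a, ref = seq_b, swapped = FALSE)
  } else {
    list(base = seq_b, ref = seq_a, swapped = TRUE)
  }
}

#' Transition penalty between consecutive shifts
#'
#' The smoothness term gamma(v_prev, v_cur): `q * (v_cur - v_prev)^2` when
#' the transition keeps matched reference frames in temporal order
#' (`v_cur >= v_prev - 1`), and `Inf` for a crossing transition. Crossing
#' transitions are excluded from the search outright (equivalent to an
#' arbitrarily large finite penalty, and numerically safer).
#'
#' @param v_prev,v_cur Integer shifts (vectorized).
#' @param params An [alignment_params()].
#' @return Numeric penalty vector.
#' @export
#' @examples
#' transition_penalty(0, 2, alignment_params(smoothness = 0.5))  # 2
#' transition_penalty(3, 1, alignment_params())                  # Inf
transition_penalty <- function(v_prev, v_cur, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  ifelse(v_cur >= v_prev - 1, params$smoothness * (v_cur - v_prev)^2, Inf)
}

.alignment_result <- function(shifts, pair_distances, loss, Nr, params) {
  nb <- length(shifts)
  stopifnot(all(diff(shifts) >= -1))  # no-crossing invariant
  structure(
    list(
      shifts = as.integer(shifts),
      base_frames = 0:(nb - 1L),
      ref_frames = 0:(nb - 1L) + as.integer(shifts),
      pair_distances = as.numeric(pair_distances),
      loss = loss,
      n_base = nb,
      n_ref = as.integer(Nr),
      params = params
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d base frames vs %d reference frames\n",
              x$n_base, x$n_ref))
  cat(sprintf("  loss = %.6g; shifts in [%d, %d]; mean pair distance = %.6g\n",
              x$loss, min(x$shifts), max(x$shifts), mean(x$pair_distances)))
  invisible(x)
}

# Per-base-frame state costs: d(base_i, ref_{i+v}) for each shift v,
# Inf where i+v falls outside the reference.
.state_costs <- function(D, i, shifts, Nr) {
  j <- i + shifts
  out <- rep(Inf, length(shifts))
  ok <- j >= 1L & j <= Nr
  out[ok] <- D[i, j[ok]]
  out
}

#' Align a base sequence to a reference sequence
#'
#' Finds the shift sequence `V` minimizing the alignment loss (pose
#' distance along the matched pairs plus the smoothness penalty) by
#' dynamic programming over the per-frame shift states. Complexity is
#' `O(Nb * (w+1)^2)` transitions — linear in the base length at fixed
#' window.
#'
#' Out-of-range shifts (`i + v` outside the reference) are infeasible
#' states, not penalized states. Ties are broken deterministically by
#' preferring the smallest shift value at each backtrack step; the same
#' rule is used by [brute_force_align()].
#'
#' @param base,ref Normalized [skeleton_sequence()] objects with
#'   `nframes(base) <= nframes(ref)`.
#' @param W A [weight_set][attention_weights()] derived from the
#'   instructor.
#' @param params An [alignment_params()].
#' @param squared Use the root-free pose distance? Default `FALSE`.
#' @return An object of class `"alignment_result"`: integer `shifts`,
#'   0-based `base_frames` and `ref_frames`, `pair_distances`, and the
#'   achieved `loss`.
#' @export
align_sequences <- function(base, ref, W, params = alignment_params(),
                            squared = FALSE) {
  stopifnot(inherits(base, "skeleton_sequence"),
            inherits(ref, "skeleton_sequence"),
            inherits(W, "weight_set"),
            inherits(params, "alignment_params"))
  nb <- nframes(base); nr <- nframes(ref)
  if (nb > nr) stop("base sequence must not be longer than the reference; see choose_base()",
                    call. = FALSE)
  half <- params$window %/% 2L
  shifts <- seq.int(-half, half)
  ns <- length(shifts)
  D <- .pair_distances(base$coords, ref$coords, W, squared = squared)
  # feasibility: every base frame needs at least one in-range shift
  for (i in seq_len(nb)) {
    if (i + shifts[ns] < 1L || i + shifts[1L] > nr) {
      stop(sprintf("no admissible shift for base frame %d; enlarge the window or trim the sequences",
                   i - 1L), call. = FALSE)
    }
  }
  q <- params$smoothness
  # trans[vp, vc]
  trans <- outer(shifts, shifts,
                 function(vp, vc) ifelse(vc >= vp - 1, q * (vc - vp)^2, Inf))
  f <- .state_costs(D, 1L, shifts, nr)
  back <- matrix(NA_integer_, nb, ns)
  if (nb >= 2L) {
    for (i in 2:nb) {
      m <- f + trans                       # [vp, vc] = f[vp] + trans[vp, vc]
      k <- max.col(-t(m), ties.method = "first")  # smallest-shift tie-break
      f <- m[cbind(k, seq_len(ns))] + .state_costs(D, i, shifts, nr)
      back[i, ] <- k
    }
  }
  if (!any(is.finite(f))) {
    stop("alignment infeasible: no admissible shift path; enlarge the window",
         call. = FALSE)
  }
  idx <- integer(nb)
  idx[nb] <- which.min(f)                  # first minimum = smallest shift
  if (nb >= 2L) {
    for (i in nb:2) idx[i - 1L] <- back[i, idx[i]]
  }
  v <- shifts[idx]
  d <- D[cbind(seq_len(nb), seq_len(nb) + v)]
  loss <- f[idx[nb]]
  .alignment_result(v, d, loss, nr, params)
}

#' Exhaustive-search alignment oracle
#'
#' Enumerates every admissible shift sequence (in-range, non-crossing) and
#' returns the global minimizer of the alignment loss, accumulating costs
#' in the same order and with the same tie-break as [align_sequences()]
#' (among equal-loss paths, the one with the smallest shift at the last
#' frame, then the second-to-last, and so on). Intended as an independent
#' correctness oracle on small instances.
#'
#' @inheritParams align_sequences
#' @param max_candidates Guard on the enumeration size `(w+1)^Nb`.
#' @return An `"alignment_result"`, as [align_sequences()].
#' @export
brute_force_align <- function(base, ref, W, params = alignment_params(),
                              squared = FALSE, max_candidates = 1e7) {
  stopifnot(inherits(base, "skeleton_sequence"),
            inherits(ref, "skeleton_sequence"),
            inherits(W, "weight_set"),
            inherits(params, "alignment_params"))
  nb <- nframes(base); nr <- nframes(ref)
  if (nb > nr) stop("base sequence must not be longer than the reference",
                    call. = FALSE)
  half <- params$window %/% 2L
  shifts <- seq.int(-half, half)
  ns <- length(shifts)
  if (ns^nb > max_candidates) {
    stop(sprintf("instance too large for exhaustive search: (w+1)^Nb = %g candidates",
                 ns^nb), call. = FALSE)
  }
  q <- params$smoothness
  D <- .pair_distances(base$coords, ref$coords, W, squared = squared)
  feasible <- function(i) shifts[i + shifts >= 1L & i + shifts <= nr]
  v1 <- feasible(1L)
  if (length(v1) == 0L) stop("no admissible shift for base frame 0", call. = FALSE)
  paths <- matrix(v1, ncol = 1L)
  costs <- D[cbind(1L, 1L + v1)]
  if (nb >= 2L) {
    for (i in 2:nb) {
      vi <- feasible(i)
      np <- list(); nc <- list()
      for (v in vi) {
        sel <- paths[, i - 1L] <= v + 1L   # v >= v_prev - 1
        if (!any(sel)) next
        vprev <- paths[sel, i - 1L]
        np[[length(np) + 1L]] <- cbind(paths[sel, , drop = FALSE], v)
        nc[[length(nc) + 1L]] <- (costs[sel] + q * (v - vprev)^2) + D[i, i + v]
      }
      if (length(np) == 0L) stop("alignment infeasible: no admissible shift path",
                                 call. = FALSE)
      paths <- do.call(rbind, np)
      costs <- unlist(nc)
    }
  }
  best <- min(costs)
  cand <- which(costs == best)
  if (length(cand) > 1L) {
    # reverse-lexicographic smallest: smallest last shift, then previous, ...
    ord <- do.call(order, lapply(rev(seq_len(nb)),
                                 function(cc) paths[cand, cc]))
    cand <- cand[ord[1L]]
  }
  v <- paths[cand[1L], ]
  d <- D[cbind(seq_len(nb), seq_len(nb) + v)]
  .alignment_result(v, d, best, nr, params)
}
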