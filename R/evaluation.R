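# Ordinal evaluation of the balanced distance: Spearman rank correlation
# per (person, position) group, dataset averaging, exhaustive search over
# the balancing angle, and leave-two-participants-out cross-validation.
#
# Ground truth is ordinal: within each (person, position) group the three
# renditions carry ranks 0 = good, 1 = intermediate, 2 = bad. Predicted
# ranks come from sorting the three records by their balanced distance to
# the instructor's reference.

.check_perm <- function(x, n, what) {
  if (!setequal(x, 0:(n - 1L))) {
    stop(sprintf("%s must be a permutation of 0..%d", what, n - 1L),
         call. = FALSE)
  }
  invisible(x)
}

#' Spearman rank correlation between two rankings
#'
#' \deqn{r_s = 1 - \frac{6 \sum_i d_i^2}{n (n^2 - 1)},}
#' with `d_i` the per-record rank differences. For the three-level design
#' (`n = 3`) this reduces to `1 - sum(d^2) / 4`. Both arguments must be
#' permutations of `0..n-1`; ties are resolved upstream
#' (see [rank_by_distance()]).
#'
#' @param predicted_ranks,true_ranks Integer rank vectors of equal length
#'   `n >= 2`, each a permutation of `0..n-1`.
#' @return The rank correlation, in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rs(c(0, 1, 2), c(0, 1, 2))  #  1
#' spearman_rs(c(2, 1, 0), c(0, 1, 2))  # -1
spearman_rs <- function(predicted_ranks, true_ranks) {
  n <- length(true_ranks)
  if (length(predicted_ranks) != n) stop("rank vectors differ in length",
                                         call. = FALSE)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  .check_perm(predicted_ranks, n, "predicted_ranks")
  .check_perm(true_ranks, n, "true_ranks")
  d <- predicted_ranks - true_ranks
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Predicted ranks of one record group by balanced distance
#'
#' Ranks the three records of one (person, position) group by ascending
#' balanced distance `D = project_score(DP, DT, phi)`. Exact ties are
#' broken by the stable order of `record_id` — a rule blind to the true
#' labels, so the evaluation cannot leak ground truth into predictions.
#'
#' @param group_scores Data frame with exactly 3 rows and columns `DP`,
#'   `DT`, `record_id`.
#' @param phi Balancing angle in degrees.
#' @return Integer vector of predicted ranks (0 = closest to instructor),
#'   in the row order of `group_scores`.
#' @export
rank_by_distance <- function(group_scores, phi) {
  stopifnot(is.data.frame(group_scores),
            all(c("DP", "DT", "record_id") %in% names(group_scores)))
  if (nrow(group_scores) != 3L) {
    stop("a record group must contain exactly 3 records", call. = FALSE)
  }
  ord <- order(group_scores$record_id)
  D <- project_score(group_scores$DP, group_scores$DT, phi)
  r <- integer(3L)
  r[ord] <- rank(D[ord], ties.method = "first")
  r - 1L
}

.split_groups <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("person", "position", "true_rank", "DP", "DT", "record_id")
                %in% names(scores)))
  groups <- split(scores, interaction(scores$person, scores$position,
                                      drop = TRUE))
  for (g in groups) {
    if (nrow(g) != 3L || !setequal(g$true_rank, 0:2)) {
      stop(sprintf("group (%s, %s) must contain exactly one record per rank 0..2",
                   g$person[1], g$position[1]), call. = FALSE)
    }
  }
  groups
}

#' Average rank correlation at a balancing angle
#'
#' Computes the per-group Spearman correlation between predicted and true
#' ranks at angle `phi` and averages it over all (person, position)
#' groups.
#'
#' @param scores Data frame of labeled score decompositions: columns
#'   `person`, `position`, `true_rank` (0/1/2), `DP`, `DT`, `record_id`.
#' @param phi Balancing angle in degrees.
#' @return The mean rank correlation over groups.
#' @export
average_rs_at_phi <- function(scores, phi) {
  groups <- .split_groups(scores)
  mean(vapply(groups, function(g) {
    spearman_rs(rank_by_distance(g, phi), g$true_rank)
  }, numeric(1)))
}

#' Exhaustive search for the balancing angle
#'
#' Scans a grid of angles (default 0..89 degrees in 1-degree steps,
#' excluding the degenerate pure-DT axis at 90), computing the average
#' rank correlation at each. The optimum is typically attained on a
#' plateau of angles; the smallest maximizing angle is returned, a
#' deterministic tie rule.
#'
#' @param scores As in [average_rs_at_phi()].
#' @param grid Numeric vector of candidate angles in `[0, 90)`.
#' @return List with `phi_opt`, `rs_max`, and `rs_curve` (data frame with
#'   columns `phi`, `rs`).
#' @export
optimize_phi <- function(scores, grid = 0:89) {
  if (length(grid) == 0L) stop("empty angle grid", call. = FALSE)
  if (nrow(scores) == 0L) stop("no scores to evaluate", call. = FALSE)
  grid <- sort(grid)
  rs <- vapply(grid, function(phi) average_rs_at_phi(scores, phi), numeric(1))
  best <- which.max(rs)   # first maximum = smallest angle on the plateau
  list(phi_opt = grid[best], rs_max = rs[best],
       rs_curve = data.frame(phi = grid, rs = rs))
}

#' Leave-two-participants-out cross-validation of the balancing angle
#'
#' Randomly partitions the participants into folds (seeded), holds out
#' each fold's records in turn, re-optimizes the balancing angle on the
#' retained records, and reports the fold-optimal angle and the average
#' rank correlation it attains on the retained records. With 22
#' participants, 2 positions and 3 levels, each of the 11 folds holds out
#' 12 records and retains 120.
#'
#' @param scores As in [average_rs_at_phi()].
#' @param n_folds Number of folds. Default 11.
#' @param persons_per_fold Participants held out per fold. Default 2.
#' @param seed Integer seed for the random partition (required; logged in
#'   the output).
#' @param grid Angle grid passed to [optimize_phi()].
#' @return A data frame with one row per fold: `fold`, `excluded`
#'   (comma-separated person ids), `phi_opt`, `avg_rs`, `n_heldout`,
#'   `n_retained`; the seed is attached as attribute `"seed"`.
#' @export
cross_validate <- function(scores, n_folds = 11L, persons_per_fold = 2L,
                           seed, grid = 0:89) {
  stopifnot(!missing(seed))
  .split_groups(scores)  # validates structure
  persons <- sort(unique(scores$person))
  if (length(persons) != n_folds * persons_per_fold) {
    stop(sprintf("%d participants cannot be split into %d folds of %d",
                 length(persons), n_folds, persons_per_fold), call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(persons)
  folds <- split(shuffled, rep(seq_len(n_folds), each = persons_per_fold))
  rows <- lapply(seq_len(n_folds), function(k) {
    held <- sort(folds[[k]])
    retained <- scores[!(scores$person %in% held), , drop = FALSE]
    opt <- optimize_phi(retained, grid)
    data.frame(fold = k, excluded = paste(held, collapse = ","),
               phi_opt = opt$phi_opt, avg_rs = opt$rs_max,
               n_heldout = sum(scores$person %in% held),
               n_retained = nrow(retained))
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Score every record of a study against its instructor
#'
#' Runs [compare_records()] for each labeled record of a synthetic or
#' loaded study against the instructor reference of the matching
#' position, producing the labeled score table consumed by
#' [optimize_phi()] and [cross_validate()].
#'
#' @param study An `"hsbtw_study"` (see [generate_study()], [load_study()]).
#' @param params An [alignment_params()].
#' @param squared Use the root-free pose distance? Default `FALSE`.
#' @return Data frame with columns `record_id`, `person`, `position`,
#'   `label`, `true_rank`, `DP`, `DT`, `M_anthro`.
#' @export
score_study <- function(study, params = alignment_params(), squared = FALSE) {
  stopifnot(inherits(study, "hsbtw_study"))
  ranks <- c(good = 0L, intermediate = 1L, bad = 2L)
  # normalize instructors once; weights are reused across that position
  norm_ins <- lapply(study$instructors, normalize_sequence)
  rows <- lapply(study$records, function(rec) {
    pos <- rec$meta$position
    sc <- compare_records(norm_ins[[pos]], rec, params = params,
                          squared = squared)
    data.frame(record_id = rec$meta$person_record_id %||% NA_character_,
               person = rec$meta$person, position = pos,
               label = rec$meta$label, true_rank = ranks[[rec$meta$label]],
               DP = sc$DP, DT = sc$DT, M_anthro = sc$M_anthro)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$record_id)) {
    out$record_id <- sprintf("%s_%s_%s", out$person, out$position, out$label)
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a study end to end
#'
#' Scores every record ([score_study()]), optimizes the balancing angle
#' ([optimize_phi()]) and, optionally, runs the leave-two-participants-out
#' cross-validation ([cross_validate()]).
#'
#' @inheritParams score_study
#' @param grid Angle grid in degrees.
#' @param cv_folds If non-`NULL`, the number of cross-validation folds.
#' @param seed Seed for the cross-validation partition.
#' @return List with `scores`, `phi_opt`, `rs_max`, `rs_curve`, and (when
#'   requested) `cv`.
#' @export
evaluate_study <- function(study, params = alignment_params(), grid = 0:89,
                           cv_folds = NULL, seed = 1L) {
  scores <- score_study(study, params)
  opt <- optimize_phi(scores, grid)
  out <- list(scores = scores, phi_opt = opt$phi_opt, rs_max = opt$rs_max,
              rs_curve = opt$rs_curve)
  if (!is.null(cv_folds)) {
    out$cv <- cross_validate(scores, n_folds = cv_folds, seed = seed,
                             grid = grid)
  }
  out
}
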