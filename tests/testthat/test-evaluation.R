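perms3 <- list(c(0, 1, 2), c(0, 2, 1), c(1, 0, 2), c(1, 2, 0),
               c(2, 0, 1), c(2, 1, 0))

test_that("spearman_rs on three ranks takes the five known values", {
  vals <- vapply(perms3, spearman_rs, numeric(1), true_ranks = c(0, 1, 2))
  expect_equal(vals, c(1, 0.5, 0.5, -0.5, -0.5, -1))
  # n = 3 short form: rs = 1 - sum(d^2)/4
  for (p in perms3) {
    expect_equal(spearman_rs(p, c(0, 1, 2)),
                 1 - sum((p - c(0, 1, 2))^2) / 4)
  }
})

test_that("spearman_rs matches a generic rank-correlation routine up to n = 6", {
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(all_perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  for (n in 2:6) {
    truth <- 0:(n - 1)
    ps <- all_perms(truth)
    if (n == 6) ps <- ps[seq(1, length(ps), by = 7)]  # thin the 720 cases
    for (p in ps) {
      expect_equal(spearman_rs(p, truth),
                   suppressWarnings(cor(p, truth, method = "spearman")),
                   tolerance = 1e-12)
    }
  }
})

test_that("spearman_rs validates its inputs", {
  expect_error(spearman_rs(c(0, 1), c(0, 1, 2)), "length")
  expect_error(spearman_rs(c(0, 1, 1), c(0, 1, 2)), "permutation")
  expect_error(spearman_rs(c(0, 1, 3), c(0, 1, 2)), "permutation")
})

make_group <- function(DP, ids = c("a", "b", "c"), true_rank = 0:2) {
  data.frame(DP = DP, DT = 0, record_id = ids, true_rank = true_rank)
}

test_that("rank_by_distance sorts by projected distance", {
  expect_equal(rank_by_distance(make_group(c(0.1, 0.2, 0.3)), 0), c(0, 1, 2))
  expect_equal(rank_by_distance(make_group(c(0.2, 0.1, 0.3)), 0), c(1, 0, 2))
  # argsort oracle on random values
  set.seed(31)
  for (rep in 1:20) {
    D <- runif(3)
    expect_equal(rank_by_distance(make_group(D), 0), order(order(D)) - 1)
  }
  expect_error(rank_by_distance(make_group(c(1, 2, 3))[1:2, ], 0), "exactly 3")
})

test_that("exact ties are broken by record id, blind to the true labels", {
  g <- make_group(c(0.5, 0.5, 0.1), ids = c("z", "a", "m"),
                  true_rank = c(2, 0, 1))
  # D ties between rows 1 and 2; id order a < m < z puts row 2 first
  expect_equal(rank_by_distance(g, 0), c(2, 1, 0))
})

# A small synthetic score table: persons x positions, with controllable
# orderings in the DP and DT axes.
toy_scores <- function(flip_groups = character(0), dp_orders = TRUE) {
  rows <- list()
  for (p in c("P1", "P2", "P3", "P4")) {
    for (pos in c("sitting", "standing")) {
      key <- paste(p, pos)
      dp <- if (dp_orders) c(0.1, 0.2, 0.3) else c(0.2, 0.2, 0.2)
      if (key %in% flip_groups) dp <- rev(dp)
      rows[[key]] <- data.frame(
        person = p, position = pos, true_rank = 0:2,
        DP = dp, DT = c(0.01, 0.02, 0.03),
        record_id = paste(p, pos, 0:2, sep = "_"))
    }
  }
  do.call(rbind, rows)
}

test_that("average rank correlation averages the per-group coefficients", {
  expect_equal(average_rs_at_phi(toy_scores(), 0), 1)
  flipped <- toy_scores(flip_groups = c("P1 sitting", "P2 sitting",
                                        "P3 standing", "P4 standing"))
  expect_equal(average_rs_at_phi(flipped, 0), 0)  # mean of +/-1
  # group-by-group hand computation at a nonzero angle
  sc <- toy_scores(flip_groups = "P1 sitting")
  groups <- split(sc, interaction(sc$person, sc$position, drop = TRUE))
  byhand <- mean(vapply(groups, function(g) {
    D <- g$DP * cospi(20 / 180) + g$DT * sinpi(20 / 180)
    spearman_rs(order(order(D)) - 1, g$true_rank)
  }, numeric(1)))
  expect_equal(average_rs_at_phi(sc, 20), byhand)
})

test_that("incomplete groups are rejected", {
  sc <- toy_scores()
  expect_error(average_rs_at_phi(sc[-1, ], 0), "exactly one record per rank")
})

test_that("the smallest angle on the optimal plateau is returned", {
  # DP alone orders every group: the whole grid is optimal, left edge 0
  opt <- optimize_phi(toy_scores())
  expect_equal(opt$phi_opt, 0)
  expect_equal(opt$rs_max, 1)
  expect_equal(nrow(opt$rs_curve), 90)

  # only DT orders the groups: small angles cannot reach the optimum
  sc <- toy_scores(dp_orders = FALSE)
  sc$DT <- rep(c(0.01, 0.02, 0.03), 8)
  # break the DP ties adversarially so phi = 0 misorders via id tie-break
  sc$record_id <- rev(sc$record_id)
  opt2 <- optimize_phi(sc)
  expect_gt(opt2$phi_opt, 0)
  expect_gt(opt2$rs_max, opt2$rs_curve$rs[opt2$rs_curve$phi == 0])
})

test_that("cross-validation folds are seeded, exhaustive and disjoint", {
  sc <- toy_scores()
  cv1 <- cross_validate(sc, n_folds = 2, persons_per_fold = 2, seed = 11)
  cv2 <- cross_validate(sc, n_folds = 2, persons_per_fold = 2, seed = 11)
  expect_identical(cv1, cv2)  # determinism
  expect_equal(nrow(cv1), 2)
  expect_equal(cv1$n_heldout, c(12, 12))
  expect_equal(cv1$n_retained, c(12, 12))
  held <- unlist(strsplit(cv1$excluded, ","))
  expect_setequal(held, c("P1", "P2", "P3", "P4"))
  expect_error(cross_validate(sc, n_folds = 3, persons_per_fold = 2, seed = 1),
               "cannot be split")
})

test_that("a fixed perfect angle is recovered by every fold", {
  sc <- toy_scores()  # phi = 0 is optimal everywhere, rs = 1
  cv <- cross_validate(sc, n_folds = 2, persons_per_fold = 2, seed = 3)
  expect_equal(cv$phi_opt, c(0, 0))
  expect_equal(cv$avg_rs, c(1, 1))
})

test_that("average rs is invariant to increasing transforms of D within groups", {
  sc <- toy_scores(flip_groups = "P2 standing")
  base <- average_rs_at_phi(sc, 0)
  sc2 <- sc
  sc2$DP <- exp(3 * sc2$DP)   # strictly increasing transform, DT ignored
  expect_equal(average_rs_at_phi(sc2, 0), base)
})
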