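test_that("input-group enumeration counts follow binomial sums", {
  g5 <- enumerate_input_groups(letters[1:5], 3, 5)
  expect_length(g5, choose(5, 3) + choose(5, 4) + choose(5, 5))  # 16
  expect_length(enumerate_input_groups(letters[1:11], 3, 11), 1981)
  expect_length(enumerate_input_groups(letters[1:3], 3, 11), 1)
  # deterministic order, no duplicates
  ids <- vapply(g5, paste, "", collapse = "+")
  expect_identical(ids, vapply(enumerate_input_groups(letters[1:5], 3, 5),
                               paste, "", collapse = "+"))
  expect_false(anyDuplicated(ids) > 0)
  expect_error(enumerate_input_groups(letters[1:5], 4, 3), "max_size")
  expect_error(enumerate_input_groups(c("a", "a", "b"), 2, 3), "duplicates")
})

test_that("MAE filter keeps the boundary and warns when empty", {
  ev <- model_evaluation(list("a", "b", "c"), mae = c(0.3, 0.5, 0.51))
  expect_equal(filter_by_mae(ev, 0.5)$mae, c(0.3, 0.5))
  expect_equal(nrow(filter_by_mae(ev, Inf)), 3)
  expect_warning(out <- filter_by_mae(ev, 0.1), "threshold")
  expect_equal(nrow(out), 0)
})

test_that("subset dominance drops supersets beaten by their subsets", {
  ev <- model_evaluation(list(c("A", "B"), c("A", "B", "C")),
                         mae = c(0.2, 0.3))
  expect_equal(subset_dominance_filter(ev)$group_id, "A+B")
  # superset that is better survives, as does its subset
  ev2 <- model_evaluation(list(c("A", "B"), c("A", "B", "C")),
                          mae = c(0.3, 0.2))
  expect_equal(nrow(subset_dominance_filter(ev2)), 2)
  # equal MAE keeps both
  ev3 <- model_evaluation(list(c("A", "B"), c("A", "B", "C")),
                          mae = c(0.25, 0.25))
  expect_equal(nrow(subset_dominance_filter(ev3)), 2)
  # random instances match the brute-force pairwise oracle
  set.seed(9)
  pool <- letters[1:6]
  for (rep in 1:10) {
    groups <- unique(lapply(1:20, function(i)
      sort(sample(pool, sample(2:5, 1)))))
    maes <- round(runif(length(groups), 0.1, 0.6), 3)
    ev <- model_evaluation(groups, mae = maes)
    got <- subset_dominance_filter(ev)
    keep <- brute_dominance(groups, maes)
    expect_setequal(got$group_id, ev$group_id[keep])
    expect_false(is.unsorted(got$mae))
  }
})

test_that("RMSE weights sum to one and favor accurate members", {
  expect_equal(ensemble_weights(c(1, 3)), c(0.75, 0.25))
  expect_equal(ensemble_weights(rep(2.5, 6)), rep(1 / 6, 6))
  expect_equal(ensemble_weights(4), 1)  # single member by convention
  expect_error(ensemble_weights(numeric(0)), "no committee")
  expect_error(ensemble_weights(c(1, 0)), "positive")
  set.seed(10)
  for (rep in 1:20) {
    r <- runif(7, 0.05, 2)
    w <- ensemble_weights(r)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(diff(w[order(r)]) <= 1e-12))  # anti-monotone in RMSE
  }
})

test_that("committee prediction is the weighted convex combination", {
  expect_equal(committee_predict(cbind(1, 3), c(0.75, 0.25)), 1.5)
  # identical members reproduce the single member
  p <- matrix(runif(30), 10, 3)
  p[, 2] <- p[, 3] <- p[, 1]
  expect_equal(committee_predict(p, c(0.2, 0.5, 0.3)), p[, 1])
  # always within the member envelope
  set.seed(6)
  p2 <- matrix(runif(40), 10, 4)
  w <- ensemble_weights(runif(4, 0.1, 1))
  cp <- committee_predict(p2, w)
  expect_true(all(cp >= apply(p2, 1, min) - 1e-12 &
                    cp <= apply(p2, 1, max) + 1e-12))
  expect_error(committee_predict(p2, c(0.5, 0.5)), "match")
})

test_that("occurrence probabilities count group membership literally", {
  p <- occurrence_probabilities(list(c("A", "B"), c("A", "C")))
  expect_equal(p[["A"]], 1)
  expect_equal(p[["B"]], 0.5)
  expect_equal(p[["C"]], 0.5)
  # shared single group: every used variable has p = 1
  p2 <- occurrence_probabilities(list(c("x", "y"), c("x", "y")))
  expect_true(all(p2 == 1))
})

test_that("Shannon entropy follows the bit-count conventions", {
  expect_equal(shannon_entropy(rep(1 / 8, 8)), 3)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5, 1)), 1)  # p = 1 contributes 0
  expect_equal(shannon_entropy(c(0, 0.5)), 0.5)     # 0 log 0 := 0
  expect_error(shannon_entropy(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("committee size selection maximizes entropy, ties to smallest", {
  # all models share one group: entropy constantly 0 -> size 1
  ev <- model_evaluation(rep(list(c("A", "B", "C")), 6),
                         mae = seq(0.1, 0.35, by = 0.05),
                         rmse = seq(0.1, 0.35, by = 0.05))
  com <- select_committee(ev, max_size = 6)
  expect_equal(com$size, 1)
  expect_equal(com$entropy, 0)
  expect_equal(com$weights, 1)
  # planted occupancy: sizes 1..4 add fresh variables, then repeats of the
  # first group pull probabilities toward imbalance -> peak at 4
  groups <- list(c("a", "b", "c"), c("d", "e", "f"), c("g", "h", "i"),
                 c("j", "k", "l"), c("a", "b", "c"), c("a", "b", "c"),
                 c("a", "b", "c"))
  ev2 <- model_evaluation(groups, mae = seq(0.1, 0.4, by = 0.05),
                          rmse = seq(0.1, 0.4, by = 0.05))
  com2 <- select_committee(ev2, max_size = 7)
  hs <- com2$entropy_by_size$entropy
  expect_equal(com2$size, which.max(hs))
  expect_equal(com2$size, 4)
  expect_equal(com2$entropy, shannon_entropy(rep(1 / 4, 12)))
  # contract: weights sum to 1, members are the MAE ranking prefix
  expect_equal(sum(com2$weights), 1, tolerance = 1e-12)
  expect_equal(com2$members, 1:4)
  expect_error(select_committee(ev2[0, ]), "empty")
})

test_that("entropy grows when new members introduce balanced variables", {
  base <- list(c("a", "b", "c"))
  h1 <- shannon_entropy(occurrence_probabilities(base))
  h2 <- shannon_entropy(occurrence_probabilities(c(base,
                                                   list(c("d", "e", "f")))))
  expect_equal(h1, 0)
  expect_gt(h2, h1)
})
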