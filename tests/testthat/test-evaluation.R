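# Evaluation machinery: classification reports against hand-computed
# confusion tables, vote-for-majority, repetition statistics, normalized
# confusion matrices.

test_that("hand-computed two-class worked example is exact", {
  truth <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "B")
  r <- classification_report(pred, truth)
  pc <- r$per_class
  expect_equal(pc$precision[pc$class == "A"], 1)
  expect_equal(pc$recall[pc$class == "A"], 0.5)
  expect_equal(pc$f1[pc$class == "A"], 2 / 3)
  expect_equal(pc$precision[pc$class == "B"], 2 / 3)
  expect_equal(pc$recall[pc$class == "B"], 1)
  expect_equal(pc$f1[pc$class == "B"], 0.8)
  expect_equal(r$accuracy, 0.75)
  expect_equal(unname(r$weighted["f1"]), 11 / 15)
})

test_that("perfect predictions give 1.0 everywhere; balanced gives macro == weighted", {
  y <- rep(c("AD", "HC", "MCI"), each = 7)
  r <- classification_report(y, y)
  expect_true(all(abs(c(r$per_class$precision, r$per_class$recall,
                        r$per_class$f1, r$accuracy, r$macro, r$weighted) - 1) < 1e-15))
  set.seed(1)
  p <- sample(y)
  rb <- classification_report(p, y)
  expect_equal(rb$macro, rb$weighted)
  expect_error(classification_report(y[-1], y), "length mismatch")
})

test_that("accuracy equals support-weighted recall (property over random cases)", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(10:200, 1)
    classes <- LETTERS[1:k]
    y <- sample(classes, n, replace = TRUE, prob = runif(k) + 0.1)
    p <- sample(classes, n, replace = TRUE)
    r <- classification_report(p, y)
    expect_lt(abs(r$accuracy - unname(r$weighted["recall"])), 1e-12)
    # never-predicted classes get precision 0, not NaN
    expect_true(all(is.finite(r$per_class$precision)))
  }
})

test_that("vote for majority: fractions, lexicographic ties, identity case", {
  sp <- data.frame(subject_id = c("s1", "s1", "s1", "s2", "s2"),
                   true_label = c("AD", "AD", "AD", "HC", "HC"),
                   predicted_label = c("AD", "AD", "HC", "AD", "HC"),
                   stringsAsFactors = FALSE)
  v <- vote_majority(sp)
  s1 <- v[v$subject_id == "s1", ]
  expect_identical(s1$predicted_label, "AD")
  expect_equal(s1$vote_AD, 2 / 3)
  expect_equal(s1$n_slices, 3L, ignore_attr = TRUE)
  # s2 ties AD/HC -> lexicographic winner AD
  expect_identical(v$predicted_label[v$subject_id == "s2"], "AD")
  expect_equal(rowSums(v[, c("vote_AD", "vote_HC")]), c(1, 1), ignore_attr = TRUE)

  # single-slice subjects: subject-level report equals slice-level report
  set.seed(3)
  one <- data.frame(subject_id = sprintf("u%02d", 1:40),
                    true_label = sample(c("AD", "HC", "MCI"), 40, TRUE),
                    predicted_label = sample(c("AD", "HC", "MCI"), 40, TRUE),
                    stringsAsFactors = FALSE)
  vs <- vote_majority(one)
  r_slice <- classification_report(one$predicted_label, one$true_label)
  r_subj <- classification_report(vs$predicted_label, vs$true_label, "subject")
  expect_equal(r_subj$per_class, r_slice$per_class)
  expect_equal(r_subj$accuracy, r_slice$accuracy)
})

test_that("vote dominance: majority-correct subjects give perfect subject level", {
  set.seed(8)
  rows <- list()
  for (s in 1:12) {
    truth <- sample(c("AD", "HC", "MCI"), 1)
    n <- sample(5:15, 1)
    ncorrect <- ceiling(n / 2) + 1   # strictly more than half correct
    wrong <- sample(setdiff(c("AD", "HC", "MCI"), truth), n - ncorrect, TRUE)
    rows[[s]] <- data.frame(subject_id = sprintf("s%02d", s), true_label = truth,
                            predicted_label = sample(c(rep(truth, ncorrect), wrong)),
                            stringsAsFactors = FALSE)
  }
  v <- vote_majority(do.call(rbind, rows))
  expect_equal(mean(v$predicted_label == v$true_label), 1)
})

test_that("soft voting averages probabilities", {
  sp <- data.frame(subject_id = "s1", true_label = "AD",
                   predicted_label = c("HC", "AD"),
                   prob_AD = c(0.4, 0.9), prob_HC = c(0.6, 0.1),
                   stringsAsFactors = FALSE)
  v <- vote_majority(sp, method = "soft")
  expect_equal(v$vote_AD, 0.65)
  expect_identical(v$predicted_label, "AD")
})

test_that("repetition aggregation: mean, population sd, permutation invariance", {
  mk <- function(acc_target) {
    # craft a report with a controlled weighted F1 via simple proportions
    n <- 100
    ncorrect <- round(acc_target * n)
    y <- rep(c("A", "B"), each = n / 2)
    p <- y
    flip <- sample(seq_len(n), n - ncorrect)
    p[flip] <- ifelse(y[flip] == "A", "B", "A")
    classification_report(p, y)
  }
  set.seed(1)
  reps <- list(mk(0.96), mk(0.97), mk(0.98))
  agg <- aggregate_repetitions(reps)
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, 0.97)
  expect_equal(acc$sd, sqrt(mean((c(0.96, 0.97, 0.98) - 0.97)^2)))
  expect_identical(acc$pretty, "0.97 ± 0.01")
  # permutation invariance
  agg2 <- aggregate_repetitions(reps[c(3, 1, 2)])
  expect_equal(agg2$mean, agg$mean)
  expect_equal(agg2$sd, agg$sd)
  # identical reports -> sd 0; single report -> mean = value, sd 0
  same <- aggregate_repetitions(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_true(all(same$sd == 0))
  single <- aggregate_repetitions(reps[1])
  expect_equal(single$mean, unname(vitad:::report_metrics(reps[[1]])))
  expect_true(all(single$sd == 0))
  mixed <- list(classification_report(c("A"), c("A"), "slice"),
                classification_report(c("A"), c("A"), "subject"))
  expect_error(aggregate_repetitions(mixed), "mixed report levels")
})

test_that("normalized confusion matrices are row-stochastic per true class", {
  y <- c("A", "A", "B")
  p <- c("A", "B", "B")
  cm <- normalized_confusion(p, y)
  expect_equal(unclass(cm), rbind(c(0.5, 0.5), c(0, 1)), ignore_attr = TRUE)
  yy <- rep(c("AD", "HC", "MCI"), 10)
  cmp <- normalized_confusion(yy, yy)
  expect_equal(unclass(cmp), diag(3), ignore_attr = TRUE)
  set.seed(2)
  pr <- sample(c("AD", "HC", "MCI"), 30, TRUE)
  cmr <- normalized_confusion(pr, yy)
  expect_equal(rowSums(cmr), rep(1, 3), ignore_attr = TRUE)
  # empty true class yields an all-zero row
  cz <- normalized_confusion(c("A", "B"), c("A", "A"), classes = c("A", "B"))
  expect_equal(unname(cz["B", ]), c(0, 0))
  expect_error(normalized_confusion(c("A"), c("A", "B")), "length mismatch")
})
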