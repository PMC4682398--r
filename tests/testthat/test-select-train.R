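test_that("discretization codes by mean +/- t*sd and passes binaries", {
  expect_equal(discretize(rep(3, 10)), rep(0L, 10))

  # mean 2.5, sd 5: only the 10 exceeds 2.5 + 5
  expect_equal(discretize(c(0, 0, 0, 10)), c(0L, 0L, 0L, 1L))

  b <- c(0, 1, 1, 0, 1)
  expect_equal(discretize(b), as.integer(b))

  X <- cbind(cont = c(-10, 0, 0, 0, 10), bin = c(0, 1, 0, 1, 1))
  codes <- discretize_matrix(X)
  expect_equal(unname(codes[, "cont"]), c(-1L, 0L, 0L, 0L, 1L))
  expect_equal(unname(codes[, "bin"]), c(0L, 1L, 0L, 1L, 1L))
})

test_that("mutual information matches direct summation", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(mutual_information(y, y), 1)

  # constructed product distribution -> exactly independent
  x <- rep(c(0, 1), times = 10)
  expect_equal(mutual_information(x, y), 0)

  # joint counts [[2,1],[1,2]]
  xj <- c(0, 0, 0, 1, 1, 1)
  yj <- c(0, 0, 1, 0, 1, 1)
  expect_equal(mutual_information(xj, yj), mi_oracle(xj, yj),
               tolerance = 1e-12)

  for (s in 1:20) {
    neddly:::with_local_seed(s, {
      a <- sample(-1:1, 40, replace = TRUE)
      b <- sample(0:1, 40, replace = TRUE)
    })
    expect_equal(mutual_information(a, b), mi_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("mRMR ranks an informative feature first and demotes duplicates", {
  neddly:::with_local_seed(8, {
    y <- rep(c("positive", "negative"), each = 20)
    strong <- as.integer(y == "positive")
    sflip <- sample(40, 2)
    strong[sflip] <- 1L - strong[sflip]
    weak <- as.integer(y == "positive")
    flip <- sample(40, 12)
    weak[flip] <- 1L - weak[flip]
    noise <- sample(0:1, 40, replace = TRUE)
  })
  codes <- cbind(a_strong = strong, b_dup = strong, c_weak = weak,
                 d_noise = noise)
  ord <- mrmr_order(codes, y, max_features = 4)
  expect_equal(ord$feature[1], "a_strong")
  # the exact duplicate is fully redundant: an independent weakly
  # informative feature outranks it
  expect_lt(match("c_weak", ord$feature), match("b_dup", ord$feature))
  # matches the exhaustive MID oracle
  expect_equal(ord$feature, mid_order_oracle(codes, y))
})

test_that("mRMR ordering is invariant to row shuffling", {
  neddly:::with_local_seed(12, {
    y <- sample(c("positive", "negative"), 60, replace = TRUE, prob = c(.3, .7))
    codes <- matrix(sample(-1:1, 60 * 8, replace = TRUE), 60, 8,
                    dimnames = list(NULL, paste0("f", 1:8)))
    perm <- sample(60)
  })
  o1 <- mrmr_order(codes, y, 8)
  o2 <- mrmr_order(codes[perm, ], y[perm], 8)
  expect_equal(o1$feature, o2$feature)
})

test_that("mRMR first element maximizes relevance on exhaustive instances", {
  for (s in 1:40) {
    neddly:::with_local_seed(4000 + s, {
      p <- sample(2:6, 1)
      n <- 30
      codes <- matrix(sample(-1:1, n * p, replace = TRUE), n, p,
                      dimnames = list(NULL, paste0("f", seq_len(p))))
      y <- sample(c("positive", "negative"), n, replace = TRUE)
    })
    if (length(unique(y)) < 2) next
    ord <- mrmr_order(codes, y, max_features = 1)
    rels <- vapply(seq_len(p), function(j) mi_oracle(codes[, j], y == "positive"),
                   numeric(1))
    best <- max(rels)
    cand <- colnames(codes)[rels >= best - 1e-12]
    expect_equal(ord$feature[1], sort(cand)[1], label = paste("instance", s))
  }
})

test_that("weighted SVM trains, predicts and thresholds decisions", {
  toy <- toy_classification()
  m <- train_svm(toy$X, toy$y, svm_config(cost = 10, gamma = 0.5,
                                          class_weight = 1))
  pr <- predict(m, toy$X)
  expect_gt(roc_auc(pr$.decision, toy$y), 0.95)

  # refit reproduces decisions exactly
  m2 <- train_svm(toy$X, toy$y, svm_config(cost = 10, gamma = 0.5,
                                           class_weight = 1))
  expect_equal(predict(m2, toy$X)$.decision, pr$.decision)

  expect_error(
    train_svm(toy$X, rep("positive", nrow(toy$X)), svm_config()),
    "single class"
  )

  # decision 0.5 is positive at medium, negative at high
  hi <- predict(m, toy$X, confidence = "high")
  expect_true(all(which(hi$.label == "positive") %in%
                    which(pr$.label == "positive")))
  expect_equal(ifelse(pr$.decision > 0, "positive", "negative"), pr$.label)
  expect_equal(ifelse(hi$.decision > 1, "positive", "negative"), hi$.label)

  expect_error(predict(m, toy$X[, 1, drop = FALSE]), "lacks model features")
})

test_that("grid search returns a member of the grid and solves a toy", {
  expect_length(neddly:::default_cost_grid(), 21)
  expect_length(neddly:::default_gamma_grid(), 19)

  toy <- toy_classification(n = 40, separation = 5)
  gs <- grid_search_svm(
    toy$X, toy$y,
    cost_grid = c(1, 100), gamma_grid = c(0.01, 1),
    weight_candidates = c(1, 15), k = 4, repeats = 2, seed = 3
  )
  expect_s3_class(gs$config, "svm_config")
  expect_true(gs$config$cost %in% c(1, 100))
  expect_true(gs$config$gamma %in% c(0.01, 1))
  expect_equal(nrow(gs$results), 2 * 2 * 2)
  expect_gte(max(gs$results$auc), 0.99)
  expect_error(
    grid_search_svm(toy$X, rep("negative", 40)),
    "both classes"
  )
})

test_that("increasing the positive weight never lowers training sensitivity", {
  toy <- toy_classification(n = 80, seed = 17, separation = 1)
  sens <- vapply(c(1, 5, 15, 30), function(w) {
    m <- train_svm(toy$X, toy$y, svm_config(cost = 1, gamma = 0.5,
                                            class_weight = w))
    pr <- predict(m, toy$X)
    cc <- neddly:::confusion_counts(pr$.label, toy$y)
    cc$tp / (cc$tp + cc$fn)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("incremental selection finds a compact planted prefix", {
  neddly:::with_local_seed(23, {
    n <- 80
    y <- rep(c("positive", "negative"), times = c(16, 64))
    informative <- vapply(1:3, function(i) {
      f <- as.numeric(y == "positive")
      flip <- sample(n, 6)
      f[flip] <- 1 - f[flip]
      f
    }, numeric(n))
    noise <- matrix(sample(0:1, n * 7, replace = TRUE), n, 7)
  })
  X <- cbind(informative, noise)
  colnames(X) <- c(paste0("sig", 1:3), paste0("noise", 1:7))
  codes <- discretize_matrix(X)
  ord <- mrmr_order(codes, y, 10)
  expect_setequal(ord$feature[1:3], paste0("sig", 1:3))

  ifs <- incremental_feature_selection(
    ord$feature, X, y,
    cost_grid = 4, gamma_grid = 0.25, class_weight = 5,
    k = 4, repeats = 2, seed = 2
  )
  expect_equal(nrow(ifs$curve), 10)
  expect_lte(ifs$k_star, 5)
  plateau <- max(ifs$curve$auc[1:3])
  expect_gte(plateau, max(ifs$curve$auc) - 0.02)
  # curve is invariant to columns beyond the evaluated prefix
  ifs2 <- incremental_feature_selection(
    ord$feature[1:4], X[, c(ord$feature[1:4], "noise7")], y,
    cost_grid = 4, gamma_grid = 0.25, class_weight = 5,
    k = 4, repeats = 2, seed = 2
  )
  expect_equal(ifs2$curve$auc, ifs$curve$auc[1:4])
})
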