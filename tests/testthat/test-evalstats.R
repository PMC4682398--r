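test_that("confusion metrics reproduce the motif worked example", {
  m <- confusion_metrics(tp = 1, fp = 0, tn = 229, fn = 10)
  expect_equal(round(m$acc, 2), 0.96)
  expect_equal(round(m$sp, 2), 1.00)
  expect_equal(round(m$sn, 2), 0.09)
  expect_equal(round(m$mcc, 2), 0.30)

  perfect <- confusion_metrics(tp = 5, fp = 0, tn = 20, fn = 0)
  expect_equal(unlist(perfect[, c("acc", "sp", "sn", "mcc")]),
               c(acc = 1, sp = 1, sn = 1, mcc = 1))

  near <- confusion_metrics(tp = 1, fp = 1, tn = 228, fn = 10)
  expect_equal(near$mcc, mcc_oracle(1, 1, 228, 10), tolerance = 1e-12)
  expect_equal(round(near$mcc, 2), 0.2)
})

test_that("MCC matches the direct formula on random tables", {
  neddly:::with_local_seed(5, {
    tabs <- matrix(sample(0:200, 4 * 200, replace = TRUE), ncol = 4)
  })
  for (i in seq_len(nrow(tabs))) {
    m <- confusion_metrics(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    expect_equal(m$mcc, mcc_oracle(tabs[i, 1], tabs[i, 2], tabs[i, 3],
                                   tabs[i, 4]),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC equals the all-pairs statistic", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("positive", "positive",
                                        "negative", "negative")), 1)
  # hand case with a tie
  s <- c(0.9, 0.5, 0.5, 0.1)
  l <- c("positive", "positive", "negative", "negative")
  expect_equal(roc_auc(s, l), auc_pairs_oracle(s, l))
  expect_equal(roc_auc(s, l), 0.875)

  neddly:::with_local_seed(6, {
    big <- stats::rnorm(2000)
    lab <- sample(c("positive", "negative"), 2000, replace = TRUE)
  })
  expect_equal(roc_auc(big, lab), 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")

  # library cross-check on a tied, imbalanced sample
  skip_if_not_installed("pROC")
  neddly:::with_local_seed(8, {
    sc <- round(stats::rnorm(80), 1)
    lb <- sample(c("positive", "negative"), 80, replace = TRUE,
                 prob = c(0.2, 0.8))
  })
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(lb, levels = c("negative", "positive")),
    predictor = sc, direction = "<", quiet = TRUE
  )))
  expect_equal(roc_auc(sc, lb), as.numeric(ref), tolerance = 1e-12)
})

test_that("roc_points trace matches the trapezoid-free AUC", {
  neddly:::with_local_seed(7, {
    s <- round(stats::rnorm(50), 1)
    l <- sample(c("positive", "negative"), 50, replace = TRUE)
  })
  pts <- roc_points(s, l)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # trapezoid over the step curve equals the rank AUC
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                 utils::tail(pts$tpr, -1)) / 2)
  expect_equal(trap, attr(pts, "auc"), tolerance = 1e-12)
})

test_that("stratified folds balance classes within one sample", {
  labels <- c(rep("positive", 10), rep("negative", 50))
  f <- stratified_kfold(labels, 5, seed = 2)
  expect_equal(as.integer(table(f[labels == "positive"])), rep(2L, 5))

  labels7 <- c(rep("positive", 7), rep("negative", 23))
  f7 <- stratified_kfold(labels7, 5, seed = 2)
  expect_true(all(table(f7[labels7 == "positive"]) %in% 1:2))

  expect_identical(stratified_kfold(labels, 5, seed = 9),
                   stratified_kfold(labels, 5, seed = 9))
})

test_that("repeated CV averages per-repeat metrics sensibly", {
  toy <- toy_classification(n = 40, separation = 5)
  cfg <- svm_config(cost = 10, gamma = 0.5, class_weight = 1)
  self <- repeated_cv(toy$X, toy$y, cfg, self_consistency = TRUE)
  expect_equal(self$mean$auc, 1)

  one <- repeated_cv(toy$X, toy$y, cfg, k = 4, repeats = 1, seed = 3)
  expect_equal(nrow(one$per_repeat), 1)
  expect_equal(one$mean$auc, one$per_repeat$auc)

  three <- repeated_cv(toy$X, toy$y, cfg, k = 4, repeats = 3, seed = 3)
  expect_gte(three$mean$auc, min(three$per_repeat$auc))
  expect_lte(three$mean$auc, max(three$per_repeat$auc))
  expect_equal(glance(three), three$mean)
})

test_that("motif parsing anchors on the central lysine", {
  spec <- parse_motif("[IL][VIT][RQ][IS][MLV]K[MAS][RHE]")
  expect_equal(spec$offset, -5:2)
  expect_equal(spec$allowed[[1]], c("I", "L"))
  expect_error(parse_motif("AAA"), "anchor K")
  expect_error(parse_motif("AKSK"), "anchor K")

  win <- "AAAAAIVRIMKSAAAAAAAAA" # flank 10, IVRIM at -5..-1, S at +1
  expect_true(match_motif("IVRIMKS", win))
  expect_true(match_motif("[IL][VIT][RQ][IS][MLV]K[MAS][RHE]",
                          sub("KSA", "KSR", win)))
  expect_false(match_motif("IV[DE]IMKS", win))
  expect_warning(long <- match_motif("AIVRIMKS", "IVRIMKS"), "beyond")
  expect_false(long)
  # gaps never match
  expect_false(match_motif("MKS", "--K--"))
})

test_that("motif evaluation scores matches as positive predictions", {
  windows <- tibble::tibble(
    window = c("AAAAAIVRIMKSAAAAAAAAA", # true positive (matches)
               paste0(strrep("A", 10), "K", strrep("A", 10)),
               paste0(strrep("G", 10), "K", strrep("G", 10))),
    label = c("positive", "negative", "negative")
  )
  m <- evaluate_motif("IVRIMKS", windows)
  expect_equal(m$tp, 1)
  expect_equal(m$fp, 0)
  expect_equal(m$sp, 1)

  never <- evaluate_motif("WWWWKWWWW", windows)
  expect_equal(never$sn, 0)
  expect_equal(never$sp, 1)
  expect_error(evaluate_motif("IVRIMKS", windows[0, ]), "no windows")
})

test_that("chi-square independence matches the closed form", {
  flat <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_raw, 1)
  expect_equal(flat$df, 1)

  tab <- matrix(c(10, 41, 21, 1010), 2, 2, byrow = TRUE)
  got <- chi_square_independence(tab)
  a <- 10; b <- 41; c_ <- 21; d <- 1010; N <- a + b + c_ + d
  closed <- N * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(got$statistic, closed, tolerance = 1e-9)
  expect_equal(round(got$statistic, 1), 53.9)
  expect_gt(chi_square_independence(tab, yates = TRUE)$statistic, 0)
  expect_lt(chi_square_independence(tab, yates = TRUE)$statistic,
            got$statistic)
})

test_that("Mann-Whitney U behaves at the extremes", {
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_raw, 0.9)

  dis <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(dis$statistic), 0) # minimal U for sample_a
  u_b <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))$statistic
  expect_equal(unname(dis$statistic + u_b), 3 * 3)
})

test_that("Bonferroni multiplies and clips", {
  expect_equal(bonferroni(rep(0.01, 5)), rep(0.05, 5))
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(c(0.001, 0.5)),
               p.adjust(c(0.001, 0.5), method = "bonferroni"))
})

test_that("positional enrichment surfaces a planted residue preference", {
  neddly:::with_local_seed(14, {
    rand_win <- function() {
      paste0(paste(sample(neddly:::AA_LETTERS, 5, replace = TRUE),
                   collapse = ""), "K",
             paste(sample(neddly:::AA_LETTERS, 5, replace = TRUE),
                   collapse = ""))
    }
    pos <- vapply(1:40, function(i) {
      w <- rand_win()
      substr(w, 5, 5) <- "M" # force M at -1
      w
    }, character(1))
    neg <- vapply(1:160, function(i) rand_win(), character(1))
  })
  windows <- tibble::tibble(
    window = c(pos, neg),
    label = c(rep("positive", 40), rep("negative", 160))
  )
  enr <- position_enrichment(windows)
  expect_lte(nrow(enr), 20 * 11)
  top <- enr[1, ]
  expect_equal(top$position, -1)
  expect_equal(top$residue, "M")
  expect_lt(top$p_adjusted, 0.001)
  expect_true(all(enr$p_adjusted >= enr$p_raw))

  # identical class compositions carry no signal
  dup <- tibble::tibble(
    window = rep(c(pos[1:10]), 2),
    label = rep(c("positive", "negative"), each = 10)
  )
  enr0 <- position_enrichment(dup)
  expect_true(all(enr0$statistic == 0))
  expect_true(all(enr0$p_adjusted == 1))
})
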