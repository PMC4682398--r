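## Feature selection (ternary discretization, mutual information, mRMR
## ordering, incremental feature selection) and the class-weighted
## radial-kernel SVM wrapped behind train/predict.

#' Ternary discretization of a continuous feature
#'
#' Values are coded -1 below `mean - t*sd`, +1 above `mean + t*sd` and 0
#' otherwise. Binary features (values all in \{0, 1\}) pass through
#' unchanged; zero-variance features code to all zeros.
#'
#' @param values Numeric vector (>= 2 samples).
#' @param t Non-negative discretization threshold in standard deviations
#'   (default 1).
#' @return Integer codes in \{-1, 0, +1\}.
#' @export
#' @examples
#' discretize(c(0, 0, 0, 10))
discretize <- function(values, t = 1) {
  stopifnot(length(values) >= 2, t >= 0)
  if (all(values %in% c(0, 1))) return(as.integer(values))
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(integer(length(values)))
  as.integer((values > m + t * s) - (values < m - t * s))
}

#' @rdname discretize
#' @param X Numeric feature matrix (samples x features).
#' @return `discretize_matrix()` returns an integer matrix of codes with
#'   the same dimnames.
#' @export
discretize_matrix <- function(X, t = 1) {
  codes <- vapply(seq_len(ncol(X)), function(j) discretize(X[, j], t),
                  integer(nrow(X)))
  dimnames(codes) <- dimnames(X)
  codes
}

#' Mutual information between two discrete variables
#'
#' Plug-in estimate over the joint empirical distribution, in bits.
#'
#' @param x,y Discrete vectors of equal length.
#' @return Non-negative mutual information (bits).
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  N <- sum(tab)
  px <- rowSums(tab) / N
  py <- colSums(tab) / N
  p <- tab / N
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

# Vectorized MI of every column of a code matrix against vector s.
# Codes are restricted to {-1, 0, 1}.
mi_profile <- function(X, s) {
  N <- nrow(X)
  vals <- c(-1L, 0L, 1L)
  S <- vapply(vals, function(v) as.numeric(s == v), numeric(N))
  ns <- colSums(S)
  mi <- numeric(ncol(X))
  for (b in seq_along(vals)) {
    Xb <- X == vals[b]
    cb <- crossprod(S, Xb) # 3 x p joint counts for this x-code
    nx <- colSums(Xb)
    for (a in seq_along(vals)) {
      nab <- cb[a, ]
      pos <- nab > 0
      mi[pos] <- mi[pos] +
        nab[pos] / N * log2(nab[pos] * N / (ns[a] * nx[pos]))
    }
  }
  names(mi) <- colnames(X)
  mi
}

#' mRMR feature ordering
#'
#' Greedy minimum-redundancy-maximum-relevance ordering in the
#' mutual-information-difference (MID) form: the first feature maximizes
#' relevance MI(f; y); each subsequent feature maximizes
#' MI(f; y) - mean over already-selected s of MI(f; s). Ties are broken
#' lexicographically by feature name for determinism.
#'
#' @param codes Discretized feature matrix (samples x features, codes in
#'   \{-1, 0, 1\}; see [discretize_matrix()]).
#' @param labels Sample class labels.
#' @param max_features Stop after this many features (default 50).
#' @return Tibble with columns `rank`, `feature`, `relevance`,
#'   `redundancy` (mean MI with previously selected features), `score`.
#' @export
mrmr_order <- function(codes, labels, max_features = 50) {
  p <- ncol(codes)
  if (max_features > p) {
    rlang::warn("max_features exceeds available features; truncating")
    max_features <- p
  }
  fnames <- colnames(codes)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(p))
  y <- as.integer(as_positive_logical(labels))
  rel <- mi_profile(codes, y)

  pick <- function(score, avail) {
    m <- max(score[avail])
    cand <- which(avail & score >= m - 1e-12)
    cand[order(fnames[cand])][1]
  }

  avail <- rep(TRUE, p)
  red_sum <- numeric(p)
  out_rank <- integer(max_features)
  out_red <- numeric(max_features)
  out_score <- numeric(max_features)
  for (r in seq_len(max_features)) {
    red <- if (r == 1) numeric(p) else red_sum / (r - 1)
    score <- rel - red
    j <- pick(score, avail)
    out_rank[r] <- j
    out_red[r] <- red[j]
    out_score[r] <- score[j]
    avail[j] <- FALSE
    if (r < max_features) {
      red_sum <- red_sum + mi_profile(codes, codes[, j])
    }
  }
  tibble::tibble(
    rank = seq_len(max_features),
    feature = fnames[out_rank],
    relevance = unname(rel[out_rank]),
    redundancy = out_red,
    score = out_score
  )
}

#' SVM configuration
#'
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width.
#' @param class_weight Weight multiplying C for the positive class (the
#'   negative class keeps weight 1); default 15.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(cost = 1, gamma = 0.01, class_weight = 15) {
  stopifnot(cost > 0, gamma > 0, class_weight > 0)
  structure(list(cost = cost, gamma = gamma, class_weight = class_weight),
            class = "svm_config")
}

label_factor <- function(labels) {
  factor(ifelse(as_positive_logical(labels), "positive", "negative"),
         levels = c("negative", "positive"))
}

fit_raw_svm <- function(X, labels, config) {
  y <- label_factor(labels)
  if (length(unique(y)) < 2) {
    rlang::abort("training labels contain a single class")
  }
  e1071::svm(
    x = X, y = y, kernel = "radial",
    cost = config$cost, gamma = config$gamma,
    class.weights = c(negative = 1, positive = config$class_weight),
    scale = FALSE
  )
}

# decision values oriented so positive class scores high
svm_decision <- function(fit, X) {
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first == "positive") as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
}

#' Train a class-weighted RBF SVM site classifier
#'
#' Fits a radial-kernel SVM with per-class weights \{negative: 1, positive:
#' `class_weight`\} (the libsvm `C*weight` scheme) on the given feature
#' matrix, and stores the feature names together with the two
#' decision-value confidence thresholds (medium = 0, high = 1).
#'
#' @param X Numeric feature matrix (samples x features) with column names.
#' @param labels Sample class labels.
#' @param config An [svm_config()].
#' @return An object of class `nedd_model`.
#' @export
train_svm <- function(X, labels, config = svm_config()) {
  if (is.null(colnames(X))) {
    rlang::abort("feature matrix must have column names")
  }
  fit <- fit_raw_svm(X, labels, config)
  structure(
    list(
      fit = fit,
      config = config,
      features = colnames(X),
      thresholds = list(medium = 0, high = 1)
    ),
    class = "nedd_model"
  )
}

#' Predict site labels and decision values
#'
#' Applies a fitted model to new feature rows. A site is called positive
#' when its decision value exceeds the threshold of the requested
#' confidence level: medium (0) or high (1). Higher absolute decision
#' values indicate more confident calls.
#'
#' @param object A `nedd_model` from [train_svm()].
#' @param newdata Feature matrix or assembled feature tibble containing the
#'   model's feature columns.
#' @param confidence `"medium"` or `"high"`.
#' @param ... Unused.
#' @return Tibble with columns `.decision` and `.label`.
#' @export
predict.nedd_model <- function(object, newdata, confidence = "medium", ...) {
  thr <- object$thresholds[[confidence]]
  if (is.null(thr)) {
    rlang::abort(paste0("unknown confidence level: ", confidence))
  }
  X <- if (is.matrix(newdata)) newdata else {
    as.matrix(newdata[, intersect(names(newdata), object$features),
                      drop = FALSE])
  }
  missing <- setdiff(object$features, colnames(X))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "newdata lacks model features: ", paste(utils::head(missing, 3),
                                              collapse = ", ")
    ))
  }
  dv <- svm_decision(object$fit, X[, object$features, drop = FALSE])
  tibble::tibble(
    .decision = dv,
    .label = ifelse(dv > thr, "positive", "negative")
  )
}

#' Repeated stratified cross-validation of the weighted SVM
#'
#' Runs `repeats` rounds of stratified k-fold cross-validation and returns
#' the mean of the per-repeat metrics (accuracy, specificity, sensitivity,
#' MCC at the medium decision threshold, and rank-based AUC). When
#' `n_features` is given, feature selection is nested inside every training
#' fold: the fold's features are discretized and mRMR-ordered on the
#' training part only, and the top `n_features` are used — held-out folds
#' never influence selection. `self_consistency = TRUE` instead trains and
#' evaluates once on the full data.
#'
#' @param X Numeric feature matrix.
#' @param labels Sample class labels.
#' @param config An [svm_config()].
#' @param k Folds (5 or 10 are customary).
#' @param repeats Number of CV repetitions.
#' @param seed Master seed; repeat r uses `seed + r`.
#' @param n_features Optional nested-selection prefix size.
#' @param t Discretization threshold for nested selection.
#' @param self_consistency Train and test on the same data instead of CV.
#' @return A list of class `nedd_cv` with elements `mean` (one-row metrics
#'   tibble) and `per_repeat`.
#' @export
repeated_cv <- function(X, labels, config = svm_config(), k = 5,
                        repeats = 10, seed = 1L, n_features = NULL,
                        t = 1, self_consistency = FALSE) {
  labels <- as.character(label_factor(labels))
  if (self_consistency) {
    model <- train_svm(X, labels, config)
    pr <- predict(model, X)
    rep_metrics <- metrics_from_scores(pr$.decision, labels)
    out <- list(mean = rep_metrics, per_repeat = rep_metrics)
    class(out) <- "nedd_cv"
    return(out)
  }
  per <- purrr::map_dfr(seq_len(repeats), function(r) {
    folds <- stratified_kfold(labels, k, seed = seed + r)
    dv <- numeric(length(labels))
    for (f in seq_len(k)) {
      te <- folds == f
      Xtr <- X[!te, , drop = FALSE]
      ytr <- labels[!te]
      Xte <- X[te, , drop = FALSE]
      if (!is.null(n_features)) {
        codes <- discretize_matrix(Xtr, t)
        ord <- mrmr_order(codes, ytr,
                          max_features = min(n_features, ncol(Xtr)))
        keep <- ord$feature
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- Xte[, keep, drop = FALSE]
      }
      fit <- fit_raw_svm(Xtr, ytr, config)
      dv[te] <- svm_decision(fit, Xte)
    }
    m <- metrics_from_scores(dv, labels)
    m$repeat_id <- r
    m
  })
  out <- list(
    mean = dplyr::summarise(per, dplyr::across(
      c("acc", "sp", "sn", "mcc", "auc"), mean
    )),
    per_repeat = per
  )
  class(out) <- "nedd_cv"
  out
}

# metrics tibble (acc/sp/sn/mcc at threshold 0, plus AUC) from scores
metrics_from_scores <- function(decision, labels, threshold = 0) {
  pred <- ifelse(decision > threshold, "positive", "negative")
  cc <- confusion_counts(pred, labels)
  m <- confusion_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
  m$auc <- roc_auc(decision, labels)
  dplyr::select(m, "acc", "sp", "sn", "mcc", "auc", "tp", "fp", "tn", "fn")
}

default_cost_grid <- function() 2^seq(-5, 15, by = 1)
default_gamma_grid <- function() 2^seq(-15, 3, by = 1)

#' Grid search for SVM cost, kernel width and class weight
#'
#' Evaluates every (C, gamma, weight) combination by mean cross-validated
#' AUC. Ties on AUC are broken by sensitivity on the validation set, then
#' by validation specificity, when a validation set is supplied; remaining
#' ties keep the earliest grid entry (C-major order).
#'
#' @param X,labels Training feature matrix and labels.
#' @param cost_grid,gamma_grid Candidate values (defaults: the doubling
#'   sequences 2^-5..2^15 and 2^-15..2^3).
#' @param weight_candidates Candidate positive-class weights (default
#'   c(1, 5, 10, 15, 20, 25, 30)).
#' @param k,repeats,seed Cross-validation settings.
#' @param validation Optional list(X, labels) used only for tie-breaking.
#' @return A list with `config` (the winning [svm_config()]) and `results`
#'   (tibble of every combination with its mean CV AUC).
#' @export
grid_search_svm <- function(X, labels,
                            cost_grid = default_cost_grid(),
                            gamma_grid = default_gamma_grid(),
                            weight_candidates = c(1, 5, 10, 15, 20, 25, 30),
                            k = 5, repeats = 5, seed = 1L,
                            validation = NULL) {
  if (length(unique(label_factor(labels))) < 2) {
    rlang::abort("grid search needs both classes in the training labels")
  }
  grid <- expand.grid(
    weight = weight_candidates, gamma = gamma_grid, cost = cost_grid,
    KEEP.OUT.ATTRS = FALSE
  )[, c("cost", "gamma", "weight")]
  res <- purrr::pmap_dfr(grid, function(cost, gamma, weight) {
    cfg <- svm_config(cost, gamma, weight)
    cv <- repeated_cv(X, labels, cfg, k = k, repeats = repeats, seed = seed)
    out <- tibble::tibble(cost = cost, gamma = gamma, weight = weight,
                          auc = cv$mean$auc)
    if (!is.null(validation)) {
      model <- train_svm(X, labels, cfg)
      pr <- predict(model, validation$X)
      vm <- metrics_from_scores(pr$.decision,
                                as.character(label_factor(validation$labels)))
      out$val_sn <- vm$sn
      out$val_sp <- vm$sp
    }
    out
  })
  best <- res
  best_auc <- max(best$auc)
  best <- best[best$auc >= best_auc - 1e-12, , drop = FALSE]
  if (!is.null(validation) && nrow(best) > 1) {
    best <- best[best$val_sn >= max(best$val_sn) - 1e-12, , drop = FALSE]
    if (nrow(best) > 1) {
      best <- best[best$val_sp >= max(best$val_sp) - 1e-12, , drop = FALSE]
    }
  }
  win <- best[1, ]
  list(
    config = svm_config(win$cost, win$gamma, win$weight),
    results = res
  )
}

#' Incremental feature selection over an mRMR-ordered list
#'
#' Starting from the top of the ordered feature list, evaluates growing
#' feature prefixes by mean cross-validated AUC and selects the prefix
#' length with the maximum mean AUC (ties resolved towards fewer
#' features). Each prefix is optionally re-tuned over a (reduced) C/gamma
#' grid.
#'
#' @param ordered_names Feature names in mRMR order (from [mrmr_order()]).
#' @param X,labels Training feature matrix and labels.
#' @param prefix_sizes Prefix lengths to evaluate (default 1..length).
#' @param cost_grid,gamma_grid Per-prefix tuning grid; give length-1 grids
#'   to fix the configuration.
#' @param class_weight Positive-class weight used throughout.
#' @param k,repeats,seed Cross-validation settings.
#' @return An object of class `nedd_ifs`: list with `curve` (tibble
#'   `n_features`, `auc`, `cost`, `gamma`), `k_star`, `config` (the winning
#'   configuration) and `features` (the selected prefix).
#' @export
incremental_feature_selection <- function(ordered_names, X, labels,
                                          prefix_sizes = NULL,
                                          cost_grid = 2^c(0, 5, 10),
                                          gamma_grid = 2^c(-7, -3),
                                          class_weight = 15,
                                          k = 5, repeats = 3, seed = 1L) {
  stopifnot(all(ordered_names %in% colnames(X)))
  if (is.null(prefix_sizes)) prefix_sizes <- seq_along(ordered_names)
  prefix_sizes <- prefix_sizes[prefix_sizes <= length(ordered_names)]
  curve <- purrr::map_dfr(prefix_sizes, function(m) {
    Xm <- X[, ordered_names[seq_len(m)], drop = FALSE]
    combos <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                          KEEP.OUT.ATTRS = FALSE)
    scores <- purrr::pmap_dfr(combos, function(gamma, cost) {
      cfg <- svm_config(cost, gamma, class_weight)
      cv <- repeated_cv(Xm, labels, cfg, k = k, repeats = repeats,
                        seed = seed)
      tibble::tibble(cost = cost, gamma = gamma, auc = cv$mean$auc)
    })
    win <- scores[which.max(scores$auc), ]
    tibble::tibble(n_features = m, auc = win$auc, cost = win$cost,
                   gamma = win$gamma)
  })
  best <- which.max(curve$auc) # first maximum -> smallest prefix on ties
  out <- list(
    curve = curve,
    k_star = curve$n_features[best],
    config = svm_config(curve$cost[best], curve$gamma[best], class_weight),
    features = ordered_names[seq_len(curve$n_features[best])]
  )
  class(out) <- "nedd_ifs"
  out
}
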