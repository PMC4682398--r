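#' Classification metrics from confusion counts
#'
#' Accuracy, specificity, sensitivity and Matthews correlation coefficient
#' from a 2x2 confusion matrix. MCC is defined as 0 when its denominator
#' vanishes.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (positive class =
#'   modified site).
#' @return One-row tibble with columns `acc`, `sp`, `sn`, `mcc`, `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_metrics(tp = 1, fp = 0, tn = 229, fn = 10)
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total <= 0) rlang::abort("empty confusion matrix")
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble::tibble(
    acc = (tp + tn) / total,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    mcc = mcc,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# confusion counts from predicted/true label vectors
confusion_counts <- function(predicted, truth) {
  pos <- truth == "positive"
  pred_pos <- predicted == "positive"
  list(
    tp = sum(pred_pos & pos), fp = sum(pred_pos & !pos),
    tn = sum(!pred_pos & !pos), fn = sum(!pred_pos & pos)
  )
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic: the probability that a random positive scores above a random
#' negative, with ties counting one half. Deterministic and identical to
#' the trapezoidal AUC over the finite score set.
#'
#' @param scores Numeric decision values (higher = more positive).
#' @param labels Character/factor/logical labels; `"positive"`/`TRUE`/`1`
#'   marks the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive_logical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("roc_auc needs both classes present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "positive"
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble of class `nedd_roc` with columns `threshold`, `fpr`,
#'   `tpr`, ordered from the all-positive to the all-negative operating
#'   point, with the AUC stored in the `"auc"` attribute.
#' @export
roc_points <- function(scores, labels) {
  pos <- as_positive_logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  out <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, cumsum(p)[keep] / sum(pos)),
    fpr = c(0, cumsum(!p)[keep] / sum(!pos))
  )
  class(out) <- c("nedd_roc", class(out))
  attr(out, "auc") <- roc_auc(scores, labels)
  out
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds by shuffling and splitting each
#' class separately, so within-class fold sizes never differ by more than
#' one and every fold preserves the class balance as closely as possible.
#'
#' @param labels Sample class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the per-class shuffles.
#' @return Integer vector of fold indices in 1..k.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  if (k < 2) rlang::abort("k must be at least 2")
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      assign <- rep(seq_len(k), length.out = length(idx))
      folds[idx] <- assign[sample.int(length(idx))]
    }
  })
  folds
}

#' Match a degenerate lysine-anchored motif against a window
#'
#' Motif patterns are PROSITE-like strings anchored on a lysine: each
#' position is a single residue or a bracketed residue set, and exactly one
#' position is the anchor `K` (e.g. `"IVRIMKS"` or
#' `"[IL][VIT][RQ][IS][MLV]K[MAS][RHE]"`). A window matches when every
#' pattern position's residue set contains the window residue at the
#' corresponding offset from the central lysine; gap positions never match.
#'
#' @param pattern Motif pattern string.
#' @param window A 2n+1 window string.
#' @return `TRUE`/`FALSE` (with a warning and `FALSE` when the pattern
#'   extends beyond the window flanks).
#' @export
match_motif <- function(pattern, window) {
  spec <- parse_motif(pattern)
  n <- window_flank(window)
  if (min(spec$offset) < -n || max(spec$offset) > n) {
    rlang::warn("motif extends beyond the window flanks; no match")
    return(FALSE)
  }
  chars <- window_chars(window)
  all(vapply(seq_len(nrow(spec)), function(i) {
    ch <- chars[spec$offset[i] + n + 1L]
    ch != GAP && ch %in% spec$allowed[[i]]
  }, logical(1)))
}

#' @rdname match_motif
#' @return `parse_motif()` returns a tibble with columns `offset` (relative
#'   to the anchor K) and `allowed` (list of residue sets).
#' @export
parse_motif <- function(pattern) {
  toks <- stringr::str_match_all(pattern, "\\[([A-Z]+)\\]|([A-Z])")[[1]]
  if (nrow(toks) == 0 || sum(nchar(toks[, 1])) != nchar(pattern)) {
    rlang::abort(paste0("cannot parse motif pattern: ", pattern))
  }
  allowed <- lapply(seq_len(nrow(toks)), function(i) {
    if (!is.na(toks[i, 2])) strsplit(toks[i, 2], "")[[1]] else toks[i, 3]
  })
  anchor <- which(vapply(allowed, function(a) identical(a, "K"), logical(1)))
  if (length(anchor) != 1) {
    rlang::abort("motif must contain exactly one anchor K position")
  }
  tibble::tibble(
    offset = seq_along(allowed) - anchor,
    allowed = allowed
  )
}

#' Evaluate a motif as a site predictor on labeled windows
#'
#' A motif match is treated as a positive prediction and scored against the
#' window labels with [confusion_metrics()].
#'
#' @param pattern Motif pattern string (see [match_motif()]).
#' @param windows Labeled window tibble (columns `window`, `label`).
#' @return One-row metrics tibble with an added `pattern` column.
#' @export
evaluate_motif <- function(pattern, windows) {
  if (nrow(windows) == 0) rlang::abort("no windows to evaluate")
  pred <- ifelse(
    vapply(windows$window, function(w) match_motif(pattern, w), logical(1)),
    "positive", "negative"
  )
  cc <- confusion_counts(pred, windows$label)
  out <- confusion_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
  out$pattern <- pattern
  dplyr::relocate(out, "pattern")
}

#' Chi-square test of independence for a 2x2 table
#'
#' @param table2x2 2x2 numeric matrix of counts.
#' @param yates Apply the Yates continuity correction (default off).
#' @return One-row tibble with `statistic`, `df`, `p_raw`.
#' @export
chi_square_independence <- function(table2x2, yates = FALSE) {
  stopifnot(is.matrix(table2x2), all(dim(table2x2) == c(2, 2)))
  if (sum(table2x2) == 0) rlang::abort("empty contingency table")
  ht <- suppressWarnings(stats::chisq.test(table2x2, correct = yates))
  stat <- unname(ht$statistic)
  # a zero margin means one variable is constant: no association testable
  if (is.nan(stat)) stat <- 0
  tibble::tibble(
    statistic = stat,
    df = unname(ht$parameter),
    p_raw = if (is.nan(ht$p.value)) 1 else unname(ht$p.value)
  )
}

#' Two-sided Mann-Whitney U test (normal approximation)
#'
#' @param sample_a,sample_b Numeric samples.
#' @return One-row tibble with `statistic` (U of `sample_a`), `df` (`NA`),
#'   `p_raw`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = FALSE, correct = FALSE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = NA_real_,
    p_raw = unname(ht$p.value)
  )
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of tests (defaults to `length(p_values)`).
#' @return Adjusted p-values, `pmin(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  pmin(1, p_values * m)
}

#' Per-position residue enrichment between positive and negative windows
#'
#' For every window offset and every residue observed there, builds the 2x2
#' presence table (class x residue-present-at-position) and applies the
#' chi-square test of independence, with Bonferroni correction over all
#' tests performed.
#'
#' @param windows Labeled window tibble (columns `window`, `label`).
#' @param yates Continuity correction flag passed through.
#' @param min_count Minimum total presence count for a (position, residue)
#'   pair to be tested (default 1).
#' @return Tibble with columns `position`, `residue`, `pos_present`,
#'   `neg_present`, `pos_total`, `neg_total`, `statistic`, `df`, `p_raw`,
#'   `p_adjusted`, sorted by adjusted then raw p-value.
#' @export
position_enrichment <- function(windows, yates = FALSE, min_count = 1) {
  stopifnot(nrow(windows) > 0)
  n <- window_flank(windows$window[1])
  chars <- do.call(rbind, strsplit(windows$window, ""))
  pos <- windows$label == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("enrichment needs both classes present")
  }
  rows <- list()
  for (j in seq_len(ncol(chars))) {
    offset <- j - n - 1L
    col <- chars[, j]
    for (res in intersect(AA_LETTERS, unique(col))) {
      a <- sum(pos & col == res)
      c_ <- sum(!pos & col == res)
      if (a + c_ < min_count) next
      tab <- matrix(c(a, n_pos - a, c_, n_neg - c_), 2, 2, byrow = TRUE)
      ht <- chi_square_independence(tab, yates = yates)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        position = offset, residue = res,
        pos_present = a, neg_present = c_,
        pos_total = n_pos, neg_total = n_neg,
        statistic = ht$statistic, df = ht$df, p_raw = ht$p_raw
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_raw)
  dplyr::arrange(out, .data$p_adjusted, .data$p_raw)
}
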