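# Independent oracles used to cross-check the implementation. These are
# deliberately naive (dynamic programming, exhaustive enumeration, direct
# formulas) and share no code with the package internals.

# Needleman-Wunsch identity: match=1, mismatch=0, gap=-1, identity =
# matched columns / total alignment columns, diagonal-preferring traceback.
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A)
  lb <- length(B)
  S <- matrix(0, la + 1, lb + 1)
  S[1, ] <- -(0:lb)
  S[, 1] <- -(0:la)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + as.numeric(A[i] == B[j]),
        S[i, j + 1] - 1,
        S[i + 1, j] - 1
      )
    }
  }
  i <- la; j <- lb; matches <- 0; cols <- 0
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + as.numeric(A[i] == B[j])) {
      matches <- matches + as.numeric(A[i] == B[j])
      i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  matches / (cols + i + j)
}

# Plug-in mutual information (bits) by direct summation over joint cells.
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  N <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) {
        total <- total +
          nij / N * log2(nij * N / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  total
}

# All-pairs Mann-Whitney AUC: fraction of (positive, negative) pairs where
# the positive scores higher, ties counting one half.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels != "positive"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Direct MCC formula.
mcc_oracle <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) 0 else (tp * tn - fp * fn) / denom
}

# Direct evaluation of the confidence-ratio feature: 1 iff the flexible
# confidence sum is at least the rigid confidence sum (zero rigid sum: 1
# when any flexible residue exists).
conf_rat_oracle <- function(calls, confidences) {
  sf <- sum(confidences[calls == "F"])
  sr <- sum(confidences[calls == "R"])
  if (sr == 0) as.numeric(any(calls == "F")) else as.numeric(sf / sr >= 1)
}

# Exhaustive greedy MID ordering on a small code matrix (reference
# implementation with plain loops; lexicographic tie-break on names).
mid_order_oracle <- function(codes, y, max_features = ncol(codes)) {
  fnames <- colnames(codes)
  rel <- vapply(seq_len(ncol(codes)), function(j) mi_oracle(codes[, j], y),
                numeric(1))
  selected <- integer(0)
  avail <- seq_len(ncol(codes))
  for (r in seq_len(max_features)) {
    score <- vapply(avail, function(j) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) mi_oracle(codes[, j], codes[, s]),
                    numeric(1)))
      }
      rel[j] - red
    }, numeric(1))
    best <- max(score)
    cand <- avail[score >= best - 1e-12]
    pick <- cand[order(fnames[cand])][1]
    selected <- c(selected, pick)
    avail <- setdiff(avail, pick)
  }
  fnames[selected]
}

# 15%-of-element secondary-structure terminus rule, evaluated directly.
ss_terminus_oracle <- function(element_length, position_in_element) {
  cut <- ceiling(0.15 * element_length)
  off <- min(position_in_element - 1, element_length - position_in_element)
  as.numeric(off < cut)
}
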