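#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted site-classification model
#'
#' @param x A `nedd_model`.
#' @param ... Unused.
#' @return Tibble of the model's feature names in training order.
#' @export
tidy.nedd_model <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$features), feature = x$features)
}

#' @rdname tidy.nedd_model
#' @return `glance()` returns a one-row tibble with the tuned
#'   hyper-parameters, feature count, support-vector count and thresholds.
#' @export
glance.nedd_model <- function(x, ...) {
  tibble::tibble(
    cost = x$config$cost,
    gamma = x$config$gamma,
    class_weight = x$config$class_weight,
    n_features = length(x$features),
    n_support = x$fit$tot.nSV,
    threshold_medium = x$thresholds$medium,
    threshold_high = x$thresholds$high
  )
}

#' Tidy an incremental-feature-selection result
#'
#' @param x A `nedd_ifs`.
#' @param ... Unused.
#' @return The AUC-vs-prefix-size curve as a tibble.
#' @export
tidy.nedd_ifs <- function(x, ...) x$curve

#' @rdname tidy.nedd_ifs
#' @export
glance.nedd_ifs <- function(x, ...) {
  tibble::tibble(
    k_star = x$k_star,
    best_auc = max(x$curve$auc),
    cost = x$config$cost,
    gamma = x$config$gamma
  )
}

#' Tidy a repeated cross-validation result
#'
#' @param x A `nedd_cv`.
#' @param ... Unused.
#' @return Per-repeat metrics (`tidy`) or the mean metric row (`glance`).
#' @export
tidy.nedd_cv <- function(x, ...) x$per_repeat

#' @rdname tidy.nedd_cv
#' @export
glance.nedd_cv <- function(x, ...) x$mean

#' Tidy a fitted pipeline
#'
#' @param x A `nedd_fit`.
#' @param ... Unused.
#' @return The mRMR selection table with a `selected` flag marking the
#'   retained prefix (`tidy`), or a one-row pipeline summary (`glance`).
#' @export
tidy.nedd_fit <- function(x, ...) {
  out <- x$mrmr
  out$selected <- out$rank <= x$ifs$k_star
  out
}

#' @rdname tidy.nedd_fit
#' @export
glance.nedd_fit <- function(x, ...) {
  tibble::tibble(
    k_star = x$ifs$k_star,
    cost = x$config$cost,
    gamma = x$config$gamma,
    class_weight = x$config$class_weight,
    n_train = x$n_train,
    window = 2 * (x$window_flank %||% 10) + 1
  )
}

#' @export
print.nedd_fit <- function(x, ...) {
  cat("Neddylation-site prediction pipeline fit\n")
  cat("  training windows: ", x$n_train, "\n", sep = "")
  cat("  selected features: ", x$ifs$k_star, " (of ", nrow(x$mrmr),
      " mRMR-ordered)\n", sep = "")
  cat("  SVM: cost=", format(x$config$cost),
      " gamma=", format(x$config$gamma),
      " positive-class weight=", format(x$config$class_weight),
      "\n", sep = "")
  cat("  decision thresholds: medium=0, high=1\n")
  invisible(x)
}

#' @export
print.nedd_model <- function(x, ...) {
  cat("Class-weighted RBF-SVM site classifier (",
      length(x$features), " features)\n", sep = "")
  print(glance.nedd_model(x))
  invisible(x)
}
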