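#' Feature sets of the two classifier variants
#'
#' `crystal` combines the CDR cavity volume with the CDR-H3 hydrophobic
#' surface area (for antibodies with crystal structures); `modeled` combines
#' the CDR-H3 hydrophobic area with the binary glycine presence at the CDR-H2
#' turn (for homology-modeled structures, whose cavity volumes are unreliable).
#'
#' @param variant `"crystal"` or `"modeled"`.
#' @return Character vector of feature column names.
#' @export
variant_features <- function(variant = c("crystal", "modeled")) {
  switch(match.arg(variant),
         crystal = c("cavity_volume", "h3_hydrophobic_area"),
         modeled = c("h3_hydrophobic_area", "gly_h2_turn_present"))
}

svm_grid <- function(c_exponents = -5:15, gamma_exponents = -15:3) {
  g <- expand.grid(C = 2^c_exponents, gamma = 2^gamma_exponents)
  g[order(g$C, g$gamma), , drop = FALSE]
}

# Scale columns to [-1, 1] by training min/max (libsvm svm-scale default);
# constant columns map to -1.
scale_features <- function(x, mins, maxs) {
  rng <- maxs - mins
  rng[rng == 0] <- 1
  -1 + 2 * sweep(sweep(x, 2, mins), 2, rng, "/")
}

feature_matrix <- function(dataset, features) {
  missing_cols <- setdiff(features, names(dataset))
  if (length(missing_cols)) {
    stop("feature(s) absent from dataset: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(dataset[, features, drop = FALSE])
  if (anyNA(x)) {
    bad <- dataset$antibody[apply(is.na(x), 1, any)]
    stop("missing feature value for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

# Grid search: for each (C, gamma) the leave-one-out cross-validation
# accuracy on (x, y); returns the first maximum in (C, gamma) order (ties
# broken toward smaller C, then smaller gamma). Deterministic: LOO folds are
# singletons, so fold assignment cannot vary.
grid_search_loo <- function(x, y, grid = svm_grid()) {
  n <- nrow(x)
  yf <- factor(y, levels = c(0, 1))
  best <- -Inf
  best_row <- NULL
  for (k in seq_len(nrow(grid))) {
    fit <- e1071::svm(x, yf, type = "C-classification", kernel = "radial",
                      cost = grid$C[k], gamma = grid$gamma[k],
                      scale = FALSE, cross = n)
    if (fit$tot.accuracy > best + 1e-9) {
      best <- fit$tot.accuracy
      best_row <- grid[k, ]
    }
  }
  list(C = best_row$C, gamma = best_row$gamma, loo_accuracy = best)
}

#' Train the immunogenicity SVM
#'
#' Radial-basis-function SVM over the chosen feature set. Features are scaled
#' to `[-1, 1]` by the training min/max (frozen into the model); `(C, gamma)`
#' are selected over the grid `C = 2^-5..2^15`, `gamma = 2^-15..2^3` (integer
#' exponents) by maximizing leave-one-out cross-validation accuracy on the
#' training set, ties broken toward smaller `C` then smaller `gamma` — the
#' libsvm-recommended selection protocol, made deterministic by using
#' leave-one-out folds.
#'
#' @param dataset A data.frame with the feature columns and a `label` column
#'   (1 = immunogenic, 0 = non-immunogenic). A `gly_count` column is
#'   converted to `gly_h2_turn_present` automatically when needed.
#' @param variant `"crystal"` or `"modeled"` (ignored when `features` given).
#' @param features Character vector of feature column names, overriding the
#'   variant presets (e.g. all three features).
#' @param grid Hyperparameter grid (data.frame with `C`, `gamma`).
#' @return A `pitha_model`: the fitted e1071 SVM plus frozen scaling, the
#'   selected `(C, gamma)` and the training leave-one-out accuracy.
#' @export
train_svm <- function(dataset, variant = c("crystal", "modeled"),
                      features = NULL, grid = svm_grid()) {
  dataset <- ensure_gly_present(dataset)
  if (is.null(features)) features <- variant_features(variant)
  y <- check_labels(dataset)
  if (nrow(dataset) < 6) stop("need at least 6 labeled antibodies", call. = FALSE)

  x <- feature_matrix(dataset, features)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  xs <- scale_features(x, mins, maxs)

  sel <- grid_search_loo(xs, y, grid)
  fit <- e1071::svm(xs, factor(y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = sel$C, gamma = sel$gamma, scale = FALSE)
  structure(
    list(fit = fit, features = features, mins = mins, maxs = maxs,
         C = sel$C, gamma = sel$gamma, loo_accuracy = sel$loo_accuracy,
         n_train = nrow(x)),
    class = "pitha_model"
  )
}

check_labels <- function(dataset) {
  if (is.null(dataset$label)) stop("dataset has no label column", call. = FALSE)
  y <- as.integer(dataset$label)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("dataset contains a single class; both labels required", call. = FALSE)
  }
  y
}

ensure_gly_present <- function(dataset) {
  if (is.null(dataset$gly_h2_turn_present) && !is.null(dataset$gly_count)) {
    dataset$gly_h2_turn_present <- gly_present(dataset$gly_count)
  }
  dataset
}

#' @export
print.pitha_model <- function(x, ...) {
  cat("RBF-SVM immunogenicity model\n")
  cat("  features:", paste(x$features, collapse = " + "), "\n")
  cat(sprintf("  C = 2^%g, gamma = 2^%g (selected by LOO on %d antibodies)\n",
              log2(x$C), log2(x$gamma), x$n_train))
  cat(sprintf("  training LOO accuracy: %.1f%%\n", x$loo_accuracy))
  invisible(x)
}

#' Predict immunogenicity labels
#'
#' @param object A `pitha_model`.
#' @param newdata data.frame carrying the model's feature columns.
#' @param ... Unused.
#' @return Integer vector of predicted labels, 1 = immunogenic,
#'   0 = non-immunogenic, named by `antibody` when present.
#' @export
predict.pitha_model <- function(object, newdata, ...) {
  newdata <- ensure_gly_present(newdata)
  x <- feature_matrix(newdata, object$features)
  xs <- scale_features(x, object$mins, object$maxs)
  pred <- as.integer(as.character(predict(object$fit, xs)))
  if (!is.null(newdata$antibody)) names(pred) <- newdata$antibody
  pred
}

#' Leave-one-out accuracy of the immunogenicity SVM
#'
#' Default protocol (the one used for the published accuracies): features are
#' scaled once on the full dataset, and the reported number is the
#' leave-one-out cross-validation accuracy at the `(C, gamma)` selected by
#' maximizing that same LOO accuracy over the grid — libsvm's recommended
#' parameter-selection procedure, with the selected model's cross-validation
#' accuracy quoted as the result. Because parameters are chosen on all `n`
#' samples, this estimate is optimistically biased; `nested = TRUE` instead
#' re-runs scaling and grid selection inside every outer fold, giving an
#' unbiased (and typically lower) estimate.
#'
#' @inheritParams train_svm
#' @param nested Use the conservative nested protocol (default `FALSE`).
#' @return List with `accuracy` (percent), `n_correct`, `n`, and (non-nested
#'   only) the selected `C` and `gamma`.
#' @export
loo_accuracy <- function(dataset, variant = c("crystal", "modeled"),
                         features = NULL, grid = svm_grid(), nested = FALSE) {
  dataset <- ensure_gly_present(dataset)
  if (is.null(features)) features <- variant_features(variant)
  y <- check_labels(dataset)
  x <- feature_matrix(dataset, features)
  n <- nrow(x)

  if (!nested) {
    xs <- scale_features(x, apply(x, 2, min), apply(x, 2, max))
    sel <- grid_search_loo(xs, y, grid)
    n_correct <- round(sel$loo_accuracy * n / 100)
    return(list(accuracy = sel$loo_accuracy, n_correct = n_correct, n = n,
                C = sel$C, gamma = sel$gamma))
  }

  correct <- 0L
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    mins <- apply(xtr, 2, min)
    maxs <- apply(xtr, 2, max)
    xs <- scale_features(xtr, mins, maxs)
    sel <- grid_search_loo(xs, y[-i], grid)
    fit <- e1071::svm(xs, factor(y[-i], levels = c(0, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = sel$C, gamma = sel$gamma, scale = FALSE)
    pred <- predict(fit, scale_features(x[i, , drop = FALSE], mins, maxs))
    if (as.integer(as.character(pred)) == y[i]) correct <- correct + 1L
  }
  list(accuracy = 100 * correct / n, n_correct = correct, n = n)
}

#' Classification accuracy of predictions against labels
#'
#' @param predicted,labels Integer 0/1 vectors of equal length.
#' @return Percentage of matching entries.
#' @export
prediction_accuracy <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  100 * mean(as.integer(predicted) == as.integer(labels))
}

#' Read and write feature-table CSVs
#'
#' The dataset dialect is
#' `antibody,cavity_volume,h3_hydrophobic_area,gly_count,label,source`
#' (columns other than `antibody` optional where the downstream variant does
#' not need them).
#'
#' @param path CSV file path.
#' @return `read_feature_csv()`: a data.frame with `gly_h2_turn_present`
#'   derived from `gly_count` when present.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$antibody)) stop("feature CSV needs an antibody column",
                                 call. = FALSE)
  if (nrow(df) == 0) stop("empty feature file: ", path, call. = FALSE)
  if (anyDuplicated(df$antibody)) stop("duplicate antibody names", call. = FALSE)
  ensure_gly_present(df)
}

#' @rdname read_feature_csv
#' @param dataset Feature data.frame.
#' @export
write_feature_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a trained model to JSON and back
#'
#' The container stores the kernel parameters, support vectors, coefficients,
#' decision offset, label order and the frozen feature scaling — everything
#' needed to reproduce the decision function exactly.
#'
#' @param model A `pitha_model`.
#' @param path Output/input JSON path.
#' @return `write_model()` the path; `read_model()` a `pitha_model_json`
#'   usable with `predict()`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pitha_model"))
  fit <- model$fit
  obj <- list(
    kernel = "radial",
    features = model$features,
    mins = as.list(model$mins),
    maxs = as.list(model$maxs),
    C = model$C,
    gamma = model$gamma,
    support_vectors = unname(apply(fit$SV, 1, as.numeric, simplify = FALSE)),
    dual_coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    labels = as.integer(as.character(fit$levels[fit$labels])),
    loo_accuracy = model$loo_accuracy,
    n_train = model$n_train
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.matrix(obj$support_vectors)) {
    obj$support_vectors <- matrix(unlist(obj$support_vectors),
                                  ncol = length(obj$features), byrow = TRUE)
  }
  obj$mins <- unlist(obj$mins)
  obj$maxs <- unlist(obj$maxs)
  class(obj) <- "pitha_model_json"
  obj
}

#' @export
predict.pitha_model_json <- function(object, newdata, ...) {
  newdata <- ensure_gly_present(newdata)
  x <- feature_matrix(newdata, object$features)
  xs <- scale_features(x, object$mins, object$maxs)
  sv <- object$support_vectors
  pred <- integer(nrow(xs))
  for (i in seq_len(nrow(xs))) {
    d2 <- rowSums(sweep(sv, 2, xs[i, ])^2)
    dec <- sum(object$dual_coefs * exp(-object$gamma * d2)) - object$rho
    pred[i] <- if (dec > 0) object$labels[1] else object$labels[2]
  }
  if (!is.null(newdata$antibody)) names(pred) <- newdata$antibody
  pred
}
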