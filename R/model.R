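#' Train the deleteriousness model
#'
#' Fits an L2-regularized logistic regression contrasting proxy-deleterious
#' (`y = 1`) against proxy-neutral (`y = 0`) variants. Features are
#' standardized to mean 0 / sd 1 and the standardization parameters,
#' imputation medians and column order are frozen into the model so that
#' scoring reproduces training-time preprocessing exactly. The
#' regularization strength is selected on a 10% holdout (by AUROC) from a
#' small grid of inverse-strength values; the model is then refit on the
#' full training set at the selected strength.
#'
#' @param features A `feature_matrix` from [build_features()].
#' @param y Binary labels, 1 = proxy-deleterious, 0 = proxy-neutral.
#' @param reg_strength Grid of inverse regularization strengths (larger =
#'   weaker penalty); a single value skips selection.
#' @param seed Integer seed controlling the holdout split.
#' @return An object of class `deleteriousness_model`.
#' @export
train_deleteriousness <- function(features, y,
                                  reg_strength = c(0.01, 0.1, 1, 10),
                                  seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("both classes must be present")
  cols <- feature_columns(features)
  X <- as.matrix(as_tibble(features)[, cols, drop = FALSE])
  if (nrow(X) != length(y)) abort("features and labels disagree in length")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0)) abort(paste0("constant feature column(s): ",
                                  paste(cols[sdv == 0], collapse = ", ")))
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  withr::local_seed(seed)
  n <- nrow(Xs)
  hold <- sample.int(n, max(2L, floor(0.1 * n)))
  chosen <- reg_strength[1]
  holdout_auroc <- NA_real_
  if (length(reg_strength) > 1) {
    if (length(unique(y[hold])) < 2 || length(unique(y[-hold])) < 2) {
      abort("holdout split lost a class; provide more data or one reg_strength")
    }
    perf <- vapply(reg_strength, function(C) {
      f <- ridge_logistic(Xs[-hold, , drop = FALSE], y[-hold], C)
      eta <- drop(Xs[hold, , drop = FALSE] %*% f$beta) + f$intercept
      auroc_u(eta, y[hold])
    }, 0)
    chosen <- reg_strength[which.max(perf)]
    holdout_auroc <- max(perf)
  }
  fit <- ridge_logistic(Xs, y, chosen)
  structure(list(
    coefficients = setNames(drop(fit$beta), cols),
    intercept = fit$intercept,
    feature_cols = cols,
    standardization = list(mean = setNames(mu, cols), sd = setNames(sdv, cols)),
    impute = attr(features, "impute"),
    cross = attr(features, "cross"),
    consequences = attr(features, "consequences"),
    metadata = list(seed = seed, reg_strength = chosen,
                    reg_grid = reg_strength, holdout_auroc = holdout_auroc,
                    n_train = as.integer(table(factor(y, levels = 0:1))),
                    solver = "glmnet (alpha = 0)", tol = 1e-10)
  ), class = "deleteriousness_model")
}

# ridge logistic fit; C is inverse strength (penalty = ||beta||^2 / (2 C n))
ridge_logistic <- function(X, y, C) {
  lam <- 1 / (C * nrow(X))
  f <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = lam, standardize = FALSE, thresh = 1e-10,
                      maxit = 1e6)
  if (f$jerr != 0) abort(paste0("logistic fit did not converge (jerr=", f$jerr, ")"))
  list(beta = as.numeric(f$beta), intercept = as.numeric(f$a0))
}

# tie-corrected Mann-Whitney AUROC (internal fast path)
auroc_u <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Raw deleteriousness scores
#'
#' Returns the linear predictor (logit) of the trained model: negative
#' values lean proxy-neutral, positive values lean proxy-deleterious. The
#' feature columns must match the training columns exactly.
#'
#' @param model A `deleteriousness_model`.
#' @param features A `feature_matrix` built with `template = model`.
#' @return Numeric vector of raw scores, one per row of `features`.
#' @export
raw_score <- function(model, features) {
  cols <- feature_columns(features) %||% colnames(features)
  missing_cols <- setdiff(model$feature_cols, cols)
  extra <- setdiff(cols, model$feature_cols)
  if (length(missing_cols) || length(extra)) {
    abort(paste0("feature columns do not match the model",
                 if (length(missing_cols)) paste0("; missing: ",
                                                  paste(missing_cols, collapse = ", ")),
                 if (length(extra)) paste0("; extra: ",
                                           paste(extra, collapse = ", "))))
  }
  X <- as.matrix(as_tibble(features)[, model$feature_cols, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$standardization$mean), 2,
              model$standardization$sd, "/")
  drop(Xs %*% model$coefficients) + model$intercept
}

#' @export
predict.deleteriousness_model <- function(object, features,
                                          type = c("link", "response"), ...) {
  eta <- raw_score(object, features)
  if (match.arg(type) == "response") stats::plogis(eta) else eta
}

#' @export
print.deleteriousness_model <- function(x, ...) {
  cat("<deleteriousness_model>\n")
  cat("  features:", length(x$feature_cols),
      "| reg strength (inverse):", x$metadata$reg_strength, "\n")
  cat("  n_train:", paste(x$metadata$n_train, collapse = " / "),
      "(neutral / deleterious)\n")
  if (!is.na(x$metadata$holdout_auroc)) {
    cat("  holdout AUROC:", sprintf("%.3f", x$metadata$holdout_auroc), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.deleteriousness_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @exportS3Method generics::glance
glance.deleteriousness_model <- function(x, ...) {
  tibble(n_neutral = x$metadata$n_train[1],
         n_deleterious = x$metadata$n_train[2],
         n_features = length(x$feature_cols),
         reg_strength = x$metadata$reg_strength,
         holdout_auroc = x$metadata$holdout_auroc)
}

#' Serialize / read a trained model as JSON
#'
#' @param model A `deleteriousness_model`.
#' @param path File path.
#' @return `path` invisibly; `read_deleteriousness_model()` returns the
#'   model.
#' @export
write_deleteriousness_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_deleteriousness_model
#' @export
read_deleteriousness_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- unlist(x$coefficients)
  x$impute <- unlist(x$impute)
  x$standardization <- lapply(x$standardization, unlist)
  structure(x, class = "deleteriousness_model")
}
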