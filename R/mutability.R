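# Regularized (elastic-net) modelling of site mutability: feature-matrix
# construction with near-zero-variance filtering and training-only
# standardization, a replicate ensemble of penalized logistic fits, binned
# calibration of predicted vs observed mutability, cross-dataset
# prediction, and a binary C>T spectrum classifier with class balancing.

#' Build a model feature matrix from context features
#'
#' Rows with any missing value are dropped; categorical predictors
#' (trinucleotide context slots, feature class) are expanded into indicator
#' columns; near-zero-variance columns (fewer than 2 distinct values, or
#' minority value frequency below `nzv_min_freq`) are removed. The matrix is
#' returned unscaled: standardization parameters are computed from training
#' rows only, at fit time.
#'
#' @param features data.frame from [context_features()].
#' @param label numeric/logical vector (0/1) aligned with `features` rows.
#' @param nzv_min_freq minority-frequency threshold for near-zero variance.
#' @return list: `x` (numeric matrix), `y`, `dropped` (column names removed),
#'   `kept_rows` (row indices of `features` retained).
#' @export
build_feature_matrix <- function(features, label, nzv_min_freq = 1e-4) {
  stopifnot(nrow(features) == length(label))
  df <- features[, setdiff(names(features), c("contig", "pos")), drop = FALSE]
  keep <- stats::complete.cases(df) & !is.na(label)
  df <- df[keep, , drop = FALSE]
  y <- as.numeric(label[keep])
  if (!nrow(df)) stop("no rows left after removing missing values")
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      for (lev in sort(unique(v)))
        cols[[paste0(nm, "_", lev)]] <- as.numeric(v == lev)
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  nzv <- vapply(seq_len(ncol(x)), function(j) {
    tab <- table(x[, j])
    length(tab) < 2L || (1 - max(tab) / nrow(x)) < nzv_min_freq
  }, logical(1))
  list(x = x[, !nzv, drop = FALSE], y = y,
       dropped = colnames(x)[nzv], kept_rows = which(keep))
}

# center/scale with training statistics; returns scaled x and the params
standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = scale(x, center = ctr, scale = scl), center = ctr, scale = scl)
}

standardize_apply <- function(x, center, scale) {
  scale(x, center = center[colnames(x)], scale = scale[colnames(x)])
}

# label-stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit the elastic-net mutability model
#'
#' Penalized logistic regression (elastic-net mixing `alpha`) of mutated vs
#' non-mutated sites. Each of `replicates` fits draws `n_nonmutated` random
#' non-mutated rows (without replacement) together with all mutated rows,
#' holds out `1 - split` of them, standardizes with training statistics
#' only, and selects the penalty strength at minimum cross-validated
#' deviance over label-stratified folds. Coefficient medians and 95%
#' intervals are taken across the replicate ensemble.
#'
#' @param fm list from [build_feature_matrix()].
#' @param n_nonmutated non-mutated rows sampled per replicate.
#' @param cv_folds cross-validation folds.
#' @param split fraction of each replicate's data used for training.
#' @param replicates ensemble size (default 10).
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param seed RNG seed.
#' @return object of class `ma_mutmodel`: per-replicate coefficients and
#'   scaling, `coef_summary` (term, median, ci_lo, ci_hi), settings.
#' @export
train_mutability <- function(fm, n_nonmutated = 1e5, cv_folds = 10L,
                             split = 0.75, replicates = 10L, alpha = 0.5,
                             seed = 1L) {
  if (length(unique(fm$y)) < 2L) stop("need both classes present")
  pos <- which(fm$y == 1)
  neg <- which(fm$y == 0)
  reps <- lapply(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, r))
    neg_r <- sample(neg, min(n_nonmutated, length(neg)))
    idx <- c(pos, neg_r)
    train <- sample(idx, round(split * length(idx)))
    sf <- standardize_fit(fm$x[train, , drop = FALSE])
    yt <- fm$y[train]
    foldid <- stratified_folds(yt, cv_folds)
    cv <- glmnet::cv.glmnet(sf$x, yt, family = "binomial", alpha = alpha,
                            foldid = foldid, standardize = FALSE)
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
    list(coef = cf, lambda = cv$lambda.min, center = sf$center,
         scale = sf$scale, seed = derive_seed(seed, r))
  })
  terms <- names(reps[[1]]$coef)
  cmat <- vapply(reps, function(r) r$coef, numeric(length(terms)))
  summ <- data.frame(
    term = terms,
    median = apply(cmat, 1, stats::median),
    ci_lo = apply(cmat, 1, stats::quantile, probs = 0.025),
    ci_hi = apply(cmat, 1, stats::quantile, probs = 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(replicates = reps, coef_summary = summ, alpha = alpha,
                 columns = colnames(fm$x), split = split,
                 cv_folds = cv_folds, seed = seed),
            class = "ma_mutmodel")
}

#' @export
print.ma_mutmodel <- function(x, ...) {
  nz <- sum(x$coef_summary$median != 0) - 1L
  cat("ma_mutmodel:", length(x$replicates), "replicate fits,",
      length(x$columns), "predictors,", nz, "nonzero median coefficients\n")
  invisible(x)
}

#' Predicted mutability for a feature matrix
#'
#' Averages the per-replicate predicted probabilities (each replicate uses
#' its own training standardization).
#'
#' @param model an `ma_mutmodel`.
#' @param x feature matrix with the model's columns.
#' @return numeric vector of predicted probabilities.
#' @export
predict_mutability <- function(model, x) {
  shared <- intersect(model$columns, colnames(x))
  if (!length(shared)) stop("feature schemas share no columns")
  preds <- vapply(model$replicates, function(r) {
    xs <- standardize_apply(x[, shared, drop = FALSE],
                            r$center, r$scale)
    eta <- r$coef["(Intercept)"] +
      as.numeric(xs %*% r$coef[shared])
    1 / (1 + exp(-eta))
  }, numeric(nrow(x)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(x))
  rowMeans(preds)
}

#' Binned calibration of predicted vs observed mutability
#'
#' Predicted probabilities are binned to 1 decimal place; the observed
#' mutation fraction is computed per bin and regressed on the bin value by
#' least squares weighted by the number of sites per bin.
#'
#' @param model an `ma_mutmodel`.
#' @param fm test feature matrix (list with `x`, `y`).
#' @return list: `bins` (data.frame p_bin, observed, n), `slope`,
#'   `r_squared`, `p_value` (NA when fewer than 2 bins).
#' @export
calibrate_predictions <- function(model, fm) {
  p <- predict_mutability(model, fm$x)
  bin <- round(p, 1)
  bins <- data.frame(
    p_bin = as.numeric(names(table(bin))),
    observed = as.numeric(tapply(fm$y, bin, mean)),
    n = as.integer(table(bin)), row.names = NULL)
  if (nrow(bins) < 2L)
    return(list(bins = bins, slope = NA_real_, r_squared = NA_real_,
                p_value = NA_real_))
  fit <- stats::lm(observed ~ p_bin, data = bins, weights = bins$n)
  sf <- summary(fit)
  list(bins = bins, slope = unname(stats::coef(fit)[2]),
       r_squared = sf$r.squared,
       p_value = sf$coefficients["p_bin", "Pr(>|t|)"])
}

#' Cross-dataset prediction
#'
#' Applies a model trained on dataset A (its scaling and coefficients) to
#' the features of dataset B, over the shared feature columns, and returns
#' the binned calibration on B.
#'
#' @param model an `ma_mutmodel` trained on A.
#' @param fm_b feature matrix of B (list with `x`, `y`).
#' @return as [calibrate_predictions()], plus `shared_columns` and
#'   `missing_columns`.
#' @export
cross_predict <- function(model, fm_b) {
  shared <- intersect(model$columns, colnames(fm_b$x))
  if (!length(shared)) stop("feature schemas share no columns")
  missing <- setdiff(model$columns, colnames(fm_b$x))
  cal <- calibrate_predictions(model, fm_b)
  cal$shared_columns <- shared
  cal$missing_columns <- missing
  cal
}

# simple SMOTE: synthesize minority rows by interpolating towards one of
# the k nearest minority neighbours
smote_minority <- function(x_min, n_new, k = 5L) {
  n <- nrow(x_min)
  k <- min(k, n - 1L)
  if (k < 1L) return(x_min[rep(seq_len(n), length.out = n_new), , drop = FALSE])
  d <- as.matrix(stats::dist(x_min))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  i <- sample.int(n, n_new, replace = TRUE)
  j <- nn[cbind(i, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  x_min[i, , drop = FALSE] +
    u * (x_min[j, , drop = FALSE] - x_min[i, , drop = FALSE])
}

balance_training <- function(x, y, balancing) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg))
    stop("a class is empty; cannot balance")
  if (balancing == "none") return(list(x = x, y = y))
  n_min <- min(length(pos), length(neg))
  n_maj <- max(length(pos), length(neg))
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  if (balancing == "down") {
    keep <- c(minority, sample(majority, n_min))
    return(list(x = x[keep, , drop = FALSE], y = y[keep]))
  }
  if (balancing == "up") {
    extra <- sample(minority, n_maj - n_min, replace = TRUE)
    keep <- c(minority, majority, extra)
    return(list(x = x[keep, , drop = FALSE], y = y[keep]))
  }
  # smote
  synth <- smote_minority(x[minority, , drop = FALSE], n_maj - n_min)
  list(x = rbind(x[c(minority, majority), , drop = FALSE], synth),
       y = c(y[c(minority, majority)], rep(y[minority[1]], nrow(synth))))
}

#' Binary C>T spectrum classifier
#'
#' Elastic-net logistic classifier of whether an SNM is a C>T transition,
#' with optional class balancing of the training split. Accuracy on the
#' held-out fraction is compared with the majority-class baseline by an
#' exact binomial test.
#'
#' @param fm feature matrix of SNM sites (list with `x`, `y` where y = 1
#'   for C>T).
#' @param balancing one of "none", "down", "up", "smote".
#' @param split training fraction (default 0.75).
#' @param alpha elastic-net mixing parameter.
#' @param cv_folds cross-validation folds.
#' @param seed RNG seed.
#' @return list: accuracy, baseline, p_value (exact binomial vs baseline),
#'   n_test, coef.
#' @export
train_ct_classifier <- function(fm, balancing = c("none", "down", "up",
                                                  "smote"),
                                split = 0.75, alpha = 0.5, cv_folds = 10L,
                                seed = 1L) {
  balancing <- match.arg(balancing)
  if (length(unique(fm$y)) < 2L) stop("need both classes present")
  set.seed(seed)
  n <- length(fm$y)
  train <- sample(seq_len(n), round(split * n))
  test <- setdiff(seq_len(n), train)
  sf <- standardize_fit(fm$x[train, , drop = FALSE])
  bal <- balance_training(sf$x, fm$y[train], balancing)
  if (length(unique(bal$y)) < 2L) stop("a class is empty after balancing")
  foldid <- stratified_folds(bal$y, cv_folds)
  cv <- glmnet::cv.glmnet(bal$x, bal$y, family = "binomial", alpha = alpha,
                          foldid = foldid, standardize = FALSE)
  xs <- standardize_apply(fm$x[test, , drop = FALSE], sf$center, sf$scale)
  p <- as.numeric(stats::predict(cv, xs, s = "lambda.min",
                                 type = "response"))
  pred <- as.numeric(p > 0.5)
  acc <- mean(pred == fm$y[test])
  baseline <- max(mean(fm$y[test]), 1 - mean(fm$y[test]))
  bt <- stats::binom.test(sum(pred == fm$y[test]), length(test),
                          p = baseline, alternative = "greater")
  list(accuracy = acc, baseline = baseline, p_value = bt$p.value,
       n_test = length(test),
       coef = as.matrix(stats::coef(cv, s = "lambda.min"))[, 1])
}
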