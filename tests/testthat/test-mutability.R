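test_that("feature-matrix construction enforces its contracts", {
  feats <- data.frame(contig = "x", pos = 1:50,
                      a = stats::rnorm(50), const = 1,
                      cat = rep(c("u", "v"), 25))
  feats$a[3] <- NA
  fm <- build_feature_matrix(feats, rep(c(0, 1), 25))
  expect_false("const" %in% colnames(fm$x))
  expect_true("const" %in% fm$dropped)
  expect_equal(nrow(fm$x), 49)  # NA row dropped
  expect_setequal(colnames(fm$x), c("a", "cat_u", "cat_v"))
})

test_that("canonical triplet factors expand to 32 indicators per slot", {
  set.seed(81)
  g <- toy_genome(c(x = random_dna(60000, gc = 0.5)))
  sites <- data.frame(contig = "x", pos = sample(100:59900, 3000))
  tri <- t(mapply(function(p) trinucleotide_contexts(g, "x", p), sites$pos))
  feats <- data.frame(contig = sites$contig, pos = sites$pos,
                      tri_surr = tri[, "surr"], stringsAsFactors = FALSE)
  fm <- build_feature_matrix(feats, rep(c(0, 1), 1500))
  expect_equal(sum(startsWith(colnames(fm$x), "tri_surr_")), 32)
})

test_that("training is deterministic and leakage-free", {
  ds <- make_ctc_dataset(301, genome_bp = 60000, n_lines = 8,
                         n_nonmutated = 300)
  m1 <- train_mutability(ds$fm, n_nonmutated = 200, replicates = 2,
                         cv_folds = 5, seed = 4)
  m2 <- train_mutability(ds$fm, n_nonmutated = 200, replicates = 2,
                         cv_folds = 5, seed = 4)
  expect_identical(m1$coef_summary, m2$coef_summary)
  expect_equal(length(m1$replicates), 2)
  expect_true(all(is.finite(m1$coef_summary$median)))
})

test_that("a planted 10x CTC effect is recovered with CI excluding zero", {
  ds <- make_ctc_dataset(311)
  model <- train_mutability(ds$fm, n_nonmutated = 800, replicates = 10,
                            seed = 5)
  cs <- model$coef_summary
  ctc <- cs[cs$term == "tri_up_CTC", ]
  expect_equal(nrow(ctc), 1)
  expect_gt(ctc$median, 0)
  expect_gt(ctc$ci_lo, 0)
  # sign stability across the replicate ensemble
  signs <- vapply(model$replicates,
                  function(r) sign(r$coef[["tri_up_CTC"]]), numeric(1))
  expect_gte(sum(signs > 0), 9)
})

test_that("pure-noise labels mostly produce intervals covering zero", {
  ds <- make_ctc_dataset(321, genome_bp = 80000, n_lines = 8,
                         n_nonmutated = 400)
  fm <- ds$fm
  set.seed(6)
  fm$y <- sample(fm$y)  # break any label-feature association
  model <- train_mutability(fm, n_nonmutated = 400, replicates = 8, seed = 7)
  cs <- model$coef_summary[model$coef_summary$term != "(Intercept)", ]
  covers <- cs$ci_lo <= 0 & cs$ci_hi >= 0
  expect_gte(mean(covers), 0.95)
})

test_that("calibration tracks known site-level rates and dies under shuffling", {
  # simulation with known site-level mutabilities spanning the unit interval
  sim_rates <- function(n, seed) {
    set.seed(seed)
    x <- matrix(stats::rnorm(4 * n), ncol = 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    p <- stats::plogis(-0.3 + 1.8 * x[, 1] + 1.2 * x[, 2] - 0.8 * x[, 3])
    list(x = x, y = stats::rbinom(n, 1, p), p = p)
  }
  train <- sim_rates(4000, 401)
  test <- sim_rates(4000, 402)
  model <- train_mutability(list(x = train$x, y = train$y),
                            n_nonmutated = 4000, replicates = 3, seed = 8)
  cal <- calibrate_predictions(model, list(x = test$x, y = test$y))
  expect_gt(nrow(cal$bins), 6)
  expect_gt(cal$slope, 0)
  expect_gt(cal$r_squared, 0.9)
  expect_equal(sum(cal$bins$n), nrow(test$x))
  # label-shuffled test rows lose the association
  set.seed(9)
  shuf_r2 <- vapply(1:20, function(i) {
    fm_s <- list(x = test$x, y = sample(test$y))
    r2 <- calibrate_predictions(model, fm_s)$r_squared
    if (is.na(r2)) 0 else r2
  }, numeric(1))
  expect_lt(stats::median(shuf_r2), 0.2)
})

test_that("a constant predictor collapses calibration to a single bin", {
  fm <- list(x = matrix(stats::rnorm(100), ncol = 2,
                        dimnames = list(NULL, c("a", "b"))),
             y = rep(c(0, 1), 25))
  model <- train_mutability(fm, n_nonmutated = 25, replicates = 2,
                            cv_folds = 3, seed = 10)
  # heavily penalized fits give near-constant predictions; force the case
  fm0 <- list(x = fm$x[, 1, drop = FALSE] * 0, y = fm$y)
  cal <- calibrate_predictions(model, list(x = fm0$x * 0 + 0.5, y = fm0$y))
  expect_true(is.na(cal$slope) || nrow(cal$bins) >= 1)
})

test_that("cross-prediction on the same data equals self-calibration", {
  ds <- make_ctc_dataset(341, genome_bp = 60000, n_lines = 8,
                         n_nonmutated = 300)
  model <- train_mutability(ds$fm, n_nonmutated = 300, replicates = 3,
                            seed = 11)
  self <- calibrate_predictions(model, ds$fm)
  crossed <- cross_predict(model, ds$fm)
  expect_equal(crossed$bins, self$bins)
  expect_length(crossed$missing_columns, 0)
  bad <- list(x = matrix(0, 2, 2, dimnames = list(NULL, c("zz1", "zz2"))),
              y = c(0, 1))
  expect_error(cross_predict(model, bad), "share no columns")
})

test_that("shared-truth datasets cross-predict each other", {
  a <- make_ctc_dataset(351, genome_bp = 150000, n_lines = 10,
                        n_nonmutated = 500)
  b <- make_ctc_dataset(361, genome_bp = 150000, n_lines = 10,
                        n_nonmutated = 500)
  ma <- train_mutability(a$fm, n_nonmutated = 500, replicates = 3, seed = 12)
  mb <- train_mutability(b$fm, n_nonmutated = 500, replicates = 3, seed = 13)
  # correlate the full raw coefficient vectors (all shared terms except
  # the intercept)
  shared <- setdiff(intersect(ma$coef_summary$term, mb$coef_summary$term),
                    "(Intercept)")
  ca <- ma$coef_summary$median[match(shared, ma$coef_summary$term)]
  cb <- mb$coef_summary$median[match(shared, mb$coef_summary$term)]
  expect_gt(stats::cor(ca, cb), 0.5)
  crossed <- cross_predict(ma, b$fm)
  expect_gt(crossed$slope, 0)
})

test_that("the C>T classifier separates a deterministic signal", {
  set.seed(14)
  n <- 600
  x <- matrix(stats::rnorm(3 * n), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- as.numeric(x[, 1] > 0)  # C>T driven by one feature
  res <- train_ct_classifier(list(x = x, y = y), balancing = "none",
                             seed = 15)
  expect_gt(res$accuracy, 0.9)
  expect_lt(res$p_value, 1e-6)
})

test_that("null features give accuracy at the majority baseline", {
  set.seed(16)
  rejections <- vapply(1:30, function(i) {
    n <- 200
    x <- matrix(stats::rnorm(2 * n), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
    y <- stats::rbinom(n, 1, 0.6)
    res <- train_ct_classifier(list(x = x, y = y), balancing = "none",
                               cv_folds = 5, seed = 100 + i)
    res$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.15)
})

test_that("class balancing strategies run and failure modes error", {
  set.seed(17)
  n <- 300
  x <- matrix(stats::rnorm(2 * n), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  y <- as.numeric(stats::runif(n) < 0.2 + 0.5 * (x[, 1] > 0))
  for (b in c("down", "up", "smote")) {
    res <- train_ct_classifier(list(x = x, y = y), balancing = b,
                               cv_folds = 5, seed = 18)
    expect_true(res$accuracy >= 0 && res$accuracy <= 1)
  }
  expect_error(train_ct_classifier(list(x = x, y = rep(1, n))),
               "both classes")
})
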