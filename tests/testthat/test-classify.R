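make_gaussian_classes <- function(n_per_class, p = 5L, delta = 0, sd = 1,
                                  seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, 0, sd), ncol = p),
             matrix(rnorm(n_per_class * p, delta, sd), ncol = p))
  tab <- data.frame(
    individual_id = sprintf("I%04d", seq_len(2L * n_per_class)),
    side = "right",
    sex = rep(c("F", "M"), each = n_per_class),
    age = 50, stringsAsFactors = FALSE)
  cbind(tab, as.data.frame(X))
}

test_that("stratified splits have exact size and proportional strata", {
  tab <- generate_measurement_cohort(cohort_config(seed = 201L), sides = "right")
  sp <- stratified_split(tab, 50L, c("sex", "age_group"), seed = 1L)
  expect_equal(nrow(sp$test), 50L)
  expect_equal(nrow(sp$train), 226L)
  expect_equal(nrow(rbind(sp$train, sp$test)), nrow(tab))
  # sex ratio preserved within one bone
  expect_lt(abs(mean(sp$test$sex == "M") - mean(tab$sex == "M")), 1.5 / 50)
  # combined scope: 100 test bones, sides balanced within one bone
  tab2 <- generate_measurement_cohort(cohort_config(seed = 202L), sides = "both")
  sp2 <- stratified_split(tab2, 100L, c("sex", "age_group", "side"), seed = 1L)
  expect_equal(nrow(sp2$test), 100L)
  expect_equal(nrow(sp2$train), 452L)
  expect_lte(abs(sum(sp2$test$side == "right") - 50L), 1L)
  # different seeds change membership, not sizes
  sp3 <- stratified_split(tab, 50L, c("sex", "age_group"), seed = 2L)
  expect_equal(nrow(sp3$test), 50L)
  expect_false(identical(sort(rownames(sp$test)), sort(rownames(sp3$test))))
  expect_error(stratified_split(tab, 300L, "sex"), "smaller")
  expect_error(stratified_split(tab, 50L, "height"), "unknown stratification")
})

test_that("well-separated classes reach perfect CV accuracy", {
  tab <- make_gaussian_classes(100L, delta = 6, seed = 211L)
  m <- tune_and_fit(tab, "svm_linear", seed = 1L, n_candidates = 15L,
                    repeats = 3L)
  expect_equal(m$train_accuracy_pct, 100)
})

test_that("permuted labels give chance-level CV accuracy", {
  tab <- make_gaussian_classes(100L, delta = 2, seed = 221L)
  set.seed(222)
  tab$sex <- sample(tab$sex)
  m <- tune_and_fit(tab, "lr_l2", seed = 3L, n_candidates = 15L, repeats = 3L)
  expect_gte(m$train_accuracy_pct, 40)
  expect_lte(m$train_accuracy_pct, 60)
})

test_that("evaluation metrics match a hand-computed confusion matrix", {
  # degenerate all-male predictor on a balanced set
  truth <- factor(rep(c("F", "M"), each = 10L), levels = c("F", "M"))
  tab <- data.frame(individual_id = sprintf("I%02d", 1:20), side = "right",
                    sex = as.character(truth), age = 50,
                    f1 = c(rnorm(10, 0), rnorm(10, 50)),
                    stringsAsFactors = FALSE)
  model <- structure(list(
    algorithm = "lr_l2", C = 1, features = "f1",
    scaler = list(center = c(f1 = 0), scale = c(f1 = 1)),
    coef = c(f1 = 0), intercept = 5, platt = c(a = 1, b = 0),
    classes = c("F", "M")), class = "sex_model")
  ev <- evaluate_model(model, tab)   # intercept 5 > 0: predicts M always
  expect_equal(ev$accuracy_pct, 50)
  expect_equal(unname(ev$recall_pct["M"]), 100)
  expect_equal(unname(ev$recall_pct["F"]), 0)
  expect_equal(unname(ev$precision_pct["M"]), 50)
  # hand-computed confusion on 20 fixed predictions
  expect_equal(as.vector(ev$confusion), c(0L, 0L, 10L, 10L))

  # a working model against an explicit 2x2 oracle
  tab2 <- make_gaussian_classes(40L, delta = 2, seed = 231L)
  m <- tune_and_fit(tab2, "lr_l2", seed = 1L, n_candidates = 10L, repeats = 2L)
  pred <- predict(m, tab2)
  cm <- table(factor(tab2$sex, c("F", "M")), pred)
  ev2 <- evaluate_model(m, tab2)
  expect_equal(ev2$accuracy_pct, 100 * sum(diag(cm)) / sum(cm))
  expect_equal(unname(ev2$recall_pct["F"]), 100 * cm[1, 1] / sum(cm[1, ]))
  expect_equal(unname(ev2$precision_pct["F"]), 100 * cm[1, 1] / sum(cm[, 1]))
})

test_that("RFECV recovers planted informative features and respects edge cases", {
  hits <- 0L
  runs <- 20L
  for (r in seq_len(runs)) {
    set.seed(240L + r)
    n <- 300L
    informative <- matrix(rnorm(n * 5L), ncol = 5L)
    y <- rep(c("F", "M"), each = n / 2L)
    informative[y == "M", ] <- informative[y == "M", ] + 1.0
    noise <- matrix(rnorm(n * 20L), ncol = 20L)
    X <- cbind(informative, noise)
    colnames(X) <- c(paste0("inf", 1:5), paste0("noise", 1:20))
    tab <- cbind(data.frame(individual_id = sprintf("I%04d", 1:n),
                            side = "right", sex = y, age = 50,
                            stringsAsFactors = FALSE),
                 as.data.frame(X))
    sel <- rfecv_select(tab, seed = 240L + r)
    if (sum(grepl("^inf", sel)) >= 4L) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * runs)
})

test_that("RFECV passes single features through and gives chance accuracy on noise", {
  tab <- make_gaussian_classes(60L, delta = 1, seed = 251L)
  expect_equal(rfecv_select(tab, features = "V1"), "V1")
  # all-noise features: selected subset scores near 50%
  set.seed(252)
  tab_null <- make_gaussian_classes(100L, delta = 0, seed = 252L)
  sel <- rfecv_select(tab_null, seed = 9L)
  acc <- attr(sel, "cv_accuracy")
  expect_gt(max(acc, na.rm = TRUE), 0.35)
  expect_lt(max(acc, na.rm = TRUE), 0.65)
})

test_that("save/load round trips reproduce predictions bit-identically", {
  tab <- make_gaussian_classes(50L, delta = 3, seed = 261L)
  for (algo in c("lr_l1", "svm_linear")) {
    m <- tune_and_fit(tab, algo, seed = 1L, n_candidates = 8L, repeats = 2L)
    f <- withr::local_tempfile(fileext = ".rds")
    save_model(m, f)
    m2 <- load_model(f)
    expect_identical(predict(m, tab), predict(m2, tab))
    expect_identical(predict_proba(m, tab), predict_proba(m2, tab))
    expect_true(file.exists(paste0(f, ".json")))
    side <- jsonlite::read_json(paste0(f, ".json"))
    expect_equal(side$algorithm, algo)
  }
})

test_that("probabilities sum to one and follow coefficient signs", {
  tab <- make_gaussian_classes(60L, delta = 2, seed = 271L)
  m <- tune_and_fit(tab, "lr_l2", seed = 1L, n_candidates = 8L, repeats = 2L)
  p <- predict_proba(m, tab)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  # monotonicity: pushing a positively weighted feature raises P(M)
  j <- names(which.max(m$coef))
  tab_up <- tab
  tab_up[[j]] <- tab_up[[j]] + 5
  expect_true(all(predict_proba(m, tab_up)[, "M"] >= p[, "M"]))
})

test_that("feature mismatch on prediction is a named error", {
  tab <- make_gaussian_classes(40L, delta = 3, seed = 281L)
  m <- tune_and_fit(tab, "lr_l2", seed = 1L, n_candidates = 5L, repeats = 2L)
  bad <- tab[, setdiff(names(tab), "V2")]
  expect_error(predict(m, bad), "V2")
})

test_that("standardization makes tuned accuracy invariant to feature rescaling", {
  tab <- generate_measurement_cohort(
    cohort_config(n_males = 70L, n_females = 70L, seed = 291L), sides = "right")
  sp <- stratified_split(tab, 30L, c("sex", "age_group"), seed = 1L)
  m1 <- tune_and_fit(sp$train, "svm_linear", seed = 2L, n_candidates = 10L,
                     repeats = 2L)
  ev1 <- evaluate_model(m1, sp$test)
  scaled <- sp
  scaled$train$pubic_symphysis_width <- scaled$train$pubic_symphysis_width * 1000
  scaled$test$pubic_symphysis_width <- scaled$test$pubic_symphysis_width * 1000
  m2 <- tune_and_fit(scaled$train, "svm_linear", seed = 2L, n_candidates = 10L,
                     repeats = 2L)
  ev2 <- evaluate_model(m2, scaled$test)
  expect_lt(abs(ev1$accuracy_pct - ev2$accuracy_pct), 5)
})

test_that("L1 regularization strength controls sparsity", {
  tab <- make_gaussian_classes(80L, delta = 1.5, seed = 301L)
  y <- factor(tab$sex, levels = c("F", "M"))
  X <- as.matrix(tab[, paste0("V", 1:5)])
  Xs <- scale(X)
  tiny <- coxmorph:::fit_linear_classifier(Xs, y, "lr_l1", C = 1e-4)
  expect_equal(sum(tiny$coef != 0), 0L)
  big <- coxmorph:::fit_linear_classifier(Xs, y, "lr_l1", C = 1e2)
  l2 <- coxmorph:::fit_linear_classifier(Xs, y, "lr_l2", C = 1e2)
  expect_gt(sum(big$coef != 0), 0L)
  expect_lt(max(abs(big$coef - l2$coef)), 0.3)
})

test_that("single-class training data is rejected", {
  tab <- make_gaussian_classes(30L, delta = 1, seed = 311L)
  tab$sex <- "M"
  expect_error(tune_and_fit(tab, "lr_l2"), "both sexes")
})
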