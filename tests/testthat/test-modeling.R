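test_that("clinical statuses encode to 0/1 and reject unknown labels", {
  df <- data.frame(er = c("ER-positive", "er-negative"),
                   pr = c("Positive", "negative"),
                   er_pct = c("80", "0"), pr_pct = c(50, 0),
                   her2_cep17 = c(3.1, 6.7), stringsAsFactors = FALSE)
  out <- encode_clinical(df)
  expect_equal(out$er, c(1, 0))
  expect_equal(out$pr, c(1, 0))
  expect_equal(out$er_pct, c(80, 0))
  df$er <- c("ER-unknown", "ER-positive")
  expect_error(encode_clinical(df), "ER-unknown")
  df2 <- data.frame(er = c(0, 2), pr = c(0, 1), er_pct = 0, pr_pct = 0,
                    her2_cep17 = 1)
  expect_error(encode_clinical(df2), "0/1")
})

test_that("standardization learns on training rows only", {
  train <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  eval <- cbind(a = c(2, 10), b = c(0, 7))
  std <- standardize_fit_apply(train, eval)
  expect_equal(std$train[, "a"], c(-1, 0, 1) * sqrt(3 / 2))
  expect_equal(std$train[, "b"], c(0, 0, 0))       # constant column
  expect_equal(unname(std$eval[1, "a"]), 0)        # eval value = train mean
  expect_equal(std$eval[, "b"], c(0, 0))           # zero-variance -> 0
  # eval rows never influence the learned parameters
  std2 <- standardize_fit_apply(train, cbind(a = c(100, -100),
                                             b = c(9, 9)))
  expect_identical(std$center, std2$center)
  expect_identical(std$scale, std2$scale)
  expect_error(standardize_fit_apply(train, cbind(x = 1:2, b = 1:2)),
               "columns do not match")
})

test_that("missing sentinels are imputed with training medians", {
  train <- cbind(a = c(1, NA, 3, 4))
  std <- standardize_fit_apply(train, cbind(a = c(NA_real_)))
  # train median of {1,3,4} = 3 imputed, then standardized
  imputed <- c(1, 3, 3, 4)
  expect_equal(std$center, c(a = mean(imputed)))
  expect_equal(unname(std$eval[1, 1]),
               (3 - mean(imputed)) / sqrt(mean((imputed -
                                                  mean(imputed))^2)))
})

test_that("rank AUC matches pair enumeration and is monotone-invariant", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  expect_equal(auc_rank(scores, labels), 0.75)
  expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels))
  withr::with_seed(14, {
    for (i in 1:20) {
      y <- c(rep(1, 8), rep(0, 7))
      s <- round(stats::runif(15), 1)   # induces ties
      expect_equal(auc_rank(s, y), oracle_auc(s, y))
      expect_equal(auc_rank(s, y),
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))))
      expect_equal(auc_rank(stats::qlogis(pmin(pmax(s, 0.01), 0.99)), y),
                   auc_rank(s, y))      # strictly monotone transform
    }
  })
  expect_error(auc_rank(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("confusion-matrix metrics handle perfect and degenerate cases", {
  perfect <- evaluate_predictions(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[c("auc", "f1", "ppv", "recall", "npv")]),
               c(auc = 1, f1 = 1, ppv = 1, recall = 1, npv = 1))
  allpos <- evaluate_predictions(c(0.9, 0.8, 0.7), c(1, 0, 1))
  expect_equal(allpos$recall, 1)
  expect_true(is.na(allpos$npv))
  # F1 identity: from PPV/recall vs directly from counts
  withr::with_seed(15, {
    y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
    s <- stats::runif(40)
    m <- evaluate_predictions(s, y)
    tp <- sum(s >= 0.5 & y == 1); fp <- sum(s >= 0.5 & y == 0)
    fn <- sum(s < 0.5 & y == 1)
    expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
  })
})

test_that("stratified folds spread classes and shrink with a warning", {
  y <- c(rep(1, 30), rep(0, 20))
  f <- make_stratified_folds(y, 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f, y)[, "1"] == 3))
  y2 <- c(rep(1, 40), rep(0, 4))
  expect_warning(f2 <- make_stratified_folds(y2, 10, seed = 1),
                 "reducing folds")
  expect_equal(max(f2), 4L)
  expect_error(make_stratified_folds(c(1, 1, 1, 0), 3), "at least 2")
})

test_that("the strongest penalty shrinks every coefficient to zero", {
  withr::with_seed(16, {
    x <- matrix(rnorm(60 * 8), 60,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
    sel <- lasso_select(x, y, lambda_grid = c(5, 4), nfolds = 5, seed = 1)
    expect_length(sel$selected, 0L)
    expect_error(lasso_select(x, rep(1, 60)), "single class")
    expect_error(lasso_select(x, y, lambda_grid = numeric(0)),
                 "empty penalty grid")
  })
})

test_that("LASSO recovers planted informative features", {
  sim <- simulate_feature_cohort(n = 150, n_features = 30,
                                 n_informative = 3, effect = 1.5,
                                 seed = 21)
  std <- standardize_fit_apply(sim$x)
  sel <- lasso_select(std$train, sim$y, seed = 21)
  expect_true(all(sim$informative %in% sel$selected))
  expect_true(all(sel$weights[sim$informative] > 0))
})

test_that("MLP separates separable data and degenerates gracefully", {
  withr::with_seed(18, {
    x <- cbind(f1 = c(rnorm(30, -3), rnorm(30, 3)),
               f2 = rnorm(60))
    y <- rep(c(0, 1), each = 30)
    fit <- train_mlp(x, y, hidden_grid = 4L, decay_grid = 1e-3,
                     nfolds = 5, seed = 1)
    expect_equal(auc_rank(predict_mlp(fit, x), y), 1)
    # zero selected features -> constant 0.5 predictor
    none <- train_mlp(x[, integer(0), drop = FALSE], y)
    expect_equal(predict_mlp(none, x), rep(0.5, 60))
  })
})

test_that("shuffled labels carry no signal through the pipeline", {
  sim <- simulate_feature_cohort(n = 160, n_features = 12,
                                 n_informative = 3, effect = 1.5,
                                 seed = 33)
  y_shuf <- withr::with_seed(34, sample(sim$y))
  df <- data.frame(sim$x, pcr = y_shuf)
  colnames(df) <- c(paste0("stil__", colnames(sim$x)), "pcr")
  rep_out <- run_pipeline(df[1:100, ], df[101:160, ],
                          compartment = "stil", use_clinical = FALSE,
                          hidden_grid = 4L, decay_grid = 1e-2, seed = 35)
  expect_lt(abs(rep_out$metrics$auc - 0.5), 0.2)
})

test_that("training fraction 1.0 reproduces the full pipeline result", {
  sim <- simulate_feature_cohort(n = 120, n_features = 10,
                                 n_informative = 2, effect = 1.5,
                                 seed = 41)
  df <- data.frame(sim$x, pcr = sim$y)
  colnames(df) <- c(paste0("stil__", colnames(sim$x)), "pcr")
  tr <- df[1:80, ]; ev <- df[81:120, ]
  full <- run_pipeline(tr, ev, compartment = "stil",
                       use_clinical = FALSE, hidden_grid = 4L,
                       decay_grid = 1e-2, seed = 5)
  curve <- training_fraction_curve(tr, ev, fractions = 1, seed = 5,
                                   compartment = "stil",
                                   use_clinical = FALSE,
                                   hidden_grid = 4L, decay_grid = 1e-2)
  expect_equal(curve$auc, full$metrics$auc)
  expect_equal(curve$n_train, 80L)
  expect_error(training_fraction_curve(tr, ev, fractions = c(0, 0.5)),
               "fractions")
})

test_that("tiny training fractions trigger the folds-reduction warning", {
  sim <- simulate_feature_cohort(n = 100, n_features = 6,
                                 n_informative = 2, effect = 1.5,
                                 seed = 51)
  df <- data.frame(sim$x, pcr = sim$y)
  colnames(df) <- c(paste0("stil__", colnames(sim$x)), "pcr")
  w <- testthat::capture_warnings(
    training_fraction_curve(df[1:70, ], df[71:100, ], fractions = 0.1,
                            replicates = 1, seed = 1,
                            compartment = "stil", use_clinical = FALSE,
                            hidden_grid = 4L, decay_grid = 1e-2))
  expect_true(any(grepl("reducing folds", w)))
})

test_that("threshold sweep is deterministic and degenerates to the default", {
  # hand-built cohort: pCR slides carry 6 planted sTIL squares, non-pCR 3;
  # all components share one area, so every threshold keeps the same set
  mk_cohort <- function(offset) {
    lapply(seq_len(24), function(i) {
      withr::with_seed(offset + i, {
        lab <- matrix(2L, 20, 20)
        lab[1:8, ] <- 1L
        pcr <- as.integer(i %% 2 == 0)
        k <- if (pcr == 1) 6 else 3
        anchors_r <- c(10, 10, 14, 14, 18, 18)
        anchors_c <- c(2, 8, 2, 8, 2, 8) + sample(0:8, 1)
        for (j in seq_len(k))
          lab[anchors_r[j] + 0:1, anchors_c[j] + 0:1] <- 5L
        make_patient(sprintf("h%02d", i), lab, pcr,
                     pr = rbinom(1, 1, 0.5))
      })
    })
  }
  tr <- mk_cohort(100); ev <- mk_cohort(200)
  args <- list(tr, ev, thresholds = c(0.01, 0.05, 0.10),
               compartments = "stil", seed = 3, use_clinical = FALSE,
               hidden_grid = 4L, decay_grid = 1e-2, nfolds = 5)
  tab1 <- do.call(threshold_sweep, args)
  tab2 <- do.call(threshold_sweep, args)
  expect_identical(tab1, tab2)
  # equal component areas -> identical features -> identical metrics
  expect_equal(tab1$auc, rep(tab1$auc[1], 3))
  expect_equal(tab1$f1, rep(tab1$f1[1], 3))
  # single-threshold sweep equals the default pipeline
  tr_df <- cohort_feature_table(tr, 0.05, "stil")
  ev_df <- cohort_feature_table(ev, 0.05, "stil")
  direct <- run_pipeline(tr_df, ev_df, compartment = "stil",
                         use_clinical = FALSE, hidden_grid = 4L,
                         decay_grid = 1e-2, nfolds = 5, seed = 3)
  row5 <- tab1[tab1$sr_threshold == 0.05, ]
  expect_equal(row5$auc, direct$metrics$auc)
})
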