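#' Feature fusion, LASSO selection, MLP prediction and evaluation
#'
#' Fuses per-compartment morphology with clinical covariates, standardizes
#' on training rows only, selects features by stratified cross-validated
#' L1-penalized logistic regression, trains an L2-regularized single-
#' hidden-layer perceptron, and evaluates on a held-out cohort.
#'
#' @name fusion_modeling
NULL

clinical_feature_names <- function() c("er", "er_pct", "pr", "pr_pct",
                                       "her2_cep17")

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% 2147483647)
}

#' Numerically encode a raw clinical table
#'
#' Binary receptor statuses may arrive as 0/1 or as strings ending in
#' "positive" / "negative" (case-insensitive, e.g. "ER-positive");
#' positive maps to 1 and negative to 0. Percentages and the HER2/CEP17
#' ratio pass through as numeric.
#'
#' @param clinical Data frame with columns `er`, `pr` (status), `er_pct`,
#'   `pr_pct`, `her2_cep17`.
#' @return The data frame with `er`, `pr` as 0/1 numerics.
#' @export
encode_clinical <- function(clinical) {
  encode_status <- function(x, what) {
    if (is.numeric(x)) {
      if (!all(x %in% c(0, 1))) stop(what, " numeric status must be 0/1")
      return(x)
    }
    lx <- tolower(trimws(x))
    out <- ifelse(grepl("positive$", lx), 1,
                  ifelse(grepl("negative$", lx), 0, NA))
    if (anyNA(out))
      stop("unrecognized ", what, " status: ",
           paste(unique(x[is.na(out)]), collapse = ", "))
    out
  }
  clinical$er <- encode_status(clinical$er, "ER")
  clinical$pr <- encode_status(clinical$pr, "PR")
  for (col in c("er_pct", "pr_pct", "her2_cep17"))
    clinical[[col]] <- as.numeric(clinical[[col]])
  clinical
}

#' Standardize evaluation data with training-derived parameters
#'
#' Missing sentinels (`NA`) are imputed with training-column medians, then
#' each column is centred by the training mean and scaled by the training
#' population standard deviation. Zero-variance columns map to 0, so no
#' information leaks from the evaluation cohort into the scaling.
#'
#' @param train,eval Numeric matrices with identical column names
#'   (`eval` may be `NULL`).
#' @return List `train`, `eval` (standardized matrices), `center`, `scale`,
#'   `medians`.
#' @export
standardize_fit_apply <- function(train, eval = NULL) {
  if (nrow(train) == 0L) stop("training matrix is empty")
  if (!is.null(eval) && !identical(colnames(train), colnames(eval)))
    stop("training and evaluation columns do not match")
  med <- apply(train, 2L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  impute <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  train <- impute(train)
  ctr <- colMeans(train)
  scl <- sqrt(colMeans(sweep(train, 2L, ctr)^2))
  apply_std <- function(m) {
    m <- sweep(impute(m), 2L, ctr)
    for (j in seq_len(ncol(m)))
      m[, j] <- if (scl[j] > 0) m[, j] / scl[j] else 0
    m
  }
  list(train = apply_std(train),
       eval = if (is.null(eval)) NULL else apply_std(eval),
       center = ctr, scale = scl, medians = med)
}

#' Stratified fold assignment
#'
#' Assigns each row to one of `k` folds so that both outcome classes are
#' spread evenly across folds. If the minority class has fewer members
#' than `k`, the fold count is reduced with a warning.
#'
#' @param y 0/1 outcome vector.
#' @param k Requested number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer fold ids of length `length(y)`.
#' @export
make_stratified_folds <- function(y, k = 10L, seed = 1L) {
  minority <- min(table(y))
  if (minority < 2L) stop("both outcome classes need at least 2 members")
  if (minority < k) {
    warning("reducing folds from ", k, " to ", minority,
            " (minority class size)")
    k <- minority
  }
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Rank-based AUC with half-credit for ties
#'
#' Equivalent to the Wilcoxon rank-sum formulation: the probability that a
#' random positive scores above a random negative, ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 outcome labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes in the labels")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' LASSO feature selection by stratified cross-validated grid search
#'
#' Fits L1-penalized logistic regression over a penalty path and picks the
#' penalty maximizing mean AUC under stratified 10-fold cross-validation;
#' features with non-zero coefficients at that penalty are selected.
#' Inputs are expected already standardized (see
#' [standardize_fit_apply()]), so coefficients are comparable across
#' features and usable as importance weights.
#'
#' @param x Standardized feature matrix with column names.
#' @param y 0/1 outcome vector.
#' @param lambda_grid Optional penalty grid; default lets glmnet build its
#'   path.
#' @param nfolds Cross-validation folds; default 10.
#' @param seed Seed for the fold shuffle.
#' @return List `selected` (feature names), `weights` (named coefficients
#'   of the selected features), `lambda` (chosen penalty), `cv_auc`.
#' @export
lasso_select <- function(x, y, lambda_grid = NULL, nfolds = 10L,
                         seed = 1L) {
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  if (!is.null(lambda_grid) && length(lambda_grid) == 0L)
    stop("empty penalty grid")
  foldid <- make_stratified_folds(y, nfolds, seed)
  full <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         lambda = lambda_grid, standardize = FALSE,
                         lambda.min.ratio = 0.001)
  path <- full$lambda
  # held-out AUC per penalty, averaged over stratified folds (cv.glmnet
  # falls back to deviance for small folds, so the AUC objective is
  # computed explicitly here)
  fold_auc <- matrix(NA_real_, max(foldid), length(path))
  for (f in seq_len(max(foldid))) {
    tr <- foldid != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 1, lambda = path,
                          standardize = FALSE)
    link <- stats::predict(fit, x[!tr, , drop = FALSE], s = path,
                           type = "link")
    fold_auc[f, ] <- apply(link, 2L, auc_rank, labels = y[!tr])
  }
  cvm <- colMeans(fold_auc, na.rm = TRUE)
  lam <- path[which.max(cvm)]   # ties resolve to the strongest penalty
  beta <- as.matrix(stats::coef(full, s = lam))[, 1L]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  sel <- names(beta)[beta != 0]
  list(selected = sel, weights = beta[sel], lambda = lam,
       cv_auc = max(cvm))
}

#' Train an L2-regularized multilayer perceptron
#'
#' Single hidden layer; hidden size and weight decay are tuned by
#' stratified cross-validated grid search maximizing mean AUC, then the
#' winning configuration is refit on all training rows. With zero input
#' features (an empty LASSO selection) the predictor degenerates to a
#' constant 0.5.
#'
#' @param x Standardized training features (selected columns).
#' @param y 0/1 outcome vector.
#' @param hidden_grid Hidden-layer sizes to try; default `c(4, 8, 16)`.
#' @param decay_grid L2 penalties to try; default `c(1e-3, 1e-2, 1e-1)`.
#' @param nfolds Cross-validation folds; default 10.
#' @param seed Seed controlling folds and weight initialization.
#' @param maxit Optimizer iterations per fit; default 300.
#' @return An `mlp_predictor`; use [predict_mlp()] for class-1
#'   probabilities.
#' @export
train_mlp <- function(x, y, hidden_grid = c(4L, 8L, 16L),
                      decay_grid = c(1e-3, 1e-2, 1e-1), nfolds = 10L,
                      seed = 1L, maxit = 300L) {
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  if (is.null(dim(x)) || ncol(x) == 0L) {
    return(structure(list(constant = 0.5), class = "mlp_predictor"))
  }
  fit_one <- function(xt, yt, size, decay, fit_seed) {
    withr::with_seed(fit_seed, nnet::nnet(
      xt, yt, size = size, decay = decay, entropy = TRUE,
      trace = FALSE, maxit = maxit, MaxNWts = 5000L))
  }
  foldid <- make_stratified_folds(y, nfolds, derive_seed(seed, 1L))
  k <- max(foldid)
  grid <- expand.grid(size = hidden_grid, decay = decay_grid)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- foldid != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        return(NA_real_)
      fit <- fit_one(x[tr, , drop = FALSE], y[tr], grid$size[g],
                     grid$decay[g], derive_seed(seed, 100L + g))
      p <- as.vector(stats::predict(fit, x[!tr, , drop = FALSE]))
      auc_rank(p, y[!tr])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  best <- which.max(cv_auc)
  fit <- fit_one(x, y, grid$size[best], grid$decay[best],
                 derive_seed(seed, 2L))
  structure(list(fit = fit, size = grid$size[best],
                 decay = grid$decay[best], cv_auc = cv_auc[best],
                 features = colnames(x)),
            class = "mlp_predictor")
}

#' Predict class-1 probabilities from an MLP predictor
#'
#' @param model An `mlp_predictor` from [train_mlp()].
#' @param x Standardized feature matrix (same columns as training).
#' @return Numeric vector of probabilities.
#' @export
predict_mlp <- function(model, x) {
  stopifnot(inherits(model, "mlp_predictor"))
  if (!is.null(model$constant)) return(rep(model$constant, nrow(x)))
  as.vector(stats::predict(model$fit, x[, model$features, drop = FALSE]))
}

#' Evaluate predictions on a held-out cohort
#'
#' AUC is computed by rank concordance (ties half-credit); the remaining
#' metrics follow from the confusion matrix at the decision cutoff:
#' PPV = TP/(TP+FP), recall = TP/(TP+FN), NPV = TN/(TN+FN),
#' F1 = 2 * PPV * recall / (PPV + recall). Ratios with empty denominators
#' are `NA`.
#'
#' @param scores Predicted class-1 probabilities.
#' @param labels 0/1 outcome labels.
#' @param threshold Decision cutoff; default 0.5.
#' @return Named list `auc`, `f1`, `ppv`, `recall`, `npv`, `threshold`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("no predictions to evaluate")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  ppv <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  npv <- ratio(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(recall) || ppv + recall == 0) NA_real_
        else 2 * ppv * recall / (ppv + recall)
  list(auc = auc_rank(scores, labels), f1 = f1, ppv = ppv,
       recall = recall, npv = npv, threshold = threshold)
}

#' Build the patients-by-features cohort table
#'
#' One row per patient: per-compartment morphological features at the
#' given significant-region threshold, tile counts, relative TME metrics,
#' clinical covariates, and the outcome pair (`pcr`, `ris_cm`).
#'
#' @param patients Cohort list (e.g. from [generate_cohort()]).
#' @param sr_threshold Significant-region threshold; default 0.05.
#' @param compartments Compartments to extract morphology for; default all
#'   five.
#' @return Data frame.
#' @export
cohort_feature_table <- function(patients, sr_threshold = 0.05,
                                 compartments = c("tumor", "stroma",
                                                  "itil", "stil", "til")) {
  morph <- t(vapply(patients, function(p)
    extract_features(p$ts, sr_threshold, compartments),
    numeric(46L * length(compartments))))
  counts <- t(vapply(patients, function(p) unlist(count_tiles(p$ts)),
                     numeric(6L)))
  ratios <- t(vapply(patients,
                     function(p) relative_metrics(count_tiles(p$ts)),
                     numeric(5L)))
  cbind(clinical_table(patients), as.data.frame(morph),
        as.data.frame(counts), as.data.frame(ratios))
}

feature_columns <- function(df, compartment = "stil",
                            use_clinical = TRUE) {
  cols <- grep(paste0("^", compartment, "__"), colnames(df), value = TRUE)
  if (use_clinical) cols <- c(cols, clinical_feature_names())
  cols
}

#' Run the full selection + prediction pipeline on feature tables
#'
#' Standardizes (training rows only), selects features by LASSO, trains
#' the MLP on the selected features, and evaluates on the held-out table.
#'
#' @param train_df,eval_df Cohort tables from [cohort_feature_table()]
#'   (or any data frame with the feature columns plus `pcr`).
#' @param compartment Morphology compartment to model; default `"stil"`.
#' @param use_clinical Include the five clinical covariates; default TRUE.
#' @param columns Explicit feature-column names (overrides `compartment` /
#'   `use_clinical` when given).
#' @param seed Seed for fold shuffles and MLP initialization.
#' @param threshold Decision cutoff for the confusion-matrix metrics.
#' @param lambda_grid,hidden_grid,decay_grid,nfolds Passed to
#'   [lasso_select()] and [train_mlp()].
#' @return A `model_report` list: `selected`, `weights`, `metrics`,
#'   `mlp` (hyperparameters), `n_train`, `n_eval`, `scores`,
#'   `training_fraction`.
#' @export
run_pipeline <- function(train_df, eval_df, compartment = "stil",
                         use_clinical = TRUE, columns = NULL, seed = 1L,
                         threshold = 0.5, lambda_grid = NULL,
                         hidden_grid = c(4L, 8L, 16L),
                         decay_grid = c(1e-3, 1e-2, 1e-1), nfolds = 10L) {
  if (is.null(columns))
    columns <- feature_columns(train_df, compartment, use_clinical)
  xt <- as.matrix(train_df[, columns, drop = FALSE])
  xe <- as.matrix(eval_df[, columns, drop = FALSE])
  yt <- train_df$pcr; ye <- eval_df$pcr
  std <- standardize_fit_apply(xt, xe)
  sel <- lasso_select(std$train, yt, lambda_grid, nfolds,
                      derive_seed(seed, 11L))
  mlp <- train_mlp(std$train[, sel$selected, drop = FALSE], yt,
                   hidden_grid, decay_grid, nfolds,
                   derive_seed(seed, 12L))
  scores <- predict_mlp(mlp, std$eval[, sel$selected, drop = FALSE])
  metrics <- evaluate_predictions(scores, ye, threshold)
  structure(list(selected = sel$selected, weights = sel$weights,
                 lambda = sel$lambda, metrics = metrics,
                 mlp = if (is.null(mlp$constant))
                   list(size = mlp$size, decay = mlp$decay)
                 else list(constant = mlp$constant),
                 n_train = nrow(train_df), n_eval = nrow(eval_df),
                 scores = scores, training_fraction = 1),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report: %d train / %d eval, %d selected features\n",
              x$n_train, x$n_eval, length(x$selected)))
  m <- x$metrics
  cat(sprintf("  AUC %.3f  F1 %.3f  PPV %.3f  recall %.3f  NPV %.3f\n",
              m$auc, m$f1, m$ppv, m$recall, m$npv))
  invisible(x)
}

#' Learning curve over training-set fractions
#'
#' For each fraction, stratified subsamples of the training table are
#' drawn (seeded, `replicates` times), the selection + MLP pipeline is
#' rerun, and the fixed evaluation cohort is scored.
#'
#' @param train_df,eval_df Cohort tables.
#' @param fractions Training fractions in `(0, 1]`.
#' @param replicates Subsampling replicates per fraction; default 10
#'   (fraction 1 is deterministic and run once).
#' @param seed Base seed; each replicate derives its own.
#' @param ... Passed to [run_pipeline()].
#' @return Data frame with one row per (fraction, replicate) holding the
#'   five evaluation metrics.
#' @export
training_fraction_curve <- function(train_df, eval_df,
                                    fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                                    replicates = 10L, seed = 1L, ...) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  rows <- list()
  for (fr in fractions) {
    reps <- if (fr == 1) 1L else replicates
    for (rep_i in seq_len(reps)) {
      rseed <- if (fr == 1) seed
               else derive_seed(seed, round(1000 * fr) * 100L + rep_i)
      sub <- if (fr == 1) train_df else {
        idx <- withr::with_seed(rseed, {
          unlist(lapply(split(seq_len(nrow(train_df)), train_df$pcr),
                        function(ix) sample(ix, max(1L,
                                                    round(fr * length(ix))))))
        })
        train_df[idx, , drop = FALSE]
      }
      rep_out <- run_pipeline(sub, eval_df, seed = rseed, ...)
      m <- rep_out$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fr, replicate = rep_i, n_train = nrow(sub),
        auc = m$auc, f1 = m$f1, ppv = m$ppv, recall = m$recall,
        npv = m$npv)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the significant-region threshold over the full pipeline
#'
#' Re-extracts morphology at each threshold, reruns selection and the MLP
#' per compartment, and tabulates the held-out metrics — the structure of
#' a per-compartment, per-threshold generalization comparison.
#'
#' @param train_patients,eval_patients Cohort lists.
#' @param thresholds Significant-region thresholds; default
#'   `c(0.01, 0.03, 0.05, 0.10)`.
#' @param compartments Compartments to model; default all five.
#' @param seed Pipeline seed (shared across cells so rows are comparable).
#' @param ... Passed to [run_pipeline()].
#' @return Data frame with columns `region`, `sr_threshold`, `auc`, `f1`,
#'   `ppv`, `recall`, `npv`.
#' @export
threshold_sweep <- function(train_patients, eval_patients,
                            thresholds = c(0.01, 0.03, 0.05, 0.10),
                            compartments = c("tumor", "stroma", "itil",
                                             "stil", "til"),
                            seed = 1L, ...) {
  rows <- list()
  for (th in thresholds) {
    train_df <- cohort_feature_table(train_patients, th, compartments)
    eval_df <- cohort_feature_table(eval_patients, th, compartments)
    for (cp in compartments) {
      rep_out <- run_pipeline(train_df, eval_df, compartment = cp,
                              seed = seed, ...)
      m <- rep_out$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        region = cp, sr_threshold = th, auc = m$auc, f1 = m$f1,
        ppv = m$ppv, recall = m$recall, npv = m$npv)
    }
  }
  do.call(rbind, rows)
}
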