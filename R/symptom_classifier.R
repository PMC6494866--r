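#' Fit the random-forest symptom index (SI)
#'
#' An ensemble of randomized decision trees is trained on per-sample
#' feature vectors (normalized abundances) with the healthy/symptomatic
#' label.  Each sample's symptom index is its out-of-bag (OOB) vote
#' fraction for the symptomatic class: only trees whose bootstrap sample
#' excluded that sample contribute, which prevents overtraining — the
#' score for a sample never uses a tree that saw it.
#'
#' @param features Numeric matrix, samples x features, rownames = sample
#'   IDs.
#' @param labels Factor or character with exactly the levels `healthy` and
#'   `symptomatic` (>= 5 samples per class).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return List of class `symptom_index` with `si` (named OOB
#'   probabilities), `auc` (from [evaluate_auc()]), `model` (the fitted
#'   forest), `n_trees`, `mtry`, `seed`.
#' @export
fit_symptom_index <- function(features, labels, n_trees = 500, seed = 1L) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels),
                   levels = c("healthy", "symptomatic"))
  if (any(is.na(labels)))
    stop_input("labels must be 'healthy' or 'symptomatic'")
  if (nlevels(droplevels(labels)) < 2L)
    stop_input("both classes must be present")
  if (any(table(labels) < 5L))
    stop_input("need >= 5 samples per class")
  stopifnot(nrow(features) == length(labels))
  rf <- with_seed(seed, randomForest::randomForest(
    x = features, y = labels, ntree = n_trees))
  si <- setNames(rf$votes[, "symptomatic"],
                 rownames(features) %||% seq_along(labels))
  structure(list(si = si,
                 auc = evaluate_auc(si, labels),
                 model = rf, n_trees = n_trees, mtry = rf$mtry,
                 seed = as.integer(seed)),
            class = "symptom_index")
}

#' @export
print.symptom_index <- function(x, ...) {
  cat(sprintf("symptom_index: %d samples, %d trees (mtry %d)\n",
              length(x$si), x$n_trees, x$mtry))
  cat(sprintf("  OOB AUC = %.3f (95%% CI %.3f-%.3f, DeLong)\n",
              x$auc$auc, x$auc$ci_low, x$auc$ci_high))
  invisible(x)
}

#' AUC with DeLong confidence interval
#'
#' The area under the ROC curve computed as the scaled Mann-Whitney U
#' statistic (ties count 1/2), with a 95% confidence interval and a
#' two-sided p-value against AUC = 0.5 from the DeLong variance estimator.
#'
#' @param si Numeric scores (higher = more symptomatic).
#' @param labels Two-class labels; the positive class is `"symptomatic"`
#'   if present, otherwise the last factor level.
#' @return List with `auc`, `ci_low`, `ci_high`, `p`.
#' @export
evaluate_auc <- function(si, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop_input("labels must have exactly 2 classes")
  pos <- if ("symptomatic" %in% classes) "symptomatic" else classes[2L]
  neg <- setdiff(classes, pos)
  x <- si[labels == pos]; y <- si[labels == neg]
  if (sd(si) == 0) {
    warning("constant scores: AUC 0.5 with degenerate CI", call. = FALSE)
    return(list(auc = 0.5, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_))
  }
  r <- rank(c(x, y))
  auc <- (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
  roc <- suppressMessages(pROC::roc(
    response = factor(labels, levels = c(neg, pos)), predictor = si,
    direction = "<", quiet = TRUE))
  # pROC warns that a degenerate (AUC = 1) curve has a point-mass CI; the
  # collapsed interval is the intended answer here
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  v <- suppressWarnings(pROC::var(roc, method = "delong"))
  p <- if (v > 0) 2 * pnorm(-abs(auc - 0.5) / sqrt(v)) else NA_real_
  list(auc = auc, ci_low = ci[1L], ci_high = ci[3L], p = p)
}

#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Each iteration shuffles every feature column to create "shadow"
#' features, fits a random forest on the real + shadow block, and scores a
#' hit for every real feature whose permutation importance exceeds the
#' maximum shadow importance.  A cumulative two-tailed binomial test at
#' `alpha` (Bonferroni-adjusted over the features still in play) confirms
#' features with significantly more hits than chance and rejects those
#' with significantly fewer; rejected features leave the pool.  Features
#' undecided after `max_iter` iterations stay `tentative`.
#'
#' @param features Numeric matrix, samples x features (>= 2 features).
#' @param labels Two-class labels.
#' @param max_iter Maximum iterations (>= 1; default 100).
#' @param alpha Significance level in (0, 1) (default 0.01).
#' @param n_trees Trees per forest (default 300).
#' @param seed Integer seed.
#' @return List of class `feature_selection` with `status` (named factor:
#'   confirmed/tentative/rejected), `hits`, `n_iter`, and
#'   `importance_history` (iterations x features).
#' @export
boruta_select <- function(features, labels, max_iter = 100, alpha = 0.01,
                          n_trees = 300, seed = 1L) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (p < 2L) stop_input("need >= 2 features")
  if (max_iter < 1L) stop_input("max_iter must be >= 1")
  if (alpha <= 0 || alpha >= 1)
    stop_input("alpha must be strictly inside (0, 1)")
  y <- factor(as.character(labels))
  feat_names <- colnames(features) %||% paste0("f", seq_len(p))
  colnames(features) <- feat_names
  status <- setNames(rep("tentative", p), feat_names)
  hits <- setNames(rep(0L, p), feat_names)
  history <- matrix(NA_real_, nrow = max_iter, ncol = p,
                    dimnames = list(NULL, feat_names))
  n_iter <- 0L
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      active <- names(status)[status == "tentative"]
      if (!length(active)) break
      n_iter <- it
      x <- features[, active, drop = FALSE]
      shadow <- apply(x, 2L, sample)
      colnames(shadow) <- paste0("shadow_", active)
      rf <- randomForest::randomForest(x = cbind(x, shadow), y = y,
                                       ntree = n_trees, importance = TRUE)
      imp <- randomForest::importance(rf, type = 1L)[, 1L]
      shadow_max <- max(imp[colnames(shadow)])
      history[it, active] <- imp[active]
      hits[active] <- hits[active] + (imp[active] > shadow_max)
      # cumulative binomial decisions, Bonferroni over features in play
      thr <- alpha / length(active)
      p_conf <- pbinom(hits[active] - 1L, it, 0.5, lower.tail = FALSE)
      p_rej <- pbinom(hits[active], it, 0.5)
      status[active][p_conf < thr] <- "confirmed"
      status[active][p_rej < thr] <- "rejected"
    }
  })
  structure(list(status = factor(status, levels = c("confirmed", "tentative",
                                                    "rejected")),
                 hits = hits, n_iter = n_iter,
                 importance_history = history[seq_len(max(n_iter, 1L)), ,
                                              drop = FALSE]),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("feature_selection: %d confirmed, %d tentative, %d rejected (%d iterations)\n",
              tab[["confirmed"]], tab[["tentative"]], tab[["rejected"]],
              x$n_iter))
  invisible(x)
}

#' Covariate associations with the symptom index
#'
#' Each covariate is tested in a simple linear regression of SI on the
#' covariate (listwise deletion per test; n used is reported), with
#' Benjamini-Hochberg correction across the covariates.  A combined model
#' with all covariates passing `q_threshold` reports their joint R².
#'
#' @param si Named per-sample SI scores.
#' @param metadata Data frame with `sample_id` and the covariate columns.
#' @param covariates Covariate column names (default the seven clinical
#'   variables: age, sex, bmi, antibiotics_recent, ppi, gi_surgery, sibo).
#' @param q_threshold FDR threshold selecting covariates for the combined
#'   model (default 0.1).
#' @return List of class `association_table`: data frame `table`
#'   (covariate, estimate, p, q, n), `combined_r2`,
#'   `combined_covariates`.
#' @export
covariate_regression <- function(si, metadata,
                                 covariates = c("age", "sex", "bmi",
                                                "antibiotics_recent", "ppi",
                                                "gi_surgery", "sibo"),
                                 q_threshold = 0.1) {
  ids <- names(si)
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if ("sibo" %in% covariates && !"sibo" %in% colnames(md) &&
      "sibo_cfu" %in% colnames(md))
    md$sibo <- classify_sibo(md$sibo_cfu) == "positive"
  covariates <- covariates[covariates %in% colnames(md)]
  if (!length(covariates)) stop_input("no requested covariate in metadata")
  rows <- lapply(covariates, function(cov) {
    x <- md[[cov]]
    if (is.character(x)) x <- factor(x)
    ok <- !is.na(x) & !is.na(si)
    if (length(unique(x[ok])) < 2L) {
      warning("covariate '", cov, "' is constant; skipped", call. = FALSE)
      return(NULL)
    }
    fit <- lm(si[ok] ~ x[ok])
    sm <- summary(fit)
    data.frame(covariate = cov,
               estimate = coef(fit)[2L],
               se = sm$coefficients[2L, 2L],
               p = sm$coefficients[2L, 4L],
               n = sum(ok), stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop_input("no testable covariates")
  tab$q <- p.adjust(tab$p, method = "BH")
  sig <- tab$covariate[tab$q < q_threshold]
  combined_r2 <- NA_real_
  if (length(sig)) {
    df <- data.frame(si = si, md[, sig, drop = FALSE])
    df <- df[complete.cases(df), , drop = FALSE]
    combined_r2 <- summary(lm(si ~ ., data = df))$r.squared
  }
  structure(list(table = tab[, c("covariate", "estimate", "se", "p", "q",
                                 "n")],
                 combined_r2 = combined_r2, combined_covariates = sig),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (length(x$combined_covariates))
    cat(sprintf("combined model (%s): R^2 = %.3f\n",
                paste(x$combined_covariates, collapse = ", "),
                x$combined_r2))
  invisible(x)
}

#' Fisher's exact association for contingency tables
#'
#' For a 2x2 table: the exact conditional test (two-sided by summing
#' tables with probability at most the observed) with the conditional
#' odds-ratio estimate and 95% CI.  For larger r x c tables: a Monte-Carlo
#' estimate of the exact p with `n_mc` simulated tables.
#'
#' @param table Non-negative integer matrix of counts.
#' @param n_mc Monte-Carlo replicates for r x c tables (default 10000).
#' @param seed Integer seed (Monte-Carlo case).
#' @return List with `p`, and for 2x2 also `odds_ratio`, `ci_low`,
#'   `ci_high`.
#' @export
categorical_association <- function(table, n_mc = 10000, seed = 1L) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)))
    stop_input("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_input("empty row or column margin")
  if (all(dim(m) == c(2L, 2L))) {
    ft <- fisher.test(m)
    return(list(p = ft$p.value, odds_ratio = unname(ft$estimate),
                ci_low = ft$conf.int[1L], ci_high = ft$conf.int[2L]))
  }
  ft <- with_seed(seed,
                  fisher.test(m, simulate.p.value = TRUE, B = n_mc))
  list(p = ft$p.value)
}
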