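#' Repeated random-split evaluation scheme
#'
#' Describes the repeated random-subsampling validation used to score each
#' candidate marker: `n_repetitions` independent stratified train/validation
#' divisions at `train_fraction` (3:2 by default), each scored on the
#' validation part.
#'
#' @param train_fraction Fraction of each stratum assigned to training
#'   (default 0.6, i.e. the 3:2 ratio).
#' @param n_repetitions Number of repetitions (default 500).
#' @param stratified Stratify splits by group (default TRUE; unstratified
#'   splits of small cohorts occasionally produce single-class validation
#'   sets on which the metrics are undefined).
#' @param seed Seed from which each repetition's split is derived
#'   deterministically.
#' @return List of class `split_scheme`.
#' @export
split_scheme <- function(train_fraction = 0.6, n_repetitions = 500,
                         stratified = TRUE, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_("train_fraction must be in (0, 1)")
  }
  if (n_repetitions < 1) stop_("n_repetitions must be >= 1")
  structure(list(train_fraction = train_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 stratified = isTRUE(stratified), seed = seed),
            class = "split_scheme")
}

#' Draw one train/validation split
#'
#' Stratified by group: per stratum, round-half-up of
#' `train_fraction * n` samples go to training and the remainder to
#' validation; the split is deterministic given `(scheme$seed, repetition)`.
#'
#' @param annotation Sample annotation (both groups with >= 2 samples).
#' @param scheme A \code{\link{split_scheme}}.
#' @param repetition Repetition index (1-based).
#' @return List with character vectors `train` and `validation` (disjoint,
#'   exhaustive).
#' @export
random_split <- function(annotation, scheme, repetition) {
  validate_annotation(annotation)
  strata <- if (scheme$stratified) {
    split(annotation$sample_id, annotation$group)
  } else {
    list(all = annotation$sample_id)
  }
  if (any(lengths(strata) < 2)) {
    stop_("every stratum needs at least 2 samples")
  }
  parts <- with_seed(derive_seed(scheme$seed, "split", repetition), {
    lapply(strata, function(ids) {
      n_train <- floor(scheme$train_fraction * length(ids) + 0.5)
      perm <- sample(ids)
      list(train = perm[seq_len(n_train)],
           validation = perm[setdiff(seq_along(ids), seq_len(n_train))])
    })
  })
  train <- unlist(lapply(parts, `[[`, "train"), use.names = FALSE)
  validation <- unlist(lapply(parts, `[[`, "validation"), use.names = FALSE)
  grp <- annotation$group[match(train, annotation$sample_id)]
  grp_v <- annotation$group[match(validation, annotation$sample_id)]
  if (!all(c("case", "control") %in% grp) ||
      !all(c("case", "control") %in% grp_v)) {
    stop_("a class is absent from the training or validation part")
  }
  list(train = train, validation = validation)
}

#' Univariate logistic regression by IRLS
#'
#' Maximum-likelihood fit of P(y = 1 | x) = plogis(a + b x) by iteratively
#' reweighted least squares on the standardized feature (at most `max_iter`
#' iterations, convergence at `tol` on the deviance). When separation is
#' detected (non-convergence, divergent deviance, or a standardized slope
#' beyond `slope_cap`), the model is refitted with a small ridge penalty
#' `ridge` on the standardized slope and flagged: the penalty leaves the
#' score ordering (and hence AUC) unchanged and only stabilizes the
#' probability scale.
#'
#' @param x_train Numeric feature vector.
#' @param y_train Labels: logical/0-1 or "case"/"control" ("case" = 1).
#' @param max_iter,tol,slope_cap,ridge Fitting controls.
#' @return List of class `logistic_model` with `intercept` and `slope` on
#'   the original feature scale, plus `separated` and `converged` flags.
#' @export
fit_logistic_univariate <- function(x_train, y_train, max_iter = 50,
                                    tol = 1e-8, slope_cap = 50, ridge = 1e-3) {
  y <- as_binary_label(y_train)
  if (length(unique(y)) < 2) stop_("training labels contain a single class")
  if (length(x_train) != length(y)) stop_("x and y lengths differ")
  mu <- mean(x_train); sdx <- stats::sd(x_train)
  if (!is.finite(sdx) || sdx == 0) {
    # non-informative constant feature: intercept-only model
    return(structure(list(intercept = stats::qlogis(mean(y)), slope = 0,
                          separated = FALSE, converged = TRUE,
                          degenerate = TRUE),
                     class = "logistic_model"))
  }
  z <- (x_train - mu) / sdx

  irls <- function(lambda) {
    beta <- c(0, 0)
    pen <- diag(c(0, lambda))
    dev_old <- Inf; converged <- FALSE
    for (iter in seq_len(max_iter)) {
      eta <- beta[1] + beta[2] * z
      p <- stats::plogis(eta)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      w <- p * (1 - p)
      XtWX <- matrix(c(sum(w), sum(w * z), sum(w * z), sum(w * z^2)), 2, 2)
      score <- c(sum(y - p), sum((y - p) * z)) - lambda * c(0, beta[2])
      step <- tryCatch(solve(XtWX + pen, score), error = function(e) NULL)
      if (is.null(step)) break
      beta <- beta + step
      dev <- -2 * sum(y * log(p) + (1 - y) * log(1 - p)) + lambda * beta[2]^2
      if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
        converged <- TRUE
        break
      }
      dev_old <- dev
    }
    list(beta = beta, converged = converged, deviance = dev_old)
  }

  fit <- irls(0)
  # saturated deviance also signals separation: probability clamping keeps
  # the standardized slope finite, so the slope cap alone can miss it
  separated <- !fit$converged || !all(is.finite(fit$beta)) ||
    abs(fit$beta[2]) > slope_cap ||
    (is.finite(fit$deviance) && fit$deviance < 1e-6)
  if (separated) fit <- irls(ridge)
  slope <- fit$beta[2] / sdx
  structure(list(intercept = fit$beta[1] - fit$beta[2] * mu / sdx,
                 slope = slope, separated = separated,
                 converged = fit$converged, degenerate = FALSE),
            class = "logistic_model")
}

as_binary_label <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (!all(y %in% c("case", "control"))) stop_("labels must be case/control")
    as.integer(y == "case")
  } else {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop_("numeric labels must be 0/1")
    y
  }
}

#' Predict case probabilities from a univariate logistic model
#'
#' @param object A `logistic_model`.
#' @param x Numeric feature vector.
#' @param ... Unused.
#' @export
predict.logistic_model <- function(object, x, ...) {
  stats::plogis(object$intercept + object$slope * x)
}

#' ROC AUC by the Mann-Whitney formulation
#'
#' AUC = (number of case-control pairs where the case scores higher, plus
#' half the tied pairs) divided by n_case * n_control; equivalently computed
#' from midranks, so ties count one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Labels ("case"/"control" or 0/1, case positive).
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score one validation split
#'
#' Predicted class is probability >= `threshold`; with case as the positive
#' class, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/n, and AUC is computed from the predicted probabilities.
#'
#' @param model A `logistic_model`.
#' @param x_valid,y_valid Validation feature and labels (both classes
#'   present).
#' @param threshold Probability threshold (default 0.5).
#' @return One-row data frame: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_split <- function(model, x_valid, y_valid, threshold = 0.5) {
  y <- as_binary_label(y_valid)
  if (length(unique(y)) < 2) stop_("validation labels contain a single class")
  prob <- predict(model, x_valid)
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  data.frame(auc = roc_auc(prob, y),
             accuracy = (tp + tn) / length(y),
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp))
}

#' Repeated random-split evaluation of one candidate marker
#'
#' Runs \code{\link{random_split}}, \code{\link{fit_logistic_univariate}}
#' and \code{\link{evaluate_split}} for repetitions 1..n, then aggregates
#' the mean of each metric; the AUC 95\% CI is the empirical 2.5th/97.5th
#' percentile across repetitions. Repetitions that fail (degenerate splits)
#' are skipped and counted; more than 10\% failures is an error.
#'
#' @param x Named numeric vector of the probe's expression values (names =
#'   sample ids) or an expression matrix row.
#' @param annotation Sample annotation.
#' @param scheme A \code{\link{split_scheme}}.
#' @param threshold Probability threshold for the confusion-matrix metrics.
#' @return One-row data frame of class `predictor_stats`: `auc_mean`,
#'   `auc_ci_lower`, `auc_ci_upper`, `accuracy_mean`, `sensitivity_mean`,
#'   `specificity_mean`, `n_repetitions_used`.
#' @export
repeat_evaluation <- function(x, annotation, scheme = split_scheme(),
                              threshold = 0.5) {
  validate_annotation(annotation)
  if (is.null(names(x)) || !all(annotation$sample_id %in% names(x))) {
    stop_("x must be named by sample id and cover the annotation")
  }
  grp <- stats::setNames(annotation$group, annotation$sample_id)
  rows <- vector("list", scheme$n_repetitions)
  failed <- 0L
  for (r in seq_len(scheme$n_repetitions)) {
    rows[[r]] <- tryCatch({
      sp <- random_split(annotation, scheme, r)
      model <- fit_logistic_univariate(x[sp$train], grp[sp$train])
      evaluate_split(model, x[sp$validation], grp[sp$validation], threshold)
    }, error = function(e) NULL)
    if (is.null(rows[[r]])) failed <- failed + 1L
  }
  if (failed > 0.10 * scheme$n_repetitions) {
    stop_(failed, " of ", scheme$n_repetitions, " repetitions failed")
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ci <- stats::quantile(res$auc, c(0.025, 0.975), type = 7, names = FALSE)
  out <- data.frame(auc_mean = mean(res$auc),
                    auc_ci_lower = ci[1], auc_ci_upper = ci[2],
                    accuracy_mean = mean(res$accuracy),
                    sensitivity_mean = mean(res$sensitivity),
                    specificity_mean = mean(res$specificity),
                    n_repetitions_used = nrow(res))
  class(out) <- c("predictor_stats", "data.frame")
  out
}

#' Evaluate a set of candidate markers
#'
#' Applies \code{\link{repeat_evaluation}} to each requested probe of an
#' expression matrix (typically the probes that passed the differential
#' expression screen).
#'
#' @param expr Expression matrix.
#' @param annotation Sample annotation.
#' @param probe_ids Probes to evaluate (default: all rows).
#' @param scheme A \code{\link{split_scheme}}.
#' @param threshold Probability threshold (default 0.5).
#' @return Data frame, one row per probe, `probe_id` first.
#' @export
evaluate_predictors <- function(expr, annotation,
                                probe_ids = rownames(expr),
                                scheme = split_scheme(), threshold = 0.5) {
  missing_ids <- setdiff(probe_ids, rownames(expr))
  if (length(missing_ids)) {
    stop_("probes not in matrix: ", paste(missing_ids, collapse = ", "))
  }
  stats_list <- lapply(probe_ids, function(p) {
    repeat_evaluation(expr[p, ], annotation, scheme, threshold)
  })
  cbind(data.frame(probe_id = probe_ids, stringsAsFactors = FALSE),
        do.call(rbind, stats_list))
}
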