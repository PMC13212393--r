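# Cohort-level statistics: group tests, ROC machinery, logistic models with
# penalized variable selection, calibration, and radio-pathology measures.

#' Mann-Whitney U test
#'
#' Rank-sum test for a two-group difference. The U statistic counts
#' `x > y` pairs with half-credit for ties. For pooled n <= `exact_max` the
#' two-sided p-value is computed by exhaustive enumeration of all label
#' assignments (valid under ties); otherwise the tie-corrected normal
#' approximation is used.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max pooled-size cutoff for the exact branch.
#' @return tibble with `U`, `p`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  U <- u_stat(x, y)
  if (n1 + n2 <= exact_max) {
    pool <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    mid <- n1 * n2 / 2
    us <- apply(combs, 2, function(idx) u_stat(pool[idx], pool[-idx]))
    p <- mean(abs(us - mid) >= abs(U - mid) - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    varU <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    z <- (U - n1 * n2 / 2) / sqrt(varU)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  tibble::tibble(U = U, p = min(p, 1), method = method)
}

#' ROC curve and AUC
#'
#' Rank-based AUC (ties get half credit), identical to `U / (n1 n2)` from
#' `mann_whitney()` on the two score groups. Curve points are computed at
#' every distinct threshold.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or two-level factor).
#' @return an `mrc_roc` object: list with `auc`, `curve` (tibble
#'   `threshold`, `sensitivity`, `specificity`), `scores`, `labels`.
#' @export
auc_roc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  curve <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   sensitivity = sum(pred & y == 1) / n1,
                   specificity = sum(!pred & y == 0) / n0)
  })
  structure(list(auc = auc, curve = curve, scores = scores, labels = y),
            class = "mrc_roc")
}

#' @export
print.mrc_roc <- function(x, ...) {
  cat(sprintf("<mrc_roc> AUC = %.3f (%d+, %d-)\n", x$auc,
              sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels)) labels <- as.integer(factor(labels)) - 1L
  stopifnot(all(labels %in% c(0, 1)))
  labels
}

#' Youden-index operating point
#'
#' The threshold maximizing `sensitivity + specificity - 1`; ties are broken
#' toward higher specificity (the more conservative call). Accuracy is
#' evaluated at that threshold.
#'
#' @param roc an `mrc_roc` from `auc_roc()`.
#' @return one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `youden`.
#' @export
youden_operating_point <- function(roc) {
  stopifnot(inherits(roc, "mrc_roc"))
  cv <- roc$curve
  j <- cv$sensitivity + cv$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(cv$specificity[best])]
  y <- roc$labels
  pred <- roc$scores >= cv$threshold[best]
  tibble::tibble(threshold = cv$threshold[best],
                 sensitivity = cv$sensitivity[best],
                 specificity = cv$specificity[best],
                 accuracy = mean(pred == (y == 1)),
                 youden = j[best])
}

#' DeLong test for two paired AUCs, and DeLong AUC confidence intervals
#'
#' Nonparametric comparison of correlated ROC curves via the
#' placement-value covariance estimator, for two score sets evaluated on
#' the same subjects. Backed by the standard implementation in \pkg{pROC}.
#'
#' @param scores_a,scores_b paired score vectors (same subjects).
#' @param labels binary labels.
#' @return tibble with `auc_a`, `auc_b`, `delta_auc`, `z`, `p`,
#'   `ci_lo_a`, `ci_hi_a`, `ci_lo_b`, `ci_hi_b` (95% DeLong CIs).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y)) {
    stop("scores must be paired on identical subjects")
  }
  ra <- pROC::roc(y, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, scores_b, quiet = TRUE, direction = "<")
  if (identical(rank(scores_a), rank(scores_b))) {
    # rank-identical scores: identical ROC curves, no difference to test
    cia <- as.numeric(pROC::ci.auc(ra, method = "delong"))
    return(tibble::tibble(auc_a = as.numeric(pROC::auc(ra)),
                          auc_b = as.numeric(pROC::auc(rb)),
                          delta_auc = 0, z = 0, p = 1,
                          ci_lo_a = cia[1], ci_hi_a = cia[3],
                          ci_lo_b = cia[1], ci_hi_b = cia[3]))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  cia <- as.numeric(pROC::ci.auc(ra, method = "delong"))
  cib <- as.numeric(pROC::ci.auc(rb, method = "delong"))
  z <- if (!is.null(tst$statistic)) unname(tst$statistic) else NA_real_
  tibble::tibble(auc_a = as.numeric(pROC::auc(ra)),
                 auc_b = as.numeric(pROC::auc(rb)),
                 delta_auc = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
                 z = z, p = unname(tst$p.value),
                 ci_lo_a = cia[1], ci_hi_a = cia[3],
                 ci_lo_b = cib[1], ci_hi_b = cib[3])
}

#' DeLong 95% confidence interval for one AUC
#'
#' @param scores,labels as in [auc_roc()].
#' @return tibble `auc`, `ci_lo`, `ci_hi`.
#' @export
auc_ci <- function(scores, labels) {
  y <- as_binary_labels(labels)
  r <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  tibble::tibble(auc = ci[2], ci_lo = ci[1], ci_hi = ci[3])
}

#' Logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`) returning
#' coefficients and in-sample probabilities; complete separation is
#' detected and raised as a warning.
#'
#' @param X data frame or matrix of predictors.
#' @param y binary outcome.
#' @return an `mrc_logistic` object: list with `coefficients`,
#'   `probabilities`, `model` (the glm), `separation`.
#' @export
logistic_fit <- function(X, y) {
  y <- as_binary_labels(y)
  X <- if (is.null(X)) data.frame(row.names = seq_along(y)) else as.data.frame(X)
  if (ncol(X) > 0 &&
      any(vapply(X, function(c) stats::sd(as.numeric(c)) == 0, TRUE))) {
    stop("constant predictor column")
  }
  dat <- cbind(X, .y = y)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  p <- stats::fitted(fit)
  sep <- any(p < 1e-8 | p > 1 - 1e-8)
  if (sep) warning("possible complete separation in logistic fit")
  if (!fit$converged) stop("logistic regression did not converge")
  structure(list(coefficients = stats::coef(fit), probabilities = unname(p),
                 model = fit, separation = sep),
            class = "mrc_logistic")
}

#' @export
print.mrc_logistic <- function(x, ...) {
  cat("<mrc_logistic>\n"); print(round(x$coefficients, 4)); invisible(x)
}

#' Penalized variable selection down to a size cap
#'
#' Combined L1/L2 (lasso with an optional small ridge floor) logistic
#' deviance path: the penalty is increased from zero and variables are
#' successively dropped as their coefficients reach zero, until at most
#' `max_vars` remain; the survivors are refit unpenalized. With `max_vars`
#' or fewer candidates no penalization is applied.
#'
#' @param X data frame/matrix of candidate predictors (standardized
#'   internally by the path fit).
#' @param y binary outcome.
#' @param max_vars retained-variable cap; 4 is a common choice for cohorts
#'   of this size.
#' @param alpha elastic-net mixing (1 = pure lasso; slightly below 1 adds
#'   the ridge floor).
#' @return list with `selected` (names), `fit` (`mrc_logistic` refit),
#'   `path` (tibble `lambda`, `n_nonzero`).
#' @export
penalized_select <- function(X, y, max_vars = 4, alpha = 1) {
  X <- as.data.frame(X)
  y <- as_binary_labels(y)
  if (ncol(X) <= max_vars) {
    return(list(selected = names(X), fit = logistic_fit(X, y),
                path = tibble::tibble(lambda = numeric(0),
                                      n_nonzero = integer(0))))
  }
  Xm <- as.matrix(X)
  gfit <- glmnet::glmnet(Xm, y, family = "binomial", alpha = alpha,
                         nlambda = 200, standardize = TRUE)
  nz <- gfit$df
  path <- tibble::tibble(lambda = gfit$lambda, n_nonzero = nz)
  ord <- order(gfit$lambda)                    # ascending: penalty grows
  pick <- ord[which(nz[ord] <= max_vars)[1]]
  if (is.na(pick)) pick <- ord[length(ord)]
  coefs <- as.matrix(stats::coef(gfit))[-1, pick]
  selected <- names(coefs)[coefs != 0]
  if (!length(selected)) selected <- names(X)[1]
  list(selected = selected, fit = logistic_fit(X[selected], y), path = path)
}

#' Calibration metrics of predicted probabilities
#'
#' Logistic recalibration of the linear predictor: `y ~ logit(p)` gives the
#' calibration slope and intercept (1 and 0 for perfect calibration), plus
#' the Brier score `mean((p - y)^2)`.
#'
#' @param probabilities predicted probabilities in (0, 1); exact 0/1 are
#'   clipped with a warning.
#' @param y binary outcomes.
#' @return tibble `slope`, `intercept`, `brier`.
#' @export
calibration_metrics <- function(probabilities, y) {
  y <- as_binary_labels(y)
  p <- probabilities
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities clipped away from {0, 1} for recalibration")
    p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  }
  brier <- mean((probabilities - y)^2)
  lp <- stats::qlogis(p)
  if (stats::sd(lp) < 1e-12) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          brier = brier))
  }
  fit <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), brier = brier)
}

#' Pearson correlation with the strong-correlation gate
#'
#' @param x,y numeric vectors, n >= 3, non-degenerate.
#' @param strong_threshold flag threshold on |r| (the radio-pathology
#'   analysis calls r > 0.7 "strong").
#' @return tibble `r`, `p`, `n`, `strong`.
#' @export
pearson_r <- function(x, y, strong_threshold = 0.7) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 strong = ct$estimate > strong_threshold)
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)` on same-shaped binary masks.
#'
#' @param mask_a,mask_b logical/0-1 arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  if (length(a) != length(b)) stop("masks must share a grid")
  if (!any(a) && !any(b)) stop("both masks are empty")
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Pathology-derived cellularity
#'
#' Segmented-nuclei count per section area, `n / A`.
#'
#' @param n_cells nuclei count(s).
#' @param area section area(s), same length or scalar; must be positive.
#' @return density, cells per unit area.
#' @export
pathology_cellularity <- function(n_cells, area) {
  if (any(area <= 0)) stop("`area` must be positive")
  n_cells / area
}

#' Classifier report for one or more metric panels
#'
#' Builds a clinical-performance table on a cohort table: for each
#' named model (a character vector of metric columns), fit an in-sample
#' logistic regression (with penalized selection down to `max_vars` when
#' more candidates are offered), and report AUC with DeLong 95% CI,
#' Youden-threshold sensitivity/specificity/accuracy, calibration slope and
#' intercept, and Brier score. All models are evaluated on the same
#' subjects, so DeLong comparisons between them are valid.
#'
#' @param cohort a cohort table: one row per subject with a `group` column
#'   (the positive class is `positive`) and metric columns.
#' @param models named list mapping model label -> character vector of
#'   metric columns.
#' @param positive group label treated as the positive class.
#' @param max_vars cap for penalized selection.
#' @return an `mrc_classifier_report`: tibble with one row per model and a
#'   `scores` attribute (per-model probability columns) for DeLong
#'   comparisons.
#' @export
cohort_report <- function(cohort, models, positive = "poor", max_vars = 4) {
  stopifnot("group" %in% names(cohort))
  y <- as.integer(cohort$group == positive)
  scores <- list()
  rows <- purrr::imap_dfr(models, function(vars, label) {
    stopifnot(all(vars %in% names(cohort)))
    sel <- penalized_select(cohort[vars], y, max_vars = max_vars)
    p <- sel$fit$probabilities
    scores[[label]] <<- p
    roc <- auc_roc(p, y)
    yj <- youden_operating_point(roc)
    ci <- auc_ci(p, y)
    cal <- calibration_metrics(p, y)
    tibble::tibble(model = label,
                   variables = paste(sel$selected, collapse = "+"),
                   auc = roc$auc, ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                   sensitivity = yj$sensitivity, specificity = yj$specificity,
                   accuracy = yj$accuracy, brier = cal$brier,
                   cal_slope = cal$slope, cal_intercept = cal$intercept)
  })
  attr(rows, "scores") <- tibble::as_tibble(scores)
  attr(rows, "labels") <- y
  class(rows) <- c("mrc_classifier_report", class(rows))
  rows
}
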