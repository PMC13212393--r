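test_that("Mann-Whitney matches independent enumeration and wilcox.test", {
  set.seed(11)
  x <- c(1.2, 3.4, 0.8, 2.2, 5.1); y <- c(2.0, 4.4, 6.3, 1.9, 7.7)
  out <- mann_whitney(x, y)
  # independently coded exhaustive oracle over all 252 assignments
  pool <- c(x, y)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  us <- combn(10, 5, function(idx) u_of(pool[idx], pool[-idx]))
  p_oracle <- mean(abs(us - 12.5) >= abs(out$U - 12.5))
  expect_equal(out$p, p_oracle)
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(out$U, unname(wt$statistic))
  expect_equal(out$p, wt$p.value)
})

test_that("Mann-Whitney edge structure: symmetry and separation", {
  z <- c(1, 2, 3)
  expect_equal(mann_whitney(z, z)$U, 4.5)           # n1 n2 / 2 under ties
  expect_equal(mann_whitney(c(1, 2), c(5, 6))$U, 0) # complete separation
  expect_equal(mann_whitney(c(5, 6), c(1, 2))$U, 4)
  expect_error(mann_whitney(numeric(0), z), "empty")
  # large-sample branch agrees with the tie-corrected normal approximation
  set.seed(3)
  x <- rnorm(30); y <- rnorm(25, 0.6)
  out <- mann_whitney(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(out$p, wt$p.value, tolerance = 1e-10)
})

test_that("AUC is the rescaled U statistic, with ties, on random tables", {
  set.seed(21)
  for (rep in 1:25) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- sample(seq(0, 1, 0.1), n1 + n0, replace = TRUE)  # forces ties
    labels <- c(rep(1, n1), rep(0, n0))
    auc <- auc_roc(scores, labels)$auc
    U <- mann_whitney(scores[labels == 1], scores[labels == 0],
                      exact_max = 0)$U
    expect_lt(abs(auc - U / (n1 * n0)), 1e-12)
  }
  expect_equal(auc_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_error(auc_roc(1:4, rep(1, 4)), "both classes")
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(5)
  scores <- rnorm(30)
  aucs <- replicate(1000, {
    auc_roc(scores, sample(c(rep(1, 15), rep(0, 15))))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("Youden operating point matches an exhaustive threshold sweep", {
  scores <- c(0.1, 0.3, 0.35, 0.6, 0.7, 0.9)
  labels <- c(0, 0, 1, 0, 1, 1)
  roc <- auc_roc(scores, labels)
  yj <- youden_operating_point(roc)
  sweep <- sapply(c(-Inf, scores, Inf), function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / 3
    spec <- sum(!pred & labels == 0) / 3
    sens + spec - 1
  })
  expect_equal(yj$youden, max(sweep))
  expect_equal(yj$accuracy,
               mean((scores >= yj$threshold) == (labels == 1)))
  # perfect separation
  yj2 <- youden_operating_point(auc_roc(c(1, 2, 8, 9), c(0, 0, 1, 1)))
  expect_equal(c(yj2$sensitivity, yj2$specificity, yj2$accuracy), c(1, 1, 1))
  # constant scores carry no information
  yj3 <- youden_operating_point(auc_roc(rep(1, 6), c(0, 0, 0, 1, 1, 1)))
  expect_equal(yj3$youden, 0)
})

test_that("DeLong test honours rank invariance and pairing", {
  set.seed(9)
  y <- c(rep(1, 20), rep(0, 20))
  a <- rnorm(40) + y
  out_same <- delong_test(a, a, y)
  expect_equal(out_same$delta_auc, 0)
  expect_equal(out_same$p, 1)
  out_mono <- delong_test(a, qlogis(plogis(a) ^ 1), y)  # monotone transform
  expect_equal(out_mono$delta_auc, 0)
  expect_error(delong_test(a, a[-1], y), "paired")
  ci <- auc_ci(a, y)
  expect_true(ci$ci_lo <= ci$auc && ci$auc <= ci$ci_hi)
})

test_that("DeLong p-value agrees with a subject-resampling bootstrap", {
  set.seed(14)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  latent <- rnorm(n) + 0.9 * y
  a <- latent + rnorm(n, 0, 0.4)
  b <- latent + rnorm(n, 0, 1.2)
  out <- delong_test(a, b, y)
  boot <- replicate(2000, {
    idx <- sample(n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc_roc(a[idx], y[idx])$auc - auc_roc(b[idx], y[idx])$auc
  })
  boot <- boot[!is.na(boot)]
  delta <- out$auc_a - out$auc_b
  z_boot <- delta / sd(boot)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_lt(abs(out$p - p_boot), 0.02)
})

test_that("logistic regression matches closed forms and a Newton oracle", {
  y <- c(rep(1, 7), rep(0, 13))
  fit0 <- logistic_fit(NULL, y)
  expect_equal(fit0$probabilities, rep(mean(y), 20))
  set.seed(8)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  yr <- rbinom(20, 1, plogis(0.3 + 0.8 * X$a - 0.5 * X$b))
  if (length(unique(yr)) == 1) yr[1] <- 1 - yr[1]
  fit <- logistic_fit(X, yr)
  # independent Newton-Raphson on the log-likelihood
  beta <- rep(0, 3)
  Xm <- cbind(1, as.matrix(X))
  for (i in 1:50) {
    p <- plogis(Xm %*% beta)
    W <- as.vector(p * (1 - p))
    beta <- beta + solve(t(Xm) %*% (Xm * W), t(Xm) %*% (yr - p))
  }
  expect_lt(max(abs(fit$coefficients - as.vector(beta))), 1e-6)
  expect_error(logistic_fit(data.frame(c0 = rep(1, 20)), yr), "constant")
})

test_that("complete separation is detected with a warning", {
  X <- data.frame(x = c(1:5, 10:14))
  y <- rep(c(0, 1), each = 5)
  expect_warning(logistic_fit(X, y), "separation")
})

test_that("penalized selection prunes to the size cap and keeps signal", {
  set.seed(4)
  n <- 86
  y <- rep(c(1, 0), c(37, 49))
  X_small <- data.frame(a = rnorm(n) + y, b = rnorm(n))
  sel <- penalized_select(X_small, y, max_vars = 4)
  expect_setequal(sel$selected, c("a", "b"))   # <= 4 candidates: no pruning
  expect_equal(nrow(sel$path), 0)
  hit <- 0
  for (rep in 1:100) {
    set.seed(1000 + rep)
    X <- data.frame(info = rnorm(n, mean = 1.5 * y),
                    matrix(rnorm(n * 7), n, 7))
    sel <- suppressWarnings(penalized_select(X, y, max_vars = 4))
    expect_lte(length(sel$selected), 4)
    if ("info" %in% sel$selected) hit <- hit + 1
  }
  expect_gte(hit, 95)
})

test_that("the L1 path drops variables monotonically as the penalty grows", {
  set.seed(6)
  n <- 86
  y <- rep(c(1, 0), c(37, 49))
  X <- data.frame(info = rnorm(n, mean = 1.5 * y), matrix(rnorm(n * 7), n, 7))
  sel <- suppressWarnings(penalized_select(X, y, max_vars = 4))
  path <- sel$path[order(sel$path$lambda), ]
  expect_true(all(diff(path$n_nonzero) <= 0))
})

test_that("calibration metrics have their closed forms", {
  y <- rep(c(1, 0), c(30, 70))
  prev <- mean(y)
  out <- calibration_metrics(rep(prev, 100), y)
  expect_equal(out$brier, prev * (1 - prev))
  expect_true(is.na(out$slope))
  # near-deterministic concordant probabilities drive the Brier score to 0
  p_det <- ifelse(y == 1, 1 - 1e-9, 1e-9)
  expect_lt(calibration_metrics(p_det, y)$brier, 1e-12)
  expect_warning(calibration_metrics(c(0, 1, rep(0.5, 98)), y), "clipped")
})

test_that("a well-specified model is calibrated in large samples", {
  set.seed(10)
  n <- 2000
  x <- rnorm(n)
  p_true <- plogis(-0.4 + 1.1 * x)
  y <- rbinom(n, 1, p_true)
  out <- calibration_metrics(p_true, y)
  expect_lt(abs(out$slope - 1), 0.1)
  expect_lt(abs(out$intercept), 0.15)
})

test_that("Pearson correlation and the strong-correlation gate", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_true(pearson_r(x, 2 * x + 1)$strong)
  set.seed(2)
  out <- pearson_r(rnorm(1000), rnorm(1000))
  expect_lt(abs(out$r), 0.1)
  expect_false(out$strong)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("Dice coefficient arithmetic", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2))
  expect_equal(dice(a, b), 0.5)
  expect_error(dice(a & FALSE, a & FALSE), "empty")
})

test_that("pathology cellularity is count per area", {
  expect_equal(pathology_cellularity(100, 0.5), 200)
  expect_equal(pathology_cellularity(0, 2), 0)
  expect_equal(pathology_cellularity(c(10, 20), 2), c(5, 10))
  expect_error(pathology_cellularity(10, 0), "positive")
})

test_that("cohort_report produces a coherent performance table", {
  set.seed(19)
  n <- 60
  tab <- tibble::tibble(
    group = rep(c("poor", "well_moderate"), c(25, 35)),
    m1 = rnorm(n) + (group == "poor") * 1.2,
    m2 = rnorm(n),
    m3 = rnorm(n) + (group == "poor") * 0.5,
    m4 = rnorm(n), m5 = rnorm(n))
  rep_tab <- suppressWarnings(cohort_report(
    tab, models = list(single = "m1",
                       combined = c("m1", "m2", "m3", "m4", "m5"))))
  expect_true(all(rep_tab$auc >= 0 & rep_tab$auc <= 1))
  expect_true(all(rep_tab$ci_lo <= rep_tab$auc & rep_tab$auc <= rep_tab$ci_hi))
  expect_true(all(rep_tab$sensitivity >= 0 & rep_tab$sensitivity <= 1))
  expect_true(all(rep_tab$accuracy >= 0 & rep_tab$accuracy <= 1))
  # combined model was pruned to at most four variables
  expect_lte(length(strsplit(rep_tab$variables[2], "\\+")[[1]]), 4)
  # paired scores are exposed for DeLong comparisons on the same subjects
  sc <- attr(rep_tab, "scores")
  expect_equal(nrow(sc), n)
  dl <- delong_test(sc$single, sc$combined, attr(rep_tab, "labels"))
  expect_true(is.finite(dl$p))
})
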