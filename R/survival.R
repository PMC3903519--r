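# two-level group factor; "short" is always the first (modeled) level
as_group_factor <- function(groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (setequal(levels(g), c("short", "long"))) {
    g <- factor(g, levels = c("short", "long"))
  }
  g
}

#' Per-pair delta tests between two survival groups
#'
#' For every delta feature, a two-sample test of the short- versus
#' long-surviving groups' delta distributions (Welch t-test by default,
#' Mann-Whitney on request). Benjamini-Hochberg adjusted p-values are always
#' co-reported because many pairs are tested at once. Degenerate pairs with
#' zero variance in both groups get p = 1 when the means agree and p = 0
#' when they differ.
#'
#' @param deltas an `nps_deltas` tibble.
#' @param groups `"short"`/`"long"` per subject (any two-level vector;
#'   levels named short/long are ordered short first, otherwise the first
#'   sorted level plays the short role).
#' @param alpha significance level for flagging (default 0.05).
#' @param method `"welch"` or `"wilcoxon"`.
#' @return A tibble of class `nps_group_tests`: `pair`, `mean_short`,
#'   `mean_long`, `mean_difference`, `p_value`, `p_adjusted` (BH),
#'   `significant` (raw p < alpha).
#' @export
survival_group_tests <- function(deltas, groups, alpha = 0.05,
                                 method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(groups) == nrow(deltas))
  g <- as_group_factor(groups)
  a <- g == levels(g)[1]
  b <- g == levels(g)[2]
  if (sum(a) < 2L || sum(b) < 2L) {
    stop("each group needs at least 2 subjects for a variance")
  }
  cols <- delta_columns(deltas)
  res <- purrr::map_dfr(cols, function(cl) {
    x <- deltas[[cl]][a]; y <- deltas[[cl]][b]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
    } else if (method == "welch") {
      p <- stats::t.test(x, y)$p.value
    } else {
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    }
    tibble::tibble(pair = cl, mean_short = mean(x), mean_long = mean(y),
                   mean_difference = mean(x) - mean(y), p_value = p)
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < alpha
  structure(res, alpha = alpha, method = method,
            n_short = sum(a), n_long = sum(b),
            class = c("nps_group_tests", class(tibble::tibble())))
}

#' Scan survival thresholds for the most discriminating dichotomization
#'
#' Splits subjects at each threshold into short (`survival <= t`) and long
#' (`survival > t`) groups, runs [survival_group_tests()] on the delta
#' features, and picks the statistically most significant split: smallest
#' minimum p-value over the pairs, ties going to the larger number of
#' significant pairs, then to the most balanced split, then to the smallest
#' threshold. The minimum p-value is the primary criterion because the
#' count of significant pairs saturates and flips on borderline pairs when
#' the features are strongly correlated, which makes it a blunt objective
#' near the optimum.
#'
#' @param deltas an `nps_deltas` tibble for the subjects with survival data.
#' @param survival_days numeric survival per subject (NA rows are dropped
#'   together with their delta rows).
#' @param lo,hi,step scan range in days (defaults 800-1900 by 10).
#' @param alpha significance level.
#' @param method test passed to [survival_group_tests()].
#' @return A list of class `nps_scan`: `scan` (tibble `threshold`,
#'   `n_short`, `n_long`, `n_significant`, `min_p`), `best_threshold`,
#'   `best_tests` (the [survival_group_tests()] result at the optimum).
#' @export
threshold_scan <- function(deltas, survival_days, lo = 800, hi = 1900,
                           step = 10, alpha = 0.05,
                           method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(survival_days) == nrow(deltas), lo < hi, step > 0)
  keep <- !is.na(survival_days)
  deltas <- deltas[keep, , drop = FALSE]
  surv <- survival_days[keep]
  thresholds <- seq(lo, hi, by = step)
  rows <- vector("list", length(thresholds))
  usable <- logical(length(thresholds))
  for (t in seq_along(thresholds)) {
    thr <- thresholds[t]
    grp <- ifelse(surv <= thr, "short", "long")
    ns <- sum(grp == "short"); nl <- sum(grp == "long")
    if (ns < 2L || nl < 2L) {
      rows[[t]] <- tibble::tibble(threshold = thr, n_short = ns, n_long = nl,
                                  n_significant = NA_integer_, min_p = NA_real_)
      next
    }
    usable[t] <- TRUE
    tests <- survival_group_tests(deltas, factor(grp, levels = c("short", "long")),
                                  alpha = alpha, method = method)
    rows[[t]] <- tibble::tibble(threshold = thr, n_short = ns, n_long = nl,
                                n_significant = sum(tests$significant),
                                min_p = min(tests$p_value))
  }
  scan <- dplyr::bind_rows(rows)
  if (!any(usable)) {
    stop("every threshold puts fewer than 2 subjects in one group; no usable split")
  }
  cand <- scan[usable, ]
  cand$balance <- -abs(cand$n_short - cand$n_long)
  cand <- dplyr::arrange(cand, .data$min_p,
                         dplyr::desc(.data$n_significant),
                         dplyr::desc(.data$balance), .data$threshold)
  best_thr <- cand$threshold[1]
  best_grp <- factor(ifelse(surv <= best_thr, "short", "long"),
                     levels = c("short", "long"))
  best_tests <- survival_group_tests(deltas, best_grp, alpha = alpha,
                                     method = method)
  structure(list(scan = scan[, c("threshold", "n_short", "n_long",
                                 "n_significant", "min_p")],
                 best_threshold = best_thr,
                 best_groups = best_grp,
                 best_tests = best_tests,
                 alpha = alpha),
            class = "nps_scan")
}

#' @export
print.nps_scan <- function(x, ...) {
  best <- x$scan[x$scan$threshold == x$best_threshold, ]
  cat("<nps_scan> ", nrow(x$scan), " thresholds; best ", x$best_threshold,
      " days (", best$n_short, " short / ", best$n_long, " long, ",
      best$n_significant, " significant pairs at alpha ", x$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.nps_scan <- function(x, ...) x$scan

#' @export
glance.nps_scan <- function(x, ...) {
  best <- x$scan[x$scan$threshold == x$best_threshold, ]
  tibble::tibble(best_threshold = x$best_threshold,
                 n_short = best$n_short, n_long = best$n_long,
                 n_significant = best$n_significant, min_p = best$min_p)
}

#' Logistic model for survival category from delta features
#'
#' Maximum-likelihood logistic regression of the short/long survival group
#' on selected delta features, exposing per-subject probabilities and odds
#' of short survival. Perfect separation triggers a warning and a ridge
#' fallback with a small fixed penalty.
#'
#' @param deltas an `nps_deltas` tibble.
#' @param pairs character vector of delta column names to use as features.
#' @param groups factor with levels `c("short","long")` (or any two-level
#'   vector; first sorted level = short = the modeled event).
#' @param ridge_penalty fixed ridge penalty used only on separation.
#' @return A list of class `nps_survival_model`: `coefficients`,
#'   `fitted` (tibble `sample_id`, `p_short`, `odds_short`), `separation`
#'   (logical), `pairs`, `model` (`"ml"` or `"ridge"`).
#' @export
survival_logistic <- function(deltas, pairs, groups, ridge_penalty = 1e-2) {
  stopifnot(length(pairs) >= 1L, length(groups) == nrow(deltas))
  missing_pairs <- setdiff(pairs, names(deltas))
  if (length(missing_pairs)) {
    stop("unknown delta pairs: ", paste(missing_pairs, collapse = ", "))
  }
  g <- as_group_factor(groups)
  y <- as.integer(g == levels(g)[1])  # short = 1
  X <- as.matrix(tibble::as_tibble(deltas)[, pairs, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial())
  )
  eps <- 1e-6
  separated <- !fit$converged ||
    (all(fit$fitted.values[y == 1] > 1 - eps) &&
       all(fit$fitted.values[y == 0] < eps))
  model <- "ml"
  if (separated || any(is.na(fit$coefficients))) {
    warning("perfect separation (or rank deficiency) detected; ",
            "falling back to ridge-penalized fit")
    model <- "ridge"
    Xr <- if (ncol(X) == 1L) cbind(X, 0) else X  # glmnet needs >= 2 columns
    rfit <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                           lambda = ridge_penalty, standardize = FALSE)
    beta <- as.numeric(rfit$beta[seq_len(ncol(X)), 1])
    coefs <- c(`(Intercept)` = as.numeric(rfit$a0), stats::setNames(beta, pairs))
    eta <- as.numeric(cbind(1, X) %*% coefs)
    p <- stats::plogis(eta)
  } else {
    coefs <- stats::setNames(fit$coefficients, c("(Intercept)", pairs))
    p <- fit$fitted.values
  }
  # standard errors from the unpenalized information matrix (ml fits only)
  se <- if (model == "ml") {
    W <- p * (1 - p)
    info <- crossprod(cbind(1, X) * sqrt(W))
    sqrt(diag(solve(info)))
  } else {
    rep(NA_real_, length(coefs))
  }
  structure(list(
    coefficients = tibble::tibble(term = names(coefs), estimate = unname(coefs),
                                  std_error = se),
    fitted = tibble::tibble(sample_id = deltas$sample_id, p_short = p,
                            odds_short = p / (1 - p)),
    separation = model == "ridge",
    pairs = pairs,
    model = model
  ), class = "nps_survival_model")
}

#' @export
tidy.nps_survival_model <- function(x, ...) x$coefficients

#' @export
glance.nps_survival_model <- function(x, ...) {
  tibble::tibble(model = x$model, separation = x$separation,
                 n_features = length(x$pairs))
}

#' Probability and odds of short survival for new subjects
#'
#' Applies a fitted [survival_logistic()] model (or coefficients reloaded
#' via [read_survival_model()]) to new delta rows — the odds worksheet as
#' code.
#'
#' @param object an `nps_survival_model`.
#' @param newdata a tibble containing the model's delta feature columns.
#' @param ... unused.
#' @return A tibble `p_short`, `odds_short`, one row per row of `newdata`.
#' @export
predict.nps_survival_model <- function(object, newdata, ...) {
  X <- as.matrix(tibble::as_tibble(newdata)[, object$pairs, drop = FALSE])
  coefs <- stats::setNames(object$coefficients$estimate,
                           object$coefficients$term)
  eta <- as.numeric(cbind(1, X) %*% coefs[c("(Intercept)", object$pairs)])
  p <- stats::plogis(eta)
  tibble::tibble(p_short = p, odds_short = p / (1 - p))
}

#' Save / load a fitted survival model as JSON
#'
#' @param model an `nps_survival_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_survival_model()` returns the model.
#' @export
write_survival_model <- function(model, path) {
  jsonlite::write_json(list(
    pairs = model$pairs, model = model$model, separation = model$separation,
    coefficients = list(term = model$coefficients$term,
                        estimate = model$coefficients$estimate)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_survival_model
#' @export
read_survival_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = tibble::tibble(term = p$coefficients$term,
                                  estimate = p$coefficients$estimate,
                                  std_error = NA_real_),
    fitted = NULL, separation = isTRUE(p$separation),
    pairs = p$pairs, model = p$model
  ), class = "nps_survival_model")
}
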