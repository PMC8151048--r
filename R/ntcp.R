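#' Univariate logistic screen
#'
#' Fits a single-predictor logistic regression per feature and retains those
#' with likelihood-ratio p-value below `alpha`. No multiple-testing
#' correction is applied (deliberately, so that a few parameters survive in
#' small cohorts); a Benjamini-Hochberg adjusted column is available via
#' `adjust = "BH"` but plays no role in retention by default. Constant
#' features are skipped and listed in the `skipped` attribute; features
#' showing complete separation are retained and flagged.
#'
#' @param data Data frame with the outcome and candidate feature columns.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param features Character vector of feature column names; default: all
#'   numeric columns except the outcome and bookkeeping columns
#'   (`id`, `split`).
#' @param alpha Significance level of the screen.
#' @param adjust Optional p-adjustment method (see [stats::p.adjust()]);
#'   reported as `p_adj`, never used for retention unless
#'   `use_adjusted = TRUE`.
#' @param use_adjusted Retain on adjusted p-values instead.
#' @return A tibble with columns `feature`, `estimate`, `p_value`,
#'   `separation`, `retained` (ordered by `p_value`), and attribute
#'   `skipped`.
#' @export
univariate_screen <- function(data, outcome, features = NULL, alpha = 0.05,
                              adjust = NULL, use_adjusted = FALSE) {
  y <- data[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1))) {
    abort("`outcome` must name a binary 0/1 column.",
          class = "dosiomics_invalid_argument")
  }
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c(outcome, "id", "split"))
  }
  skipped <- character(0)
  rows <- purrr::map(features, function(f) {
    x <- data[[f]]
    if (length(unique(x[!is.na(x)])) < 2) {
      skipped <<- c(skipped, f)
      return(NULL)
    }
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    sep <- detect_separation(fit)
    p_lrt <- pchisq(fit$null.deviance - fit$deviance, df = 1,
                    lower.tail = FALSE)
    tibble(feature = f, estimate = unname(coef(fit)[2]), p_value = p_lrt,
           separation = sep)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(feature = character(), estimate = numeric(),
                  p_value = numeric(), separation = logical(),
                  retained = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }
  if (!is.null(adjust)) {
    out$p_adj <- stats::p.adjust(out$p_value, method = adjust)
  }
  crit <- if (use_adjusted && !is.null(adjust)) out$p_adj else out$p_value
  out$retained <- crit < alpha
  out <- dplyr::arrange(out, .data$p_value, .data$feature)
  attr(out, "skipped") <- skipped
  out
}

# complete/quasi-complete separation: fitted probabilities pinned at 0/1.
# (No coefficient-magnitude heuristic: per-unit slopes are scale-dependent
# and radiomic features legitimately span orders of magnitude.)
detect_separation <- function(fit) {
  mu <- fitted(fit)
  any(mu < 1e-8 | mu > 1 - 1e-8)
}

#' Spearman redundancy filter
#'
#' Among retained candidates, removes redundant features: whenever two
#' features have absolute Spearman rank correlation above `rho_max`, the one
#' with the larger univariate p-value is dropped. Implemented greedily in
#' ascending univariate p (ties broken by feature name), which makes "keep
#' the smaller p" deterministic for chains of correlated features.
#'
#' @param data Data frame holding the feature columns.
#' @param screened Tibble from [univariate_screen()] (or any tibble with
#'   `feature` and `p_value`); only rows with `retained = TRUE` are used if
#'   that column exists.
#' @param rho_max Correlation threshold (exclusive); default 0.80.
#' @return The surviving rows of `screened`, with attribute `dropped`.
#' @export
spearman_redundancy_filter <- function(data, screened, rho_max = 0.80) {
  cand <- screened
  if ("retained" %in% names(cand)) cand <- cand[cand$retained, , drop = FALSE]
  if (nrow(cand) == 0) {
    attr(cand, "dropped") <- character(0)
    return(cand)
  }
  cand <- dplyr::arrange(cand, .data$p_value, .data$feature)
  feats <- cand$feature
  if (length(feats) > 1) {
    rho <- suppressWarnings(
      cor(as.matrix(data[feats]), method = "spearman",
          use = "pairwise.complete.obs"))
    rho[is.na(rho)] <- 0
  }
  kept <- character(0)
  for (f in feats) {
    if (length(kept) == 0 ||
        all(abs(rho[f, kept]) <= rho_max)) {
      kept <- c(kept, f)
    }
  }
  out <- cand[cand$feature %in% kept, , drop = FALSE]
  attr(out, "dropped") <- setdiff(feats, kept)
  out
}

#' Backward-elimination multivariate logistic NTCP model
#'
#' Starting from the filtered feature set, iteratively refits the
#' multivariate logistic model and drops the feature with the largest
#' likelihood-ratio p-value at or above `p_remove`, until every remaining
#' feature is below `p_remove`. The model may reduce to intercept-only. If
#' the number of starting features exceeds events/5 a warning is raised but
#' fitting proceeds. Separation or non-convergence triggers a Firth-type
#' penalized-likelihood refit (Wald p-values), flagged in the result.
#'
#' The returned model carries odds ratios with both a 10th-90th percentile
#' interval (profile-likelihood 80% interval on the OR scale) and a
#' conventional 95% CI, the training ROC AUC with DeLong 95% CI, and the
#' Youden-index probability cutoff frozen on the training data.
#'
#' @inheritParams univariate_screen
#' @param features Starting feature set (character).
#' @param p_remove Removal threshold; default 0.05, matching the screening
#'   alpha.
#' @param endpoint_label,family_set Labels carried into reports.
#' @return An object of class `ntcp_model`.
#' @export
backward_elimination <- function(data, outcome, features, p_remove = 0.05,
                                 endpoint_label = NA_character_,
                                 family_set = NA_character_) {
  y <- data[[outcome]]
  events <- sum(y)
  if (length(features) > 0 && length(features) > events / 5) {
    warn(sprintf("%d features for %d events exceeds the events/5 guard",
                 length(features), events))
  }
  feats <- features
  flags <- character(0)
  repeat {
    fit <- fit_logistic(data, outcome, feats)
    if (length(feats) == 0) break
    pv <- fit$p_values
    worst <- which.max(pv)
    if (pv[worst] >= p_remove) {
      feats <- setdiff(feats, names(pv)[worst])
    } else {
      break
    }
  }
  flags <- fit$flags

  scores <- fit$predict(data)
  roc <- roc_auc(scores, y)
  cut <- youden_cutoff(scores, y)

  no_feats <- length(feats) == 0
  structure(
    list(endpoint = endpoint_label, family_set = family_set,
         features = feats,
         coefficients = fit$coefficients,
         p_values = fit$p_values,
         odds_ratio = if (no_feats) numeric(0) else
           exp(fit$coefficients[feats]),
         or_p10 = if (no_feats) numeric(0) else exp(fit$ci80[feats, 1]),
         or_p90 = if (no_feats) numeric(0) else exp(fit$ci80[feats, 2]),
         or_ci95_lo = if (no_feats) numeric(0) else exp(fit$ci95[feats, 1]),
         or_ci95_hi = if (no_feats) numeric(0) else exp(fit$ci95[feats, 2]),
         auc_train = roc$auc, auc_ci = c(roc$ci_lo, roc$ci_hi),
         cutoff = cut_to_unit(cut),
         n_train = length(y), events_train = events,
         flags = flags, predict_fun = fit$predict),
    class = "ntcp_model"
  )
}

cut_to_unit <- function(cut) min(max(as.numeric(cut), 1e-12), 1 - 1e-12)

# Fit a logistic model, with Firth fallback on separation/non-convergence.
# Returns coefficients, per-feature LRT (or Wald) p-values, 80%/95%
# intervals and a prediction closure.
fit_logistic <- function(data, outcome, features) {
  y <- data[[outcome]]
  flags <- character(0)
  if (length(features) == 0) {
    b0 <- qlogis(pmin(pmax(mean(y), 1e-12), 1 - 1e-12))
    co <- c("(Intercept)" = b0)
    return(list(coefficients = co, p_values = setNames(numeric(0),
                                                       character(0)),
                ci80 = matrix(NA_real_, 0, 2), ci95 = matrix(NA_real_, 0, 2),
                flags = flags,
                predict = function(newdata) rep(plogis(b0), nrow(newdata))))
  }
  fml <- stats::as.formula(paste0("`", outcome, "` ~ ",
                                  paste0("`", features, "`",
                                         collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = data, family = binomial()))
  use_firth <- !fit$converged || detect_separation(fit)
  if (!use_firth) {
    dr <- suppressWarnings(stats::drop1(fit, test = "Chisq"))
    pv <- setNames(dr[["Pr(>Chi)"]][-1], features)
    ci80 <- tryCatch(
      suppressWarnings(suppressMessages(confint(fit, level = 0.80))),
      error = function(e) NULL)
    ci95 <- tryCatch(
      suppressWarnings(suppressMessages(confint(fit, level = 0.95))),
      error = function(e) NULL)
    if (is.null(ci80) || is.null(ci95) || any(is.na(ci80)) ||
        any(is.na(ci95))) {
      use_firth <- TRUE
    } else {
      if (length(features) == 0) {
        ci80 <- matrix(ci80, ncol = 2); ci95 <- matrix(ci95, ncol = 2)
      }
      ci80 <- matrix(ci80[-1, ], ncol = 2,
                     dimnames = list(features, NULL))
      ci95 <- matrix(ci95[-1, ], ncol = 2,
                     dimnames = list(features, NULL))
      co <- coef(fit)
      names(co) <- c("(Intercept)", features)
      pred <- local({
        beta <- co; fts <- features
        function(newdata) {
          x <- cbind(1, as.matrix(newdata[fts]))
          plogis(drop(x %*% beta))
        }
      })
      return(list(coefficients = co, p_values = pv, ci80 = ci80,
                  ci95 = ci95, flags = flags, predict = pred))
    }
  }
  # Firth-type penalized fallback, on column-standardized predictors for
  # numerical stability; coefficients are mapped back to the raw scale.
  flags <- c(flags, "firth_fallback")
  xm <- as.matrix(data[features])
  mu_x <- colMeans(xm)
  sd_x <- apply(xm, 2, sd)
  sd_x[sd_x == 0] <- 1
  xs <- sweep(sweep(xm, 2, mu_x), 2, sd_x, "/")
  x <- cbind(`(Intercept)` = 1, xs)
  ff <- firth_logistic(x, y)
  if (!ff$converged) flags <- c(flags, "non_convergence")
  # back-transform to raw scale
  b_raw <- ff$coefficients
  b_raw[-1] <- ff$coefficients[-1] / sd_x
  b_raw[1] <- ff$coefficients[1] - sum(ff$coefficients[-1] * mu_x / sd_x)
  se_raw <- ff$se
  se_raw[-1] <- ff$se[-1] / sd_x
  ff$coefficients <- b_raw
  ff$se <- se_raw
  z <- ff$coefficients / ff$se
  pv <- setNames(2 * stats::pnorm(-abs(z[-1])), features)
  q80 <- stats::qnorm(0.90)
  q95 <- stats::qnorm(0.975)
  ci80 <- cbind(ff$coefficients[-1] - q80 * ff$se[-1],
                ff$coefficients[-1] + q80 * ff$se[-1])
  ci95 <- cbind(ff$coefficients[-1] - q95 * ff$se[-1],
                ff$coefficients[-1] + q95 * ff$se[-1])
  rownames(ci80) <- rownames(ci95) <- features
  co <- ff$coefficients
  pred <- local({
    beta <- co; fts <- features
    function(newdata) {
      xm <- cbind(1, as.matrix(newdata[fts]))
      plogis(drop(xm %*% beta))
    }
  })
  list(coefficients = co, p_values = pv, ci80 = ci80, ci95 = ci95,
       flags = flags, predict = pred)
}

#' ROC AUC with 95% confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability (ties credited 0.5),
#' computed directly from ranks; the 95% CI uses the DeLong variance.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 outcomes.
#' @return List with `auc`, `ci_lo`, `ci_hi`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ci <- tryCatch(
    as.numeric(pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                      direction = "<"),
                            method = "delong"))[c(1, 3)],
    error = function(e) c(NA_real_, NA_real_))
  list(auc = auc, ci_lo = max(ci[1], 0), ci_hi = min(ci[2], 1))
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    abort("both outcome classes must be present.",
          class = "dosiomics_invalid_argument")
  }
}

#' Youden-index classification cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the midpoints between
#' adjacent sorted unique scores, plus the two boundary rules (classify
#' everything positive / everything negative, both with J = 0), so the
#' returned J is never below zero. Classification rule: positive if score
#' >= cutoff. Ties are broken toward the lower threshold. If all scores are
#' equal the common value is returned with J = 0 and a `degenerate` flag.
#'
#' @inheritParams roc_auc
#' @return The cutoff, with attributes `J`, `sensitivity`, `specificity`
#'   and `degenerate`.
#' @export
youden_cutoff <- function(scores, labels) {
  check_two_classes(labels)
  su <- sort(unique(scores))
  if (length(su) == 1) {
    return(structure(su, J = 0, sensitivity = 1, specificity = 0,
                     degenerate = TRUE))
  }
  mids <- c(su[1],                          # everything positive
            (su[-1] + su[-length(su)]) / 2,
            su[length(su)] + min(diff(su)) / 2)  # everything negative
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  best <- NULL
  for (t in mids) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  structure(best$t, J = best$j, sensitivity = best$sens,
            specificity = best$spec, degenerate = FALSE)
}

#' Balanced accuracy
#'
#' The average of sensitivity and specificity, robust to class imbalance.
#'
#' @param predicted Binary 0/1 predictions.
#' @param labels Binary 0/1 true outcomes (both classes required).
#' @return List with `bacc`, `sensitivity`, `specificity`.
#' @export
balanced_accuracy <- function(predicted, labels) {
  check_two_classes(labels)
  sens <- sum(predicted == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(predicted == 0 & labels == 0) / sum(labels == 0)
  list(bacc = (sens + spec) / 2, sensitivity = sens, specificity = spec)
}

#' DeLong test comparing two correlated ROC curves
#'
#' Two-sided DeLong test for paired risk scores on the same patients. A
#' degenerate variance (e.g. identical score vectors) yields p = 1 with a
#' flag.
#'
#' @param scores_a,scores_b Paired risk scores.
#' @param labels Binary 0/1 outcomes.
#' @return List with `p_value`, `auc_a`, `auc_b`, `flag`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  check_two_classes(labels)
  auc_a <- roc_auc(scores_a, labels)$auc
  auc_b <- roc_auc(scores_b, labels)$auc
  res <- tryCatch({
    ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
    tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    p <- as.numeric(tt$p.value)
    if (is.nan(p)) list(p = 1, flag = "degenerate_variance")
    else list(p = p, flag = NA_character_)
  }, error = function(e) list(p = 1, flag = "degenerate_variance"))
  list(p_value = res$p, auc_a = auc_a, auc_b = auc_b, flag = res$flag)
}

#' @export
print.ntcp_model <- function(x, ...) {
  cat("<ntcp_model> ", x$endpoint,
      if (!is.na(x$family_set)) paste0(" [", x$family_set, "]"), "\n",
      sep = "")
  if (length(x$features) == 0) {
    cat("  intercept-only (no features retained)\n")
  } else {
    print(tidy(x))
  }
  cat(sprintf("  training AUC %.3f (95%% CI %.3f-%.3f), cutoff %.3f, n = %d (%d events)\n",
              x$auc_train, x$auc_ci[1], x$auc_ci[2], x$cutoff, x$n_train,
              x$events_train))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
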