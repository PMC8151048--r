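#' Feature families available for one endpoint
#'
#' Maps an endpoint to its organ (rectal endpoints use the rectum, GU the
#' bladder, vaginal the vagina) and selects the matching columns: clinical
#' covariates, the organ's DVH metrics with the endpoint-appropriate
#' alpha/beta routing (acute endpoints see the physical EBRT metrics plus
#' the alpha/beta = 10 EQD2-summed metrics; late endpoints the alpha/beta =
#' 3 ones), and the organ's `RA_` radiomic features.
#'
#' @param table A cohort table.
#' @param endpoint One of [endpoint_labels()].
#' @return Named list of character vectors: `clinical`, `DVH`, `RA`.
#' @export
endpoint_families <- function(table, endpoint) {
  organ <- endpoint_organ(endpoint)
  timing <- sub("^.*_", "", endpoint)
  ab <- if (timing == "acute") "ab10" else "ab3"
  dvh_cols <- grep(paste0("^DVH_", organ, "_"), names(table), value = TRUE)
  dvh_cols <- dvh_cols[grepl("_EBRT$", dvh_cols) |
                       grepl(paste0("_", ab, "$"), dvh_cols)]
  list(
    clinical = intersect(c("figo_stage", "age", "baseline_symptoms",
                           "prior_abdominal_surgery", "rectal_comorbidities",
                           "tnm_n_positive"), names(table)),
    DVH = dvh_cols,
    RA = grep(paste0("^RA_", organ, "_"), names(table), value = TRUE)
  )
}

parameter_sets <- function() {
  list(clinical = "clinical", DVH = "DVH", RA = "RA",
       `clinical+DVH` = c("clinical", "DVH"),
       `clinical+RA` = c("clinical", "RA"),
       `clinical+DVH+RA` = c("clinical", "DVH", "RA"))
}

#' Run the full NTCP study design on a cohort table
#'
#' For each endpoint with at least one event in the training split, builds
#' the six parameter-set models (clinical, DVH, RA, clinical+DVH,
#' clinical+RA, clinical+DVH+RA) on the training split only — univariate
#' screen, Spearman redundancy filter, backward elimination — evaluates the
#' frozen signature and Youden cutoff on the testing split (balanced
#' accuracy, sensitivity, specificity), and runs the paired DeLong
#' comparison of clinical+DVH vs clinical+DVH+RA training scores.
#' Everything is deterministic given the table.
#'
#' @param table Cohort tibble with `id`, `split`, covariates, feature and
#'   endpoint columns (e.g. `gen_cohort(...)$table`).
#' @param endpoints Endpoints to analyse; default all six.
#' @param alpha Univariate screening level.
#' @param rho_max Spearman redundancy threshold.
#' @param p_remove Backward-elimination removal threshold.
#' @return An `ntcp_report`: per endpoint a list with `models` (named
#'   `ntcp_model` list), `evaluation` (tibble of AUC/BAcc per set) and
#'   `auc_comparison`.
#' @export
run_endpoint_analysis <- function(table, endpoints = endpoint_labels(),
                                  alpha = 0.05, rho_max = 0.80,
                                  p_remove = 0.05) {
  train <- table[table$split == "training", , drop = FALSE]
  test <- table[table$split == "testing", , drop = FALSE]
  out <- list()
  for (ep in endpoints) {
    if (!ep %in% names(table)) next
    if (sum(train[[ep]]) == 0) {
      inform(paste0("endpoint ", ep, " has zero training events; skipped"))
      next
    }
    fams <- endpoint_families(table, ep)
    models <- list()
    evals <- list()
    for (set_name in names(parameter_sets())) {
      pool <- unlist(fams[parameter_sets()[[set_name]]], use.names = FALSE)
      scr <- univariate_screen(train, ep, pool, alpha)
      red <- spearman_redundancy_filter(train, scr, rho_max)
      mod <- backward_elimination(train, ep, red$feature, p_remove,
                                  endpoint_label = ep,
                                  family_set = set_name)
      models[[set_name]] <- mod
      ev <- evaluate_on_test(mod, test, ep)
      evals[[set_name]] <- tibble(
        endpoint = ep, set = set_name,
        n_features = length(mod$features),
        auc_train = mod$auc_train,
        auc_ci_lo = mod$auc_ci[1], auc_ci_hi = mod$auc_ci[2],
        cutoff = mod$cutoff,
        bacc_test = ev$bacc, sensitivity = ev$sensitivity,
        specificity = ev$specificity)
    }
    cmp <- compare_auc(
      models[["clinical+DVH"]]$predict_fun(train),
      models[["clinical+DVH+RA"]]$predict_fun(train),
      train[[ep]])
    out[[ep]] <- list(models = models,
                      evaluation = dplyr::bind_rows(evals),
                      auc_comparison = tibble(
                        endpoint = ep,
                        set_a = "clinical+DVH", set_b = "clinical+DVH+RA",
                        auc_a = cmp$auc_a, auc_b = cmp$auc_b,
                        p_value = cmp$p_value, flag = cmp$flag))
  }
  structure(out, class = "ntcp_report")
}

evaluate_on_test <- function(model, test, endpoint) {
  if (nrow(test) == 0 || length(unique(test[[endpoint]])) < 2) {
    return(list(bacc = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_))
  }
  scores <- model$predict_fun(test)
  pred <- as.integer(scores >= model$cutoff)
  balanced_accuracy(pred, test[[endpoint]])
}

#' @export
print.ntcp_report <- function(x, ...) {
  cat("<ntcp_report> ", length(x), " endpoint(s)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy an NTCP model or report
#'
#' `tidy()` on an `ntcp_model` gives one row per retained feature
#' (coefficient, LRT p, OR with 10th-90th percentile interval and 95% CI);
#' `glance()` one row of model-level summaries. On an `ntcp_report`, the
#' rows of all endpoint/parameter-set combinations are stacked.
#'
#' @param x An `ntcp_model` or `ntcp_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ntcp_model <- function(x, ...) {
  if (length(x$features) == 0) {
    return(tibble(endpoint = x$endpoint, set = x$family_set,
                  feature = character(), estimate = numeric(),
                  p_value = numeric(), odds_ratio = numeric(),
                  or_p10 = numeric(), or_p90 = numeric(),
                  or_ci95_lo = numeric(), or_ci95_hi = numeric()))
  }
  tibble(endpoint = x$endpoint, set = x$family_set, feature = x$features,
         estimate = unname(x$coefficients[x$features]),
         p_value = unname(x$p_values[x$features]),
         odds_ratio = unname(x$odds_ratio),
         or_p10 = unname(x$or_p10), or_p90 = unname(x$or_p90),
         or_ci95_lo = unname(x$or_ci95_lo),
         or_ci95_hi = unname(x$or_ci95_hi))
}

#' @rdname tidy.ntcp_model
#' @export
glance.ntcp_model <- function(x, ...) {
  tibble(endpoint = x$endpoint, set = x$family_set,
         n_features = length(x$features),
         auc_train = x$auc_train, auc_ci_lo = x$auc_ci[1],
         auc_ci_hi = x$auc_ci[2], cutoff = x$cutoff,
         n_train = x$n_train, events_train = x$events_train,
         flags = paste(x$flags, collapse = ";"))
}

#' @rdname tidy.ntcp_model
#' @export
tidy.ntcp_report <- function(x, ...) {
  purrr::map_dfr(x, function(ep) {
    purrr::map_dfr(ep$models, tidy)
  })
}

#' @rdname tidy.ntcp_model
#' @export
glance.ntcp_report <- function(x, ...) {
  purrr::map_dfr(x, function(ep) ep$evaluation)
}

#' Write model reports mirroring the published table layout
#'
#' Per endpoint: a delimited file of feature-level rows (feature | P | OR |
#' 10th-90th percentile interval | AUC | 95% CI), a human-readable text
#' table, and a cohort-level `summary.csv` of training AUC and testing
#' balanced accuracy per parameter set. Intercept-only models appear as a
#' "no features retained" row in the text table.
#'
#' @param report An `ntcp_report`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (ep in names(report)) {
    blk <- report[[ep]]
    tt <- purrr::map_dfr(blk$models, tidy)
    gl <- purrr::map_dfr(blk$models, glance)
    readr::write_csv(tt, file.path(path, paste0(ep, "_models.csv")))
    txt <- c(sprintf("Endpoint: %s", ep), strrep("-", 72))
    for (set_name in names(blk$models)) {
      m <- blk$models[[set_name]]
      g <- glance(m)
      txt <- c(txt, sprintf("%s  (AUC %.2f, 95%% CI %.2f-%.2f)",
                            set_name, g$auc_train, g$auc_ci_lo,
                            g$auc_ci_hi))
      td <- tidy(m)
      if (nrow(td) == 0) {
        txt <- c(txt, "  no features retained")
      } else {
        txt <- c(txt, sprintf(
          "  %-40s P=%-8.3g OR=%-8.3g %.3g-%.3g",
          td$feature, td$p_value, td$odds_ratio, td$or_p10, td$or_p90))
      }
    }
    writeLines(txt, file.path(path, paste0(ep, "_models.txt")))
  }
  readr::write_csv(glance(report), file.path(path, "summary.csv"))
  readr::write_csv(purrr::map_dfr(report, function(b) b$auc_comparison),
                   file.path(path, "auc_comparisons.csv"))
  invisible(path)
}

#' ROC curve plot for an NTCP model
#'
#' @param object An `ntcp_model`.
#' @param data The data (with outcome column) to score; defaults to nothing
#'   being plotted without data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ntcp_model <- function(object, data, ...) {
  scores <- object$predict_fun(data)
  y <- data[[object$endpoint]]
  th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  pts <- purrr::map_dfr(th, function(t) {
    tibble(fpr = mean(scores[y == 0] >= t), tpr = mean(scores[y == 1] >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("%s [%s], AUC %.2f", object$endpoint,
                                  object$family_set, object$auc_train)) +
    ggplot2::theme_minimal()
}
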