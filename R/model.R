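## Logistic risk model over pooled (patient, prediction-time) rows:
## weakly L2-penalized maximum likelihood, recursive feature elimination with
## patient-grouped cross-validation, rolling prediction with per-feature
## contributions.

# Penalized logistic fit by iteratively reweighted least squares. The
# intercept is unpenalized; `lambda` is the L2 strength on the remaining
# coefficients (on the scale of the summed log-likelihood). lambda = 0 is
# the plain ML fit.
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100, tol = 1e-9) {
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  storage.mode(X1) <- "double"
  y <- as.numeric(y)
  p <- ncol(X1)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * w, X1)
    diag(H) <- diag(H) + pen
    score <- crossprod(X1, y - mu) - pen * beta
    step <- tryCatch(solve(H, score), error = function(e) {
      diag(H) <- diag(H) + 1e-8 * max(diag(H))
      solve(H, score)
    })
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  list(intercept = unname(beta[1]),
       coefficients = stats::setNames(unname(beta[-1]), colnames(X1)[-1]),
       converged = converged, iterations = it)
}

# Elimination ranking: repeatedly drop the candidate with the smallest
# |coefficient| (ties broken lexicographically by name). Returns candidate
# names best-first. `forced` columns stay in every fit and are never dropped.
rfe_ranking <- function(X, y, candidates, forced, lambda) {
  active <- candidates
  eliminated <- character(0)
  while (length(active) > 1L) {
    fit <- ridge_logistic(X[, c(active, forced), drop = FALSE], y, lambda)
    ab <- abs(fit$coefficients[active])
    drop_one <- active[order(ab, active)][1L]
    eliminated <- c(drop_one, eliminated)
    active <- setdiff(active, drop_one)
  }
  c(active, eliminated)
}

#' Recursive feature elimination with patient-grouped cross-validation
#'
#' Selects the dynamic feature subset for the risk model: within each inner
#' cross-validation split (stratified by outcome, grouped by patient so no
#' patient contributes rows to both sides), features are eliminated one at a
#' time by smallest absolute coefficient and every feature count is scored by
#' held-out AUC on the pooled prediction-time rows. The count with the best
#' mean score wins (ties favour fewer features), and the final ranking on all
#' rows supplies that many features. Deterministic given `seed`.
#'
#' @param features Normalized feature matrix rows (`patient_id`, `label`,
#'   feature columns). Rows with missing candidate values are dropped
#'   (complete-case; the pipeline never imputes).
#' @param candidates Dynamic feature columns to select among; defaults to the
#'   matrix's candidate attribute.
#' @param forced Columns always kept in the model and never eliminated
#'   (default `"agecat"`).
#' @param n_folds Inner CV folds (default 5).
#' @param seed Integer seed for the fold draw.
#' @param lambda L2 strength of the underlying logistic fits.
#' @return Character vector of selected feature names, best-first; the
#'   per-count CV scores are attached as attribute `"scores"`.
#' @export
select_features_rfe <- function(features, candidates = NULL,
                                forced = "agecat", n_folds = 5, seed = 1L,
                                lambda = 1e-3) {
  candidates <- candidates %||% attr(features, "candidates")
  if (is.null(candidates) || length(candidates) == 0L) {
    abort("no candidate features to select among")
  }
  check_columns(features, c("patient_id", "label", candidates, forced),
                "feature matrix")
  cc <- stats::complete.cases(features[, c(candidates, forced), drop = FALSE])
  df <- features[cc, , drop = FALSE]
  if (length(unique(df$label)) < 2L) {
    abort("feature selection needs both outcome classes")
  }
  if (length(candidates) == 1L) {
    return(candidates)
  }
  X <- as.matrix(df[, c(candidates, forced), drop = FALSE])
  y <- as.numeric(df$label)

  pts <- dplyr::distinct(df, .data$patient_id, .data$label)
  fold <- assign_folds(pts$patient_id, pts$label, n_folds, seed)
  fold_of <- stats::setNames(fold, pts$patient_id)
  row_fold <- fold_of[df$patient_id]

  K <- length(candidates)
  scores <- matrix(NA_real_, nrow = K, ncol = n_folds)
  for (f in seq_len(n_folds)) {
    tr <- row_fold != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
    ranking <- rfe_ranking(X[tr, , drop = FALSE], y[tr], candidates, forced,
                           lambda)
    for (k in seq_len(K)) {
      feats <- c(ranking[seq_len(k)], forced)
      fit <- ridge_logistic(X[tr, feats, drop = FALSE], y[tr], lambda)
      risk <- stats::plogis(fit$intercept +
                              drop(X[!tr, feats, drop = FALSE] %*%
                                     fit$coefficients))
      scores[k, f] <- auc(risk, y[!tr])
    }
  }
  mean_score <- rowMeans(scores, na.rm = TRUE)
  best_k <- which.max(mean_score)  # ties resolve to the smaller count
  final_ranking <- rfe_ranking(X, y, candidates, forced, lambda)
  selected <- final_ranking[seq_len(best_k)]
  attr(selected, "scores") <- tibble::tibble(
    n_features = seq_len(K), mean_auc = mean_score)
  selected
}

#' Fit the dynamic logistic risk model
#'
#' Trains the 30-day mortality model on pooled (patient, prediction-time)
#' rows: fits the min-max normalizer on the training rows, optionally runs
#' recursive feature elimination, then fits a weakly L2-penalized logistic
#' regression on the selected features plus the age category. The fitted
#' coefficients are constant across prediction times; only the feature
#' values roll forward.
#'
#' @param features Raw (unnormalized) feature matrix from
#'   [build_feature_matrix()], training rows only.
#' @param seed Seed for the elimination's inner fold draw.
#' @param rfe Run recursive feature elimination (default `TRUE`); otherwise
#'   all candidates enter the model.
#' @param lambda L2 strength (default `1e-3`), recorded in the artifact.
#' @param rfe_folds Inner CV folds for the elimination.
#' @return An `icudyn_model`: variant, selected features, coefficients and
#'   intercept (log-odds units), normalization bounds, training metadata.
#' @export
fit_dynamic_model <- function(features, seed = 1L, rfe = TRUE,
                              lambda = 1e-3, rfe_folds = 5) {
  variant <- attr(features, "variant")
  candidates <- attr(features, "candidates")
  if (is.null(variant) || is.null(candidates)) {
    abort("`features` must come from build_feature_matrix()")
  }
  if (length(unique(features$label)) < 2L) {
    abort("model fitting needs both outcome classes")
  }
  normalizer <- fit_normalizer(features, candidates)
  norm <- apply_normalizer(features, normalizer)
  selected <- if (rfe) {
    select_features_rfe(norm, candidates, forced = "agecat",
                        n_folds = rfe_folds, seed = seed, lambda = lambda)
  } else {
    candidates
  }
  model_cols <- c(selected, "agecat")
  cc <- stats::complete.cases(norm[, model_cols, drop = FALSE])
  df <- norm[cc, , drop = FALSE]
  fit <- ridge_logistic(as.matrix(df[, model_cols, drop = FALSE]),
                        as.numeric(df$label), lambda)
  if (!fit$converged) {
    warn(sprintf("logistic fit did not converge in %d iterations",
                 fit$iterations))
  }
  structure(
    list(variant = variant,
         features = as.character(selected),
         coefficients = fit$coefficients,
         intercept = fit$intercept,
         normalizer = normalizer,
         lambda = lambda,
         seed = as.integer(seed),
         rfe = rfe,
         rfe_scores = attr(selected, "scores"),
         n_train_rows = nrow(df),
         n_train_patients = dplyr::n_distinct(df$patient_id),
         converged = fit$converged,
         iterations = fit$iterations),
    class = "icudyn_model"
  )
}

#' @export
print.icudyn_model <- function(x, ...) {
  cat(sprintf(
    "<icudyn_model> %s: %d dynamic features + agecat, lambda = %g\n",
    x$variant, length(x$features), x$lambda))
  cat(sprintf("  trained on %d rows from %d patients (seed %d)\n",
              x$n_train_rows, x$n_train_patients, x$seed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.icudyn_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @exportS3Method generics::glance
glance.icudyn_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, n_features = length(x$features),
    n_train_rows = x$n_train_rows, n_train_patients = x$n_train_patients,
    lambda = x$lambda, converged = x$converged
  )
}

#' Rolling risk predictions with per-feature contributions
#'
#' Scores every available prediction time of every patient with one constant
#' model artifact: 30-day mortality risk plus the signed contribution
#' (coefficient x normalized value) of each model feature. Timepoints where
#' a required feature window is completely missing are skipped for that
#' patient; the prediction schedule never extends past the patient's usable
#' end.
#'
#' @param model An `icudyn_model`.
#' @param newdata An `icudyn_censored` cohort or a raw feature matrix from
#'   [build_feature_matrix()] with matching variant.
#' @param times_hours Prediction schedule used when `newdata` is a cohort.
#' @return Tibble `patient_id`, `t_hours`, `risk`, and one `contrib_*`
#'   column per model feature (including `agecat`).
#' @export
predict_rolling <- function(model, newdata,
                            times_hours = seq(24, 120, by = 8)) {
  stopifnot(inherits(model, "icudyn_model"))
  features <- if (inherits(newdata, "icudyn_censored")) {
    build_feature_matrix(newdata, model$variant, times_hours)
  } else {
    newdata
  }
  variant <- attr(features, "variant")
  if (!identical(variant, model$variant)) {
    abort(sprintf("model variant '%s' does not match feature variant '%s'",
                  model$variant, variant %||% "<none>"))
  }
  norm <- apply_normalizer(features, model$normalizer)
  model_cols <- names(model$coefficients)
  cc <- stats::complete.cases(norm[, model_cols, drop = FALSE])
  df <- norm[cc, , drop = FALSE]
  X <- as.matrix(df[, model_cols, drop = FALSE])
  contrib <- sweep(X, 2, model$coefficients, `*`)
  colnames(contrib) <- paste0("contrib_", model_cols)
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = df$patient_id, t_hours = df$t_hours,
                   risk = stats::plogis(model$intercept + rowSums(contrib))),
    tibble::as_tibble(contrib)
  )
  dplyr::arrange(out, .data$patient_id, .data$t_hours)
}

#' Classify patients from their last rolling prediction
#'
#' A patient counts as predicted-to-die when the *last* given mortality
#' probability is strictly above the threshold. A survivor above the
#' threshold is a false positive, a non-survivor at or below it a false
#' negative. Patients without any prediction are unclassifiable and reported
#' as such.
#'
#' @param tracks Prediction tibble from [predict_rolling()].
#' @param labels Tibble with `patient_id` and logical `label` (died within
#'   30 days), e.g. the `patients` element of an `icudyn_censored`.
#' @param threshold Decision threshold, default 0.5.
#' @return Tibble `patient_id`, `label`, `n_predictions`, `last_t_hours`,
#'   `last_risk`, `classification` (`TP`/`FP`/`TN`/`FN`/`unclassifiable`).
#' @export
classify_at_threshold <- function(tracks, labels, threshold = 0.5) {
  check_columns(labels, c("patient_id", "label"), "labels")
  last <- tracks |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_predictions = dplyr::n(),
                     last_t_hours = max(.data$t_hours),
                     last_risk = .data$risk[which.max(.data$t_hours)],
                     .groups = "drop")
  dplyr::select(labels, "patient_id", "label") |>
    dplyr::left_join(last, by = "patient_id") |>
    dplyr::mutate(
      n_predictions = dplyr::coalesce(.data$n_predictions, 0L),
      classification = dplyr::case_when(
        n_predictions == 0L ~ "unclassifiable",
        last_risk > threshold & label ~ "TP",
        last_risk > threshold & !label ~ "FP",
        last_risk <= threshold & !label ~ "TN",
        TRUE ~ "FN"
      )
    )
}

#' Serialize a fitted dynamic model to JSON
#'
#' The artifact carries the variant, selected features, coefficients,
#' intercept, normalization bounds, L2 strength and seed with full numeric
#' precision, so save -> load -> predict reproduces risks bit-identically.
#'
#' @param model An `icudyn_model`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "icudyn_model"))
  payload <- list(
    variant = model$variant,
    features = model$features,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    normalizer = list(feature = model$normalizer$feature,
                      min = model$normalizer$min,
                      max = model$normalizer$max),
    lambda = model$lambda,
    seed = model$seed,
    rfe = model$rfe,
    n_train_rows = model$n_train_rows,
    n_train_patients = model$n_train_patients
  )
  write_json_file(payload, path)
}

#' Load a dynamic model artifact written by [write_model()]
#'
#' @param path JSON path.
#' @return An `icudyn_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: '%s'", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- tibble::tibble(feature = p$normalizer$feature,
                         min = as.numeric(p$normalizer$min),
                         max = as.numeric(p$normalizer$max))
  class(norm) <- c("icudyn_normalizer", class(norm))
  structure(
    list(variant = p$variant,
         features = as.character(p$features),
         coefficients = unlist(p$coefficients),
         intercept = as.numeric(p$intercept),
         normalizer = norm,
         lambda = as.numeric(p$lambda),
         seed = as.integer(p$seed),
         rfe = isTRUE(p$rfe),
         rfe_scores = NULL,
         n_train_rows = p$n_train_rows,
         n_train_patients = p$n_train_patients,
         converged = TRUE,
         iterations = NA_integer_),
    class = "icudyn_model"
  )
}
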