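#' Harrell's concordance index
#'
#' The fraction of comparable patient pairs ranked correctly by the risk
#' score: a pair is comparable when the earlier observed time is an event
#' (or, at tied times, exactly one of the two is an event); it is concordant
#' when the patient with the shorter survival has the higher score. Tied
#' scores receive half credit; pairs tied in time with both events are not
#' comparable. 0.5 is random, 1 perfect.
#'
#' @param theta Risk scores (higher = higher hazard).
#' @param times Survival / follow-up times.
#' @param events Event indicators (0/1).
#' @return Scalar C in `[0, 1]`; errors when no pair is comparable.
#' @export
concordance_index <- function(theta, times, events) {
  n <- length(theta)
  stopifnot(length(times) == n, length(events) == n,
            all(events %in% c(0, 1)))
  E_i <- matrix(events, n, n)
  Th_i <- matrix(theta, n, n)
  earlier_event <- outer(times, times, "<") & E_i == 1
  tied_one_event <- outer(times, times, "==") & E_i == 1 & t(E_i) == 0
  comp <- earlier_event | tied_one_event
  n_comp <- sum(comp)
  if (n_comp == 0L) stop("no comparable pairs")
  conc <- sum(comp & (Th_i > t(Th_i)))
  ties <- sum(comp & (Th_i == t(Th_i)))
  (conc + 0.5 * ties) / n_comp
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times,events Survival data for one group.
#' @return A `km_estimate` data frame: `time` (distinct event/censor times),
#'   `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing, starting from
#'   1 at time 0).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' @param times,events Survival data.
#' @param group Group labels with exactly the values 0 and 1 (or a
#'   two-level factor); both groups must be non-empty.
#' @return List with `chi2` (1-df statistic) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    stop("both groups must be non-empty")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- fit$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Median risk stratification
#'
#' Splits patients at the median score: strictly above the median is
#' `"high"`, at or below is `"low"` (so with an even split the two middle
#' patients fall on the low side, and identical scores put everyone low).
#'
#' @param theta Risk scores, length >= 2.
#' @return Factor with levels `low`, `high`.
#' @export
median_stratify <- function(theta) {
  stopifnot(length(theta) >= 2)
  med <- stats::median(theta)
  factor(ifelse(theta > med, "high", "low"), levels = c("low", "high"))
}

#' Clinical Cox proportional-hazards baseline
#'
#' Fits the standard Cox model on clinical covariates (Breslow ties,
#' Newton-Raphson to gradient tolerance 1e-9 or 50 iterations) and returns
#' the coefficients and per-patient linear predictors. Rank-deficient
#' covariates are rejected up front; convergence problems are surfaced as
#' warnings rather than silently returned.
#'
#' @param covariates Numeric matrix or data frame of clinical covariates.
#' @param times,events Survival data.
#' @return List with `coefficients`, `theta` (linear predictor, centered as
#'   by `coxph`), and the underlying `fit`.
#' @export
coxph_baseline <- function(covariates, times, events) {
  X <- as.matrix(covariates)
  if (ncol(X) == 0L) stop("no covariates supplied")
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank-deficient")
  df <- data.frame(X)
  df$.time <- times; df$.event <- events
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(colnames(df)[seq_len(ncol(X))],
                                             collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(warn))
    warning("coxph_baseline: possible separation or non-convergence: ", warn)
  list(coefficients = stats::coef(fit),
       theta = unname(fit$linear.predictors), fit = fit)
}

#' Fixed-horizon AUC of a risk score
#'
#' Binary discrimination of the score between patients with an event by the
#' horizon (cases) and patients event-free past the horizon (controls).
#' Patients censored at or before the horizon are excluded; their count is
#' attached as attribute `"n_excluded"`. Invariant to strictly monotone
#' transforms of the score.
#'
#' @param theta Risk scores.
#' @param times,events Survival data.
#' @param horizon_days Evaluation horizon (> 0), e.g. 1825 for five years.
#' @return Scalar AUC (Mann-Whitney statistic, ties counted half).
#' @export
horizon_auc <- function(theta, times, events, horizon_days) {
  stopifnot(horizon_days > 0)
  case <- events == 1 & times <= horizon_days
  control <- times > horizon_days
  excl <- sum(!case & !control)
  if (!any(case) || !any(control))
    stop("need at least one case and one control at the horizon")
  tc <- theta[case]; tk <- theta[control]
  gt <- outer(tc, tk, ">")
  eq <- outer(tc, tk, "==")
  auc <- (sum(gt) + 0.5 * sum(eq)) / (length(tc) * length(tk))
  attr(auc, "n_excluded") <- excl
  auc
}

#' Cross-validated evaluation harness
#'
#' Patient-level k-fold cross-validation: fits the supplied model on each
#' training split, scores the held-out fold, and reports the per-fold
#' concordance, its mean and sd, and the pooled concordance over the
#' concatenated out-of-fold predictions. A fold draw leaving any fold
#' without events is re-drawn with an offset seed (logged via `message`).
#'
#' @param cohort A cohort object with a `survival` table.
#' @param model_spec List with `fit = function(cohort, ids, seed)` returning
#'   a fitted object and `predict = function(fit, cohort, ids)` returning
#'   named theta scores.
#' @param folds Number of folds (default 10); must not exceed the cohort
#'   size.
#' @param seed Fold-assignment and fit seed.
#' Because Cox scores are identified only up to an additive constant per
#' fitted model, out-of-fold predictions are centered within each fold
#' before pooling; without this, arbitrary per-model intercept drift leaks
#' into cross-fold pair comparisons and biases the pooled concordance even
#' on null data. Per-fold C values are unaffected (C is shift-invariant).
#'
#' @return List: `assignment` (patient_id, fold), `per_fold` C values,
#'   `mean_c`, `sd_c`, `pooled` (patient_id, fold, theta centered per
#'   fold), `pooled_c`.
#' @export
cv_harness <- function(cohort, model_spec, folds = 10L, seed = 1L) {
  ids <- cohort$survival$patient_id
  n <- length(ids)
  stopifnot(n >= folds, folds >= 2)
  force(model_spec)
  fold <- assign_folds(ids, cohort$survival$event, folds, seed)

  pooled <- vector("list", folds)
  per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    train_ids <- ids[fold != f]
    test_ids <- ids[fold == f]
    fit <- model_spec$fit(cohort, train_ids, derive_seed(seed, paste0("fold", f)))
    theta <- model_spec$predict(fit, cohort, test_ids)
    sb <- surv_of(cohort, test_ids)
    per_fold[f] <- tryCatch(
      concordance_index(theta, sb$time, sb$event),
      error = function(e) NA_real_)
    pooled[[f]] <- data.frame(patient_id = test_ids, fold = f,
                              theta = unname(theta) - mean(theta))
  }
  pooled <- do.call(rbind, pooled)
  sp <- surv_of(cohort, pooled$patient_id)
  list(assignment = data.frame(patient_id = ids, fold = fold),
       per_fold = per_fold,
       mean_c = mean(per_fold, na.rm = TRUE),
       sd_c = stats::sd(per_fold, na.rm = TRUE),
       pooled = pooled,
       pooled_c = concordance_index(pooled$theta, sp$time, sp$event))
}

# Seeded patient-level fold assignment; re-drawn with an offset seed (and a
# message) whenever a draw leaves any fold, or any training complement,
# without events.
assign_folds <- function(ids, events, folds, seed) {
  n <- length(ids)
  ev <- stats::setNames(events, ids)
  offset <- 0L
  repeat {
    fold <- with_seed(seed + offset,
                      sample(rep(seq_len(folds), length.out = n)))
    ok <- all(vapply(seq_len(folds), function(f)
      sum(ev[ids[fold == f]]) >= 1 && sum(ev[ids[fold != f]]) >= 1,
      logical(1)))
    if (ok) return(fold)
    offset <- offset + 1L
    message("fold draw left a fold without events; redrawing (offset ",
            offset, ")")
  }
}
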