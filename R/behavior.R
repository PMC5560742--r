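# Linking replay duration to memory behavior.

#' Mixed-effects model of replay length on behavior
#'
#' Fits, per outcome, a linear mixed-effects model (REML) with the probe's
#' replay length as the fixed effect and a per-subject random intercept.
#' Binary accuracies are modeled on the 0/1 scale (linear treatment); a
#' logistic variant is available via `family = "binomial"`. A singular fit
#' falls back to pooled ordinary regression with a warning.
#'
#' @param data Data frame with one row per probed trial: `subject`,
#'   `replay_ms`, and the outcome column.
#' @param outcome Name of the outcome column (numeric or logical).
#' @param family `"gaussian"` (linear, default) or `"binomial"` (logistic).
#' @return A `mixed_model_fit`: coefficient (per ms), SE, t, df, p, the
#'   random-intercept SD, `n_observations`, and flags.
#' @export
fit_replay_behavior_lmm <- function(data, outcome, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (length(unique(data$subject)) < 2L) stopf("need at least 2 subjects")
  d <- data.frame(y = as.numeric(data[[outcome]]), replay_ms = data$replay_ms,
                  subject = factor(data$subject))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  singular <- FALSE
  if (family == "binomial") {
    fit <- lme4::glmer(y ~ replay_ms + (1 | subject), data = d, family = stats::binomial)
    co <- summary(fit)$coefficients
    est <- co["replay_ms", ]
    out <- list(estimate = est[["Estimate"]], se = est[["Std. Error"]],
                t = est[["z value"]], df = NA_real_, p = est[["Pr(>|z|)"]])
  } else {
    fit <- suppressMessages(lmerTest::lmer(y ~ replay_ms + (1 | subject), data = d))
    singular <- lme4::isSingular(fit)
    if (singular) {
      warning("singular random-intercept fit; falling back to pooled regression")
      lmfit <- stats::lm(y ~ replay_ms, data = d)
      co <- summary(lmfit)$coefficients["replay_ms", ]
      out <- list(estimate = co[["Estimate"]], se = co[["Std. Error"]],
                  t = co[["t value"]], df = lmfit$df.residual, p = co[["Pr(>|t|)"]])
    } else {
      co <- summary(fit)$coefficients["replay_ms", ]
      out <- list(estimate = co[["Estimate"]], se = co[["Std. Error"]],
                  t = co[["t value"]], df = co[["df"]], p = co[["Pr(>|t|)"]])
    }
  }
  vc <- if (singular || family == "binomial") NA_real_ else {
    sqrt(as.numeric(lme4::VarCorr(fit)$subject[1, 1]))
  }
  structure(c(out, list(outcome = outcome, family = family,
                        random_intercept_sd = vc, singular = singular,
                        n_observations = nrow(d))),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> %s ~ replay_ms: %.3g per ms (SE %.3g, p = %.3g, n = %d)%s\n",
              x$outcome, x$estimate, x$se, x$p, x$n_observations,
              if (isTRUE(x$singular)) " [singular -> pooled]" else ""))
  invisible(x)
}

#' Group probed trials by replay duration
#'
#' Assigns every probe to `none` (the probe's category never replayed during
#' retention), `short` (longest epoch 20-1100 ms), or `long` (> 1100 ms,
#' strict), and summarizes per-subject hit rates and response times per
#' group.
#'
#' @param trials Data frame with one row per probed trial: `subject`,
#'   `probe_longest_ms`, `detail_response`, `detail_rt`, `order_response`,
#'   `order_correct` (logical), `order_rt`.
#' @return A list with `trials` (the input plus `replay_group`) and
#'   `by_subject` (per subject x group counts, hit rates in %, mean RTs).
#' @export
group_by_replay_duration <- function(trials) {
  trials$replay_group <- ifelse(trials$probe_longest_ms > 1100, "long",
                                ifelse(trials$probe_longest_ms >= 20, "short", "none"))
  trials$replay_group <- factor(trials$replay_group, levels = c("none", "short", "long"))
  agg <- expand.grid(subject = unique(trials$subject),
                     replay_group = levels(trials$replay_group),
                     stringsAsFactors = FALSE)
  stat <- function(su, g, f) {
    r <- trials$subject == su & trials$replay_group == g
    if (!any(r)) return(NA_real_)
    f(trials[r, , drop = FALSE])
  }
  agg$n_trials <- mapply(function(su, g) stat(su, g, nrow), agg$subject, agg$replay_group)
  agg$detail_hit_pct <- mapply(function(su, g)
    stat(su, g, function(d) 100 * mean(d$detail_response, na.rm = TRUE)),
    agg$subject, agg$replay_group)
  agg$detail_rt_ms <- mapply(function(su, g)
    stat(su, g, function(d) mean(d$detail_rt, na.rm = TRUE)),
    agg$subject, agg$replay_group)
  if (!is.null(trials$order_correct)) {
    agg$order_hit_pct <- mapply(function(su, g)
      stat(su, g, function(d) 100 * mean(d$order_correct, na.rm = TRUE)),
      agg$subject, agg$replay_group)
    agg$order_rt_ms <- mapply(function(su, g)
      stat(su, g, function(d) mean(d$order_rt, na.rm = TRUE)),
      agg$subject, agg$replay_group)
  }
  list(trials = trials, by_subject = agg)
}

#' Repeated-measures ANOVA and post hoc tests on replay-grouped behavior
#'
#' One-way within-subject ANOVA of the per-subject hit rate across the
#' none/short/long replay groups, followed by paired t tests of long vs
#' short and long vs none. Subjects missing any group are excluded and
#' listed.
#'
#' @param grouped Output of [group_by_replay_duration()].
#' @param measure Column of the per-subject table to analyze
#'   (default `"detail_hit_pct"`).
#' @return A list with the ANOVA F/df/p, both post hoc paired t results,
#'   the per-subject wide table, and excluded subjects.
#' @export
behavior_anova_posthoc <- function(grouped, measure = "detail_hit_pct") {
  ag <- grouped$by_subject
  wide <- stats::reshape(ag[, c("subject", "replay_group", measure)],
                         idvar = "subject", timevar = "replay_group",
                         direction = "wide")
  names(wide) <- c("subject", "none", "short", "long")
  complete <- stats::complete.cases(wide)
  excluded <- wide$subject[!complete]
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2L) stopf("fewer than 2 subjects with all three replay groups")
  long_df <- data.frame(
    subject = factor(rep(wide$subject, 3)),
    group = factor(rep(c("none", "short", "long"), each = nrow(wide)),
                   levels = c("none", "short", "long")),
    y = c(wide$none, wide$short, wide$long))
  fit <- stats::aov(y ~ group + Error(subject / group), data = long_df)
  tt <- summary(fit)[["Error: subject:group"]][[1]]
  anova_res <- list(F = tt["group", "F value"], df1 = tt["group", "Df"],
                    df2 = tt["Residuals", "Df"], p = tt["group", "Pr(>F)"])
  ph <- function(a, b) {
    if (isTRUE(all.equal(a, b))) return(list(t = 0, p = 1, df = length(a) - 1))
    ht <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
  }
  list(measure = measure, anova = anova_res,
       long_vs_short = ph(wide$long, wide$short),
       long_vs_none = ph(wide$long, wide$none),
       by_subject = wide, excluded_subjects = excluded)
}
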