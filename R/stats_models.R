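#' Ordinary least-squares fit with tidy output
#'
#' Fits an OLS regression (with intercept) of `outcome` on the given
#' predictors and interactions, with listwise deletion of incomplete rows.
#' `group` is coded with ASD as the reference level, so the group term
#' estimates the NT effect. Perfect collinearity is an error naming the
#' aliased terms rather than a silent drop.
#'
#' @param data Data frame of analysis rows.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @param interactions Character vector of interaction terms in formula
#'   notation, e.g. `"group:age"`.
#' @return An object of class `regression_result`: a list with `terms` (a
#'   tibble of estimate/SE/t/p per term), `r_squared`, `adj_r_squared`,
#'   `n`, `df_residual`, `formula`, `n_dropped` (incomplete rows removed)
#'   and the underlying `lm` fit.
#' @export
fit_ols <- function(data, outcome, predictors, interactions = character(0)) {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  cols <- unique(c(outcome, predictors,
                   unlist(strsplit(interactions, ":", fixed = TRUE))))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(data)[cols]
  if ("group" %in% names(df)) {
    df$group <- factor(df$group, levels = c("ASD", "NT"))
  }
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  rhs <- paste(c(predictors, interactions), collapse = " + ")
  if (rhs == "") rhs <- "1"
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  n_terms_expected <- length(attr(stats::terms(fml), "term.labels")) + 1L
  if (nrow(df) < n_terms_expected + 2L) {
    stop("too few complete rows (", nrow(df), ") for ", n_terms_expected, " terms")
  }
  fit <- stats::lm(fml, data = df)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    stop("singular design: aliased term(s) ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(
    list(
      terms = tibble::tibble(
        term = rownames(ct),
        estimate = unname(ct[, "Estimate"]),
        se = unname(ct[, "Std. Error"]),
        t = unname(ct[, "t value"]),
        p = unname(ct[, "Pr(>|t|)"])
      ),
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      n = nrow(df),
      df_residual = fit$df.residual,
      formula = fml,
      n_dropped = n_dropped,
      fit = fit
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("OLS:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, residual df = %d, R^2 = %.3f, adjusted R^2 = %.3f\n",
              x$n, x$df_residual, x$r_squared, x$adj_r_squared))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' One-way two-group ANOVA
#'
#' One-way analysis of variance for a two-level grouping, computed from the
#' between/within sum-of-squares definitions so that degenerate inputs
#' (identical values in both groups) give F = 0 exactly. Equivalent to the
#' squared pooled-variance t statistic.
#'
#' @param values Numeric outcome per subject.
#' @param groups Grouping vector with exactly two levels, each n >= 2.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  counts <- tapply(values, groups, length)
  ss_between <- sum(counts * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- 1L
  df2 <- n - 2L
  f <- if (ss_between == 0) 0 else (ss_between / df1) / (ss_within / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Cohen's d from a two-group one-way F statistic
#'
#' Converts a one-way, two-group F statistic into the two-sample
#' standardised mean difference: `d = sign * sqrt(F * (1/n1 + 1/n2))`
#' (F = t^2 and d = t * sqrt(1/n1 + 1/n2) for the pooled t test). The sign
#' carries the direction of the difference, which the F statistic itself
#' discards.
#'
#' @param f F statistic (>= 0).
#' @param n1,n2 Group sizes (>= 2).
#' @param direction_sign +1 or -1, the sign of the group difference.
#' @return Cohen's d.
#' @export
cohens_d_from_f <- function(f, n1, n2, direction_sign = 1) {
  stopifnot(f >= 0, n1 >= 2, n2 >= 2, direction_sign %in% c(-1, 1))
  direction_sign * sqrt(f * (1 / n1 + 1 / n2))
}

# the study's frozen final model specs plus the always-reported full model
family_specs <- function(family) {
  base_full <- c("group", "age", "gender", "celf_core", "nonverbal_iq", "partner_id")
  switch(family,
    conversation_level = list(
      outcome = "delta_ent",
      final = list(predictors = c("group", "age", "celf_core"),
                   interactions = "group:age"),
      full = list(predictors = base_full, interactions = "group:age")
    ),
    contribution_level = list(
      outcome = "contribution",
      final = list(predictors = c("group", "celf_core"),
                   interactions = character(0)),
      full = list(predictors = base_full, interactions = "group:age")
    ),
    adjusted_level = list(
      outcome = "adjusted",
      final = list(predictors = c("group", "age", "celf_core"),
                   interactions = "group:age"),
      full = list(predictors = base_full, interactions = "group:age")
    ),
    f0_range_family = list(
      outcome = "delta_ent",
      final = list(predictors = c("group", "age", "gender", "celf_core",
                                  "nonverbal_iq"),
                   interactions = character(0)),
      full = list(predictors = base_full, interactions = "group:age")
    ),
    stop("unknown model family: ", family)
  )
}

#' Fit a study model family
#'
#' Fits the frozen final regression model for one of the study's outcome
#' families, plus the full model that additionally carries gender,
#' non-verbal IQ and conversation partner. Families:
#' `conversation_level` (dyad-level `delta_ent`), `contribution_level`
#' (per-participant signed `contribution`), `adjusted_level`
#' (per-participant `adjusted` contribution in Hz), and `f0_range_family`
#' (dyad-level `delta_ent` for the IQR feature, full predictor set). With
#' few conversations per partner the partner factor can be aliased; it is
#' then dropped from the full model with a warning.
#'
#' @param data Analysis table: entrainment results joined to metadata, with
#'   the family's outcome column present.
#' @param family Family name (see above).
#' @return List with `final` and `full` [fit_ols()] results.
#' @export
run_model_family <- function(data, family = c("conversation_level",
                                              "contribution_level",
                                              "adjusted_level",
                                              "f0_range_family")) {
  family <- match.arg(family)
  spec <- family_specs(family)
  final <- fit_ols(data, spec$outcome, spec$final$predictors,
                   spec$final$interactions)
  full <- tryCatch(
    fit_ols(data, spec$outcome, spec$full$predictors, spec$full$interactions),
    error = function(e) {
      if (grepl("singular design", conditionMessage(e)) &&
          grepl("partner_id", conditionMessage(e))) {
        warning("partner_id aliased in full ", family,
                " model; refitting without it")
        fit_ols(data, spec$outcome, setdiff(spec$full$predictors, "partner_id"),
                spec$full$interactions)
      } else {
        stop(e)
      }
    }
  )
  list(final = final, full = full)
}

#' Tidy export of one or more regression results
#'
#' @param results A `regression_result` or named list of them.
#' @return Tibble with columns `model`, `term`, `estimate`, `se`, `t`, `p`.
#' @export
tidy_models <- function(results) {
  if (inherits(results, "regression_result")) results <- list(model = results)
  rows <- lapply(names(results), function(nm) {
    out <- results[[nm]]$terms
    out$model <- nm
    out[c("model", "term", "estimate", "se", "t", "p")]
  })
  do.call(rbind, rows)
}
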