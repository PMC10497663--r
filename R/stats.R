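#' Model specification for the coordination model battery
#'
#' Describes one (mixed) linear model over an aggregate table: a response, a
#' fixed-effect descriptor in which \code{"A/B"} means B nested under A
#' (expanded as \code{A + A:B}, the usual nesting convention), an optional
#' random intercept grouping, and factor baselines.
#'
#' @param response response column name (\code{"mean_power"},
#'   \code{"phase_ms"}, \code{"qom"}, ...).
#' @param fixed character vector of fixed-effect terms; each may use the
#'   nesting shorthand \code{"A/B"}.
#' @param random_intercept optional grouping column for a random intercept
#'   (e.g. \code{"duo_id"}).
#' @param baselines named list mapping factor columns to their reference
#'   level (e.g. \code{list(level = "four_bars", take = "0")}).
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(response, fixed, random_intercept = NULL,
                       baselines = list()) {
  if (!is.character(response) || length(response) != 1L)
    stop_ds("response must be a single column name")
  if (!is.character(fixed) || length(fixed) < 1L)
    stop_ds("fixed must name at least one term")
  structure(list(response = response, fixed = fixed,
                 random_intercept = random_intercept, baselines = baselines),
            class = "model_spec")
}

# expand "A/B" nesting shorthand into A + A:B
expand_fixed <- function(fixed) {
  unlist(lapply(fixed, function(tm) {
    if (grepl("/", tm, fixed = TRUE)) {
      parts <- strsplit(tm, "/", fixed = TRUE)[[1L]]
      out <- parts[1L]
      for (i in 2:length(parts))
        out <- c(out, paste(parts[seq_len(i)], collapse = ":"))
      out
    } else tm
  }))
}

spec_columns <- function(spec) {
  unique(unlist(strsplit(expand_fixed(spec$fixed), ":", fixed = TRUE)))
}

#' Fit one model of the battery, with the singular-random-effect fallback
#'
#' Fits the specified model by REML (\code{lmerTest::lmer}) when a random
#' intercept is requested. Mirroring the analysis procedure for negligible
#' between-duo variance, the model is automatically refit by ordinary least
#' squares (and flagged) when the random-intercept variance is below 1e-3 of
#' the residual variance or the fit is singular. Reports coefficients with
#' Wald 95% CIs, t statistics and p values, plus marginal and conditional
#' R-squared (Nakagawa variance decomposition).
#'
#' @param spec a \code{\link{model_spec}}.
#' @param table data frame of aggregate rows.
#' @return Object of class \code{duo_model_fit}: list with \code{engine}
#'   (\code{"lmer"} or \code{"lm"}), \code{fallback} flag,
#'   \code{coefficients} table, \code{r2_marginal}, \code{r2_conditional},
#'   and the underlying \code{model}.
#' @export
fit_model <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  table <- as.data.frame(table)
  need <- c(spec$response, spec_columns(spec), spec$random_intercept)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L)
    stop_ds("table lacks columns: ", paste(missing_cols, collapse = ", "))
  # factor coercion + baselines
  for (cl in spec_columns(spec)) {
    if (!is.numeric(table[[cl]]) || cl %in% names(spec$baselines))
      table[[cl]] <- factor(table[[cl]])
    if (cl %in% names(spec$baselines))
      table[[cl]] <- relevel(table[[cl]],
                             ref = as.character(spec$baselines[[cl]]))
  }
  fixed_terms <- expand_fixed(spec$fixed)
  rhs <- paste(fixed_terms, collapse = " + ")
  fallback <- FALSE
  engine <- "lm"
  model <- NULL
  if (!is.null(spec$random_intercept)) {
    gvar <- table[[spec$random_intercept]]
    if (length(unique(gvar)) < 2L)
      stop_ds("random intercept grouping needs at least 2 groups")
    fml <- as.formula(paste(spec$response, "~", rhs,
                            "+ (1 |", spec$random_intercept, ")"))
    model <- suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = table, REML = TRUE)))
    vc <- as.data.frame(lme4::VarCorr(model))
    re_var <- vc$vcov[vc$grp == spec$random_intercept][1L]
    resid_var <- vc$vcov[vc$grp == "Residual"][1L]
    singular <- lme4::isSingular(model)
    if (singular || re_var < 1e-3 * resid_var) {
      fallback <- TRUE
    } else {
      engine <- "lmer"
    }
  }
  if (engine == "lm") {
    fml <- as.formula(paste(spec$response, "~", rhs))
    model <- lm(fml, data = table)
    if (any(is.na(coef(model))))
      stop_ds("rank-deficient design; aliased terms: ",
              paste(names(coef(model))[is.na(coef(model))], collapse = ", "))
  }
  coefs <- extract_coefs(model)
  r2 <- model_r2(model)
  structure(list(engine = engine, fallback = fallback, model = model,
                 coefficients = coefs,
                 r2_marginal = r2$marginal, r2_conditional = r2$conditional,
                 spec = spec, formula = fml, n = nrow(table)),
            class = "duo_model_fit")
}

extract_coefs <- function(model) {
  if (inherits(model, "lmerModLmerTest") || inherits(model, "merMod")) {
    sm <- as.data.frame(coef(summary(model)))
    ci <- suppressMessages(confint(model, parm = "beta_", method = "Wald"))
    data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
               ci_lo = ci[, 1L], ci_hi = ci[, 2L],
               statistic = sm[, "t value"],
               df = if ("df" %in% colnames(sm)) sm[, "df"] else NA_real_,
               p_value = if ("Pr(>|t|)" %in% colnames(sm))
                 sm[, "Pr(>|t|)"] else NA_real_,
               row.names = NULL)
  } else {
    sm <- coef(suppressWarnings(summary(model)))
    ci <- suppressWarnings(confint(model))
    data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
               ci_lo = ci[, 1L], ci_hi = ci[, 2L],
               statistic = sm[, "t value"], df = model$df.residual,
               p_value = sm[, "Pr(>|t|)"], row.names = NULL)
  }
}

# marginal / conditional R2 via the Nakagawa variance decomposition for a
# Gaussian mixed model; collapses to ordinary R2 for lm (0 when the response
# has zero variance)
model_r2 <- function(model) {
  if (inherits(model, "merMod")) {
    var_f <- var(as.vector(model.matrix(model) %*% lme4::fixef(model)))
    vc <- as.data.frame(lme4::VarCorr(model))
    var_r <- sum(vc$vcov[vc$grp != "Residual"])
    var_e <- vc$vcov[vc$grp == "Residual"][1L]
    tot <- var_f + var_r + var_e
    list(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
  } else {
    tss <- sum((model$model[[1L]] - mean(model$model[[1L]]))^2)
    r2 <- if (tss == 0) 0 else suppressWarnings(summary(model))$r.squared
    list(marginal = r2, conditional = r2)
  }
}

#' @export
print.duo_model_fit <- function(x, ...) {
  cat("<duo_model_fit> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  engine %s%s | n = %d | R2 marginal %.3f conditional %.3f\n",
              x$engine, if (x$fallback) " (OLS fallback: negligible/singular random effect)" else "",
              x$n, x$r2_marginal, x$r2_conditional))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts for one factor of a fitted model
#'
#' @param fit a \code{\link{fit_model}} result.
#' @param factor name of a factor in the model with at least two levels.
#' @return Data frame with \code{contrast}, \code{estimate}, \code{se},
#'   \code{df}, \code{t_ratio}, \code{p_value} (Tukey-adjusted).
#' @export
tukey_contrasts <- function(fit, factor) {
  stopifnot(inherits(fit, "duo_model_fit"))
  data_fac <- if (inherits(fit$model, "merMod"))
    fit$model@frame[[factor]] else fit$model$model[[factor]]
  if (is.null(data_fac)) stop_ds("factor ", factor, " not in the model frame")
  if (length(unique(data_fac)) < 2L)
    stop_ds("factor ", factor, " has fewer than 2 levels")
  emm <- suppressMessages(emmeans::emmeans(fit$model, specs = factor))
  pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  data.frame(contrast = as.character(pr$contrast), estimate = pr$estimate,
             se = pr$SE, df = pr$df, t_ratio = pr$t.ratio,
             p_value = pr$p.value)
}

#' Bonferroni-corrected p-value threshold
#'
#' @param alpha familywise error rate (0 < alpha < 1).
#' @param m number of comparisons (>= 1).
#' @return \code{alpha / m}.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 24)  # 0.002083...
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_ds("alpha must be a probability in (0, 1)")
  if (!is_count(m) || m < 1) stop_ds("m must be an integer >= 1")
  alpha / m
}
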