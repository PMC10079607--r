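#' Random-intercept variance components and ICC
#'
#' Fits a linear random-intercept model to one metric's per-trial values,
#' with subject-specific intercepts as random effects, by REML. The
#' intraclass correlation coefficient is the between-subject share of the
#' total variance, \eqn{ICC = \sigma^2_u / (\sigma^2_u + \sigma^2_e)}. The
#' unconditional variant has no fixed effects beyond the intercept; the
#' conditional variant adds hand group and difficulty as categorical fixed
#' effects (reference-coded), so its ICC describes consistency after
#' adjusting for those covariates. Boundary fits (\eqn{\sigma^2_u = 0}) are
#' returned as such, not errored.
#'
#' @param table A trial table: data.frame with columns `subject`, `group`,
#'   `difficulty`, `metric`, `value` (long format, one row per trial and
#'   metric). Unbalanced designs (missing trials) are supported.
#' @param metric Which metric's rows to fit.
#' @param covariates `"none"` (unconditional) or `"group_difficulty"`
#'   (conditional).
#' @return An object of class `variance_components`: `sigma2_u`, `sigma2_e`,
#'   `icc`, `covariates`, `logLik` (REML criterion), `n_subjects`, `n_obs`.
#' @examples
#' set.seed(1)
#' tab <- data.frame(
#'   subject = rep(paste0("S", 1:6), each = 20),
#'   group = "contra", difficulty = "deep_ball", metric = "movement_time",
#'   value = rep(rnorm(6, 3, 1), each = 20) + rnorm(120, 0, 1)
#' )
#' fit_random_intercept(tab, "movement_time")
#' @export
fit_random_intercept <- function(table, metric,
                                 covariates = c("none", "group_difficulty")) {
  covariates <- match.arg(covariates)
  stopifnot(is.data.frame(table),
            all(c("subject", "metric", "value") %in% names(table)))
  d <- table[table$metric == metric & is.finite(table$value), , drop = FALSE]
  if (nrow(d) == 0) stop("fit_random_intercept: no rows for metric ", metric,
                         call. = FALSE)
  d$subject <- factor(d$subject)
  if (nlevels(d$subject) < 2) {
    stop("fit_random_intercept: need at least 2 subjects", call. = FALSE)
  }
  if (max(table(d$subject)) < 2) {
    stop("fit_random_intercept: need at least 2 trials for some subject",
         call. = FALSE)
  }
  if (stats::var(d$value) == 0) {
    stop("fit_random_intercept: constant response", call. = FALSE)
  }
  form <- value ~ 1 + (1 | subject)
  if (covariates == "group_difficulty") {
    terms <- character(0)
    for (cv in c("group", "difficulty")) {
      if (cv %in% names(d) && length(unique(d[[cv]])) >= 2) {
        d[[cv]] <- factor(d[[cv]])
        terms <- c(terms, cv)
      }
    }
    if (length(terms)) {
      form <- stats::as.formula(paste(
        "value ~", paste(terms, collapse = " + "), "+ (1 | subject)"))
    }
  }
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_u <- vc$vcov[vc$grp == "subject"]
  sigma2_e <- vc$vcov[vc$grp == "Residual"]
  structure(
    list(
      sigma2_u = sigma2_u, sigma2_e = sigma2_e,
      icc = sigma2_u / (sigma2_u + sigma2_e),
      covariates = covariates,
      logLik = as.numeric(stats::logLik(fit)),
      n_subjects = nlevels(d$subject), n_obs = nrow(d),
      metric = metric
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components: %s (%s)>\n  sigma2_u = %.4g, sigma2_e = %.4g, ICC = %.3f  (%d subjects, %d trials)\n",
    x$metric, x$covariates, x$sigma2_u, x$sigma2_e, x$icc,
    x$n_subjects, x$n_obs))
  invisible(x)
}

#' Closed-form one-way ANOVA ICC(1,1) on balanced data
#'
#' Independent cross-check of the REML fit: for a balanced one-way layout
#' with k trials per subject, \eqn{ICC = (MS_B - MS_W)/(MS_B + (k-1)MS_W)},
#' truncated at 0 when the moment estimate of the between-subject variance
#' is negative.
#'
#' @param values Numeric responses.
#' @param subject Subject labels (equal counts required).
#' @return The ANOVA ICC estimate.
#' @export
anova_icc <- function(values, subject) {
  subject <- factor(subject)
  k <- unique(table(subject))
  if (length(k) != 1) stop("anova_icc: design not balanced", call. = FALSE)
  aovt <- stats::anova(stats::lm(values ~ subject))
  msb <- aovt$`Mean Sq`[1]
  msw <- aovt$`Mean Sq`[2]
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  max(0, icc)
}

#' Per-metric ICC report
#'
#' One row per metric with both ICC variants (unconditional and
#' conditional), for a hand-group subset of the trial table.
#'
#' @param table Trial table (see [fit_random_intercept()]).
#' @param groups Optional character vector of hand groups to keep (e.g.
#'   `c("contra", "ipsi")` to pool both stroke sides); `NULL` keeps all.
#' @return data.frame with columns `metric`, `icc_unconditional`,
#'   `icc_conditional`, `sigma2_u`, `sigma2_e` (from the unconditional
#'   fit), `n_subjects`, `n_obs`.
#' @export
icc_report <- function(table, groups = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(groups)) {
    table <- table[table$group %in% groups, , drop = FALSE]
  }
  if (nrow(table) == 0) stop("icc_report: empty subset", call. = FALSE)
  metrics <- unique(table$metric)
  rows <- lapply(metrics, function(m) {
    un <- fit_random_intercept(table, m, "none")
    co <- fit_random_intercept(table, m, "group_difficulty")
    data.frame(
      metric = m,
      icc_unconditional = un$icc,
      icc_conditional = co$icc,
      sigma2_u = un$sigma2_u,
      sigma2_e = un$sigma2_e,
      n_subjects = un$n_subjects,
      n_obs = un$n_obs
    )
  })
  do.call(rbind, rows)
}
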