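#' Logistic regression fit for binding-site designs
#'
#' Fits a binomial GLM of a binary outcome (e.g. membership in the
#' ancestral target set) on binary site-presence predictors, with Wald
#' standard errors and per-term odds ratios exp(beta) with 95% CIs
#' (exp(beta +/- 1.96 SE)). Perfect separation (diverging coefficients) and
#' collinear terms raise errors unless `allow_aliased` permits the latter.
#'
#' @param data Data frame with the outcome and predictor columns (binary).
#' @param formula Model formula, e.g. `target ~ site1 + site2`.
#' @param allow_aliased Tolerate aliased (collinear) terms, leaving their
#'   coefficients `NA` (used by [stepwise_select()]).
#' @param allow_separation Tolerate (quasi-)separated fits instead of
#'   erroring; the boundary fit is flagged via `$separated`. Deviances and
#'   likelihood-ratio statistics remain well defined for such fits, which
#'   is what [stepwise_select()] needs.
#' @return A `site_logistic` object wrapping the glm fit.
#' @export
logistic_fit <- function(data, formula, allow_aliased = FALSE,
                         allow_separation = FALSE) {
  fit <- suppressWarnings(stats::glm(formula, family = stats::binomial(), data = data))
  coefs <- stats::coef(fit)
  if (any(is.na(coefs)) && !allow_aliased) {
    stop("collinear terms in the design (aliased coefficients)", call. = FALSE)
  }
  separated <- any(abs(coefs) > 15, na.rm = TRUE)
  if (separated && !allow_separation) {
    stop("separation: coefficient estimates diverge", call. = FALSE)
  }
  structure(list(fit = fit, formula = formula, separated = separated),
            class = "site_logistic")
}

#' @export
print.site_logistic <- function(x, ...) {
  cat("<logistic site model> ", deparse(x$formula), "  deviance ",
      round(stats::deviance(x$fit), 2), "\n", sep = "")
  invisible(x)
}

#' Stepwise (forward) selection among nested binding-site models
#'
#' Fits the nested sequence: model 0 (constant), model 1 (+ first site),
#' model 2 (+ second site), model 3 (+ interaction). Each addition is
#' assessed by the likelihood-ratio chi-square (the deviance drop) with
#' degrees of freedom equal to the number of added estimable terms; the
#' accepted model is the largest one reached before the first addition with
#' p >= `alpha`. An aliased addition contributes zero deviance drop and is
#' rejected.
#'
#' @param data Data frame with binary columns named by `outcome`, `x1`, `x2`.
#' @param outcome,x1,x2 Column names (defaults `"target"`, `"site1"`,
#'   `"site2"`).
#' @param alpha Forward-selection significance level (default 0.05).
#' @return A `stepwise_sites` object: list with `accepted` (0-3), `steps`
#'   tibble (`model`, `delta_x2`, `df`, `p_value`), and `fits`.
#' @export
stepwise_select <- function(data, outcome = "target", x1 = "site1",
                            x2 = "site2", alpha = 0.05) {
  stopifnot(all(c(outcome, x1, x2) %in% names(data)))
  f <- function(rhs) stats::as.formula(paste(outcome, "~", rhs))
  forms <- list(f("1"),
                f(x1),
                f(paste(x1, "+", x2)),
                f(paste(x1, "+", x2, "+", x1, ":", x2)))
  fits <- lapply(forms, function(fm) logistic_fit(data, fm, allow_aliased = TRUE,
                                                  allow_separation = TRUE))
  dev <- vapply(fits, function(x) stats::deviance(x$fit), numeric(1))
  dfres <- vapply(fits, function(x) x$fit$df.residual, numeric(1))
  steps <- tibble::tibble(model = 1:3,
                          delta_x2 = pmax(0, dev[1:3] - dev[2:4]),
                          df = dfres[1:3] - dfres[2:4])
  steps$p_value <- ifelse(steps$df > 0,
                          stats::pchisq(steps$delta_x2, steps$df, lower.tail = FALSE),
                          1)
  accepted <- 0L
  for (i in 1:3) {
    if (steps$p_value[i] < alpha) accepted <- i else break
  }
  structure(list(accepted = accepted, steps = steps, fits = fits,
                 alpha = alpha), class = "stepwise_sites")
}

#' @export
print.stepwise_sites <- function(x, ...) {
  cat("<stepwise site-dependence selection> accepted model ", x$accepted, "\n", sep = "")
  print(x$steps)
  invisible(x)
}

#' Fisher's exact test for dependence between two binding sites
#'
#' Over a gene set (e.g. the ancestral targets), tests whether genes with a
#' site for one protein are more or less likely than chance to carry a site
#' for the other, labelling the direction of the dependence.
#'
#' @param both,only_1,only_2,neither Gene counts by joint site presence.
#' @param alpha Significance level for the label.
#' @return One-row tibble: the Fisher columns plus `dependence` in
#'   `"overlap more"`, `"overlap less"`, `"none"`.
#' @export
fisher_dependence <- function(both, only_1, only_2, neither, alpha = 0.05) {
  res <- fisher_exact(both, only_1, only_2, neither)
  res$dependence <- dplyr::case_when(
    res$p_value >= alpha ~ "none",
    res$odds_ratio > 1 ~ "overlap more",
    TRUE ~ "overlap less")
  res
}
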