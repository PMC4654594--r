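#' @importFrom generics tidy glance
NULL

#' Tidy a logistic site-model fit
#'
#' One row per term: coefficient, Wald SE, odds ratio exp(beta) with 95% CI.
#'
#' @param x A `site_logistic` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.site_logistic <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  tibble::tibble(term = rownames(sm), estimate = unname(est),
                 std_error = unname(se),
                 odds_ratio = exp(unname(est)),
                 or_conf_low = exp(unname(est - 1.96 * se)),
                 or_conf_high = exp(unname(est + 1.96 * se)))
}

#' Model-level summary of a logistic site fit
#' @param x A `site_logistic` object.
#' @param ... Unused.
#' @return One-row tibble with deviance, df and AIC.
#' @export
glance.site_logistic <- function(x, ...) {
  tibble::tibble(deviance = stats::deviance(x$fit),
                 df_residual = x$fit$df.residual,
                 null_deviance = x$fit$null.deviance,
                 aic = stats::AIC(x$fit))
}

#' Tidy a stepwise site-dependence selection
#'
#' Table-shaped output: one row per (model, term) with the model-level
#' likelihood-ratio statistic repeated on each model's rows.
#'
#' @param x A `stepwise_sites` object.
#' @param ... Unused.
#' @return A tibble `model`, `delta_x2`, `p_value`, `term`, `estimate`,
#'   `std_error`, `odds_ratio`, `or_conf_low`, `or_conf_high`, `accepted`.
#' @export
tidy.stepwise_sites <- function(x, ...) {
  purrr::map_dfr(0:3, function(mid) {
    tt <- tidy(x$fits[[mid + 1]])
    step <- if (mid == 0) tibble::tibble(delta_x2 = NA_real_, p_value = NA_real_)
            else x$steps[mid, c("delta_x2", "p_value")]
    dplyr::bind_cols(tibble::tibble(model = mid), step[rep(1, nrow(tt)), ], tt,
                     tibble::tibble(accepted = mid == x$accepted))
  })
}

#' @export
glance.stepwise_sites <- function(x, ...) {
  tibble::tibble(accepted_model = x$accepted, alpha = x$alpha)
}

#' Tidy posterior rate samples from a gain/loss MCMC
#' @param x An `mcmc_gainloss` object.
#' @param ... Unused.
#' @return Tibble `rate`, `median`, `q025`, `q975`.
#' @export
tidy.mcmc_gainloss <- function(x, ...) {
  qs <- apply(x$samples, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  tibble::tibble(rate = colnames(x$samples),
                 median = qs[2, ], q025 = qs[1, ], q975 = qs[3, ])
}

#' @export
glance.mcmc_gainloss <- function(x, ...) {
  tibble::tibble(model = x$model, log_harmonic_mean = x$log_harmonic_mean,
                 acceptance_rate = x$acceptance_rate,
                 n_samples = nrow(x$samples), n_genes = x$n_genes,
                 iterations = x$iterations, burnin = x$burnin, thin = x$thin)
}

#' Tidy a conservation analysis
#' @param x A `conservation_analysis` object.
#' @param ... Unused.
#' @return The per-ortholog-set results tibble.
#' @export
tidy.conservation_analysis <- function(x, ...) x$results

#' @export
glance.conservation_analysis <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x$results), n_perm = x$n_perm,
                 fdr_threshold = x$fdr_threshold,
                 n_conserved = sum(x$results$conserved, na.rm = TRUE))
}

#' Plot conservation score versus permutation FDR
#' @param object A `conservation_analysis` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conservation_analysis <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cs, y = .data$fdr,
                                   colour = .data$conserved)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$fdr_threshold, linetype = 2) +
    ggplot2::labs(x = "conservation score (weighted branch length)",
                  y = "permutation FDR (capped at 1)",
                  colour = paste0("FDR ≤ ", object$fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' Presence-matrix heatmap (ortholog sets x species)
#' @param calls Long tibble from [presence_calls()].
#' @param order_by Optional named score vector used to order columns
#'   (anchors) left-to-right by decreasing value.
#' @return A ggplot.
#' @export
plot_presence <- function(calls, order_by = NULL) {
  if (!is.null(order_by)) {
    lev <- names(sort(order_by, decreasing = TRUE))
    calls$anchor <- factor(calls$anchor, levels = lev)
  }
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$anchor, y = .data$species,
                                      fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey85", `1` = "steelblue"),
                               na.value = "white", name = "site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "ortholog set", y = NULL)
}

#' ROC-style curve of an iterative k-mer search
#' @param object A `ranked_kmers` tibble from [iterative_search()].
#' @param cutoff Optional keep-count (e.g. from [roc_cutoff()]) drawn as a
#'   marker.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ranked_kmers <- function(object, cutoff = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff) && cutoff >= 1) {
    p <- p + ggplot2::geom_point(data = object[cutoff, ], colour = "red", size = 2)
  }
  p
}
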