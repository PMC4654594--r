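#' Two-tailed Fisher's exact test on a 2 x 2 table
#'
#' Two-tailed p-value by the sum-of-small-probabilities convention (all
#' margin-fixed tables whose conditional probability does not exceed the
#' observed table's). The reported odds ratio is the sample cross-product
#' ratio a*d / (b*c); the confidence interval is the conditional exact
#' interval. A degenerate margin gives p = 1 and an undefined odds ratio.
#'
#' @param a,b,c,d Cell counts: rows = group 1/2, columns = outcome yes/no.
#'   Alternatively `a` may be a 2 x 2 matrix.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return One-row tibble: `odds_ratio`, `p_value`, `conf_low`, `conf_high`,
#'   `ci_method`.
#' @examples
#' fisher_exact(2, 0, 0, 2)
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (is.matrix(a)) {
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2, 2)
  }
  stopifnot(all(tab >= 0), sum(tab) >= 1)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(tibble::tibble(odds_ratio = NaN, p_value = 1,
                          conf_low = NA_real_, conf_high = NA_real_,
                          ci_method = "degenerate"))
  }
  ft <- stats::fisher.test(tab, conf.level = conf_level)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble::tibble(odds_ratio = or_sample,
                 p_value = ft$p.value,
                 conf_low = unname(ft$conf.int[1]),
                 conf_high = unname(ft$conf.int[2]),
                 ci_method = "conditional-exact")
}

#' Motif enrichment in a target gene set
#'
#' Tests whether UTRs of target genes are enriched for motif matches
#' relative to all other UTRs (Fisher's exact test on targets/non-targets x
#' match/no-match), and reports the percentage of targets with a match plus
#' the background match frequency across all UTRs.
#'
#' @param utrs Named character vector of UTR sequences for one species.
#' @param target_ids Gene ids of the target set (ids missing from `utrs`
#'   are dropped with a warning).
#' @param m Motif or motif collection.
#' @param bonferroni_factor Multiplier for the reported corrected p.
#' @return One-row tibble with the Fisher columns plus `pct_targets_with_motif`,
#'   `background_freq`, `n_targets`, `p_bonferroni`.
#' @export
target_enrichment <- function(utrs, target_ids, m, bonferroni_factor = 1) {
  if (length(target_ids) == 0L) stop("empty target set", call. = FALSE)
  missing <- setdiff(target_ids, names(utrs))
  if (length(missing) > 0L) {
    warning(length(missing), " target id(s) have no UTR and were dropped")
    target_ids <- setdiff(target_ids, missing)
  }
  if (length(target_ids) == 0L) stop("no target has a UTR sequence", call. = FALSE)
  hit <- seq_has_match(utrs, m)
  is_target <- names(utrs) %in% target_ids
  a <- sum(is_target & hit); b <- sum(is_target & !hit)
  c_ <- sum(!is_target & hit); d <- sum(!is_target & !hit)
  res <- fisher_exact(a, b, c_, d)
  dplyr::mutate(res,
                pct_targets_with_motif = 100 * a / (a + b),
                background_freq = mean(hit),
                n_targets = a + b,
                p_bonferroni = pmin(1, .data$p_value * bonferroni_factor))
}

#' Two-sided exact binomial sign test
#'
#' Exact two-sided p-value summing the point probabilities of all outcomes
#' no more probable than the observed count (the convention of the standard
#' exact binomial test).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability (default 0.5).
#' @return A single p-value.
#' @examples
#' binomial_sign_test(11, 11) # ~0.001: all 11 species in the same direction
#' @export
binomial_sign_test <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Sequence-context preference at an offset from motif matches
#'
#' Compares the prevalence of a given base at a fixed offset relative to
#' motif matches between two groups of sequences (e.g. cytosine two
#' nucleotides upstream, offset -2, in conserved targets versus all other
#' genes). Only the 5'-most match per sequence is used; matches whose
#' offset position falls outside the sequence are dropped.
#'
#' @param seqs_target,seqs_other Named character vectors of sequences.
#' @param m Motif or motif collection.
#' @param offset Signed offset from the match start (0-based; -2 means two
#'   bases upstream of the first motif position).
#' @param base The base whose prevalence is compared (default `"C"`).
#' @return One-row tibble: counts per group, prevalences, and the Fisher
#'   columns.
#' @export
context_preference_test <- function(seqs_target, seqs_other, m, offset = -2,
                                    base = "C") {
  count_group <- function(seqs) {
    with_b <- 0L; without_b <- 0L
    for (s in seqs) {
      hits <- scan_sequence(s, as_motif_set(m))
      if (nrow(hits) == 0L) next
      pos <- hits$start[1] + offset            # 0-based
      if (pos < 0 || pos >= nchar(s)) next
      ch <- substr(s, pos + 1L, pos + 1L)
      if (ch == base) with_b <- with_b + 1L else without_b <- without_b + 1L
    }
    c(with_b, without_b)
  }
  tg <- count_group(seqs_target)
  ot <- count_group(seqs_other)
  if (sum(tg) == 0L || sum(ot) == 0L) {
    stop("no usable motif matches in one of the groups", call. = FALSE)
  }
  res <- fisher_exact(tg[1], tg[2], ot[1], ot[2])
  dplyr::bind_cols(
    tibble::tibble(target_with = tg[1], target_without = tg[2],
                   other_with = ot[1], other_without = ot[2],
                   target_prevalence = tg[1] / sum(tg),
                   other_prevalence = ot[1] / sum(ot)),
    res)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by enumeration when the pooled sample size is at most 12 with no
#' ties, otherwise the normal approximation with tie correction.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return A single two-sided p-value.
#' @export
rank_sum_test <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  pooled <- c(values_a, values_b)
  no_ties <- !anyDuplicated(pooled)
  exact <- (length(pooled) <= 12L) && no_ties
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = !exact)$p.value
  )
}

#' Bonferroni correction
#' @param p Vector of p-values.
#' @param factor Number of tests.
#' @return Corrected p-values, capped at 1.
#' @export
bonferroni <- function(p, factor) pmin(1, p * factor)
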