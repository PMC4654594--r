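#' Motif co-occurrence table for a species pair
#'
#' Classifies each ortholog set shared by two species by motif match /
#' no-match in each species' UTR, yielding the 2 x 2 table of sets with a
#' match in both, only one, or neither species. A gene mapped to several
#' orthologs counts as matching if any ortholog's UTR matches. Pairs whose
#' genes lack a UTR sequence are dropped (with a message).
#'
#' @param utrs_a,utrs_b Named character vectors of UTR sequences.
#' @param pairs Tibble with columns `gene_a`, `gene_b` (several `gene_b`
#'   rows per `gene_a` allowed).
#' @param m Motif or motif collection.
#' @return Tibble with one row: `n_both`, `n_only_a`, `n_only_b`,
#'   `n_neither`, `n_total`.
#' @export
pair_overlap <- function(utrs_a, utrs_b, pairs, m) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("empty ortholog pair map", call. = FALSE)
  m <- as_motif_set(m)
  hit_a <- seq_has_match(utrs_a, m)
  hit_b <- seq_has_match(utrs_b, m)
  usable <- pairs$gene_a %in% names(utrs_a) & pairs$gene_b %in% names(utrs_b)
  if (any(!usable)) {
    message(sum(!usable), " ortholog pair row(s) dropped for lack of a UTR sequence")
  }
  pairs <- pairs[usable, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no ortholog pair has UTRs in both species", call. = FALSE)
  if (!anyDuplicated(pairs$gene_a)) {   # 1:1 map fast path
    a <- unname(hit_a[pairs$gene_a])
    b <- unname(hit_b[pairs$gene_b])
  } else {
    per_set <- pairs |>
      dplyr::group_by(.data$gene_a) |>
      dplyr::summarise(a = any(hit_a[.data$gene_a]),
                       b = any(hit_b[.data$gene_b]), .groups = "drop")
    a <- per_set$a; b <- per_set$b
  }
  tibble::tibble(n_both = sum(a & b),
                 n_only_a = sum(a & !b),
                 n_only_b = sum(!a & b),
                 n_neither = sum(!a & !b),
                 n_total = length(a))
}

#' One-tailed hypergeometric p-value for pair overlap
#'
#' The probability of observing at least the seen number of ortholog sets
#' with a motif match in both species, given the per-species match totals:
#' P(X >= n_both) for X hypergeometric with population `n_total`, successes
#' `n_both + n_only_a`, and draws `n_both + n_only_b`.
#'
#' @param tab One-row tibble from [pair_overlap()] (or a list with the same
#'   fields).
#' @return A single p-value.
#' @export
hypergeom_p <- function(tab) {
  with(tab, {
    total <- n_both + n_only_a + n_only_b + n_neither
    K <- n_both + n_only_a
    draws <- n_both + n_only_b
    stats::phyper(n_both - 1, K, total - K, draws, lower.tail = FALSE)
  })
}

#' Pairwise conservation test with a permuted-motif empirical null
#'
#' Ranks the real motif's one-tailed hypergeometric p-value against the
#' p-values obtained from position permutations of the motif. Ties count
#' against the real motif (rank = 1 + number of permutation p-values <= the
#' real one). The pair is called significant only if the Bonferroni-corrected
#' hypergeometric p is below 0.05 AND the real motif ranks in the top 1%
#' (empirical p < 0.01). With fewer than 100 permutations the empirical p
#' cannot reach < 0.01 and the result is flagged underpowered.
#'
#' @inheritParams pair_overlap
#' @param n_perm `"all"` or an integer count of permuted motifs.
#' @param bonferroni_factor Multiplier for the hypergeometric p (number of
#'   species pairs tested in the surrounding screen).
#' @param seed Seed for the permutation sample.
#' @return One-row tibble: table counts, `p_hyper`, `p_bonferroni`, `rank`,
#'   `p_empirical`, `n_perm`, `significant`, `underpowered`.
#' @export
permutation_rank_test <- function(utrs_a, utrs_b, pairs, m, n_perm = "all",
                                  bonferroni_factor = 1, seed = NULL) {
  m <- as_motif_set(m)
  tab <- pair_overlap(utrs_a, utrs_b, pairs, m)
  p_real <- hypergeom_p(tab)
  perms <- permute_motif(m, max_count = n_perm, seed = seed)
  if (length(perms) == 0L) stop("motif has no permutations", call. = FALSE)
  p_perm <- vapply(perms, function(pm) {
    hypergeom_p(pair_overlap(utrs_a, utrs_b, pairs, pm))
  }, numeric(1))
  rank <- 1L + sum(p_perm <= p_real)
  n_used <- length(perms)
  p_emp <- rank / (n_used + 1)
  p_bonf <- min(1, p_real * bonferroni_factor)
  underpowered <- 1 / (n_used + 1) >= 0.01
  dplyr::bind_cols(tab, tibble::tibble(
    p_hyper = p_real, p_bonferroni = p_bonf, rank = rank,
    p_empirical = p_emp, n_perm = n_used,
    significant = (p_bonf < 0.05) && (p_emp < 0.01) && !underpowered,
    underpowered = underpowered))
}
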