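#' Per-species presence calls for ortholog sets
#'
#' For each ortholog set (anchor gene) and species: `present` (1) if at least
#' one ortholog's UTR contains a match to the motif collection, `absent` (0)
#' if orthologs exist but none match, and missing (`NA`) if the species has
#' no ortholog. An ortholog listed in the table but lacking a UTR sequence is
#' treated as missing for that entry (with a message).
#'
#' @param ortho Tibble with columns `anchor`, `species`, `ortholog`.
#' @param utrs Tibble with columns `species`, `gene_id`, `seq` (see
#'   [utr_table()]).
#' @param m Motif or motif collection.
#' @param species Character vector fixing the species universe (defaults to
#'   the species present in `utrs`).
#' @return Long tibble `anchor`, `species`, `present` (integer 1/0/NA).
#' @export
presence_calls <- function(ortho, utrs, m, species = NULL) {
  stopifnot(all(c("anchor", "species", "ortholog") %in% names(ortho)))
  if (nrow(ortho) == 0L) stop("empty ortholog table", call. = FALSE)
  if (is.null(species)) species <- unique(utrs$species)

  hits <- tibble::tibble(species = utrs$species, ortholog = utrs$gene_id,
                         hit = seq_has_match(utrs$seq, m))
  joined <- dplyr::left_join(ortho, hits, by = c("species", "ortholog"))
  n_missing_seq <- sum(is.na(joined$hit))
  if (n_missing_seq > 0L) {
    message(n_missing_seq, " listed ortholog(s) had no UTR sequence; treated as missing")
  }
  per_cell <- joined |>
    dplyr::filter(!is.na(.data$hit)) |>
    dplyr::group_by(.data$anchor, .data$species) |>
    dplyr::summarise(present = as.integer(any(.data$hit)), .groups = "drop")
  grid <- tidyr::expand_grid(anchor = unique(ortho$anchor), species = species)
  out <- dplyr::left_join(grid, per_cell, by = c("anchor", "species"))
  if (all(is.na(out$present))) stop("no ortholog set has any scored species", call. = FALSE)
  out
}

#' Convert long presence calls to an anchors x species matrix
#' @param calls Tibble from [presence_calls()].
#' @return Integer matrix with `NA` for missing.
#' @export
presence_matrix <- function(calls) {
  wide <- tidyr::pivot_wider(calls, names_from = "species", values_from = "present")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$anchor
  storage.mode(mat) <- "integer"
  mat
}

# subtree branch-length totals and the score recursion for one pruned
# binary tree, vectorised over genes (rows of `calls`, columns = tip labels)
cs_engine <- function(tree, calls) {
  stopifnot(is.matrix(calls))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("pruned tree must retain >= 2 leaves", call. = FALSE)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop("tree has polytomies; resolve them first (see `resolve = TRUE`)", call. = FALSE)
  }
  calls <- calls[, tree$tip.label, drop = FALSE]
  tree <- stats::reorder(tree, "postorder")
  nnode <- ntip + tree$Nnode
  ngene <- nrow(calls)

  stem <- numeric(nnode)            # branch length of node's own stem
  stem[tree$edge[, 2]] <- tree$edge.length
  subtot <- numeric(nnode)          # total branch length strictly below node
  S <- numeric(nnode)               # stem + subtot
  P <- matrix(0, ngene, nnode)      # proportion of branch spent with site
  CS <- matrix(0, ngene, nnode)
  leafsum <- matrix(0, ngene, nnode)  # for zero-length guard: mean leaf call
  leafn <- numeric(nnode)

  P[, seq_len(ntip)] <- calls
  leafsum[, seq_len(ntip)] <- calls
  leafn[seq_len(ntip)] <- 1

  parents <- unique(tree$edge[, 1])  # postorder guarantees children first
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  for (nd in parents) {
    ch <- children_of[[as.character(nd)]]
    S[ch] <- stem[ch] + subtot[ch]
    subtot[nd] <- sum(S[ch])
    leafsum[, nd] <- leafsum[, ch[1]] + leafsum[, ch[2]]
    leafn[nd] <- leafn[ch[1]] + leafn[ch[2]]
    CS[, nd] <- P[, ch[1]] * S[ch[1]] + P[, ch[2]] * S[ch[2]]
    if (subtot[nd] > 0) {
      P[, nd] <- CS[, nd] / subtot[nd]
    } else {
      # zero-length subtree: fall back to the subtree's leaf-call average
      P[, nd] <- leafsum[, nd] / leafn[nd]
    }
  }
  root <- ntip + 1L
  list(cs = CS[, root], total_bl = subtot[root])
}

#' Branch-length-weighted conservation score
#'
#' The conservation score of an ortholog set is the weighted sum of branch
#' lengths over which the motif is inferred present, computed recursively
#' from the leaves: a leaf contributes its presence call (0/1) times its
#' stem branch length; an internal descendant contributes its subtree score
#' divided by its subtree branch length, times the total branch length from
#' the ancestor through that descendant's subtree (stem included). Species
#' with missing calls are pruned from the tree first (suppressed degree-2
#' nodes have their branch lengths summed).
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param calls Named 0/1 vector over species; `NA` = missing (pruned).
#' @param resolve Resolve polytomies with zero-length branches instead of
#'   erroring (default `FALSE`; the recursion is defined for binary nodes).
#' @return A single non-negative score, at most the pruned tree's total
#'   branch length.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.5);")
#' conservation_score(tr, c(A = 1, B = 1, C = 0)) # 0.5
#' @export
conservation_score <- function(tree, calls, resolve = FALSE) {
  if (sum(!is.na(calls)) < 2L) {
    stop("pruned tree must retain >= 2 leaves", call. = FALSE)
  }
  m <- matrix(calls, nrow = 1, dimnames = list(NULL, names(calls)))
  conservation_scores(tree, m, resolve = resolve)[[1]]
}

#' Conservation scores for a matrix of presence calls
#'
#' Vectorised over ortholog sets: rows sharing a missingness pattern are
#' scored on one pruned tree. Rows with fewer than two non-missing species
#' get `NA` (the score is undefined there).
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param calls Integer matrix (ortholog sets x species, `NA` = missing)
#'   with column names matching tip labels.
#' @param resolve Resolve polytomies with zero-length branches.
#' @return Numeric vector of scores, named by rownames of `calls`.
#' @export
conservation_scores <- function(tree, calls, resolve = FALSE) {
  validate_tree(tree)
  # a trifurcating root reads as "unrooted" in ape but is a polytomy here
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (!resolve) stop("tree has polytomies; pass resolve = TRUE to resolve them",
                       call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (is.null(colnames(calls)) || !all(colnames(calls) %in% tree$tip.label)) {
    stop("call columns must be named by tree tip labels", call. = FALSE)
  }
  out <- rep(NA_real_, nrow(calls))
  pattern <- apply(!is.na(calls), 1, function(z) paste(which(z), collapse = ","))
  for (pat in unique(pattern)) {
    idx <- which(pattern == pat)
    keep <- colnames(calls)[!is.na(calls[idx[1], ])]
    if (length(keep) < 2L) next
    sub <- if (length(keep) == length(tree$tip.label)) tree else
      ape::keep.tip(tree, keep)
    out[idx] <- cs_engine(sub, calls[idx, keep, drop = FALSE])$cs
  }
  names(out) <- rownames(calls)
  out
}

#' Permutation-based false discovery rate for conservation scores
#'
#' For each ortholog set A, the FDR is the average (over permuted motifs) of
#' the number of sets whose permuted-motif score is at least A's real score,
#' divided by the number of sets whose real score is at least A's (the
#' denominator always includes A itself). The raw ratio may exceed 1; the
#' reported `fdr` is capped at 1, with the raw value retained.
#'
#' @param real Numeric vector of real-motif scores (one per ortholog set).
#' @param perm Numeric matrix of permuted-motif scores, one column per
#'   permuted motif (rows in the same set order as `real`).
#' @return Tibble `anchor` (names of `real`, if any), `cs`, `fdr_raw`, `fdr`.
#' @export
permutation_fdr <- function(real, perm) {
  perm <- as.matrix(perm)
  if (ncol(perm) < 1L) stop("need at least one permuted-motif score column", call. = FALSE)
  if (nrow(perm) != length(real)) {
    stop("real and permuted scores must cover the same ortholog sets", call. = FALSE)
  }
  m <- ncol(perm)
  allperm <- sort(perm[!is.na(perm)])
  realv <- real[!is.na(real)]
  sreal <- sort(realv)
  fdr_raw <- vapply(real, function(t) {
    if (is.na(t)) return(NA_real_)
    num <- (length(allperm) - findInterval(t, allperm, left.open = TRUE)) / m
    den <- length(sreal) - findInterval(t, sreal, left.open = TRUE)
    num / den
  }, numeric(1))
  tibble::tibble(anchor = if (is.null(names(real))) seq_along(real) else names(real),
                 cs = unname(real),
                 fdr_raw = unname(fdr_raw),
                 fdr = pmin(1, unname(fdr_raw)))
}

#' Ortholog sets conserved at an FDR threshold
#'
#' @param results Tibble with `anchor` and `fdr` (from [permutation_fdr()]
#'   or [conservation_analysis()]).
#' @param fdr_threshold Inclusive threshold (default 0.01, i.e. <= 1% FDR).
#' @return Character vector of anchor gene ids.
#' @export
conserved_set <- function(results, fdr_threshold = 0.01) {
  results$anchor[!is.na(results$fdr) & results$fdr <= fdr_threshold]
}

#' End-to-end conservation analysis
#'
#' Presence calls for the real motif and for an ensemble of position-permuted
#' motifs, conservation scores on the pruned phylogeny, permutation FDR, and
#' the conserved-set call at the threshold.
#'
#' @inheritParams presence_calls
#' @param tree Rooted binary `phylo` covering the UTR species.
#' @param n_perm Number of permuted motifs (default 100); if the permutation
#'   space is smaller, all are used.
#' @param fdr_threshold Inclusive FDR threshold for the conserved flag.
#' @param seed Seed for the permutation sample.
#' @param resolve Resolve polytomies with zero-length branches.
#' @return A `conservation_analysis` object: list with `results` tibble
#'   (`anchor`, `cs`, `fdr_raw`, `fdr`, `conserved`), `calls`, `tree`,
#'   `n_perm`, `fdr_threshold`.
#' @export
conservation_analysis <- function(ortho, utrs, m, tree, n_perm = 100,
                                  fdr_threshold = 0.01, seed = NULL,
                                  resolve = FALSE) {
  m <- as_motif_set(m)
  validate_tree(tree)
  calls <- presence_calls(ortho, utrs, m)
  mat <- presence_matrix(calls)
  real <- conservation_scores(tree, mat, resolve = resolve)

  perms <- permute_motif(m, max_count = n_perm, seed = seed)
  if (length(perms) == 0L) stop("motif has no permutations; cannot build a null", call. = FALSE)
  perm_scores <- matrix(vapply(perms, function(pm) {
    pcalls <- presence_calls(ortho, utrs, pm)
    conservation_scores(tree, presence_matrix(pcalls), resolve = resolve)
  }, numeric(nrow(mat))), nrow = nrow(mat))

  fdr <- permutation_fdr(real, perm_scores)
  fdr$conserved <- !is.na(fdr$fdr) & fdr$fdr <= fdr_threshold
  structure(list(results = fdr, calls = calls, tree = tree,
                 n_perm = length(perms), fdr_threshold = fdr_threshold),
            class = "conservation_analysis")
}

#' @export
print.conservation_analysis <- function(x, ...) {
  cat("<conservation analysis> ", nrow(x$results), " ortholog sets, ",
      x$n_perm, " permuted motifs, ", sum(x$results$conserved, na.rm = TRUE),
      " conserved at FDR <= ", x$fdr_threshold, "\n", sep = "")
  invisible(x)
}

#' Conservation test for collapsed gene groups
#'
#' Several anchor genes (e.g. the paralogous genes encoding one histone
#' type) are collapsed into one unit: a species is called present if any
#' ortholog of any member gene has a motif match. The unit's conservation
#' score is compared to scores from permuted motifs, yielding an empirical
#' p-value. A group is reported "not tested" when even the maximum possible
#' score (site present in every scored species) could not reach significance
#' against the permutation null.
#'
#' @param groups Named list of character vectors of anchor gene ids.
#' @param ortho,utrs,m,tree,seed As in [conservation_analysis()].
#' @param n_perm Number of permuted motifs.
#' @param alpha Significance level used for the underpowered guard.
#' @return Tibble `group`, `cs`, `max_cs`, `p_empirical`, `tested`.
#' @export
collapse_gene_groups <- function(groups, ortho, utrs, m, tree, n_perm = 100,
                                 alpha = 0.05, seed = NULL) {
  stopifnot(length(groups) > 0L, !is.null(names(groups)))
  m <- as_motif_set(m)
  perms <- permute_motif(m, max_count = n_perm, seed = seed)
  mm <- length(perms)

  group_calls <- function(motif_use, members) {
    sub <- ortho[ortho$anchor %in% members, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub$anchor <- "group"
    calls <- presence_calls(sub, utrs, motif_use)
    stats::setNames(calls$present, calls$species)
  }

  purrr::map_dfr(names(groups), function(g) {
    members <- groups[[g]]
    calls <- group_calls(m, members)
    if (is.null(calls) || sum(!is.na(calls)) < 2L) {
      return(tibble::tibble(group = g, cs = NA_real_, max_cs = NA_real_,
                            p_empirical = NA_real_, tested = FALSE))
    }
    cs <- conservation_score(tree, calls)
    keep <- names(calls)[!is.na(calls)]
    max_cs <- sum(ape::keep.tip(tree, keep)$edge.length)
    perm_cs <- vapply(perms, function(pm) {
      pc <- group_calls(pm, members)
      conservation_score(tree, pc)
    }, numeric(1))
    p_min <- (1 + sum(perm_cs >= max_cs)) / (mm + 1)
    if (p_min > alpha) {
      return(tibble::tibble(group = g, cs = cs, max_cs = max_cs,
                            p_empirical = NA_real_, tested = FALSE))
    }
    p_emp <- (1 + sum(perm_cs >= cs)) / (mm + 1)
    tibble::tibble(group = g, cs = cs, max_cs = max_cs,
                   p_empirical = p_emp, tested = TRUE)
  })
}
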