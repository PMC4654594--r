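# Independent oracles used to freeze expected values. Each takes a route
# deliberately different from the implementation it checks.

# P(overlap >= b) by exhaustively enumerating every way the B-matched draw
# can fall among the population of ortholog sets
hyper_enum_p <- function(n_both, n_only_a, n_only_b, n_neither) {
  total <- n_both + n_only_a + n_only_b + n_neither
  K <- n_both + n_only_a            # sets matched in species A
  ndraw <- n_both + n_only_b        # sets matched in species B
  if (ndraw == 0 || K == 0) return(1)
  draws <- utils::combn(total, ndraw)
  mean(colSums(draws <= K) >= n_both)
}

# two-tailed Fisher p by margin-fixed table enumeration with exact
# rational-style probabilities (choose products), summing tables whose
# probability does not exceed the observed one
fisher_enum_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# mutual information via the entropy identity H(R) + H(C) - H(R,C)
mi_entropy_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  H <- function(p) {
    p <- p[p > 0] / sum(p)
    -sum(p * log2(p))
  }
  H(c(a + b, c + d)) + H(c(a + c, b + d)) - H(c(a, b, c, d))
}

# sliding-window set-membership scan, position by position
naive_scan <- function(seq, pattern_sets) {
  L <- length(pattern_sets)
  chars <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  if (length(chars) >= L) {
    for (s in 1:(length(chars) - L + 1)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!(chars[s + j - 1] %in% pattern_sets[[j]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s - 1L)
    }
  }
  hits
}

# all distinct position reorderings of a motif, by brute-force enumeration
# of index permutations (feasible for length <= 8)
brute_permutations <- function(position_strings) {
  L <- length(position_strings)
  perms <- expand_perms(L)
  pats <- vapply(perms, function(idx) paste(position_strings[idx], collapse = "|"),
                 character(1))
  setdiff(unique(pats), paste(position_strings, collapse = "|"))
}

expand_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in expand_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# 2-state Felsenstein pruning for a binary trait (gain/loss chain), the
# factorization oracle for the 4-state independence model
prune2_loglik <- function(tree, calls_mat, gain, loss) {
  p2 <- function(t) {
    tot <- gain + loss
    if (tot == 0) return(diag(2))
    pi1 <- gain / tot
    e <- exp(-tot * t)
    matrix(c(1 - pi1 + pi1 * e, pi1 - pi1 * e,
             (1 - pi1) - (1 - pi1) * e, pi1 + (1 - pi1) * e),
           2, 2, byrow = TRUE)
  }
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  calls_mat <- calls_mat[, tree$tip.label, drop = FALSE]
  total <- 0
  for (g in seq_len(nrow(calls_mat))) {
    partial <- vector("list", ntip + tree$Nnode)
    for (i in seq_len(ntip)) {
      v <- calls_mat[g, i]
      partial[[i]] <- if (is.na(v)) c(1, 1) else if (v == 0) c(1, 0) else c(0, 1)
    }
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      contrib <- p2(tree$edge.length[e]) %*% partial[[ch]]
      partial[[par]] <- if (is.null(partial[[par]])) contrib else partial[[par]] * contrib
    }
    total <- total + log(sum(0.5 * partial[[ntip + 1]]))
  }
  total
}

# random DNA string helper for property tests
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random degenerate motif of given length
rand_motif <- function(len) {
  motif(lapply(seq_len(len), function(i) {
    sample(c("A", "C", "G", "T"), sample(1:3, 1))
  }))
}
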