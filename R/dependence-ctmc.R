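#' Single-step gain/loss rate matrix for two binary sites
#'
#' Four states `00`, `01`, `10`, `11` (first digit = site 1 presence,
#' second = site 2). Only single-step transitions (one site changing) have
#' non-zero rates; simultaneous changes are disallowed. The dependence
#' model has eight free rates (each gain/loss rate conditional on the other
#' site's state); the independence model ties parallel rates, leaving four.
#'
#' @param rates Named numeric vector. Dependence:
#'   `g1.0`, `g1.1`, `l1.0`, `l1.1`, `g2.0`, `g2.1`, `l2.0`, `l2.1`
#'   (`g1.0` = gain of site 1 while site 2 absent, etc.).
#'   Independence: `g1`, `l1`, `g2`, `l2`.
#' @param model `"dependence"` or `"independence"`.
#' @return 4 x 4 generator matrix with rows summing to zero.
#' @export
gainloss_generator <- function(rates, model = c("dependence", "independence")) {
  model <- match.arg(model)
  need <- gainloss_rate_names(model)
  stopifnot(all(need %in% names(rates)), all(rates[need] >= 0))
  r <- rates
  if (model == "independence") {
    r <- c(g1.0 = unname(r["g1"]), g1.1 = unname(r["g1"]),
           l1.0 = unname(r["l1"]), l1.1 = unname(r["l1"]),
           g2.0 = unname(r["g2"]), g2.1 = unname(r["g2"]),
           l2.0 = unname(r["l2"]), l2.1 = unname(r["l2"]))
  }
  st <- c("00", "01", "10", "11")
  Q <- matrix(0, 4, 4, dimnames = list(st, st))
  Q["00", "10"] <- r[["g1.0"]]; Q["01", "11"] <- r[["g1.1"]]
  Q["10", "00"] <- r[["l1.0"]]; Q["11", "01"] <- r[["l1.1"]]
  Q["00", "01"] <- r[["g2.0"]]; Q["10", "11"] <- r[["g2.1"]]
  Q["01", "00"] <- r[["l2.0"]]; Q["11", "10"] <- r[["l2.1"]]
  diag(Q) <- -rowSums(Q)
  Q
}

gainloss_rate_names <- function(model) {
  if (model == "independence") c("g1", "l1", "g2", "l2")
  else c("g1.0", "g1.1", "l1.0", "l1.1", "g2.0", "g2.1", "l2.0", "l2.1")
}

# transition matrices exp(Q t) for a set of branch lengths; eigen route with
# a Pade (Matrix::expm) fallback when the reconstruction is poor
expm_edges <- function(Q, times) {
  out <- vector("list", length(times))
  ok <- FALSE
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(ev) && all(is.finite(ev$values))) {
    Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      ok <- TRUE
      for (i in seq_along(times)) {
        P <- Re(ev$vectors %*% (exp(ev$values * times[i]) * Vi))
        if (any(!is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-8 || min(P) < -1e-8) {
          ok <- FALSE
          break
        }
        out[[i]] <- pmax(P, 0)
      }
    }
  }
  if (!ok) {
    for (i in seq_along(times)) {
      P <- as.matrix(Matrix::expm(Q * times[i]))
      out[[i]] <- pmax(P, 0)
    }
  }
  out
}

# internal: compress per-gene leaf states into unique pattern columns
ctmc_patterns <- function(tree, states) {
  states <- states[, tree$tip.label, drop = FALSE]
  nonmiss <- rowSums(!is.na(states))
  keep <- nonmiss >= 2L
  states <- states[keep, , drop = FALSE]
  if (nrow(states) == 0L) stop("no gene has >= 2 non-missing species", call. = FALSE)
  key <- apply(states, 1, function(z) paste(ifelse(is.na(z), "-", z), collapse = "|"))
  counts <- table(key)
  pat <- do.call(rbind, strsplit(names(counts), "|", fixed = TRUE))
  list(patterns = pat, counts = as.numeric(counts), n_genes = nrow(states),
       n_excluded = sum(!keep))
}

#' Log-likelihood of paired presence data under a gain/loss model
#'
#' Felsenstein pruning over the 4-state single-step chain, summed over
#' genes. Leaf observations are the joint states `"00"`, `"01"`, `"10"`,
#' `"11"`; a missing leaf (`NA`, no ortholog) is ambiguous and sums over
#' all states. Genes observed in fewer than two species are excluded. The
#' root state distribution is uniform over the four states by default, or
#' the chain's stationary distribution.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param states Character matrix (genes x species; values `"00"`..`"11"`
#'   or `NA`) with columns named by tip labels, or a tibble with columns
#'   `gene`, `species`, `site1`, `site2` (0/1/NA) which is spread
#'   internally.
#' @param rates,model As in [gainloss_generator()].
#' @param root `"uniform"` (default) or `"stationary"`.
#' @return Log-likelihood (sum over genes).
#' @export
ctmc_loglik <- function(tree, states, rates, model = c("dependence", "independence"),
                        root = c("uniform", "stationary")) {
  model <- match.arg(model)
  root <- match.arg(root)
  validate_tree(tree)
  if (is.data.frame(states)) states <- states_matrix(states)
  pats <- ctmc_patterns(tree, states)
  Q <- gainloss_generator(rates, model)
  ctmc_loglik_patterns(tree, pats, Q, root)
}

ctmc_loglik_patterns <- function(tree, pats, Q, root = "uniform") {
  st <- colnames(Q)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- nrow(pats$patterns)

  Pmats <- expm_edges(Q, tree$edge.length)
  prior <- if (root == "uniform") rep(0.25, 4) else stationary_dist(Q)

  # partial likelihoods: list over nodes of 4 x npat matrices
  partial <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    obs <- pats$patterns[, i]
    m <- matrix(0, 4, npat)
    known <- obs != "-"
    m[, !known] <- 1
    if (any(known)) m[cbind(match(obs[known], st), which(known))] <- 1
    partial[[i]] <- m
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    contrib <- Pmats[[e]] %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
    }
  }
  root_node <- ntip + 1L
  lik <- as.numeric(prior %*% partial[[root_node]])
  if (any(lik <= 0)) return(-Inf)
  sum(pats$counts * log(lik))
}

stationary_dist <- function(Q) {
  A <- t(Q)
  A[4, ] <- 1
  pi <- solve(A, c(0, 0, 0, 1))
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Spread a long site table into a gene x species state matrix
#' @param df Tibble with columns `gene`, `species`, `site1`, `site2`.
#' @return Character matrix of joint states with `NA` for missing.
#' @export
states_matrix <- function(df) {
  stopifnot(all(c("gene", "species", "site1", "site2") %in% names(df)))
  df$state <- ifelse(is.na(df$site1) | is.na(df$site2), NA_character_,
                     paste0(df$site1, df$site2))
  wide <- tidyr::pivot_wider(df[c("gene", "species", "state")],
                             names_from = "species", values_from = "state")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$gene
  mat
}

#' MCMC over gain/loss rates with marginal-likelihood estimates
#'
#' Random-scan Metropolis-Hastings with multiplicative lognormal proposals
#' on each rate, bounded uniform priors on `[0, r_max]`, and proposal
#' scales adapted only during burn-in. Posterior summaries are medians of
#' the post-burn-in thinned samples. The log marginal likelihood is
#' estimated by the harmonic mean of the sampled likelihoods (retained for
#' comparability with the classical discrete-trait workflow despite its
#' known instability); a stepping-stone estimate is available as a
#' separately-labelled alternative via [stepping_stone()].
#'
#' @inheritParams ctmc_loglik
#' @param iterations Total MCMC iterations.
#' @param burnin Burn-in iterations (discarded; adaptation happens here).
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param r_max Upper bound of the uniform rate prior.
#' @param seed Integer seed; identical seeds give identical chains.
#' @param init Optional named initial rate vector.
#' @return An `mcmc_gainloss` object: samples (matrix), `median_rates`,
#'   `log_harmonic_mean`, acceptance rate, and the run settings.
#' @export
mcmc_rates <- function(tree, states, model = c("dependence", "independence"),
                       iterations = 2e5, burnin = 2e4, thin = 100,
                       r_max = 100, seed = 1, root = c("uniform", "stationary"),
                       init = NULL) {
  model <- match.arg(model)
  root <- match.arg(root)
  validate_tree(tree)
  if (is.data.frame(states)) states <- states_matrix(states)
  pats <- ctmc_patterns(tree, states)
  pnames <- gainloss_rate_names(model)
  k <- length(pnames)
  stopifnot(iterations > burnin)

  run <- function() {
    x <- if (is.null(init)) stats::setNames(rep(1, k), pnames) else init[pnames]
    ll <- ctmc_loglik_patterns(tree, pats, gainloss_generator(x, model), root)
    sds <- stats::setNames(rep(0.5, k), pnames)
    acc <- stats::setNames(rep(0, k), pnames)
    try_ <- stats::setNames(rep(0, k), pnames)
    keep_idx <- seq(burnin + thin, iterations, by = thin)
    samples <- matrix(NA_real_, length(keep_idx), k, dimnames = list(NULL, pnames))
    lls <- numeric(length(keep_idx))
    ki <- 1L
    for (it in seq_len(iterations)) {
      j <- sample.int(k, 1L)
      prop <- x
      prop[j] <- x[j] * exp(sds[j] * stats::rnorm(1))
      try_[j] <- try_[j] + 1
      if (prop[j] <= r_max) {
        llp <- ctmc_loglik_patterns(tree, pats, gainloss_generator(prop, model), root)
        # lognormal multiplicative proposal: Hastings term log(prop/current)
        if (log(stats::runif(1)) < llp - ll + log(prop[j]) - log(x[j])) {
          x <- prop; ll <- llp; acc[j] <- acc[j] + 1
        }
      }
      if (it <= burnin && it %% 500 == 0) {
        rate <- ifelse(try_ > 0, acc / try_, 0.3)
        sds <- pmin(5, pmax(0.01, sds * exp(rate - 0.3)))
        acc[] <- 0; try_[] <- 0
      }
      if (ki <= length(keep_idx) && it == keep_idx[ki]) {
        samples[ki, ] <- x
        lls[ki] <- ll
        ki <- ki + 1L
      }
    }
    acc_rate <- sum(acc) / max(1, sum(try_))
    if (acc_rate < 0.05 || acc_rate > 0.95) {
      warning("MCMC acceptance rate ", round(acc_rate, 3),
              " outside [0.05, 0.95] after adaptation")
    }
    list(samples = samples, lls = lls, acc_rate = acc_rate)
  }
  res <- withr::with_seed(seed, run())

  # harmonic mean: log m = log N - logsumexp(-loglik)
  lhm <- log(length(res$lls)) - logsumexp(-res$lls)
  structure(list(samples = res$samples,
                 loglik = res$lls,
                 median_rates = apply(res$samples, 2, stats::median),
                 log_harmonic_mean = lhm,
                 acceptance_rate = res$acc_rate,
                 model = model, root = root,
                 iterations = iterations, burnin = burnin, thin = thin,
                 r_max = r_max, seed = seed,
                 n_genes = pats$n_genes, n_excluded = pats$n_excluded),
            class = "mcmc_gainloss")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.mcmc_gainloss <- function(x, ...) {
  cat("<gain/loss MCMC> ", x$model, " model, ", nrow(x$samples),
      " samples, log harmonic-mean ML ", round(x$log_harmonic_mean, 2), "\n", sep = "")
  print(round(x$median_rates, 4))
  invisible(x)
}

#' Bayes factor comparing dependence and independence gain/loss models
#'
#' Runs [mcmc_rates()] under both models and reports
#' `log BF = 2 * (log HM(dependence) - log HM(independence))` from the
#' harmonic-mean marginal likelihoods; negative values favour the simpler
#' independence model.
#'
#' @inheritParams mcmc_rates
#' @return List with both `mcmc_gainloss` fits and `log_bayes_factor`.
#' @export
bayes_factor_dependence <- function(tree, states, iterations = 2e5,
                                    burnin = 2e4, thin = 100, r_max = 100,
                                    seed = 1, root = c("uniform", "stationary")) {
  root <- match.arg(root)
  dep <- mcmc_rates(tree, states, "dependence", iterations, burnin, thin,
                    r_max, seed, root)
  ind <- mcmc_rates(tree, states, "independence", iterations, burnin, thin,
                    r_max, seed + 1L, root)
  list(dependence = dep, independence = ind,
       log_bayes_factor = 2 * (dep$log_harmonic_mean - ind$log_harmonic_mean))
}

#' Stepping-stone marginal-likelihood estimate (alternative estimator)
#'
#' Power-posterior stepping-stone estimate of the log marginal likelihood,
#' provided as a numerically steadier alternative to the harmonic mean; it
#' is not part of the classical workflow this package mirrors and is
#' labelled accordingly in outputs.
#'
#' @inheritParams mcmc_rates
#' @param n_rungs Number of power-posterior rungs.
#' @param iter_per_rung MCMC iterations per rung (half discarded as
#'   burn-in).
#' @return List with `log_marginal` and the per-rung contributions.
#' @export
stepping_stone <- function(tree, states, model = c("dependence", "independence"),
                           n_rungs = 10, iter_per_rung = 5000, r_max = 100,
                           seed = 1, root = c("uniform", "stationary")) {
  model <- match.arg(model)
  root <- match.arg(root)
  validate_tree(tree)
  if (is.data.frame(states)) states <- states_matrix(states)
  pats <- ctmc_patterns(tree, states)
  pnames <- gainloss_rate_names(model)
  k <- length(pnames)
  betas <- (seq(0, n_rungs) / n_rungs)^(1 / 0.3)  # Beta(0.3,1) quantile spacing

  run <- function() {
    x <- stats::setNames(rep(1, k), pnames)
    ll <- ctmc_loglik_patterns(tree, pats, gainloss_generator(x, model), root)
    contribs <- numeric(n_rungs)
    for (rk in seq_len(n_rungs)) {
      beta <- betas[rk]        # sample at the lower rung, evaluate the step up
      dbeta <- betas[rk + 1] - beta
      lls <- numeric(iter_per_rung)
      for (it in seq_len(iter_per_rung)) {
        j <- sample.int(k, 1L)
        prop <- x
        prop[j] <- x[j] * exp(0.5 * stats::rnorm(1))
        if (prop[j] <= r_max) {
          llp <- ctmc_loglik_patterns(tree, pats, gainloss_generator(prop, model), root)
          if (log(stats::runif(1)) < beta * (llp - ll) + log(prop[j]) - log(x[j])) {
            x <- prop; ll <- llp
          }
        }
        lls[it] <- ll
      }
      use <- lls[(iter_per_rung %/% 2 + 1):iter_per_rung]
      contribs[rk] <- logsumexp(dbeta * use) - log(length(use))
    }
    contribs
  }
  contribs <- withr::with_seed(seed, run())
  list(log_marginal = sum(contribs), rung_contributions = contribs,
       estimator = "stepping-stone (alternative, not the classical workflow)")
}
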