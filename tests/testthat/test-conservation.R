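three_leaf_tree <- function() ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.5);")

test_that("presence calls implement the any-ortholog / missing rules", {
  utrs <- utr_table(
    spA = c(a1 = "CCTGTAAATACC", a2 = "CCCCCCCCCCCC"),
    spB = c(b1 = "CCCCCCCCCCCC", b2 = "CCTGTAAATACC"),
    spC = c(c1 = "CCCCCCCCCCCC"))
  ortho <- tibble::tibble(
    anchor   = c("g1", "g1", "g1", "g1", "g2"),
    species  = c("spA", "spB", "spB", "spC", "spA"),
    ortholog = c("a1", "b1", "b2", "c1", "a2"))
  m <- motif("TGTAAATA")
  calls <- presence_calls(ortho, utrs, m)
  mat <- presence_matrix(calls)
  expect_equal(mat["g1", "spB"], 1L)   # one of two orthologs matches
  expect_equal(mat["g1", "spC"], 0L)   # single non-matching ortholog
  expect_equal(mat["g2", "spB"], NA_integer_)  # no ortholog: missing
  expect_equal(mat["g2", "spA"], 0L)

  # listed ortholog without a sequence becomes missing, with a message
  ortho2 <- tibble::tibble(anchor = "g3", species = "spC", ortholog = "ghost")
  expect_error(expect_message(presence_calls(ortho2, utrs, m), "missing"))
})

test_that("conservation score matches the printed recursion on small trees", {
  two <- ape::read.tree(text = "(A:0.3,B:0.7);")
  expect_equal(conservation_score(two, c(A = 1, B = 1)), 1.0)
  expect_equal(conservation_score(two, c(A = 0, B = 0)), 0)
  expect_equal(conservation_score(three_leaf_tree(), c(A = 1, B = 1, C = 0)), 0.5)
  expect_equal(conservation_score(three_leaf_tree(), c(A = 1, B = 1, C = 1)), 1.0)
})

test_that("species with missing calls are pruned with branch lengths summed", {
  # pruning C collapses the inner node; A-B path keeps total length
  cs <- conservation_score(three_leaf_tree(), c(A = 1, B = 1, C = NA))
  expect_equal(cs, 0.4)  # pruned two-leaf tree A:0.2 + B:0.2 (stem dropped)
  expect_error(conservation_score(three_leaf_tree(), c(A = 1, B = NA, C = NA)),
               ">= 2 leaves")
})

test_that("all-present equals total branch length and all-absent zero", {
  set.seed(21)
  for (i in 1:25) {
    tr <- simulate_tree(sample(2:16, 1), seed = 300 + i)
    n <- length(tr$tip.label)
    ones <- setNames(rep(1, n), tr$tip.label)
    expect_equal(conservation_score(tr, ones), sum(tr$edge.length),
                 tolerance = 1e-12)
    expect_equal(conservation_score(tr, ones * 0), 0)
  }
})

test_that("score never decreases when an absent call flips to present", {
  set.seed(22)
  for (i in 1:60) {
    tr <- simulate_tree(sample(3:16, 1), seed = 400 + i)
    n <- length(tr$tip.label)
    calls <- setNames(rbinom(n, 1, 0.4), tr$tip.label)
    base <- conservation_score(tr, calls)
    absent <- names(calls)[calls == 0]
    if (length(absent) == 0) next
    flip <- calls
    flip[sample(absent, 1)] <- 1
    expect_gte(conservation_score(tr, flip), base - 1e-12)
  }
})

test_that("score is invariant to the tree description's leaf order", {
  tr1 <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,(C:0.4,D:0.5):0.2);")
  tr2 <- ape::read.tree(text = "((D:0.5,C:0.4):0.2,(B:0.3,A:0.2):0.1);")
  calls <- c(A = 1, B = 0, C = 1, D = 1)
  expect_equal(conservation_score(tr1, calls), conservation_score(tr2, calls),
               tolerance = 1e-12)
})

test_that("polytomies error unless resolved with zero-length branches", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.3);")
  calls <- c(A = 1, B = 1, C = 0)
  expect_error(conservation_score(tr, calls), "polytom")
  cs <- conservation_score(tr, calls, resolve = TRUE)
  expect_gte(cs, 0)
  expect_lte(cs, sum(tr$edge.length))
})

test_that("zero-length subtrees fall back to the leaf-call average", {
  tr <- ape::read.tree(text = "((A:0,B:0):0.5,C:0.5);")
  # A present, B absent: inner P = mean(1, 0) = 0.5; CS = 0.5*0.5 + 0
  expect_equal(conservation_score(tr, c(A = 1, B = 0, C = 0)), 0.25)
})

test_that("permutation FDR reproduces the defining ratio", {
  expect_equal(permutation_fdr(c(10, 5), matrix(0, 2, 3))$fdr_raw, c(0, 0))
  expect_equal(permutation_fdr(c(10, 5),
                               matrix(c(10, 5, 10, 5), 2, 2))$fdr_raw, c(1, 1))
  f <- permutation_fdr(c(10, 5, 0), cbind(c(6, 0, 0), c(12, 0, 0)))
  expect_equal(f$fdr_raw, c(0.5, 0.5, 1))
  # raw FDR can exceed 1; reporting caps it
  f2 <- permutation_fdr(c(10, 1), cbind(c(10, 10), c(10, 10)))
  expect_equal(f2$fdr_raw[1], 2)   # 2 permuted sets >= 10 on average, 1 real
  expect_equal(f2$fdr[1], 1)
})

test_that("conserved_set keeps the boundary FDR (inclusive threshold)", {
  res <- tibble::tibble(anchor = c("a", "b", "c"), fdr = c(0, 0.01, 0.011))
  expect_equal(conserved_set(res), c("a", "b"))
  expect_equal(conserved_set(tibble::tibble(anchor = "x", fdr = 1),
                             fdr_threshold = 1), "x")
})

test_that("gene-group collapsing uses any-member matches and the power guard", {
  tr <- ape::read.tree(text = "((spA:0.05,spB:0.05):0.02,spC:0.08);")
  utrs <- utr_table(
    spA = c(hta1_A = "CCCCCCCCCCCC", hta2_A = "CCTGTAAATACC"),
    spB = c(hta1_B = "CCTGTAAATACC"),
    spC = c(hta1_C = "CCTGTAAATACC", none_C = "CCCCCCCCCCCC"))
  ortho <- tibble::tibble(
    anchor   = c("hta1", "hta2", "hta1", "hta1", "none"),
    species  = c("spA", "spA", "spB", "spC", "spC"),
    ortholog = c("hta1_A", "hta2_A", "hta1_B", "hta1_C", "none_C"))
  m <- motif("TGTAAATA")
  res <- collapse_gene_groups(list(h2a = c("hta1", "hta2"), ctrl = "none"),
                              ortho, utrs, m, tr, n_perm = 60, seed = 5)
  h2a <- res[res$group == "h2a", ]
  # one matching member per species -> present everywhere -> CS = total BL
  expect_equal(h2a$cs, sum(tr$edge.length), tolerance = 1e-12)
  ctrl <- res[res$group == "ctrl", ]
  expect_true(is.na(ctrl$cs) || ctrl$cs == 0 || !ctrl$tested)
})

test_that("underpowered lineages are reported as not tested", {
  tr <- ape::read.tree(text = "(spA:0.1,spB:0.1);")
  utrs <- utr_table(spA = c(gA = "CCTTTTTTTTCC"), spB = c(gB = "CCTTTTTTTTCC"))
  ortho <- tibble::tibble(anchor = c("g", "g"), species = c("spA", "spB"),
                          ortholog = c("gA", "gB"))
  # motif of all-T matches: permutations of TTTTTTTT are identical, so the
  # permuted scores always tie the maximum -> guard must fire
  m <- motif("T[AT]TTTTTT")
  res <- collapse_gene_groups(list(g = "g"), ortho, utrs, m, tr,
                              n_perm = 30, seed = 2)
  expect_false(res$tested)
  expect_true(is.na(res$p_empirical))
})

test_that("full conservation analysis is deterministic and typed", {
  sim <- simulate_conservation_study(n_species = 6, n_conserved = 8,
                                     n_background = 24, seed = 12)
  ca <- suppressMessages(
    conservation_analysis(sim$ortho, sim$utrs, sim$motif, sim$tree,
                          n_perm = 25, seed = 3))
  res <- tidy(ca)
  expect_named(res, c("anchor", "cs", "fdr_raw", "fdr", "conserved"))
  expect_equal(nrow(res), 32)
  ca2 <- suppressMessages(
    conservation_analysis(sim$ortho, sim$utrs, sim$motif, sim$tree,
                          n_perm = 25, seed = 3))
  expect_identical(res, tidy(ca2))
  g <- glance(ca)
  expect_equal(g$n_perm, 25)
})
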