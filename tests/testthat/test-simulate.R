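test_that("simulated trees are rooted, binary, seeded and labelled", {
  tr <- simulate_tree(8, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr) && ape::is.binary(tr))
  expect_setequal(tr$tip.label, paste0("sp", 1:8))
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(8, seed = 1)))
  # two leaves: a single cherry
  expect_equal(length(simulate_tree(2, seed = 2)$tip.label), 2L)
})

test_that("degenerate rate settings behave deterministically", {
  tr <- simulate_tree(6, seed = 3)
  # loss 0, root present: site never disappears
  st <- simulate_sites(tr, 30, c(gain = 0.5, loss = 0), n_factors = 1,
                       root_probs = c(0, 1), seed = 4)
  expect_true(all(st$site1 == 1))
  # all rates 0: leaves copy the root state
  st0 <- simulate_sites(tr, 30, c(gain = 0, loss = 0), n_factors = 1,
                        root_probs = c(1, 0), seed = 5)
  expect_true(all(st0$site1 == 0))
})

test_that("leaf marginals match the analytic transition probability", {
  tr <- ape::read.tree(text = "(A:0.4,B:1.2);")
  gain <- 0.6; loss <- 1.1
  st <- simulate_sites(tr, 10000, c(gain = gain, loss = loss), n_factors = 1,
                       root_probs = c(1, 0), seed = 6)
  # analytic P(present at leaf | absent root) for a 2-state chain
  p_t <- function(t) (gain / (gain + loss)) * (1 - exp(-(gain + loss) * t))
  for (leaf in c("A", "B")) {
    t_leaf <- tr$edge.length[tr$edge[, 2] == match(leaf, tr$tip.label)]
    obs <- mean(st$site1[st$species == leaf])
    expected <- p_t(t_leaf)
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_lt(abs(obs - expected), 3 * se)
  }
})

test_that("dependence-mode simulation respects conditional rates", {
  tr <- simulate_tree(4, mean_branch = 0.5, seed = 7)
  # site 2 can only be gained when site 1 is present
  rates <- c(g1.0 = 1, g1.1 = 1, l1.0 = 0.2, l1.1 = 0.2,
             g2.0 = 0, g2.1 = 2, l2.0 = 0.5, l2.1 = 0.5)
  st <- simulate_sites(tr, 200, rates, model = "dependence",
                       root_probs = c(1, 0, 0, 0), seed = 8)
  # joint 01 states are possible only transiently after losing site 1,
  # so site2 presence should be strongly associated with site1
  tab <- table(st$site1, st$site2)
  expect_gt(mutual_information(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1]), 0.01)
})

test_that("clade-conserved histories separate clade from background", {
  tr <- simulate_tree(12, seed = 9)
  hist <- simulate_clade_conserved(tr, 40, 160, seed = 10)
  wide <- tidyr::pivot_wider(hist$calls, names_from = "species",
                             values_from = "present")
  mat <- as.matrix(wide[-1]); rownames(mat) <- wide$gene
  cons <- hist$truth$gene[hist$truth$conserved]
  expect_gt(mean(mat[cons, hist$clade], na.rm = TRUE), 0.8)
  expect_lt(mean(mat[!rownames(mat) %in% cons, ], na.rm = TRUE), 0.1)
  expect_gt(mean(is.na(mat)), 0.01)   # dropout produced missing calls
})

test_that("emitted sequences contain matches exactly where sites are present", {
  tr <- simulate_tree(5, seed = 11)
  hist <- simulate_clade_conserved(tr, 10, 20, dropout = 0.1, seed = 12)
  m <- motif("TGTA[ACT]ATA")
  emit <- emit_utrs(hist$calls, m, utr_length = 300, scrub = TRUE, seed = 13)
  hit <- seq_has_match(emit$utrs$seq, m)
  joined <- dplyr::inner_join(
    emit$utrs,
    dplyr::mutate(hist$calls, gene_id = paste(species, gene, sep = "_")),
    by = "gene_id")
  expect_true(all(hit[joined$present == 1]))
  expect_true(!any(hit[joined$present == 0]))   # scrubbed background
  # missing calls emit nothing
  n_missing <- sum(is.na(hist$calls$present))
  expect_equal(nrow(emit$utrs), nrow(hist$calls) - n_missing)
  expect_equal(nrow(emit$ortho), nrow(emit$utrs))
})

test_that("accidental match rate without scrubbing matches the i.i.d. rate", {
  calls <- tibble::tibble(gene = sprintf("g%05d", 1:12000), species = "spA",
                          present = 0L)
  m <- motif("TGTA[ACT]ATA")
  emit <- emit_utrs(calls, m, utr_length = 500, gc = 0.5, scrub = FALSE,
                    seed = 14)
  counts <- vapply(emit$utrs$seq, function(s) nrow(scan_sequence(s, m)),
                   numeric(1), USE.NAMES = FALSE)
  expected <- 493 * (1 / 4)^7 * (3 / 4)
  se <- sqrt(expected / 12000)   # Poisson-scale error on the mean
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("two present factors are planted without overlap", {
  tr <- simulate_tree(3, seed = 15)
  st <- simulate_sites(tr, 40, c(g1 = 2, l1 = 0.1, g2 = 2, l2 = 0.1),
                       model = "independence", seed = 16)
  m1 <- motif("TGTA[ACT]ATA"); m2 <- motif("TGTA[CT]AACA")
  emit <- emit_utrs(st, list(m1, m2), utr_length = 120, scrub = TRUE, seed = 17)
  both <- dplyr::count(emit$planted, .data$gene, .data$species) |>
    dplyr::filter(n == 2)
  planted2 <- dplyr::semi_join(emit$planted, both, by = c("gene", "species"))
  overlaps <- planted2 |>
    dplyr::group_by(.data$gene, .data$species) |>
    dplyr::summarise(ov = {
      o <- order(.data$start)
      .data$start[o][2] < .data$start[o][1] + .data$length[o][1]
    }, .groups = "drop")
  expect_true(!any(overlaps$ov))
  expect_error(emit_utrs(st, list(m1, m2), utr_length = 12),
               "non-overlapping")
})

test_that("the reference study wrapper is a pure function of its seed", {
  s1 <- simulate_conservation_study(n_species = 5, n_conserved = 5,
                                    n_background = 10, seed = 18)
  s2 <- simulate_conservation_study(n_species = 5, n_conserved = 5,
                                    n_background = 10, seed = 18)
  expect_identical(s1$utrs, s2$utrs)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$truth, s2$truth)
})

test_that("site designs follow the logistic generative model", {
  d <- simulate_site_design(20000, beta0 = -2, beta1 = 1, beta2 = 0,
                            seed = 19)
  p0 <- mean(d$target[d$site1 == 0])
  p1 <- mean(d$target[d$site1 == 1])
  expect_lt(abs(p0 - plogis(-2)), 0.01)
  expect_lt(abs(p1 - plogis(-1)), 0.015)
})
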