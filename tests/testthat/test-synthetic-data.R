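test_that("dated tree simulation: shape, determinism, validity", {
  ch <- simulate_dated_tree(3, birth = 0.01, root_age = 1000, seed = 1)
  expect_equal(ch$phy$Nnode, 2L)
  n_tip <- ape::Ntip(ch$phy)
  internal <- (n_tip + 1):(n_tip + ch$phy$Nnode)
  expect_equal(max(ch$ages[internal]), 1000)
  expect_true(all(ch$ages[internal][-which.max(ch$ages[internal])] < 1000))
  expect_true(ape::is.ultrametric(ch$phy, tol = 1e-8))
  a <- simulate_dated_tree(15, birth = 0.003, death = 0.001,
                           root_age = 1500, seed = 7)
  b <- simulate_dated_tree(15, birth = 0.003, death = 0.001,
                           root_age = 1500, seed = 7)
  expect_identical(ape::write.tree(a$phy), ape::write.tree(b$phy))
  expect_silent(validate_chronogram(a))
  expect_error(simulate_dated_tree(2, birth = 1, root_age = 10, seed = 1))
})

test_that("pure-birth node ages match the order-statistics oracle", {
  # independent closed form for the Yule age CDF conditioned on the root
  b <- 0.002
  t1 <- 1200
  yule_cdf <- function(s) (1 - exp(-b * s)) / (1 - exp(-b * t1))
  ages <- c()
  for (i in 1:500) {
    ch <- simulate_dated_tree(6, birth = b, death = 0, root_age = t1,
                              seed = 2000 + i)
    n_tip <- ape::Ntip(ch$phy)
    a <- ch$ages[(n_tip + 1):(n_tip + ch$phy$Nnode)]
    ages <- c(ages, a[a < t1 - 1e-9])
  }
  ks <- suppressWarnings(stats::ks.test(ages, yule_cdf))
  expect_gt(ks$p.value, 0.01)
  # generator's own cdf agrees with the closed form when death = 0
  s_grid <- seq(10, t1, length.out = 50)
  expect_equal(bd_age_cdf(s_grid, birth = b, death = 0, root_age = t1),
               yule_cdf(s_grid), tolerance = 1e-12)
})

test_that("branch rates: clock limit, mean preservation, autocorrelation", {
  ch <- simulate_dated_tree(20, birth = 0.004, root_age = 1000, seed = 3)
  r0 <- simulate_branch_rates(ch, "autocorrelated", sigma2 = 0, seed = 4)
  expect_equal(r0$rate, rep(0.02625, nrow(r0)))
  r0u <- simulate_branch_rates(ch, "uncorrelated", sigma2 = 0, seed = 4)
  expect_equal(r0u$rate, rep(0.02625, nrow(r0u)))
  # law of large numbers for the uncorrelated model
  big <- simulate_dated_tree(400, birth = 0.004, root_age = 1000, seed = 5)
  ru <- simulate_branch_rates(big, "uncorrelated", sigma2 = 0.25, seed = 6)
  mu <- 0.02625
  se <- stats::sd(ru$rate) / sqrt(nrow(ru))
  expect_lt(abs(mean(ru$rate) - mu), 3 * se)
  # parent-child correlation over >= 2000 branch pairs
  pair_cor <- function(kind) {
    logs <- c()
    logs_child <- c()
    for (i in 1:40) {
      tr <- simulate_dated_tree(40, birth = 0.004, root_age = 1000,
                                seed = 300 + i)
      rr <- simulate_branch_rates(tr, kind, sigma2 = 1, seed = 600 + i)
      edge_of <- stats::setNames(seq_len(nrow(rr)), rr$child)
      for (e in seq_len(nrow(rr))) {
        p <- rr$parent[e]
        pe <- edge_of[as.character(p)]
        if (!is.na(pe)) {
          logs <- c(logs, log(rr$rate[pe]))
          logs_child <- c(logs_child, log(rr$rate[e]))
        }
      }
    }
    list(r = stats::cor(logs, logs_child), n = length(logs))
  }
  ac <- pair_cor("autocorrelated")
  uc <- pair_cor("uncorrelated")
  expect_gte(ac$n, 2000)
  expect_gt(ac$r, 0.3)
  expect_lt(abs(uc$r), 0.1)
})

test_that("posterior trace simulation: degenerate, reproducible, ordered", {
  ch <- chronogram_from_test_text("((A:400,B:400):600,(C:700,D:700):300);")
  tr0 <- simulate_posterior_trace(ch, cv = 0, n_samples = 50, seed = 8)
  s <- summarize_trace(tr0)
  expect_equal(sort(s$median), sort(c(1000, 400, 700)))
  expect_equal(s$hpd_older - s$hpd_younger, rep(0, 3))
  t1 <- simulate_posterior_trace(ch, cv = 0.1, n_samples = 100, seed = 9)
  t2 <- simulate_posterior_trace(ch, cv = 0.1, n_samples = 100, seed = 9)
  expect_identical(t1$samples, t2$samples)
  # parent >= child in every sample
  root_col <- t1$samples$t_n5
  expect_true(all(t1$samples$t_n6 <= root_col))
  expect_true(all(t1$samples$t_n7 <= root_col))
  # near-equal node ages + large noise make the ordering constraint
  # unsatisfiable within the rejection budget
  tight <- chronogram_from_test_text("((A:999,B:999):1,(C:998,D:998):2);")
  expect_error(simulate_posterior_trace(tight, cv = 3, n_samples = 20,
                                        seed = 10, max_reject = 3),
               "smaller cv")
})

test_that("95% HPDs of simulated traces cover the truth at the nominal rate", {
  ch <- chronogram_from_test_text("((A:400,B:400):600,(C:700,D:700):300);")
  truth <- c(1000, 400, 700)
  hits <- 0
  total <- 0
  for (i in 1:170) {
    tr <- simulate_posterior_trace(ch, cv = 0.1, n_samples = 800,
                                   seed = 3000 + i)
    s <- summarize_trace(tr)
    ord <- order(as.integer(sub("^t_n", "", s$node)))
    s <- s[ord, ]
    hits <- hits + sum(truth >= s$hpd_younger & truth <= s$hpd_older)
    total <- total + 3
  }
  expect_gt(total, 500)
  expect_equal(hits / total, 0.95, tolerance = 0.03)
})

test_that("EGT gene simulation: vertical genes, clean transfers, robustness", {
  sp <- ape::read.tree(
    text = "(((R1,R2),((C1,C2),(G1,G2))),((O1,O2),(H1,H2)));")
  tax <- stats::setNames(c("Rho", "Rho", "Cry", "Cry", "Glc", "Glc",
                           "Och", "Och", "Hap", "Hap"), sp$tip.label)
  none <- simulate_egt_genes(sp, tax, "Rho", "Cry", n_genes = 5,
                             transfer_fraction = 0, bootstrap_n = 3,
                             epsilon = 0, seed = 12)
  for (g in none) {
    expect_true(ape::all.equal.phylo(g$ml, sp, use.edge.length = FALSE))
    expect_false(g$transferred)
  }
  all_t <- simulate_egt_genes(sp, tax, "Rho", "Cry", n_genes = 5,
                              transfer_fraction = 1, bootstrap_n = 10,
                              epsilon = 0, seed = 13)
  m <- sister_frequencies(all_t[[1]]$bootstrap, tax)
  expect_equal(m$freq["Cry", "Rho"], 1)
  # reproducibility
  again <- simulate_egt_genes(sp, tax, "Rho", "Cry", n_genes = 5,
                              transfer_fraction = 1, bootstrap_n = 10,
                              epsilon = 0, seed = 13)
  expect_identical(lapply(all_t, function(g) ape::write.tree(g$ml)),
                   lapply(again, function(g) ape::write.tree(g$ml)))
  expect_error(simulate_egt_genes(sp, tax, "Rho", "Missing", n_genes = 1,
                                  transfer_fraction = 0, bootstrap_n = 1,
                                  epsilon = 0, seed = 1),
               "no tips labelled")
})

test_that("biased alignments: null calibration and targeted enrichment", {
  taxa <- paste0("t", 1:8)
  # strength 0: H indistinguishable from a column-permutation null
  aln0 <- simulate_biased_alignment(taxa, n_sites = 300, bias_strength = 0,
                                    biased_taxa = taxa[1:4], seed = 14)
  H0 <- compositional_heterogeneity(aln0)
  set.seed(15)
  null_H <- replicate(199, {
    m <- unclass(aln0)
    perm <- matrix(sample(m), nrow = nrow(m),
                   dimnames = dimnames(m))
    compositional_heterogeneity(aa_alignment(perm))
  })
  p <- (1 + sum(null_H >= H0)) / 200
  expect_gt(p, 0.01)
  # strength 0.5: targeted stripping beats random stripping
  set.seed(16)
  wins <- 0
  for (i in 1:100) {
    aln <- simulate_biased_alignment(taxa, n_sites = 120,
                                     biased_taxa = taxa[1:4],
                                     bias_strength = 0.5,
                                     seed = 4000 + i)
    targeted <- compositional_heterogeneity(strip_sites(aln, 0.25))
    keep <- sort(sample(120, 90))
    random <- compositional_heterogeneity(
      aa_alignment(unclass(aln)[, keep, drop = FALSE]))
    if (targeted < random) wins <- wins + 1
  }
  expect_gt(wins, 80)
  # determinism
  a <- simulate_biased_alignment(taxa, n_sites = 50, seed = 17)
  b <- simulate_biased_alignment(taxa, n_sites = 50, seed = 17)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
})
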