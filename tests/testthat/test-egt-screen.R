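# Exhaustive oracle for maximal label-pure clades: enumerate every node,
# test purity from scratch via phangorn::Descendants, filter non-maximal.
pure_clades_oracle <- function(tree, taxonomy) {
  n_tip <- ape::Ntip(tree)
  nn <- n_tip + tree$Nnode
  lab <- taxonomy[tree$tip.label]
  desc <- phangorn::Descendants(tree, seq_len(nn), type = "tips")
  pure <- vapply(seq_len(nn), function(i) {
    l <- unique(lab[desc[[i]]])
    if (length(l) == 1L && !is.na(l)) l else NA_character_
  }, character(1))
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  keep <- Filter(function(i) parent[i] == 0L || is.na(pure[parent[i]]),
                 which(!is.na(pure)))
  lapply(keep, function(i) {
    list(node = i, label = pure[i],
         tips = sort(tree$tip.label[desc[[i]]]))
  })
}

# Oracle for the sister-frequency matrix: re-enumerate everything from
# scratch per tree with the phangorn-based clade scan.
sister_freq_oracle <- function(trees, taxonomy) {
  acc <- list()
  for (tr in trees) {
    parent <- integer(ape::Ntip(tr) + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    desc <- phangorn::Descendants(tr, type = "tips")
    lab <- taxonomy[tr$tip.label]
    for (cl in pure_clades_oracle(tr, taxonomy)) {
      p <- parent[cl$node]
      if (p == 0L) next
      sibs <- setdiff(tr$edge[tr$edge[, 1] == p, 2], cl$node)
      stips <- unlist(desc[sibs])
      comp <- table(lab[stips]) / length(stips)
      row <- acc[[cl$label]]
      if (is.null(row)) row <- numeric(0)
      for (nm in names(comp)) {
        row[nm] <- (if (nm %in% names(row)) row[[nm]] else 0) + comp[[nm]]
      }
      acc[[cl$label]] <- row
    }
  }
  lapply(acc, function(v) v / sum(v))
}

test_that("maximal pure clades: sorted, mixed and random trees", {
  sorted <- ape::read.tree(text = "(((A1,A2),(B1,B2)),(C1,C2));")
  tax <- stats::setNames(substr(sorted$tip.label, 1, 1), sorted$tip.label)
  cl <- label_pure_clades(sorted, tax)
  expect_length(cl, 3L)
  expect_setequal(vapply(cl, `[[`, character(1), "label"),
                  c("A", "B", "C"))
  mixed <- ape::read.tree(text = "((A1,B1),(A2,B2));")
  tax2 <- stats::setNames(substr(mixed$tip.label, 1, 1), mixed$tip.label)
  cl2 <- label_pure_clades(mixed, tax2)
  expect_length(cl2, 4L)
  expect_true(all(lengths(lapply(cl2, `[[`, "tips")) == 1L))
  # random labelled trees vs exhaustive oracle
  for (i in 1:50) {
    fx <- rand_labelled_tree(400 + i, n_tips = sample(5:12, 1))
    got <- label_pure_clades(fx$tree, fx$taxonomy)
    want <- pure_clades_oracle(fx$tree, fx$taxonomy)
    key <- function(cl) paste(cl$label, paste(sort(cl$tips), collapse = ","))
    expect_setequal(vapply(got, key, character(1)),
                    vapply(want, key, character(1)))
  }
})

test_that("sister composition augments mixed sisters in proportion", {
  tr <- ape::read.tree(text = "((A1,A2),(B1,(B2,C1)));")
  tax <- stats::setNames(substr(tr$tip.label, 1, 1), tr$tip.label)
  focal <- ape::getMRCA(tr, c("A1", "A2"))
  comp <- sister_composition(tr, focal, tax)
  expect_equal(comp[["B"]], 2 / 3)
  expect_equal(comp[["C"]], 1 / 3)
  expect_equal(sum(comp), 1)
  tr2 <- ape::read.tree(text = "((A1,A2),(B1,B2));")
  tax2 <- stats::setNames(substr(tr2$tip.label, 1, 1), tr2$tip.label)
  comp2 <- sister_composition(tr2, ape::getMRCA(tr2, c("A1", "A2")), tax2)
  expect_equal(comp2, c(B = 1))
  # 5-tip sister with label counts 3/1/1
  tr3 <- ape::read.tree(text = "((A1,A2),((B1,B2),(B3,(C1,D1))));")
  tax3 <- stats::setNames(substr(tr3$tip.label, 1, 1), tr3$tip.label)
  comp3 <- sister_composition(tr3, ape::getMRCA(tr3, c("A1", "A2")), tax3)
  expect_equal(comp3[["B"]], 0.6)
  expect_equal(comp3[["C"]], 0.2)
  expect_equal(comp3[["D"]], 0.2)
  root <- ape::Ntip(tr3) + 1L
  expect_error(sister_composition(tr3, root, tax3), "no sister")
})

test_that("sister frequencies: hand-enumerated single tree and averaging", {
  tr <- ape::read.tree(text = "(((A1,A2),(B1,B2)),(C1,C2));")
  tax <- stats::setNames(substr(tr$tip.label, 1, 1), tr$tip.label)
  m <- sister_frequencies(tr, tax)
  expect_equal(m$freq["A", "B"], 1)
  expect_equal(m$freq["C", "A"], 0.5)
  expect_equal(m$freq["C", "B"], 0.5)
  # averaging over two trees with different pure-B / pure-C sisters of A
  t1 <- ape::read.tree(text = "(((A1,A2),(B1,B2)),(C1,C2));")
  t2 <- ape::read.tree(text = "(((A1,A2),(C1,C2)),(B1,B2));")
  m2 <- sister_frequencies(list(t1, t2), tax)
  expect_equal(m2$freq["A", "B"], 0.5)
  expect_equal(m2$freq["A", "C"], 0.5)
  expect_equal(m2$n_trees, 2L)
})

test_that("rows are normalized and tip order never matters", {
  for (i in 1:30) {
    fx <- rand_labelled_tree(600 + i, n_tips = sample(6:12, 1),
                             n_groups = 4)
    m <- sister_frequencies(fx$tree, fx$taxonomy)
    if (nrow(m$freq)) {
      expect_equal(unname(rowSums(m$freq)), rep(1, nrow(m$freq)),
                   tolerance = 1e-9)
    }
    rot <- ape::rotate(fx$tree, ape::Ntip(fx$tree) + 1L)
    m2 <- sister_frequencies(rot, fx$taxonomy)
    expect_equal(m$freq[rownames(m$freq), colnames(m$freq), drop = FALSE],
                 m2$freq[rownames(m$freq), colnames(m$freq), drop = FALSE])
  }
})

test_that("sister frequencies equal the exhaustive oracle on small trees", {
  for (i in 1:40) {
    fx <- rand_labelled_tree(700 + i, n_tips = sample(5:12, 1),
                             n_groups = 3)
    m <- sister_frequencies(fx$tree, fx$taxonomy)
    oracle <- sister_freq_oracle(list(fx$tree), fx$taxonomy)
    expect_setequal(rownames(m$freq), names(oracle))
    for (f in names(oracle)) {
      v <- oracle[[f]]
      expect_equal(unname(m$freq[f, names(v)]), unname(v[names(v)]))
      expect_equal(sum(m$freq[f, !colnames(m$freq) %in% names(v)]), 0)
    }
  }
})

test_that("marker screen flags implanted transfers and not vertical genes", {
  sp <- ape::read.tree(
    text = "(((R1,R2),((C1,C2),(G1,G2))),((O1,O2),(H1,H2)));")
  tax <- stats::setNames(c("Rho", "Rho", "Cry", "Cry", "Glc", "Glc",
                           "Och", "Och", "Hap", "Hap"), sp$tip.label)
  pos <- simulate_egt_genes(sp, tax, donor = "Rho", recipient = "Cry",
                            n_genes = 6, transfer_fraction = 1,
                            bootstrap_n = 60, epsilon = 0, seed = 9)
  scr <- screen_markers(pos, tax, expected_sisters = c(Cry = "Glc"),
                        threshold = 0.5)
  flagged <- scr$dominance[scr$dominance$focal == "Cry", ]
  expect_true(all(flagged$non_vertical_dominant))
  expect_true(all(flagged$top_sister == "Rho"))
  expect_true(all(flagged$top_frequency == 1))
  neg <- simulate_egt_genes(sp, tax, donor = "Rho", recipient = "Cry",
                            n_genes = 6, transfer_fraction = 0,
                            bootstrap_n = 60, epsilon = 0, seed = 10)
  scr2 <- screen_markers(neg, tax, expected_sisters = c(Cry = "Glc"),
                         threshold = 0.5)
  expect_false(any(scr2$dominance$non_vertical_dominant))
  # one gene, one tree: pooled matrix equals that gene's matrix
  one <- list(g1 = list(ml = sp, bootstrap = list(sp)))
  scr3 <- screen_markers(one, tax, expected_sisters = c(Cry = "Glc"))
  expect_equal(scr3$pooled$freq, scr3$per_gene$g1$freq)
})

test_that("screen survives moderate bootstrap perturbation", {
  sp <- ape::read.tree(
    text = "(((R1,R2),((C1,C2),(G1,G2))),((O1,O2),(H1,H2)));")
  tax <- stats::setNames(c("Rho", "Rho", "Cry", "Cry", "Glc", "Glc",
                           "Och", "Och", "Hap", "Hap"), sp$tip.label)
  pos <- simulate_egt_genes(sp, tax, donor = "Rho", recipient = "Cry",
                            n_genes = 3, transfer_fraction = 1,
                            bootstrap_n = 150, epsilon = 0.05, seed = 11)
  scr <- screen_markers(pos, tax, expected_sisters = c(Cry = "Glc"))
  cry <- scr$dominance[scr$dominance$focal == "Cry", ]
  expect_true(all(cry$top_sister == "Rho"))
})
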