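# Shared fixture builders. Everything is generated in code; no binary data.

# Random dated chronogram with HPD annotations bracketing each internal age.
rand_annotated_chronogram <- function(seed, n_tips = NULL) {
  set.seed(seed)
  if (is.null(n_tips)) n_tips <- sample(4:12, 1)
  ch <- simulate_dated_tree(n_tips, birth = 0.005, death = 0.001,
                            root_age = stats::runif(1, 500, 2500),
                            seed = seed + 10000L)
  n_tip <- ape::Ntip(ch$phy)
  ids <- (n_tip + 1L):(n_tip + ch$phy$Nnode)
  u <- stats::runif(length(ids), 0.01, 0.3)
  v <- stats::runif(length(ids), 0.01, 0.3)
  ch$hpd_older[ids] <- ch$ages[ids] * (1 + u)
  ch$hpd_younger[ids] <- ch$ages[ids] * (1 - v)
  validate_chronogram(ch)
  ch
}

# Random rooted binary tree with tips labelled by taxonomic group prefix.
rand_labelled_tree <- function(seed, n_tips = 10, n_groups = 3) {
  set.seed(seed)
  phy <- ape::rtree(n_tips, rooted = TRUE)
  phy$edge.length <- NULL
  groups <- paste0("G", seq_len(n_groups))
  tax <- stats::setNames(sample(groups, n_tips, replace = TRUE),
                         phy$tip.label)
  list(tree = phy, taxonomy = tax)
}

# Chronogram rebuilt from a phylo topology and explicit node ages.
chronogram_with_ages <- function(phy, ages, ...) {
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  chronogram(phy, ...)
}

# Parse a chronogram from an inline Newick string.
chronogram_from_test_text <- function(text) {
  tf <- tempfile(fileext = ".nwk")
  on.exit(unlink(tf))
  writeLines(text, tf)
  read_chronogram(tf)
}

# Internal node ids keyed by sorted tip-label sets, independent of the
# serialization order (used to align nodes across a write/read cycle).
clade_keys_for_test <- function(ch) {
  phy <- ch$phy
  n_tip <- ape::Ntip(phy)
  ids <- (n_tip + 1L):(n_tip + phy$Nnode)
  keys <- vapply(ids, function(i) {
    tips <- ape::extract.clade(phy, i)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
  stats::setNames(ids, keys)
}
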