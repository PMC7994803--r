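# Generators for every input the pipeline consumes: dated birth-death
# trees, relaxed-clock branch rates, posterior node-age traces, gene trees
# with implanted endosymbiotic transfers plus bootstrap replicates, and
# compositionally biased alignments. All generators are pure functions of
# their arguments including `seed`.

#' Simulate a dated birth-death tree
#'
#' A rooted binary ultrametric chronogram with `n_tips` extant tips,
#' conditioned on the root age: the `n_tips - 2` non-root divergence times
#' are drawn i.i.d. from the birth-death age density conditioned on the
#' root age (inverse-CDF sampling), and the ranked topology is built by
#' uniformly choosing the lineage that splits at each successive age.
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth,death Per-lineage rates (Myr^-1); `birth > death >= 0`.
#' @param root_age Root age in Ma.
#' @param seed Integer seed.
#' @return A [chronogram()].
#' @export
simulate_dated_tree <- function(n_tips, birth = 1, death = 0,
                                root_age = 1000, seed = 1) {
  stopifnot(n_tips >= 3, birth > death, death >= 0, root_age > 0)
  set.seed(seed)
  # conditioned node-age CDF (ages measured back from the present, root at
  # root_age); reduces to (1 - exp(-b s)) / (1 - exp(-b t)) for death = 0
  r <- birth - death
  t1 <- root_age
  cdf_scale <- (1 - exp(-r * t1)) / (birth - death * exp(-r * t1))
  q_age <- function(u) {
    q <- u * cdf_scale
    -log((1 - q * birth) / (1 - q * death)) / r
  }
  ages <- sort(q_age(stats::runif(n_tips - 2L)), decreasing = TRUE)
  int_ages <- c(t1, ages)                  # internal node ages, root first
  n_int <- n_tips - 1L
  int_ids <- n_tips + seq_len(n_int)       # ape ids in age order
  edges <- matrix(0L, nrow = 2L * n_tips - 2L, ncol = 2L)
  lengths <- numeric(2L * n_tips - 2L)
  n_edge <- 0L
  # active lineages: parent internal id of each open slot
  active <- c(int_ids[1], int_ids[1])
  age_of <- stats::setNames(int_ages, int_ids)
  if (n_int >= 2L) {
    for (j in 2L:n_int) {
      slot <- sample.int(length(active), 1L)
      p <- active[slot]
      n_edge <- n_edge + 1L
      edges[n_edge, ] <- c(p, int_ids[j])
      lengths[n_edge] <- age_of[[as.character(p)]] - int_ages[j]
      active <- c(active[-slot], int_ids[j], int_ids[j])
    }
  }
  for (k in seq_along(active)) {
    n_edge <- n_edge + 1L
    edges[n_edge, ] <- c(active[k], k)
    lengths[n_edge] <- age_of[[as.character(active[k])]]
  }
  phy <- list(edge = edges, edge.length = lengths,
              tip.label = paste0("t", seq_len(n_tips)), Nnode = n_int)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  chronogram(phy)
}

#' Analytic node-age CDF of the conditioned birth-death tree
#'
#' The distribution from which [simulate_dated_tree()] draws its non-root
#' divergence times; exposed for calibration checks.
#'
#' @param s Ages (Ma).
#' @param birth,death Rates.
#' @param root_age Root age (Ma).
#' @return CDF values in `[0, 1]`.
#' @export
bd_age_cdf <- function(s, birth = 1, death = 0, root_age = 1000) {
  r <- birth - death
  num <- (1 - exp(-r * s)) / (birth - death * exp(-r * s))
  den <- (1 - exp(-r * root_age)) / (birth - death * exp(-r * root_age))
  pmin(pmax(num / den, 0), 1)
}

#' Simulate relaxed-clock branch rates on a dated tree
#'
#' Autocorrelated model: rates evolve by geometric Brownian motion, the
#' child's log-rate drawn `Normal(parent log-rate - sigma2 * t / 2,
#' sigma2 * t)` over a branch of duration `t` time units (mean-preserving,
#' so the expected rate stays `mu`). Uncorrelated model: each branch's
#' log-rate is drawn independently `Normal(log mu - sigma2 / 2, sigma2)`.
#' Branch lengths in expected replacements per site are
#' `rate * duration / time_unit`.
#'
#' Default mean rates follow the dating set-up this generator emulates:
#' 0.02625 replacements per site per 100 Myr, with the rate-variance
#' parameter drawn from a Gamma(shape 2, rate 2) hyperprior (mean 1) unless
#' fixed, and a 100 Ma time unit.
#'
#' @param chron A [chronogram()].
#' @param kind `"autocorrelated"` or `"uncorrelated"`.
#' @param mu Mean rate (replacements / site / time unit); default 0.02625.
#' @param sigma2 Rate-variance parameter; `NULL` (default) draws it from
#'   the gamma hyperprior.
#' @param sigma2_shape,sigma2_rate Gamma hyperprior parameters (defaults 2
#'   and 2).
#' @param time_unit Time unit in Ma; default 100.
#' @param seed Integer seed.
#' @return Data frame with one row per edge: `parent`, `child`,
#'   `duration_ma`, `rate`, `expected_subs`; attribute `sigma2` holds the
#'   value used, `node_log_rate` the per-node log rates (autocorrelated
#'   model).
#' @export
simulate_branch_rates <- function(chron,
                                  kind = c("autocorrelated",
                                           "uncorrelated"),
                                  mu = 0.02625, sigma2 = NULL,
                                  sigma2_shape = 2, sigma2_rate = 2,
                                  time_unit = 100, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(chron, "chronogram"), mu > 0)
  set.seed(seed)
  if (is.null(sigma2)) sigma2 <- stats::rgamma(1, shape = sigma2_shape,
                                               rate = sigma2_rate)
  stopifnot(sigma2 >= 0)
  phy <- ape::reorder.phylo(chron$phy, "cladewise")
  ages <- node_ages_from_lengths(phy)
  n_tip <- ape::Ntip(phy)
  root <- n_tip + 1L
  nn <- n_tip + phy$Nnode
  durations <- (ages[phy$edge[, 1]] - ages[phy$edge[, 2]]) / time_unit
  if (kind == "uncorrelated") {
    lograte <- stats::rnorm(nrow(phy$edge), log(mu) - sigma2 / 2,
                            sqrt(sigma2))
    rate <- exp(lograte)
    node_log_rate <- NULL
  } else {
    node_log_rate <- rep(NA_real_, nn)
    node_log_rate[root] <- log(mu)
    # cladewise order guarantees parents precede children
    rate <- numeric(nrow(phy$edge))
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]
      ch <- phy$edge[e, 2]
      t_e <- durations[e]
      node_log_rate[ch] <- stats::rnorm(
        1, node_log_rate[p] - sigma2 * t_e / 2, sqrt(sigma2 * t_e))
      rate[e] <- exp(node_log_rate[ch])
    }
  }
  out <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                    duration_ma = durations * time_unit, rate = rate,
                    expected_subs = rate * durations)
  attr(out, "sigma2") <- sigma2
  attr(out, "node_log_rate") <- node_log_rate
  attr(out, "kind") <- kind
  out
}

#' Simulate a posterior trace of node ages around a chronogram
#'
#' Emulates the output of a Bayesian dating run without running a sampler:
#' for each internal node with true age `theta`, a replicate-specific
#' posterior location is drawn (`log-normal` error with coefficient of
#' variation `cv`), and `n_samples` samples are drawn log-normally around
#' it with the same `cv`, so that a 95% HPD of the samples covers the truth
#' about 95% of the time. Samples violating parent-older-than-child
#' ordering are rejected and redrawn.
#'
#' @param chron A [chronogram()].
#' @param cv Coefficient of variation of the log-normal noise (0 gives a
#'   degenerate trace equal to the truth).
#' @param n_samples Number of MCMC samples to emit.
#' @param seed Integer seed.
#' @param max_reject Maximum rejection attempts per sample before erroring
#'   (advises a smaller `cv`).
#' @return A `posterior_trace` whose columns `t_n<id>` correspond to
#'   internal node ape ids; a bookkeeping column `Gen` is included.
#' @export
simulate_posterior_trace <- function(chron, cv = 0.1, n_samples = 1000,
                                     seed = 1, max_reject = 1000) {
  stopifnot(inherits(chron, "chronogram"), cv >= 0, n_samples >= 1)
  set.seed(seed)
  phy <- chron$phy
  n_tip <- ape::Ntip(phy)
  ids <- (n_tip + 1L):(n_tip + phy$Nnode)
  theta <- chron$ages[ids]
  parent <- node_parents(phy)
  sdlog <- sqrt(log(1 + cv^2))
  # replicate-level posterior location per node
  centre <- log(theta) + stats::rnorm(length(ids), 0, sdlog)
  ord_parent <- match(parent[ids], ids)     # index into ids, NA for root
  draw_row <- function() {
    for (attempt in seq_len(max_reject)) {
      x <- exp(centre + stats::rnorm(length(ids), 0, sdlog))
      ok <- TRUE
      if (any(!is.na(ord_parent))) {
        ok <- all(x[!is.na(ord_parent)] <=
                    x[ord_parent[!is.na(ord_parent)]])
      }
      if (ok) return(x)
    }
    stop("rejection rate too high; use a smaller cv", call. = FALSE)
  }
  mat <- if (cv == 0) {
    matrix(rep(theta, each = n_samples), nrow = n_samples)
  } else {
    t(vapply(seq_len(n_samples), function(i) draw_row(),
             numeric(length(ids))))
  }
  samples <- as.data.frame(mat)
  names(samples) <- paste0("t_n", ids)
  samples <- cbind(Gen = seq_len(n_samples), samples)
  posterior_trace(samples)
}

# One rooted NNI move across the internal edge above `child`: swap a random
# child of `child` with its sibling subtree.
rooted_nni <- function(phy, edge_idx) {
  p <- phy$edge[edge_idx, 1]
  ch <- phy$edge[edge_idx, 2]
  n_tip <- ape::Ntip(phy)
  if (ch <= n_tip) return(phy)             # needs an internal child
  sibs <- phy$edge[phy$edge[, 1] == p, 2]
  sibs <- sibs[sibs != ch]
  if (!length(sibs)) return(phy)
  sib <- sibs[sample.int(length(sibs), 1L)]
  kids <- which(phy$edge[, 1] == ch)
  k <- kids[sample.int(length(kids), 1L)]
  sib_edge <- which(phy$edge[, 2] == sib)
  # swap endpoints: sibling moves below ch, grandchild moves below p
  phy$edge[sib_edge, 1] <- ch
  phy$edge[k, 1] <- p
  phy
}

perturb_tree_nni <- function(phy, epsilon) {
  internal <- which(phy$edge[, 2] > ape::Ntip(phy))
  if (!length(internal)) return(phy)
  n_moves <- stats::rbinom(1, length(internal), epsilon)
  if (n_moves == 0L) return(phy)
  for (m in seq_len(n_moves)) {
    internal <- which(phy$edge[, 2] > ape::Ntip(phy))
    e <- internal[sample.int(length(internal), 1L)]
    phy <- rooted_nni(phy, e)
  }
  # topology-only output
  phy$edge.length <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Simulate marker gene trees with an implanted endosymbiotic transfer
#'
#' For a `transfer_fraction` of genes the recipient clade is pruned from
#' the species tree and regrafted as sister to the donor clade (the
#' topological signature of endosymbiotic gene replacement); the remaining
#' genes keep the species topology. Bootstrap replicates are emulated by
#' random rooted NNI moves applied with per-internal-branch probability
#' `epsilon`, giving direct control of topological noise.
#'
#' @param species_tree Rooted `phylo` or [chronogram()].
#' @param taxonomy Named character vector, tip name -> group label.
#' @param donor,recipient Group labels; each must be monophyletic in the
#'   species tree.
#' @param n_genes Number of marker genes.
#' @param transfer_fraction Fraction of genes carrying the transfer.
#' @param bootstrap_n Bootstrap replicates per gene; default 1000, the
#'   ultrafast-bootstrap sample size this generator emulates.
#' @param epsilon Per-internal-branch NNI perturbation probability.
#' @param seed Integer seed.
#' @return Named list of genes, each a list with `ml` (rooted `phylo`),
#'   `bootstrap` (list of rooted trees) and `transferred` (logical).
#' @export
simulate_egt_genes <- function(species_tree, taxonomy, donor, recipient,
                               n_genes = 10, transfer_fraction = 0.5,
                               bootstrap_n = 1000, epsilon = 0.05,
                               seed = 1) {
  if (inherits(species_tree, "chronogram")) species_tree <- species_tree$phy
  stopifnot(ape::is.rooted(species_tree),
            transfer_fraction >= 0, transfer_fraction <= 1,
            epsilon >= 0, epsilon <= 1)
  set.seed(seed)
  lab <- taxonomy[species_tree$tip.label]
  for (grp in c(donor, recipient)) {
    tips <- species_tree$tip.label[!is.na(lab) & lab == grp]
    if (length(tips) == 0L) stop("no tips labelled '", grp, "'",
                                 call. = FALSE)
    if (length(tips) > 1L) {
      m <- ape::getMRCA(species_tree, tips)
      desc <- clade_tip_sets(species_tree)[[m]]
      if (!setequal(species_tree$tip.label[desc], tips)) {
        stop("label '", grp, "' is not monophyletic in the species tree",
             call. = FALSE)
      }
    }
  }
  base <- species_tree
  base$edge.length <- NULL
  transferred_tree <- implant_transfer(base, taxonomy, donor, recipient)
  n_transfer <- round(transfer_fraction * n_genes)
  is_transfer <- c(rep(TRUE, n_transfer), rep(FALSE, n_genes - n_transfer))
  genes <- lapply(seq_len(n_genes), function(i) {
    ml <- if (is_transfer[i]) transferred_tree else base
    boots <- lapply(seq_len(bootstrap_n), function(b) {
      perturb_tree_nni(ml, epsilon)
    })
    list(ml = ml, bootstrap = boots, transferred = is_transfer[i])
  })
  names(genes) <- paste0("gene", seq_len(n_genes))
  genes
}

# Prune the recipient clade and regraft it as sister to the donor clade.
implant_transfer <- function(phy, taxonomy, donor, recipient) {
  lab <- taxonomy[phy$tip.label]
  rec_tips <- phy$tip.label[!is.na(lab) & lab == recipient]
  pruned <- ape::drop.tip(phy, rec_tips)
  pruned$edge.length <- rep(1, nrow(pruned$edge))
  lab_p <- taxonomy[pruned$tip.label]
  don_tips <- pruned$tip.label[!is.na(lab_p) & lab_p == donor]
  where <- if (length(don_tips) == 1L) {
    match(don_tips, pruned$tip.label)
  } else {
    ape::getMRCA(pruned, don_tips)
  }
  graft <- if (length(rec_tips) == 1L) {
    # bind.tree needs a proper phylo; build a 1-tip tree
    structure(list(edge = matrix(c(2L, 1L), 1, 2),
                   tip.label = rec_tips, Nnode = 1L,
                   edge.length = 1), class = "phylo")
  } else {
    g <- ape::keep.tip(phy, rec_tips)
    g$edge.length <- rep(1, nrow(g$edge))
    g
  }
  graft$root.edge <- 1   # keep the graft a clade (avoid polytomy fusion)
  out <- ape::bind.tree(pruned, graft, where = where, position = 0.5)
  out <- ape::collapse.singles(out)
  out$edge.length <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Simulate a compositionally biased protein alignment
#'
#' Unbiased taxa draw residues i.i.d. from `base_freqs`; biased taxa draw,
#' with probability `bias_strength`, from a uniform distribution over
#' `biased_residues` instead. `bias_strength = 0` recovers the homogeneous
#' null.
#'
#' @param taxa Character vector of taxon names.
#' @param n_sites Number of sites.
#' @param biased_taxa Subset of `taxa` receiving the bias.
#' @param bias_strength Mixture weight in `[0, 1]`.
#' @param base_freqs Named numeric vector over the 20 amino acids
#'   (defaults to uniform); normalized internally.
#' @param biased_residues Residues favoured by biased taxa; default
#'   `c("A", "I", "L", "V")`.
#' @param seed Integer seed.
#' @return An [aa_alignment()].
#' @export
simulate_biased_alignment <- function(taxa, n_sites = 500,
                                      biased_taxa = character(0),
                                      bias_strength = 0.5,
                                      base_freqs = NULL,
                                      biased_residues = c("A", "I", "L",
                                                          "V"),
                                      seed = 1) {
  stopifnot(bias_strength >= 0, bias_strength <= 1,
            all(biased_taxa %in% taxa))
  set.seed(seed)
  if (is.null(base_freqs)) {
    base_freqs <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  base_freqs <- base_freqs[AA_ALPHABET]
  base_freqs[is.na(base_freqs)] <- 0
  base_freqs <- base_freqs / sum(base_freqs)
  stopifnot(all(biased_residues %in% AA_ALPHABET))
  bias_freqs <- stats::setNames(rep(0, 20), AA_ALPHABET)
  bias_freqs[biased_residues] <- 1 / length(biased_residues)
  mix <- (1 - bias_strength) * base_freqs + bias_strength * bias_freqs
  m <- matrix("", nrow = length(taxa), ncol = n_sites,
              dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    f <- if (taxa[i] %in% biased_taxa) mix else base_freqs
    m[i, ] <- sample(AA_ALPHABET, n_sites, replace = TRUE, prob = f)
  }
  aa_alignment(m)
}
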