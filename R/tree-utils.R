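# Shared tree helpers (internal).

# List, indexed by ape node id, of the tip indices descending from each node
# (a tip's set is itself). Single postorder sweep.
clade_tip_sets <- function(phy) {
  n_tip <- ape::Ntip(phy)
  nn <- n_tip + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Parent of each node (0 for root), indexed by ape node id.
node_parents <- function(phy) {
  nn <- ape::Ntip(phy) + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  parent
}

# MRCA of a set of tip labels; errors if any label is missing.
mrca_of_tips <- function(phy, tips) {
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) {
    stop("tips not in tree: ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(phy, idx)
}
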