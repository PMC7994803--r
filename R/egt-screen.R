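# Endosymbiotic-gene-transfer screen: per marker gene, the relative
# frequencies with which each taxonomic group appears as the closest sister
# of each label-pure clade, averaged over bootstrap trees.

tip_labels_for_tree <- function(phy, taxonomy, ignore_unmapped = FALSE) {
  lab <- taxonomy[phy$tip.label]
  if (anyNA(lab)) {
    if (!ignore_unmapped) {
      stop("unmapped tips: ",
           paste(phy$tip.label[is.na(lab)], collapse = ", "),
           "; map them or set ignore_unmapped = TRUE", call. = FALSE)
    }
  }
  unname(lab)
}

ensure_rooted <- function(phy, rooting = c("error", "midpoint")) {
  rooting <- match.arg(rooting)
  if (ape::is.rooted(phy)) return(phy)
  if (rooting == "error") {
    stop("tree is unrooted; supply rooting = \"midpoint\"", call. = FALSE)
  }
  phangorn::midpoint(phy)
}

#' Maximal label-pure clades of a rooted tree
#'
#' Returns every clade (including single tips) whose tips all carry the same
#' taxonomy label and that is not contained in a larger pure clade of the
#' same label.
#'
#' @param tree Rooted `phylo`.
#' @param taxonomy Named character vector, tip name -> group label.
#' @param ignore_unmapped Drop unmapped tips from consideration instead of
#'   erroring; an unmapped tip breaks the purity of any clade containing it.
#' @param rooting `"error"` (default) or `"midpoint"` for unrooted input.
#' @return List of clades; each a list with `node` (ape id), `label`,
#'   `tips` (character).
#' @examples
#' tr <- ape::read.tree(text = "(((A1,A2),(B1,B2)),(C1,C2));")
#' tax <- setNames(substr(tr$tip.label, 1, 1), tr$tip.label)
#' length(label_pure_clades(tr, tax))   # 3
#' @export
label_pure_clades <- function(tree, taxonomy, ignore_unmapped = FALSE,
                              rooting = c("error", "midpoint")) {
  tree <- ensure_rooted(tree, rooting)
  lab <- tip_labels_for_tree(tree, taxonomy, ignore_unmapped)
  n_tip <- ape::Ntip(tree)
  nn <- n_tip + tree$Nnode
  sets <- clade_tip_sets(tree)
  parent <- node_parents(tree)
  # purity label per node: the single label of all mapped descendant tips,
  # NA if mixed or if any descendant tip is unmapped
  pure <- rep(NA_character_, nn)
  for (i in seq_len(nn)) {
    l <- unique(lab[sets[[i]]])
    if (length(l) == 1L && !is.na(l)) pure[i] <- l
  }
  out <- list()
  for (i in seq_len(nn)) {
    if (is.na(pure[i])) next
    p <- parent[i]
    if (p != 0L && !is.na(pure[p])) next   # contained in a larger pure clade
    out[[length(out) + 1L]] <- list(node = i, label = pure[i],
                                    tips = tree$tip.label[sets[[i]]])
  }
  out
}

#' Label composition of a clade's sister group
#'
#' The sister is the union of the other children of the clade's parent
#' (polytomies pool all siblings). When the sister contains mixed taxonomy,
#' each label is credited in proportion to its tip count, so the fractions
#' sum to 1.
#'
#' @param tree Rooted `phylo`.
#' @param node ape node id of the focal clade (must not be the root).
#' @param taxonomy Named character vector, tip name -> group label.
#' @param ignore_unmapped Drop unmapped sister tips from the composition.
#' @return Named numeric vector of label fractions summing to 1.
#' @export
sister_composition <- function(tree, node, taxonomy,
                               ignore_unmapped = FALSE) {
  stopifnot(ape::is.rooted(tree))
  parent <- node_parents(tree)
  p <- parent[node]
  if (p == 0L) stop("focal clade is the entire tree; it has no sister",
                    call. = FALSE)
  sets <- clade_tip_sets(tree)
  sibs <- tree$edge[tree$edge[, 1] == p, 2]
  sibs <- sibs[sibs != node]
  sister_tips <- unlist(sets[sibs], use.names = FALSE)
  lab <- tip_labels_for_tree(tree, taxonomy, ignore_unmapped)[sister_tips]
  lab <- lab[!is.na(lab)]
  if (!length(lab)) {
    stop("sister clade contains no mapped tips", call. = FALSE)
  }
  tab <- table(lab)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Sister-group frequency matrix over a set of trees
#'
#' For every tree (typically bootstrap replicates of one marker gene) and
#' every maximal label-pure clade in it, the label composition of the
#' clade's sister group is accumulated into the focal label's row; each row
#' is finally normalized by its accumulated mass. Maximal pure clades are
#' re-identified independently in every tree. Each pure clade contributes
#' weight 1 per tree regardless of its tip count.
#'
#' @param trees List of rooted `phylo` objects (`multiPhylo` accepted).
#' @param taxonomy Named character vector, tip name -> group label.
#' @param ignore_unmapped Passed to [label_pure_clades()].
#' @param rooting `"error"` or `"midpoint"` for unrooted inputs.
#' @return A `sister_freq_matrix`: list with `freq` (matrix, focal labels x
#'   sister labels, rows summing to 1), `clade_counts` (contributing clades
#'   per focal label), `n_trees`, `notes` (labels never forming a pure
#'   clade).
#' @export
sister_frequencies <- function(trees, taxonomy, ignore_unmapped = FALSE,
                               rooting = c("error", "midpoint")) {
  rooting <- match.arg(rooting)
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  acc <- list()          # focal label -> named numeric accumulator
  counts <- integer(0)   # focal label -> contributing clades
  for (tr in trees) {
    tr <- ensure_rooted(tr, rooting)
    clades <- label_pure_clades(tr, taxonomy,
                                ignore_unmapped = ignore_unmapped)
    parent <- node_parents(tr)
    for (cl in clades) {
      if (parent[cl$node] == 0L) next    # whole tree is pure: no sister
      comp <- sister_composition(tr, cl$node, taxonomy,
                                 ignore_unmapped = ignore_unmapped)
      cur <- acc[[cl$label]]
      if (is.null(cur)) cur <- numeric(0)
      for (nm in names(comp)) {
        cur[nm] <- (if (nm %in% names(cur)) cur[[nm]] else 0) + comp[[nm]]
      }
      acc[[cl$label]] <- cur
      counts[cl$label] <- (if (cl$label %in% names(counts))
                             counts[[cl$label]] else 0L) + 1L
    }
  }
  all_labels <- sort(unique(stats::na.omit(unname(taxonomy))))
  focal <- sort(names(acc))
  sister <- sort(unique(c(unlist(lapply(acc, names)), character(0))))
  freq <- matrix(0, nrow = length(focal), ncol = length(sister),
                 dimnames = list(focal, sister))
  for (f in focal) {
    v <- acc[[f]]
    freq[f, names(v)] <- v / sum(v)
  }
  notes <- setdiff(all_labels, focal)
  structure(list(freq = freq, clade_counts = counts[focal],
                 n_trees = length(trees), notes = notes),
            class = "sister_freq_matrix")
}

#' @export
print.sister_freq_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Sister-group frequencies over %d tree(s), %d focal label(s)\n",
              x$n_trees, nrow(x$freq)))
  print(round(x$freq, digits))
  if (length(x$notes)) {
    cat("  labels never forming a pure clade:",
        paste(x$notes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a sister-frequency matrix as TSV (wide and long formats)
#' @param x A `sister_freq_matrix`.
#' @param path Output path for the wide matrix; a companion
#'   `<path>.long.tsv` holds the long format.
#' @return `path`, invisibly.
#' @export
write_sister_frequencies <- function(x, path) {
  stopifnot(inherits(x, "sister_freq_matrix"))
  wide <- data.frame(focal = rownames(x$freq), x$freq, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long <- expand.grid(focal = rownames(x$freq), sister = colnames(x$freq),
                      stringsAsFactors = FALSE)
  long$frequency <- as.vector(x$freq)
  utils::write.table(long, paste0(path, ".long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen marker genes for dominant non-vertical sister signal
#'
#' Computes a sister-frequency matrix per gene from its bootstrap trees,
#' flags focal labels whose top sister differs from the expected (vertical)
#' sister with frequency at or above the dominance threshold, and pools the
#' per-gene matrices with equal gene weighting.
#'
#' @param genes List of genes; each element a list with components `ml`
#'   (rooted `phylo`) and `bootstrap` (list/`multiPhylo` of rooted trees).
#'   When `bootstrap` is empty the ML tree alone is used.
#' @param taxonomy Named character vector, tip name -> group label.
#' @param expected_sisters Named character vector: focal label -> the
#'   sister label expected under vertical descent.
#' @param threshold Dominance threshold on the top sister frequency;
#'   default 0.5.
#' @param ignore_unmapped,rooting Passed through to
#'   [sister_frequencies()].
#' @return An `egt_screen`: list with `per_gene` (list of
#'   `sister_freq_matrix`), `dominance` (data frame: gene, focal,
#'   top_sister, top_frequency, expected, non_vertical_dominant), `pooled`
#'   (equal-weight average matrix), `skipped` (character vector of
#'   unreadable genes).
#' @export
screen_markers <- function(genes, taxonomy, expected_sisters,
                           threshold = 0.5, ignore_unmapped = FALSE,
                           rooting = c("error", "midpoint")) {
  rooting <- match.arg(rooting)
  stopifnot(length(genes) >= 1)
  nms <- names(genes)
  if (is.null(nms)) nms <- paste0("gene", seq_along(genes))
  per_gene <- list()
  skipped <- character(0)
  dom <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    trees <- if (!is.null(g$bootstrap) && length(g$bootstrap)) g$bootstrap
             else list(g$ml)
    m <- tryCatch(
      sister_frequencies(trees, taxonomy,
                         ignore_unmapped = ignore_unmapped,
                         rooting = rooting),
      error = function(e) e)
    if (inherits(m, "error")) {
      warning("gene '", nms[i], "' skipped: ", conditionMessage(m),
              call. = FALSE)
      skipped <- c(skipped, nms[i])
      next
    }
    per_gene[[nms[i]]] <- m
    for (f in rownames(m$freq)) {
      j <- which.max(m$freq[f, ])
      top <- colnames(m$freq)[j]
      top_f <- m$freq[f, j]
      expd <- if (f %in% names(expected_sisters)) expected_sisters[[f]]
              else NA_character_
      flag <- !is.na(expd) && top != expd && top_f >= threshold
      dom[[length(dom) + 1L]] <- data.frame(
        gene = nms[i], focal = f, top_sister = top, top_frequency = top_f,
        expected = expd, non_vertical_dominant = flag,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(per_gene)) stop("no readable genes", call. = FALSE)
  dominance <- do.call(rbind, dom)
  rownames(dominance) <- NULL
  pooled <- pool_matrices(per_gene)
  structure(list(per_gene = per_gene, dominance = dominance,
                 pooled = pooled, skipped = skipped, threshold = threshold),
            class = "egt_screen")
}

# Equal-weight average of sister_freq_matrix objects (rows averaged over
# the genes in which the focal label appears; rows remain normalized).
pool_matrices <- function(mats) {
  focal <- sort(unique(unlist(lapply(mats, function(m) rownames(m$freq)))))
  sister <- sort(unique(unlist(lapply(mats, function(m) colnames(m$freq)))))
  acc <- matrix(0, length(focal), length(sister),
                dimnames = list(focal, sister))
  nref <- stats::setNames(integer(length(focal)), focal)
  for (m in mats) {
    for (f in rownames(m$freq)) {
      acc[f, colnames(m$freq)] <- acc[f, colnames(m$freq)] + m$freq[f, ]
      nref[f] <- nref[f] + 1L
    }
  }
  freq <- acc / nref[rownames(acc)]
  structure(list(freq = freq, clade_counts = nref, n_trees = NA_integer_,
                 notes = character(0)),
            class = "sister_freq_matrix")
}

#' @export
print.egt_screen <- function(x, ...) {
  flagged <- x$dominance[x$dominance$non_vertical_dominant, , drop = FALSE]
  cat(sprintf("EGT screen: %d gene(s), dominance threshold %.2f\n",
              length(x$per_gene), x$threshold))
  if (nrow(flagged) == 0L) {
    cat("  no dominant non-vertical signals detected\n")
  } else {
    cat(sprintf("  %d dominant non-vertical signal(s):\n", nrow(flagged)))
    print.data.frame(flagged)
  }
  if (length(x$skipped)) {
    cat("  skipped genes:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Heatmap of a sister-frequency matrix
#' @param x A `sister_freq_matrix`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sister_freq_matrix <- function(x, ...) {
  m <- x$freq
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "sister label", ylab = "focal label",
                  ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1, cex.axis = 0.7)
  invisible(x)
}
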