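#' Dated phylogeny with node ages and HPD annotations
#'
#' A `chronogram` wraps a rooted `ape::phylo` tree whose branch lengths are in
#' Ma, together with per-node age point estimates, optional 95% (or other
#' mass) HPD intervals, and optional tip taxonomy labels. Node indexing
#' follows ape: tips `1..n`, internal nodes `n+1..n+Nnode`, root `n+1`.
#'
#' Ages are measured in Ma before present: they are computed as the maximum
#' root-to-tip path length minus the node's depth, so in an ultrametric tree
#' all tips sit at age 0.
#'
#' @param phy A rooted `phylo` with branch lengths in Ma.
#' @param hpd_older,hpd_younger Optional numeric vectors (length
#'   `Ntip + Nnode`) of HPD bounds per node; `NA` where absent.
#' @param taxonomy Optional named character vector mapping tip name to group
#'   label.
#' @param node_labels Optional character vector of node labels (length
#'   `Ntip + Nnode`).
#' @param validate Check internal consistency (default `TRUE`).
#' @param tol Numeric tolerance for age comparisons.
#' @return An object of class `chronogram`: a list with elements `phy`,
#'   `ages`, `hpd_older`, `hpd_younger`, `taxonomy`, `node_labels`.
#' @seealso [read_chronogram()], [write_chronogram()],
#'   [lineage_windows_from_chronogram()]
#' @export
chronogram <- function(phy, hpd_older = NULL, hpd_younger = NULL,
                       taxonomy = NULL, node_labels = NULL,
                       validate = TRUE, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("chronogram requires a rooted tree",
                                 call. = FALSE)
  if (is.null(phy$edge.length)) stop("chronogram requires branch lengths",
                                     call. = FALSE)
  nn <- ape::Ntip(phy) + phy$Nnode
  ages <- node_ages_from_lengths(phy)
  if (is.null(hpd_older)) hpd_older <- rep(NA_real_, nn)
  if (is.null(hpd_younger)) hpd_younger <- rep(NA_real_, nn)
  if (is.null(node_labels)) node_labels <- rep(NA_character_, nn)
  stopifnot(length(hpd_older) == nn, length(hpd_younger) == nn)
  x <- structure(list(phy = phy, ages = ages,
                      hpd_older = as.numeric(hpd_older),
                      hpd_younger = as.numeric(hpd_younger),
                      taxonomy = taxonomy,
                      node_labels = node_labels),
                 class = "chronogram")
  if (validate) validate_chronogram(x, tol = tol)
  x
}

node_ages_from_lengths <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

node_name <- function(x, node) {
  n_tip <- ape::Ntip(x$phy)
  if (node <= n_tip) return(x$phy$tip.label[node])
  lbl <- x$node_labels[node]
  if (!is.na(lbl) && nzchar(lbl)) lbl else paste0("node ", node)
}

#' Validate the internal consistency of a chronogram
#'
#' Checks that (i) every parent node is at least as old as each of its
#' children (ultrametric consistency of ages, within `tol`), and (ii) where an
#' HPD annotation is present, it is a proper interval bracketing the node's
#' point age.
#'
#' @param x A [chronogram()].
#' @param tol Numeric tolerance in Ma.
#' @return `x`, invisibly; errors describe the offending node.
#' @export
validate_chronogram <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "chronogram"))
  ed <- x$phy$edge
  bad <- which(x$ages[ed[, 2]] > x$ages[ed[, 1]] + tol)
  if (length(bad)) {
    stop("chronogram invalid: child older than parent at ",
         node_name(x, ed[bad[1], 2]), " (child age ",
         signif(x$ages[ed[bad[1], 2]], 6), " > parent age ",
         signif(x$ages[ed[bad[1], 1]], 6), ")", call. = FALSE)
  }
  has <- !is.na(x$hpd_older) & !is.na(x$hpd_younger)
  if (any(has)) {
    idx <- which(has)
    rev_ok <- x$hpd_older[idx] >= x$hpd_younger[idx] - tol
    if (!all(rev_ok)) {
      b <- idx[which(!rev_ok)[1]]
      stop("chronogram invalid: HPD with younger > older at ",
           node_name(x, b), call. = FALSE)
    }
    inside <- x$ages[idx] >= x$hpd_younger[idx] - tol &
      x$ages[idx] <= x$hpd_older[idx] + tol
    if (!all(inside)) {
      b <- idx[which(!inside)[1]]
      stop("chronogram invalid: age ", signif(x$ages[b], 6),
           " outside HPD [", x$hpd_older[b], ", ", x$hpd_younger[b],
           "] at ", node_name(x, b), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.chronogram <- function(x, ...) {
  n_hpd <- sum(!is.na(x$hpd_older) & !is.na(x$hpd_younger))
  cat(sprintf("Chronogram: %d tips, %d internal nodes, root age %.4g Ma\n",
              ape::Ntip(x$phy), x$phy$Nnode, max(x$ages)))
  cat(sprintf("  %d node(s) carry HPD annotations%s\n", n_hpd,
              if (is.null(x$taxonomy)) "" else "; taxonomy attached"))
  invisible(x)
}

#' Node ages of a chronogram
#' @param x A [chronogram()].
#' @return Numeric vector of ages (Ma) indexed by ape node id.
#' @export
node_ages <- function(x) {
  stopifnot(inherits(x, "chronogram"))
  x$ages
}

#' HPD interval stored at a node
#' @param x A [chronogram()].
#' @param node ape node id.
#' @return A [time_interval()], or `NULL` if the node carries no HPD.
#' @export
node_hpd <- function(x, node) {
  stopifnot(inherits(x, "chronogram"))
  if (is.na(x$hpd_older[node]) || is.na(x$hpd_younger[node])) return(NULL)
  time_interval(x$hpd_older[node], x$hpd_younger[node])
}

#' Attach a taxonomy map to a chronogram
#' @param x A [chronogram()].
#' @param taxonomy Named character vector (tip name -> group label), e.g. from
#'   [read_taxonomy_map()].
#' @return The chronogram with `$taxonomy` set.
#' @export
set_taxonomy <- function(x, taxonomy) {
  stopifnot(inherits(x, "chronogram"))
  missing <- setdiff(x$phy$tip.label, names(taxonomy))
  if (length(missing)) {
    stop("taxonomy map lacks tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x$taxonomy <- taxonomy
  x
}

#' @export
as.phylo.chronogram <- function(x, ...) x$phy
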