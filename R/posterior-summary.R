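#' Highest posterior density interval of a sample of ages
#'
#' The shortest contiguous interval over the sorted samples containing
#' `ceiling(mass * n)` samples. When several windows tie on width the one
#' with the smallest younger bound is returned, making the output
#' deterministic.
#'
#' @param samples Numeric vector of ages (Ma); at least 2 values.
#' @param mass HPD mass in (0, 1); default 0.95.
#' @return A [time_interval()].
#' @examples
#' hpd_interval(0:999, 0.95)   # width 949
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 2L) {
    stop("hpd_interval needs at least 2 samples", call. = FALSE)
  }
  if (!(mass > 0 && mass < 1)) {
    stop("hpd_interval mass must be in (0, 1)", call. = FALSE)
  }
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k > n) k <- n
  lower <- s[seq_len(n - k + 1L)]
  upper <- s[seq.int(k, n)]
  widths <- upper - lower
  i <- which.min(widths)      # first minimum = smallest younger bound
  time_interval(older = upper[i], younger = lower[i])
}

#' Summarize a posterior trace of node ages
#'
#' Produces one row per node-age column: posterior mean, median and HPD
#' interval at the stated mass, plus analysis-level statistics (median of
#' node medians, median of node means, median HPD width). Sampler
#' bookkeeping columns are excluded by a name pattern.
#'
#' @param trace A `posterior_trace` (see [read_trace()]).
#' @param mass HPD mass; default 0.95.
#' @param exclude Regular expression for bookkeeping columns to drop
#'   (case-insensitive).
#' @return A `trace_summary`: data frame with columns `node`, `mean`,
#'   `median`, `hpd_older`, `hpd_younger`, and attributes
#'   `median_of_medians`, `median_of_means`, `median_hpd_width`, `mass`.
#' @export
summarize_trace <- function(trace, mass = 0.95,
                            exclude = "^(gen|iter|state|sample|lnl|loglik|likelihood|prior|posterior)") {
  stopifnot(inherits(trace, "posterior_trace"))
  kept <- retained_samples(trace)
  cols <- names(kept)[!grepl(exclude, names(kept), ignore.case = TRUE)]
  if (!length(cols)) stop("no node-age columns left after exclusion",
                          call. = FALSE)
  rows <- lapply(cols, function(cn) {
    v <- kept[[cn]]
    h <- if (length(unique(v)) == 1L) {
      time_interval(v[1], v[1])
    } else {
      hpd_interval(v, mass)
    }
    data.frame(node = cn, mean = mean(v), median = stats::median(v),
               hpd_older = h$older, hpd_younger = h$younger,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "median_of_medians") <- stats::median(out$median)
  attr(out, "median_of_means") <- stats::median(out$mean)
  attr(out, "median_hpd_width") <- stats::median(out$hpd_older -
                                                   out$hpd_younger)
  attr(out, "mass") <- mass
  class(out) <- c("trace_summary", class(out))
  out
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf("Node-age summary (%d nodes, %.0f%% HPD)\n", nrow(x),
              100 * attr(x, "mass")))
  cat(sprintf("  median of node medians: %.4g Ma | of node means: %.4g Ma | median HPD width: %.4g Ma\n",
              attr(x, "median_of_medians"), attr(x, "median_of_means"),
              attr(x, "median_hpd_width")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a trace summary as TSV
#' @param x A `trace_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_summary <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Key internal clades of a chronogram by sorted tip-label sets.
clade_keys <- function(x) {
  phy <- x$phy
  n_tip <- ape::Ntip(phy)
  tips <- clade_tip_sets(phy)
  ids <- (n_tip + 1L):(n_tip + phy$Nnode)
  keys <- vapply(ids, function(i) {
    paste(sort(phy$tip.label[tips[[i]]]), collapse = "\r")
  }, character(1))
  stats::setNames(ids, keys)
}

#' Compare node ages between two chronograms of identical topology
#'
#' Internal nodes are matched by their tip sets. Reports per-node age
#' differences (`b - a`), the fraction of nodes shifted strictly towards the
#' present in `b`, the mean shift magnitude among shifted nodes, the median
#' signed age difference, and the median HPD-width difference where both
#' trees carry HPDs.
#'
#' @param a,b [chronogram()] objects over the same tip set and topology.
#' @return An `analysis_comparison`: list with `per_node` data frame and
#'   scalar summary statistics.
#' @export
compare_chronograms <- function(a, b) {
  stopifnot(inherits(a, "chronogram"), inherits(b, "chronogram"))
  ka <- clade_keys(a)
  kb <- clade_keys(b)
  only_a <- setdiff(names(ka), names(kb))
  only_b <- setdiff(names(kb), names(ka))
  if (length(only_a) || length(only_b)) {
    fmt_key <- function(k) paste0("{", gsub("\r", ",", k), "}")
    stop("chronogram topologies differ; unmatched clades: ",
         paste(vapply(c(only_a, only_b), fmt_key, character(1)),
               collapse = " "), call. = FALSE)
  }
  keys <- names(ka)
  ia <- unname(ka[keys])
  ib <- unname(kb[keys])
  diff <- b$ages[ib] - a$ages[ia]
  wa <- a$hpd_older[ia] - a$hpd_younger[ia]
  wb <- b$hpd_older[ib] - b$hpd_younger[ib]
  per_node <- data.frame(clade = gsub("\r", ",", keys),
                         age_a = a$ages[ia], age_b = b$ages[ib],
                         diff = diff, width_a = wa, width_b = wb,
                         stringsAsFactors = FALSE)
  shifted <- diff < 0
  width_diff <- wb - wa
  out <- list(
    per_node = per_node,
    fraction_shifted_younger = mean(shifted),
    mean_shift_younger = if (any(shifted)) mean(-diff[shifted]) else 0,
    median_age_difference = stats::median(diff),
    median_width_difference = if (all(is.na(width_diff))) NA_real_
                              else stats::median(width_diff, na.rm = TRUE)
  )
  class(out) <- "analysis_comparison"
  out
}

#' @export
print.analysis_comparison <- function(x, ...) {
  cat(sprintf("Chronogram comparison over %d internal nodes\n",
              nrow(x$per_node)))
  cat(sprintf("  shifted younger: %.1f%% (mean shift %.4g Ma among shifted)\n",
              100 * x$fraction_shifted_younger, x$mean_shift_younger))
  cat(sprintf("  median age difference (b - a): %.4g Ma\n",
              x$median_age_difference))
  if (!is.na(x$median_width_difference)) {
    cat(sprintf("  median HPD-width difference: %.4g Ma\n",
                x$median_width_difference))
  }
  invisible(x)
}

#' Write an analysis comparison as TSV (per-node rows + summary footer)
#' @param x An `analysis_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "analysis_comparison"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(x$per_node, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# fraction_shifted_younger\t%g\n# mean_shift_younger\t%g\n# median_age_difference\t%g\n# median_width_difference\t%g\n",
              x$fraction_shifted_younger, x$mean_shift_younger,
              x$median_age_difference, x$median_width_difference),
      file = con)
  invisible(path)
}

#' Rank gene trees by clock-likeness (root-to-tip variance)
#'
#' Ranks trees ascending by the variance of root-to-tip path lengths, the
#' statistic used to pick the most clock-like genes for dating. A perfectly
#' ultrametric tree has variance 0 and ranks first. This intentionally uses
#' the root-to-tip criterion only (no bipartition-support filter).
#'
#' @param gene_trees List of rooted `phylo` objects with branch lengths
#'   (a `multiPhylo` is accepted). Unrooted trees are an error unless
#'   `rooting = "midpoint"`.
#' @param rooting `"error"` (default) or `"midpoint"` for unrooted inputs.
#' @param top Optionally return only the `top` most clock-like genes.
#' @return Data frame with columns `gene`, `root_to_tip_variance`, `rank`,
#'   ordered by rank.
#' @export
clocklikeness_rank <- function(gene_trees, rooting = c("error", "midpoint"),
                               top = NULL) {
  rooting <- match.arg(rooting)
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  nms <- names(gene_trees)
  if (is.null(nms)) nms <- paste0("gene", seq_along(gene_trees))
  vars <- vapply(seq_along(gene_trees), function(i) {
    tr <- gene_trees[[i]]
    if (!ape::is.rooted(tr)) {
      if (rooting == "error") {
        stop("tree '", nms[i], "' is unrooted; supply rooting = \"midpoint\"",
             call. = FALSE)
      }
      tr <- phangorn::midpoint(tr)
    }
    if (is.null(tr$edge.length)) {
      stop("tree '", nms[i], "' has no branch lengths", call. = FALSE)
    }
    depth <- ape::node.depth.edgelength(tr)
    stats::var(depth[seq_len(ape::Ntip(tr))])
  }, numeric(1))
  out <- data.frame(gene = nms, root_to_tip_variance = vars,
                    stringsAsFactors = FALSE)
  out <- out[order(out$root_to_tip_variance, seq_len(nrow(out))), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  out
}
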