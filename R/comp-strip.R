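# Compositional heterogeneity scoring and site stripping for protein
# alignments. Alignments are character matrices (taxa x sites) over the
# 20 amino acids plus gap '-' and missing 'X'.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Coerce and validate a protein alignment matrix
#'
#' @param x Character matrix (taxa x sites) with rownames, or an `AAbin`.
#' @return Validated uppercase character matrix of class `aa_alignment`.
#' @export
aa_alignment <- function(x) {
  if (inherits(x, "AAbin")) x <- as.character(x)
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  x <- toupper(x)
  ok <- x %in% c(AA_ALPHABET, "-", "X", "?", "*")
  if (!all(ok)) {
    bad <- unique(x[!ok])
    stop("invalid alignment symbol(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  x[x %in% c("?", "*")] <- "X"
  class(x) <- c("aa_alignment", class(x))
  x
}

#' Read a protein alignment (FASTA or relaxed PHYLIP)
#'
#' FASTA goes through `ape::read.FASTA`; relaxed PHYLIP (sequential,
#' `name sequence` per record after the `ntaxa nsites` header) is parsed
#' directly.
#'
#' @param path Path to the alignment.
#' @param format `"auto"` (default; PHYLIP detected by a numeric header),
#'   `"fasta"`, or `"phylip"`.
#' @return An [aa_alignment()] matrix.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^\\s*\\d+\\s+\\d+\\s*$", first)) "phylip" else
      "fasta"
  }
  if (format == "fasta") {
    bin <- ape::read.FASTA(path, type = "AA")
    m <- toupper(do.call(rbind, lapply(as.character(bin), identity)))
    rownames(m) <- names(bin)
    return(aa_alignment(m))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1]
  if (length(body) != hdr[1]) {
    stop("relaxed PHYLIP: expected ", hdr[1], " sequence rows, found ",
         length(body), call. = FALSE)
  }
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[[`, character(1), 1)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""),
                 character(1))
  if (any(nchar(seqs) != hdr[2])) {
    stop("relaxed PHYLIP: sequence length mismatch with header",
         call. = FALSE)
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- nm
  aa_alignment(m)
}

#' Write a protein alignment (FASTA or relaxed PHYLIP)
#'
#' @param aln An [aa_alignment()].
#' @param path Output path.
#' @param format `"fasta"` (default) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  aln <- aa_alignment(unclass(aln))
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(aln))) {
      cat(">", rownames(aln)[i], "\n",
          paste(aln[i, ], collapse = ""), "\n", sep = "", file = con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    cat(nrow(aln), " ", ncol(aln), "\n", sep = "", file = con)
    for (i in seq_len(nrow(aln))) {
      cat(rownames(aln)[i], "  ",
          paste(aln[i, ], collapse = ""), "\n", sep = "", file = con)
    }
  }
  invisible(path)
}

aa_counts <- function(aln) {
  aln <- unclass(aln)
  t(apply(aln, 1, function(row) {
    tab <- table(factor(row, levels = AA_ALPHABET))
    as.integer(tab)
  }))
}

#' Per-taxon amino-acid composition
#'
#' Residue frequencies per taxon over the 20 amino acids; gaps and missing
#' states are excluded, so each row sums to 1.
#'
#' @param aln An [aa_alignment()].
#' @return Numeric matrix (taxa x 20) of frequencies.
#' @export
taxon_composition <- function(aln) {
  aln <- aa_alignment(unclass(aln))
  counts <- aa_counts(aln)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("taxon with zero residues: ",
         rownames(aln)[which(tot == 0)[1]], call. = FALSE)
  }
  f <- counts / tot
  colnames(f) <- AA_ALPHABET
  rownames(f) <- rownames(aln)
  f
}

comp_H_from_counts <- function(counts, tot) {
  keep <- tot > 0
  f <- counts[keep, , drop = FALSE] / tot[keep]
  mbar <- colMeans(f)
  sum(sweep(f, 2, mbar)^2)
}

#' Alignment-level compositional heterogeneity
#'
#' `H = sum over taxa and residues of (f_taxon,residue - mean_residue)^2`,
#' the total squared deviation of per-taxon compositions from the average
#' composition. `H = 0` iff all per-taxon compositions are identical.
#'
#' @param aln An [aa_alignment()].
#' @return Non-negative scalar.
#' @export
compositional_heterogeneity <- function(aln) {
  counts <- aa_counts(aln)
  comp_H_from_counts(counts, rowSums(counts))
}

#' Leave-one-site-out heterogeneity scores
#'
#' The score of site `s` is `H(full alignment) - H(alignment without s)`:
#' how much compositional heterogeneity the site contributes. Computed
#' incrementally from the count matrix rather than by rebuilding the
#' alignment. Higher scores mean more heterogeneity; the ranking breaks
#' ties by site index ascending. Scores can be slightly negative for sites
#' that dilute heterogeneity.
#'
#' @param aln An [aa_alignment()] with at least 2 taxa and 2 sites.
#' @return A `site_scores` object: list with `score` (numeric per site),
#'   `ranking` (site indices, most heterogeneous first), `H_full`.
#' @export
site_heterogeneity_scores <- function(aln) {
  aln <- aa_alignment(unclass(aln))
  if (nrow(aln) < 2L || ncol(aln) < 2L) {
    stop("need >= 2 taxa and >= 2 sites", call. = FALSE)
  }
  counts <- aa_counts(aln)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("taxon with zero residues: ",
         rownames(aln)[which(tot == 0)[1]], call. = FALSE)
  }
  H_full <- comp_H_from_counts(counts, tot)
  n_sites <- ncol(aln)
  aa_idx <- match(unclass(aln), AA_ALPHABET)   # taxa x sites, NA for gaps
  dim(aa_idx) <- dim(unclass(aln))
  score <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    cs <- counts
    ts <- tot
    col <- aa_idx[, s]
    hit <- which(!is.na(col))
    for (t in hit) {
      cs[t, col[t]] <- cs[t, col[t]] - 1L
      ts[t] <- ts[t] - 1L
    }
    score[s] <- H_full - comp_H_from_counts(cs, ts)
  }
  ranking <- order(-score, seq_len(n_sites))
  structure(list(score = score, ranking = ranking, H_full = H_full),
            class = "site_scores")
}

#' @export
print.site_scores <- function(x, ...) {
  cat(sprintf("Site heterogeneity scores: %d sites, H(full) = %.6g\n",
              length(x$score), x$H_full))
  cat("  top sites:", paste(utils::head(x$ranking, 10), collapse = ", "),
      "\n")
  invisible(x)
}

#' Strip the most compositionally heterogeneous sites
#'
#' Removes the `floor(fraction * n_sites)` top-ranked sites (floor, so the
#' requested fraction is never exceeded), preserving taxon order and the
#' relative order of the remaining sites.
#'
#' @param aln An [aa_alignment()].
#' @param fraction Fraction of sites to remove, in `[0, 1)`.
#' @param scores Optional precomputed [site_heterogeneity_scores()].
#' @return The stripped [aa_alignment()]; attribute `kept_sites` maps the
#'   retained columns to original site indices, `removed_sites` lists the
#'   stripped ones.
#' @export
strip_sites <- function(aln, fraction, scores = NULL) {
  aln <- aa_alignment(unclass(aln))
  if (!(fraction >= 0 && fraction < 1)) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  k <- floor(fraction * ncol(aln))
  if (k == 0L) {
    out <- aln
    attr(out, "kept_sites") <- seq_len(ncol(aln))
    attr(out, "removed_sites") <- integer(0)
    return(out)
  }
  if (is.null(scores)) scores <- site_heterogeneity_scores(aln)
  drop <- sort(scores$ranking[seq_len(k)])
  keep <- setdiff(seq_len(ncol(aln)), drop)
  out <- aa_alignment(unclass(aln)[, keep, drop = FALSE])
  attr(out, "kept_sites") <- keep
  attr(out, "removed_sites") <- drop
  out
}

#' Write site scores and kept indices as TSV
#' @param scores A `site_scores` object.
#' @param path Output path.
#' @param kept Optional integer vector of kept site indices.
#' @return `path`, invisibly.
#' @export
write_site_scores <- function(scores, path, kept = NULL) {
  df <- data.frame(site = seq_along(scores$score), score = scores$score,
                   rank = match(seq_along(scores$score), scores$ranking))
  if (!is.null(kept)) df$kept <- df$site %in% kept
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
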