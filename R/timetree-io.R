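#' Read an annotated chronogram from Newick or NEXUS
#'
#' Reads a dated tree with optional per-node 95% HPD annotations in bracketed
#' node comments. Three dialects are accepted: `"plain"` (bare Newick, no
#' comments), `"figtree-annotated"` (`[&95%HPD={low,high}]`) and
#' `"mcmctree-out"` (`[&95%={low, high}]`). The annotation key is recognised
#' in all three cases, so the dialect argument mostly documents provenance;
#' HPD bounds are accepted in either order and normalized to
#' (older, younger) on read. NEXUS files (detected by the `#NEXUS` header)
#' may carry a `translate` table.
#'
#' @param path Path to a Newick or NEXUS file.
#' @param dialect One of `"plain"`, `"figtree-annotated"`, `"mcmctree-out"`.
#' @param validate Validate the resulting chronogram (default `TRUE`).
#' @return A [chronogram()].
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1)[&95%HPD={0.8,1.2}]:1,C:2);", tf)
#' ch <- read_chronogram(tf)
#' node_hpd(ch, 5)
#' @export
read_chronogram <- function(path,
                            dialect = c("plain", "figtree-annotated",
                                        "mcmctree-out"),
                            validate = TRUE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) && grepl("^\\s*#NEXUS", lines[1], ignore.case = TRUE)) {
    parsed <- nexus_first_tree(lines)
  } else {
    parsed <- parse_annotated_newick(paste(lines, collapse = "\n"))
  }
  chronogram_from_parsed(parsed, validate = validate)
}

chronogram_from_text <- function(text, validate = TRUE) {
  chronogram_from_parsed(parse_annotated_newick(text), validate = validate)
}

chronogram_from_parsed <- function(parsed, validate = TRUE) {
  phy <- parsed$phy
  nn <- ape::Ntip(phy) + phy$Nnode
  hpd_older <- rep(NA_real_, nn)
  hpd_younger <- rep(NA_real_, nn)
  for (i in seq_len(nn)) {
    nm <- if (i <= ape::Ntip(phy)) phy$tip.label[i] else {
      lb <- parsed$node_label[i]
      if (!is.na(lb) && nzchar(lb)) lb else paste0("node ", i)
    }
    h <- extract_hpd(parsed$comment[i], nm)
    hpd_older[i] <- h[1]
    hpd_younger[i] <- h[2]
  }
  chronogram(phy, hpd_older = hpd_older, hpd_younger = hpd_younger,
             node_labels = parsed$node_label, validate = validate)
}

# Extract and parse the first tree statement from a NEXUS trees block,
# applying an optional translate table to the tip labels.
nexus_first_tree <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  translate <- NULL
  tr_m <- regmatches(txt, regexpr("(?is)translate\\s.*?;", txt, perl = TRUE))
  if (length(tr_m) && nzchar(tr_m)) {
    body <- sub("(?is)^translate\\s+", "", tr_m, perl = TRUE)
    body <- sub(";\\s*$", "", body)
    entries <- trimws(strsplit(body, ",")[[1]])
    entries <- entries[nzchar(entries)]
    kv <- do.call(rbind, lapply(entries, function(e) {
      parts <- strsplit(e, "\\s+")[[1]]
      c(parts[1], paste(parts[-1], collapse = " "))
    }))
    translate <- stats::setNames(gsub("^'|'$", "", kv[, 2]), kv[, 1])
  }
  m <- regmatches(txt,
                  regexpr("(?is)\\btree\\s+[^=]+=\\s*(\\[[^]]*\\]\\s*)?[^;]*;",
                          txt, perl = TRUE))
  if (!length(m) || !nzchar(m)) {
    stop("no tree statement found in NEXUS file", call. = FALSE)
  }
  nwk <- sub("(?is)^\\btree\\s+[^=]+=\\s*", "", m, perl = TRUE)
  parsed <- parse_annotated_newick(nwk)
  if (!is.null(translate)) {
    hit <- parsed$phy$tip.label %in% names(translate)
    parsed$phy$tip.label[hit] <- unname(translate[parsed$phy$tip.label[hit]])
  }
  parsed
}

#' Write a chronogram to annotated Newick
#'
#' Serializes branch lengths (Ma) and, where present, per-node HPD
#' annotations as `[&95%HPD={younger,older}]` node comments. Reading the
#' file back with [read_chronogram()] reproduces ages and HPD bounds.
#'
#' @param x A [chronogram()].
#' @param path Output file path.
#' @param digits Significant digits for branch lengths and bounds.
#' @return `path`, invisibly.
#' @export
write_chronogram <- function(x, path, digits = 12) {
  stopifnot(inherits(x, "chronogram"))
  phy <- x$phy
  n_tip <- ape::Ntip(phy)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  fmt <- function(v) sprintf(paste0("%.", digits, "g"), v)
  annot <- function(id) {
    if (is.na(x$hpd_older[id]) || is.na(x$hpd_younger[id])) return("")
    sprintf("[&95%%HPD={%s,%s}]", fmt(x$hpd_younger[id]), fmt(x$hpd_older[id]))
  }
  build <- function(id, parent_age) {
    if (id <= n_tip) {
      core <- quote_newick_label(phy$tip.label[id])
    } else {
      kids <- children[[as.character(id)]]
      core <- paste0("(", paste(vapply(kids, build, character(1),
                                       parent_age = x$ages[id]),
                                collapse = ","), ")")
      lbl <- x$node_labels[id]
      if (!is.na(lbl) && nzchar(lbl)) core <- paste0(core,
                                                     quote_newick_label(lbl))
    }
    out <- paste0(core, annot(id))
    if (!is.na(parent_age)) {
      out <- paste0(out, ":", fmt(parent_age - x$ages[id]))
    }
    out
  }
  root <- n_tip + 1L
  txt <- paste0(build(root, NA_real_), ";")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Posterior traces

#' Read an MCMC posterior trace
#'
#' Generic header-plus-columns trace format: a first header row of parameter
#' names, then whitespace/tab-delimited numeric rows (one per MCMC sample).
#'
#' @param path Path to the trace file.
#' @param burnin_fraction Fraction of initial samples to flag as burn-in;
#'   `floor(burnin_fraction * n_samples)` samples are excluded by downstream
#'   summaries.
#' @return A `posterior_trace`: list with `samples` (data frame), `burnin`
#'   (integer count) and `n_samples`.
#' @export
read_trace <- function(path, burnin_fraction = 0) {
  stopifnot(burnin_fraction >= 0, burnin_fraction < 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("trace file needs a header and >= 1 row",
                               call. = FALSE)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "[ \t]+")
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop("ragged trace row ", bad, ": expected ", length(header),
         " fields, found ", nf[bad], call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(header))
  for (j in seq_along(header)) {
    col <- vapply(rows, `[[`, character(1), j)
    val <- suppressWarnings(as.numeric(col))
    if (anyNA(val)) {
      stop("non-numeric value in trace column '", header[j], "' (row ",
           which(is.na(val))[1], ")", call. = FALSE)
    }
    mat[, j] <- val
  }
  samples <- as.data.frame(mat)
  names(samples) <- header
  posterior_trace(samples, burnin_fraction = burnin_fraction)
}

#' Construct a posterior trace object
#'
#' @param samples Data frame of numeric sample columns (one row per MCMC
#'   sample).
#' @param burnin_fraction Fraction of initial samples flagged as burn-in.
#' @return A `posterior_trace` object.
#' @export
posterior_trace <- function(samples, burnin_fraction = 0) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1,
            burnin_fraction >= 0, burnin_fraction < 1)
  burnin <- floor(burnin_fraction * nrow(samples))
  structure(list(samples = samples, burnin = as.integer(burnin),
                 n_samples = nrow(samples)),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("Posterior trace: %d samples x %d parameters (%d burn-in)\n",
              x$n_samples, ncol(x$samples), x$burnin))
  invisible(x)
}

#' Post-burn-in samples of a trace
#' @param x A `posterior_trace`.
#' @return Data frame of retained samples.
#' @export
retained_samples <- function(x) {
  stopifnot(inherits(x, "posterior_trace"))
  if (x$burnin == 0L) return(x$samples)
  x$samples[-seq_len(x$burnin), , drop = FALSE]
}

#' Write a posterior trace to the generic header+columns format
#' @param x A `posterior_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "posterior_trace"))
  utils::write.table(x$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Calibration tables

#' Read a fossil-calibration table
#'
#' TSV with columns `clade`, `age` (Ma), `type` (`Min`/`Max`) and optional
#' `note`. Lines starting with `#` are comments. Following common practice
#' for Proterozoic calibrations, clades flagged with note `a` (or any clade
#' with a minimum but no maximum) receive a default maximum bound
#' (`default_max`, 1900 Ma). Calibration "Min"/"Max" vocabulary maps onto the
#' interval vocabulary used everywhere else in this package as: Min = the
#' younger bound of permissible node ages, Max = the older bound.
#'
#' @param path Path to the TSV.
#' @param default_max Default older bound (Ma) for minimum-only clades.
#' @return A `calibration_table`: data frame with one row per clade and
#'   columns `clade`, `younger` (from Min), `older` (from Max),
#'   `max_is_default` (logical).
#' @export
read_calibration_table <- function(path, default_max = 1900) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  if (nrow(raw) == 0L) {
    out <- data.frame(clade = character(0), younger = numeric(0),
                      older = numeric(0), max_is_default = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("calibration_table", class(out))
    return(out)
  }
  need <- c("clade", "age", "type")
  if (!all(need %in% names(raw))) {
    stop("calibration table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok_type <- raw$type %in% c("Min", "Max")
  if (!all(ok_type)) {
    stop("unknown calibration type token '", raw$type[!ok_type][1],
         "' (expected Min or Max)", call. = FALSE)
  }
  if (!"note" %in% names(raw)) raw$note <- ""
  clades <- unique(raw$clade)
  rows <- lapply(clades, function(cl) {
    sub <- raw[raw$clade == cl, , drop = FALSE]
    mins <- sub$age[sub$type == "Min"]
    maxs <- sub$age[sub$type == "Max"]
    younger <- if (length(mins)) max(mins) else NA_real_
    older <- if (length(maxs)) min(maxs) else NA_real_
    max_is_default <- FALSE
    if (is.na(older) && !is.na(younger)) {
      older <- default_max
      max_is_default <- TRUE
    }
    if (!is.na(younger) && !is.na(older) && older < younger) {
      stop("calibration for clade '", cl, "' has max (", older,
           ") < min (", younger, ")", call. = FALSE)
    }
    data.frame(clade = cl, younger = younger, older = older,
               max_is_default = max_is_default, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("calibration_table", class(out))
  out
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration table: %d clades (%d with default maximum)\n",
              nrow(x), sum(x$max_is_default)))
  NextMethod()
}

# ---------------------------------------------------------------------------
# Taxonomy maps and scenario configs

#' Read a tip-to-group taxonomy map
#'
#' TSV with columns `tip` and `group` (header required, `#` comments
#' allowed).
#'
#' @param path Path to the TSV.
#' @return Named character vector: `names` are tip labels, values group
#'   labels.
#' @export
read_taxonomy_map <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           quote = "")
  if (!all(c("tip", "group") %in% names(raw))) {
    stop("taxonomy map needs columns: tip, group", call. = FALSE)
  }
  stats::setNames(as.character(raw$group), as.character(raw$tip))
}

#' Read an endosymbiosis scenario definition
#'
#' Structured text: one event per line in order, formatted
#' `"donor -> recipient, level N"`; blank lines and `#` comments ignored.
#'
#' @param path Path to the config file.
#' @param name Scenario name; defaults to the file stem.
#' @return An `endosymbiosis_scenario` (see [endosymbiosis_scenario()]).
#' @export
read_scenario_config <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("scenario config is empty", call. = FALSE)
  m <- regmatches(lines,
                  regexec("^(.+?)\\s*->\\s*(.+?)\\s*,\\s*level\\s+(\\d+)\\s*$",
                          lines))
  bad <- which(lengths(m) == 0L | vapply(m, length, integer(1)) != 4L)
  if (length(bad)) {
    stop("malformed scenario event line: '", lines[bad[1]], "'",
         call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  endosymbiosis_scenario(
    name = name,
    donor = vapply(m, `[[`, character(1), 2),
    recipient = vapply(m, `[[`, character(1), 3),
    level = as.integer(vapply(m, `[[`, character(1), 4))
  )
}
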