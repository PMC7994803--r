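# Recursive-descent Newick parser that *retains* bracketed node comments
# (FigTree/MCMCTree style "[&95%HPD={low,high}]"). ape and phangorn discard
# comments on read, so annotated chronograms are parsed here; plain trees use
# the same code path (comments simply absent).

new_parser_state <- function(text) {
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$pos <- 1L
  env$n <- length(env$chars)
  env
}

parser_error <- function(st, msg) {
  consumed <- st$chars[seq_len(min(st$pos - 1L, st$n))]
  line <- sum(consumed == "\n") + 1L
  last_nl <- max(c(0L, which(consumed == "\n")))
  col <- st$pos - last_nl
  stop(sprintf("Newick parse error at line %d, column %d: %s", line, col, msg),
       call. = FALSE)
}

peek_char <- function(st) {
  if (st$pos > st$n) return(NA_character_)
  st$chars[st$pos]
}

skip_ws <- function(st) {
  while (st$pos <= st$n && grepl("^[[:space:]]$", st$chars[st$pos])) {
    st$pos <- st$pos + 1L
  }
}

read_comment <- function(st) {
  # assumes current char is '['
  depth <- 0L
  start <- st$pos
  while (st$pos <= st$n) {
    ch <- st$chars[st$pos]
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") {
      depth <- depth - 1L
      if (depth == 0L) {
        out <- paste(st$chars[(start + 1L):(st$pos - 1L)], collapse = "")
        st$pos <- st$pos + 1L
        return(out)
      }
    }
    st$pos <- st$pos + 1L
  }
  parser_error(st, "unterminated comment '['")
}

collect_comments <- function(st) {
  out <- character(0)
  repeat {
    skip_ws(st)
    if (identical(peek_char(st), "[")) {
      out <- c(out, read_comment(st))
    } else {
      break
    }
  }
  if (length(out)) paste(out, collapse = " ") else NA_character_
}

read_label <- function(st) {
  skip_ws(st)
  ch <- peek_char(st)
  if (is.na(ch)) return("")
  if (ch == "'") {
    st$pos <- st$pos + 1L
    buf <- character(0)
    repeat {
      if (st$pos > st$n) parser_error(st, "unterminated quoted label")
      ch <- st$chars[st$pos]
      if (ch == "'") {
        if (st$pos < st$n && st$chars[st$pos + 1L] == "'") {
          buf <- c(buf, "'")
          st$pos <- st$pos + 2L
        } else {
          st$pos <- st$pos + 1L
          break
        }
      } else {
        buf <- c(buf, ch)
        st$pos <- st$pos + 1L
      }
    }
    return(paste(buf, collapse = ""))
  }
  buf <- character(0)
  while (st$pos <= st$n) {
    ch <- st$chars[st$pos]
    if (ch %in% c("(", ")", ",", ":", ";", "[") ||
        grepl("^[[:space:]]$", ch)) break
    buf <- c(buf, ch)
    st$pos <- st$pos + 1L
  }
  paste(buf, collapse = "")
}

read_number <- function(st) {
  skip_ws(st)
  buf <- character(0)
  while (st$pos <= st$n) {
    ch <- st$chars[st$pos]
    if (!grepl("^[0-9eE.+-]$", ch)) break
    buf <- c(buf, ch)
    st$pos <- st$pos + 1L
  }
  if (!length(buf)) parser_error(st, "expected a branch length")
  val <- suppressWarnings(as.numeric(paste(buf, collapse = "")))
  if (is.na(val)) parser_error(st, "malformed branch length")
  val
}

parse_subtree <- function(st) {
  skip_ws(st)
  node <- list(children = NULL, label = "", length = NA_real_,
               comment = NA_character_)
  if (identical(peek_char(st), "(")) {
    st$pos <- st$pos + 1L
    children <- list(parse_subtree(st))
    repeat {
      skip_ws(st)
      ch <- peek_char(st)
      if (identical(ch, ",")) {
        st$pos <- st$pos + 1L
        children[[length(children) + 1L]] <- parse_subtree(st)
      } else if (identical(ch, ")")) {
        st$pos <- st$pos + 1L
        break
      } else {
        parser_error(st, "expected ',' or ')'")
      }
    }
    node$children <- children
    node$label <- read_label(st)
  } else {
    node$label <- read_label(st)
    if (!nzchar(node$label)) parser_error(st, "expected a tip label")
  }
  node$comment <- collect_comments(st)
  skip_ws(st)
  if (identical(peek_char(st), ":")) {
    st$pos <- st$pos + 1L
    cmt <- collect_comments(st)
    node$length <- read_number(st)
    cmt2 <- collect_comments(st)
    extra <- c(cmt, cmt2)
    extra <- extra[!is.na(extra)]
    if (length(extra)) {
      node$comment <- if (is.na(node$comment)) paste(extra, collapse = " ")
                      else paste(c(node$comment, extra), collapse = " ")
    }
  }
  node
}

count_tips <- function(node) {
  if (is.null(node$children)) return(1L)
  sum(vapply(node$children, count_tips, integer(1)))
}

count_internal <- function(node) {
  if (is.null(node$children)) return(0L)
  1L + sum(vapply(node$children, count_internal, integer(1)))
}

# Convert nested parse into an ape "phylo" plus per-node comment/label vectors
# indexed by ape node id (tips 1..n, internals n+1..n+m, root n+1).
nested_to_phylo <- function(root) {
  n_tip <- count_tips(root)
  n_int <- count_internal(root)
  if (n_tip < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$edge <- matrix(0L, nrow = n_tip + n_int - 1L, ncol = 2L)
  env$edge_length <- rep(NA_real_, n_tip + n_int - 1L)
  env$tip_label <- character(n_tip)
  env$comment <- rep(NA_character_, n_tip + n_int)
  env$node_label <- rep(NA_character_, n_tip + n_int)
  env$next_tip <- 1L
  env$next_int <- n_tip + 1L
  env$next_edge <- 1L
  assign_ids <- function(node) {
    if (is.null(node$children)) {
      id <- env$next_tip
      env$next_tip <- env$next_tip + 1L
      env$tip_label[id] <- node$label
    } else {
      id <- env$next_int
      env$next_int <- env$next_int + 1L
      if (nzchar(node$label)) env$node_label[id] <- node$label
      for (ch in node$children) {
        cid <- assign_ids(ch)
        e <- env$next_edge
        env$next_edge <- e + 1L
        env$edge[e, ] <- c(id, cid)
        env$edge_length[e] <- ch$length
      }
    }
    env$comment[id] <- node$comment
    id
  }
  assign_ids(root)
  phy <- list(edge = env$edge, tip.label = env$tip_label, Nnode = n_int)
  if (!all(is.na(env$edge_length))) {
    phy$edge.length <- ifelse(is.na(env$edge_length), 0, env$edge_length)
  }
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  list(phy = phy, comment = env$comment, node_label = env$node_label,
       root_length = root$length)
}

parse_annotated_newick <- function(text) {
  st <- new_parser_state(text)
  collect_comments(st)          # leading comments (e.g. "[&R]") are ignored
  root <- parse_subtree(st)
  skip_ws(st)
  if (!identical(peek_char(st), ";")) parser_error(st, "expected ';'")
  nested_to_phylo(root)
}

# Extract a 95%-HPD-style annotation from a node comment.  Accepts both
# "[&95%HPD={low,high}]" (FigTree) and "[&95%={low, high}]" (MCMCTree), with
# bounds in either order; normalized on return to c(older, younger).
extract_hpd <- function(comment, node_name) {
  if (is.na(comment)) return(c(NA_real_, NA_real_))
  m <- regmatches(comment,
                  regexec("95%[_ ]?(HPD)?[_ ]?=?[ ]?\\{([^}]*)\\}", comment))[[1]]
  if (length(m) == 0L) return(c(NA_real_, NA_real_))
  parts <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(vals) != 2L || anyNA(vals)) {
    stop("malformed HPD annotation at ", node_name, ": {", m[3], "}",
         call. = FALSE)
  }
  c(max(vals), min(vals))
}

quote_newick_label <- function(x) {
  if (grepl("[(),:;\\[\\]' \t]", x)) {
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  } else {
    x
  }
}
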