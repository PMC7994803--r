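#' Endosymbiosis scenario: an ordered chain of plastid transfers
#'
#' An ordered list of directed transfer events (donor lineage -> recipient
#' lineage) with their endosymbiosis level (2 = secondary, 3 = tertiary,
#' 4 = quaternary). Two presets are shipped: `"stiller"`
#' (Rho->Cry, Cry->Och, Och->Hap, Och->Myz) and `"bodyl"`
#' (Rho->Cry, Cry->Och, Cry->Hap, Hap->Myz).
#'
#' @param name Scenario name.
#' @param donor,recipient Character vectors of lineage names, in event
#'   order.
#' @param level Integer endosymbiosis levels (2, 3 or 4).
#' @return An `endosymbiosis_scenario`: data frame with columns `order`,
#'   `donor`, `recipient`, `level` and a `name` attribute.
#' @seealso [scenario_preset()], [read_scenario_config()]
#' @export
endosymbiosis_scenario <- function(name, donor, recipient, level) {
  stopifnot(length(donor) == length(recipient),
            length(donor) == length(level), length(donor) >= 1)
  if (any(donor == recipient)) {
    stop("scenario event with donor == recipient: ",
         donor[donor == recipient][1], call. = FALSE)
  }
  if (!all(level %in% 2:4)) {
    stop("endosymbiosis level must be 2, 3 or 4", call. = FALSE)
  }
  # chain connectivity: every donor after the first event must already have
  # appeared as a recipient or donor
  seen <- donor[1]
  for (i in seq_along(donor)) {
    if (!(donor[i] %in% seen)) {
      stop("scenario not a connected transfer chain: donor '", donor[i],
           "' of event ", i, " has not yet appeared", call. = FALSE)
    }
    seen <- union(seen, c(donor[i], recipient[i]))
  }
  out <- data.frame(order = seq_along(donor), donor = donor,
                    recipient = recipient, level = as.integer(level),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("endosymbiosis_scenario", class(out))
  out
}

#' @export
print.endosymbiosis_scenario <- function(x, ...) {
  cat(sprintf("Endosymbiosis scenario '%s' (%d events)\n", attr(x, "name"),
              nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %d. %s -> %s (level %d)\n", x$order[i], x$donor[i],
                x$recipient[i], x$level[i]))
  }
  invisible(x)
}

#' Load a packaged scenario preset
#'
#' @param name `"stiller"` or `"bodyl"`.
#' @return An [endosymbiosis_scenario()].
#' @export
scenario_preset <- function(name = c("stiller", "bodyl")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("scenario_", name, ".txt"),
                      package = "rhodochron", mustWork = TRUE)
  read_scenario_config(path, name = name)
}

#' Feasibility window of one plastid transfer
#'
#' The transfer from donor to recipient can only have happened while both
#' stem lineages existed: the window is the intersection of the two
#' availability intervals, `older = min` of the older bounds and
#' `younger = max` of the younger bounds. Disjoint intervals give an
#' infeasible result (not an error), reported with a negative overlap
#' deficit for diagnosis.
#'
#' @param donor,recipient [time_interval()] availability windows.
#' @return A `transfer_window`: list with `feasible` (logical), `window`
#'   (a [time_interval()], or `NULL` if infeasible), `width` (Ma; negative
#'   overlap deficit `younger - older` when infeasible).
#' @examples
#' transfer_window(time_interval(1675, 1281), time_interval(1658, 440))
#' @export
transfer_window <- function(donor, recipient) {
  stopifnot(is_time_interval(donor), is_time_interval(recipient))
  older <- min(donor$older, recipient$older)
  younger <- max(donor$younger, recipient$younger)
  feasible <- older >= younger
  structure(list(
    feasible = feasible,
    window = if (feasible) time_interval(older, younger) else NULL,
    width = older - younger
  ), class = "transfer_window")
}

#' @export
print.transfer_window <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("Transfer window [%g, %g] Ma, width %g\n", x$window$older,
                x$window$younger, x$width))
  } else {
    cat(sprintf("Transfer infeasible (overlap deficit %g Ma)\n", -x$width))
  }
  invisible(x)
}

as_lineage_windows <- function(windows) {
  if (is.data.frame(windows)) {
    stopifnot(all(c("lineage", "older", "younger") %in% names(windows)))
    out <- lapply(seq_len(nrow(windows)), function(i) {
      time_interval(windows$older[i], windows$younger[i])
    })
    names(out) <- windows$lineage
    return(out)
  }
  stopifnot(is.list(windows), !is.null(names(windows)))
  stopifnot(all(vapply(windows, is_time_interval, logical(1))))
  windows
}

#' Transfer windows for every event of a scenario
#'
#' One [transfer_window()] per event, each the pairwise intersection of the
#' donor and recipient availability windows. No sequential narrowing is
#' applied (the realized time of an earlier transfer is not propagated into
#' later donor windows); ordering constraints are assessed separately by
#' [sequential_feasibility()].
#'
#' @param scenario An [endosymbiosis_scenario()].
#' @param windows Named list of [time_interval()] (lineage -> availability)
#'   or a data frame with columns `lineage`, `older`, `younger`.
#' @return A data frame with one row per event: `order`, `donor`,
#'   `recipient`, `level`, `older`, `younger` (NA when infeasible), `width`,
#'   `feasible`.
#' @export
scenario_windows <- function(scenario, windows) {
  stopifnot(inherits(scenario, "endosymbiosis_scenario"))
  windows <- as_lineage_windows(windows)
  need <- union(scenario$donor, scenario$recipient)
  missing <- setdiff(need, names(windows))
  if (length(missing)) {
    stop("no availability window for lineage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(scenario)), function(i) {
    tw <- transfer_window(windows[[scenario$donor[i]]],
                          windows[[scenario$recipient[i]]])
    data.frame(order = scenario$order[i], donor = scenario$donor[i],
               recipient = scenario$recipient[i], level = scenario$level[i],
               older = if (tw$feasible) tw$window$older else NA_real_,
               younger = if (tw$feasible) tw$window$younger else NA_real_,
               width = tw$width, feasible = tw$feasible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$order), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Envelope of a set of feasible transfer windows
#'
#' The overall interval spanned by all event windows: oldest older bound to
#' youngest younger bound, i.e. the maximal span of the serial-transfer
#' chronology.
#'
#' @param results Data frame from [scenario_windows()]; all events must be
#'   feasible.
#' @return A list with `window` (a [time_interval()]) and `width` (Ma).
#' @export
scenario_envelope <- function(results) {
  stopifnot(is.data.frame(results), all(c("older", "younger", "feasible")
                                        %in% names(results)))
  if (!all(results$feasible)) {
    stop("scenario_envelope: infeasible event(s): ",
         paste(paste(results$donor[!results$feasible], "->",
                     results$recipient[!results$feasible]), collapse = "; "),
         call. = FALSE)
  }
  w <- time_interval(max(results$older), min(results$younger))
  list(window = w, width = interval_width(w))
}

#' Can the transfers have happened in the stated order?
#'
#' True when every event window is non-empty and the ordered chain admits a
#' weakly age-decreasing assignment of one event time per window (an
#' earlier event occurring no later than each subsequent one). Checked
#' greedily from the first event; the report also itemises consecutive
#' pairs that fail the simpler pairwise overlap-order condition
#' (`older bound of event i` >= `younger bound of event i+1`).
#'
#' @param results Data frame from [scenario_windows()], in event order.
#' @return A list: `feasible` (logical), `event_times` (a witness
#'   assignment of ages when feasible), `violations` (data frame of
#'   consecutive-pair violations).
#' @export
sequential_feasibility <- function(results) {
  stopifnot(is.data.frame(results))
  results <- results[order(results$order), , drop = FALSE]
  n <- nrow(results)
  viol <- list()
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      if (results$feasible[i] && results$feasible[i + 1L] &&
          results$older[i] < results$younger[i + 1L]) {
        viol[[length(viol) + 1L]] <- data.frame(
          earlier = paste(results$donor[i], "->", results$recipient[i]),
          later = paste(results$donor[i + 1L], "->",
                        results$recipient[i + 1L]),
          detail = sprintf("event %d window entirely younger than event %d",
                           i, i + 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(earlier = character(0), later = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  if (!all(results$feasible)) {
    return(list(feasible = FALSE, event_times = NULL,
                violations = violations))
  }
  # greedy witness: place each event as old as its window and the previous
  # event allow; feasible iff no event drops below its younger bound
  times <- numeric(n)
  ok <- TRUE
  prev <- Inf
  for (i in seq_len(n)) {
    times[i] <- min(results$older[i], prev)
    if (times[i] < results$younger[i]) {
      ok <- FALSE
      break
    }
    prev <- times[i]
  }
  list(feasible = ok, event_times = if (ok) times else NULL,
       violations = violations)
}

#' Lineage availability windows from an annotated chronogram
#'
#' The availability window of a lineage is the time span along its stem plus
#' crown uncertainty during which a plastid could have been acquired: from
#' the older 95% HPD bound of the node *opening* the stem (the crown node's
#' parent) down to the younger 95% HPD bound of the crown node itself. A
#' single-tip lineage has crown age 0 and its window reaches the present.
#'
#' @param chron A [chronogram()] with HPD annotations.
#' @param lineages Named list: lineage name -> character vector of tip
#'   labels (must be monophyletic).
#' @return Named list of [time_interval()] availability windows.
#' @export
lineage_windows_from_chronogram <- function(chron, lineages) {
  stopifnot(inherits(chron, "chronogram"), is.list(lineages),
            !is.null(names(lineages)))
  phy <- chron$phy
  n_tip <- ape::Ntip(phy)
  sets <- clade_tip_sets(phy)
  parent <- node_parents(phy)
  out <- vector("list", length(lineages))
  names(out) <- names(lineages)
  for (nm in names(lineages)) {
    tips <- lineages[[nm]]
    crown <- mrca_of_tips(phy, tips)
    if (crown > n_tip) {
      desc <- sort(phy$tip.label[sets[[crown]]])
      if (!identical(desc, sort(tips))) {
        stop("lineage '", nm, "' is not monophyletic: MRCA also contains ",
             paste(setdiff(desc, tips), collapse = ", "), call. = FALSE)
      }
    }
    stem_node <- parent[crown]
    if (stem_node == 0L) {
      stop("lineage '", nm, "' is the whole tree; no stem node exists",
           call. = FALSE)
    }
    if (is.na(chron$hpd_older[stem_node])) {
      stop("missing HPD at stem node of lineage '", nm, "' (",
           node_name(chron, stem_node), ")", call. = FALSE)
    }
    younger <- if (crown <= n_tip) 0 else {
      if (is.na(chron$hpd_younger[crown])) {
        stop("missing HPD at crown node of lineage '", nm, "' (",
             node_name(chron, crown), ")", call. = FALSE)
      }
      chron$hpd_younger[crown]
    }
    out[[nm]] <- time_interval(chron$hpd_older[stem_node], younger)
  }
  out
}

#' Read lineage availability windows from TSV
#'
#' TSV with columns `lineage`, `older`, `younger` (`#` comments allowed).
#'
#' @param path Path to the TSV.
#' @return Named list of [time_interval()].
#' @export
read_lineage_windows <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  as_lineage_windows(raw)
}

# ---------------------------------------------------------------------------
# Classed front end

#' Plastid-transfer chronology under an endosymbiosis scenario
#'
#' The central analysis: given lineage availability windows (95% HPD-derived
#' age intervals for the stem of each plastid donor/recipient lineage) and a
#' scenario of serial transfers, computes the feasibility window of every
#' transfer, the scenario envelope, and whether the transfers can have
#' occurred in the stated order.
#'
#' @param scenario An [endosymbiosis_scenario()], or a preset name
#'   (`"stiller"`, `"bodyl"`).
#' @param windows Named list of [time_interval()] or a data frame with
#'   columns `lineage`, `older`, `younger` (e.g. from
#'   [read_lineage_windows()] or [lineage_windows_from_chronogram()]).
#' @return A `plastid_chronology` object with components `scenario`,
#'   `windows`, `events` (the [scenario_windows()] table), `envelope`
#'   (`NULL` if any event is infeasible) and `sequential` (the
#'   [sequential_feasibility()] report). Methods: `print`, `summary`,
#'   `as.data.frame`, `plot`.
#' @examples
#' w <- list(Rho = time_interval(1675, 1281), Cry = time_interval(1658, 440),
#'           Och = time_interval(1298, 622), Hap = time_interval(1943, 579),
#'           Myz = time_interval(1520, 696))
#' fit <- plastid_chronology("bodyl", w)
#' fit
#' @export
plastid_chronology <- function(scenario, windows) {
  if (is.character(scenario) && length(scenario) == 1L) {
    scenario <- scenario_preset(scenario)
  }
  stopifnot(inherits(scenario, "endosymbiosis_scenario"))
  windows <- as_lineage_windows(windows)
  events <- scenario_windows(scenario, windows)
  envelope <- if (all(events$feasible)) scenario_envelope(events) else NULL
  seq_rep <- sequential_feasibility(events)
  structure(list(scenario = scenario, windows = windows, events = events,
                 envelope = envelope, sequential = seq_rep),
            class = "plastid_chronology")
}

#' @export
print.plastid_chronology <- function(x, ...) {
  cat(sprintf("Plastid-transfer chronology, scenario '%s'\n",
              attr(x$scenario, "name")))
  ev <- x$events
  for (i in seq_len(nrow(ev))) {
    if (ev$feasible[i]) {
      cat(sprintf("  %s -> %s: [%g, %g] Ma, width %g\n", ev$donor[i],
                  ev$recipient[i], ev$older[i], ev$younger[i], ev$width[i]))
    } else {
      cat(sprintf("  %s -> %s: INFEASIBLE (overlap deficit %g Ma)\n",
                  ev$donor[i], ev$recipient[i], -ev$width[i]))
    }
  }
  if (!is.null(x$envelope)) {
    cat(sprintf("  envelope: [%g, %g] Ma, width %g\n",
                x$envelope$window$older, x$envelope$window$younger,
                x$envelope$width))
  }
  cat(sprintf("  sequential order feasible: %s\n",
              ifelse(x$sequential$feasible, "yes", "no")))
  invisible(x)
}

#' @export
summary.plastid_chronology <- function(object, ...) {
  ev <- object$events
  out <- list(
    scenario = attr(object$scenario, "name"),
    n_events = nrow(ev),
    n_feasible = sum(ev$feasible),
    narrowest_width = if (any(ev$feasible)) min(ev$width[ev$feasible])
                      else NA_real_,
    widest_width = if (any(ev$feasible)) max(ev$width[ev$feasible])
                   else NA_real_,
    envelope_width = if (!is.null(object$envelope)) object$envelope$width
                     else NA_real_,
    sequential_feasible = object$sequential$feasible
  )
  class(out) <- "summary.plastid_chronology"
  out
}

#' @export
print.summary.plastid_chronology <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d/%d transfers feasible\n", x$scenario,
              x$n_feasible, x$n_events))
  cat(sprintf("  event widths %g-%g Ma; envelope width %g Ma; order feasible: %s\n",
              x$narrowest_width, x$widest_width, x$envelope_width,
              ifelse(x$sequential_feasible, "yes", "no")))
  invisible(x)
}

#' @export
as.data.frame.plastid_chronology <- function(x, ...) x$events

#' @export
plot.plastid_chronology <- function(x, ...) {
  win <- x$windows
  ev <- x$events
  labels <- c(paste0(names(win), " (stem)"),
              paste(ev$donor, "->", ev$recipient))
  older <- c(vapply(win, function(w) w$older, numeric(1)), ev$older)
  younger <- c(vapply(win, function(w) w$younger, numeric(1)), ev$younger)
  n <- length(labels)
  cols <- c(rep("grey60", length(win)),
            ifelse(ev$feasible, "firebrick", "grey85"))
  graphics::plot(NULL, xlim = rev(range(c(older, younger), na.rm = TRUE)),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Age (Ma before present)", ylab = "",
                 main = sprintf("Transfer windows: %s",
                                attr(x$scenario, "name")), ...)
  graphics::axis(2, at = rev(seq_len(n)), labels = labels, las = 1,
                 cex.axis = 0.8)
  for (i in seq_len(n)) {
    if (is.na(older[i])) next
    y <- n - i + 1
    graphics::segments(older[i], y, younger[i], y, lwd = 6, col = cols[i],
                       lend = 1)
  }
  invisible(x)
}

#' Write a scenario report as TSV (events + envelope footer row)
#'
#' @param x A `plastid_chronology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chronology_report <- function(x, path) {
  stopifnot(inherits(x, "plastid_chronology"))
  ev <- x$events[, c("order", "donor", "recipient", "level", "older",
                     "younger", "width", "feasible")]
  if (!is.null(x$envelope)) {
    ev <- rbind(ev, data.frame(order = NA, donor = "(envelope)",
                               recipient = "", level = NA,
                               older = x$envelope$window$older,
                               younger = x$envelope$window$younger,
                               width = x$envelope$width, feasible = TRUE,
                               stringsAsFactors = FALSE))
  }
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Round an age to integer Ma, half away from zero
#'
#' Helper for comparing computed bounds against published integer tables.
#'
#' @param x Numeric ages.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
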