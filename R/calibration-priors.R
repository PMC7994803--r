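# Fossil-calibration prior densities used in the dating sensitivity
# analyses. Each constructor returns a "calibration_density": a list of
# vectorized pdf/cdf/quantile functions plus a sampler, on the age axis in
# Ma before present.

new_calibration_density <- function(family, pdf, cdf, quantile, sample,
                                    params) {
  structure(list(family = family, pdf = pdf, cdf = cdf, quantile = quantile,
                 sample = sample, params = params),
            class = "calibration_density")
}

#' @export
print.calibration_density <- function(x, ...) {
  q <- x$quantile(c(0.025, 0.5, 0.975))
  cat(sprintf("Calibration prior (%s): 2.5%% = %.4g, median = %.4g, 97.5%% = %.4g Ma\n",
              x$family, q[1], q[2], q[3]))
  invisible(x)
}

#' Soft-bound uniform calibration prior
#'
#' Constant density on `[tL, tU]` carrying mass `1 - 2 * tail_mass`, with a
#' continuous power-law decay below `tL` and a continuous exponential decay
#' above `tU`, each carrying exactly `tail_mass` (default 2.5%, the standard
#' soft-bound convention: `cdf(tL) = 0.025`, `cdf(tU) = 0.975`). The tail
#' families are matched for continuity of the density at the bounds.
#'
#' @param tL Younger bound (calibration minimum), Ma; must be `> 0`.
#' @param tU Older bound (calibration maximum), Ma; `tU > tL`.
#' @param tail_mass Prior mass beyond each bound; default 0.025.
#' @return A `calibration_density` with elements `pdf`, `cdf`, `quantile`,
#'   `sample(n)`.
#' @examples
#' d <- soft_uniform_density(1047, 1600)
#' d$cdf(c(1047, 1600))   # 0.025, 0.975
#' @export
soft_uniform_density <- function(tL, tU, tail_mass = 0.025) {
  if (!(tL > 0)) stop("soft_uniform_density: tL must be > 0", call. = FALSE)
  if (!(tU > tL)) stop("soft_uniform_density: need tL < tU", call. = FALSE)
  if (!(tail_mass > 0 && tail_mass < 0.5)) {
    stop("tail_mass must be in (0, 0.5)", call. = FALSE)
  }
  h <- (1 - 2 * tail_mass) / (tU - tL)       # plateau density
  gam <- h * tL / tail_mass - 1              # left power exponent, > -1
  lam <- h / tail_mass                       # right exponential rate
  pdf <- function(x) {
    out <- numeric(length(x))
    lo <- x > 0 & x < tL
    mid <- x >= tL & x <= tU
    hi <- x > tU
    out[lo] <- h * (x[lo] / tL)^gam
    out[mid] <- h
    out[hi] <- h * exp(-lam * (x[hi] - tU))
    out
  }
  cdf <- function(x) {
    out <- numeric(length(x))
    lo <- x > 0 & x < tL
    mid <- x >= tL & x <= tU
    hi <- x > tU
    out[lo] <- tail_mass * (x[lo] / tL)^(gam + 1)
    out[mid] <- tail_mass + h * (x[mid] - tL)
    out[hi] <- 1 - tail_mass * exp(-lam * (x[hi] - tU))
    out
  }
  quantile <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    out <- numeric(length(p))
    lo <- p < tail_mass
    mid <- p >= tail_mass & p <= 1 - tail_mass
    hi <- p > 1 - tail_mass
    out[lo] <- tL * (p[lo] / tail_mass)^(1 / (gam + 1))
    out[mid] <- tL + (p[mid] - tail_mass) / h
    out[hi] <- tU - log((1 - p[hi]) / tail_mass) / lam
    out
  }
  sample <- function(n) quantile(stats::runif(n))
  new_calibration_density("soft_uniform", pdf, cdf, quantile, sample,
                          list(tL = tL, tU = tU, tail_mass = tail_mass))
}

# Owen's T function by quadrature; accurate enough for the 1e-8 solver
# tolerance used below.
owens_t <- function(h, a) {
  if (a == 0) return(0)
  f <- function(x) exp(-0.5 * h^2 * (1 + x^2)) / (1 + x^2)
  sgn <- sign(a)
  val <- stats::integrate(f, 0, abs(a), rel.tol = 1e-12,
                          abs.tol = 1e-14)$value
  sgn * val / (2 * pi)
}

skew_normal_cdf <- function(x, xi, beta, alpha) {
  vapply(x, function(xx) {
    z <- (xx - xi) / beta
    p <- stats::pnorm(z) - 2 * owens_t(z, alpha)
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Skew-normal calibration prior with solved scale
#'
#' A skew-normal density with location anchored at the calibration minimum
#' `tL` (the "literal" reading of the fossil record: minima close to the
#' true node age), fixed shape `alpha` (default 10), and scale `beta` solved
#' by root-finding so that the cumulative probability at the maximum bound
#' `tU` equals `1 - tail_mass` (97.5% by default), to within 1e-8.
#'
#' @param tL Younger bound (location anchor), Ma.
#' @param tU Older bound at which the 97.5% cumulative probability is
#'   anchored, Ma; `tU > tL`.
#' @param alpha Skewness parameter; default 10.
#' @param tail_mass Upper-tail mass beyond `tU`; default 0.025.
#' @return A `calibration_density`; `$params$beta` holds the solved scale.
#' @examples
#' d <- solve_skew_normal(1047, 1600)
#' d$cdf(1600)    # 0.975
#' @export
solve_skew_normal <- function(tL, tU, alpha = 10, tail_mass = 0.025) {
  if (!(tU > tL)) stop("solve_skew_normal: need tL < tU", call. = FALSE)
  target <- 1 - tail_mass
  g <- function(beta) skew_normal_cdf(tU, tL, beta, alpha) - target
  lo <- (tU - tL) * 1e-6
  hi <- (tU - tL) * 10
  flo <- g(lo)
  fhi <- g(hi)
  tries <- 0L
  while (flo * fhi > 0 && tries < 60L) {
    hi <- hi * 2
    fhi <- g(hi)
    tries <- tries + 1L
  }
  if (flo * fhi > 0) {
    stop(sprintf("skew-normal scale solver failed to bracket a root: g(%g) = %g, g(%g) = %g",
                 lo, flo, hi, fhi), call. = FALSE)
  }
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10 * (tU - tL))$root
  pdf <- function(x) {
    z <- (x - tL) / beta
    2 / beta * stats::dnorm(z) * stats::pnorm(alpha * z)
  }
  cdf <- function(x) skew_normal_cdf(x, tL, beta, alpha)
  quantile <- function(p) {
    stopifnot(all(p > 0 & p < 1))
    vapply(p, function(pp) {
      lo_q <- tL - 10 * beta
      hi_q <- tL + 50 * beta
      stats::uniroot(function(x) cdf(x) - pp, c(lo_q, hi_q),
                     tol = 1e-10 * beta)$root
    }, numeric(1))
  }
  delta <- alpha / sqrt(1 + alpha^2)
  sample <- function(n) {
    u0 <- stats::rnorm(n)
    u1 <- stats::rnorm(n)
    z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
    tL + beta * z
  }
  new_calibration_density("skew_normal", pdf, cdf, quantile, sample,
                          list(tL = tL, tU = tU, alpha = alpha, beta = beta,
                               tail_mass = tail_mass))
}

#' Truncated-Cauchy calibration prior
#'
#' The loose, heavy-tailed reading of a fossil minimum: above `tL` a Cauchy
#' density with location `tL * (1 + p)` and scale `c * tL`, truncated at
#' `tL` and carrying mass `1 - pL`; below `tL` a continuous power-law decay
#' carrying the soft-minimum mass `pL`. Defaults follow the short-tail
#' variant (`p = 0`, `c = 0.1`, `pL = 0.01`); `c = 10` gives the long-tail
#' variant. The density is proper, so sampling uses the exact inverse CDF;
#' an optional `ceiling` (e.g. a root maximum of 3200 Ma) truncates draws
#' for downstream use.
#'
#' @param tL Younger bound (calibration minimum), Ma; `> 0`.
#' @param p Mode offset as a fraction of `tL`; default 0.
#' @param c_spread Spread as a fraction of `tL`; default 0.1.
#' @param pL Mass below `tL`; default 0.01.
#' @return A `calibration_density`; `$sample(n, ceiling = Inf)`.
#' @examples
#' d <- trunc_cauchy_density(1047)
#' d$cdf(1047)   # 0.01
#' @export
trunc_cauchy_density <- function(tL, p = 0, c_spread = 0.1, pL = 0.01) {
  if (!(tL > 0)) stop("trunc_cauchy_density: tL must be > 0", call. = FALSE)
  if (p < 0) stop("trunc_cauchy_density: p must be >= 0", call. = FALSE)
  if (!(c_spread > 0)) stop("trunc_cauchy_density: c must be > 0",
                            call. = FALSE)
  if (!(pL > 0 && pL < 1)) stop("trunc_cauchy_density: pL must be in (0,1)",
                                call. = FALSE)
  loc <- tL * (1 + p)
  sc <- c_spread * tL
  A <- 1 - stats::pcauchy(tL, loc, sc)        # Cauchy mass above tL
  f_tL <- (1 - pL) * stats::dcauchy(tL, loc, sc) / A
  gam <- f_tL * tL / pL - 1                   # left power exponent, > -1
  pdf <- function(x) {
    out <- numeric(length(x))
    lo <- x > 0 & x < tL
    hi <- x >= tL
    out[lo] <- f_tL * (x[lo] / tL)^gam
    out[hi] <- (1 - pL) * stats::dcauchy(x[hi], loc, sc) / A
    out
  }
  cdf <- function(x) {
    out <- numeric(length(x))
    lo <- x > 0 & x < tL
    hi <- x >= tL
    out[lo] <- pL * (x[lo] / tL)^(gam + 1)
    out[hi] <- pL + (1 - pL) *
      (stats::pcauchy(x[hi], loc, sc) - stats::pcauchy(tL, loc, sc)) / A
    out
  }
  quantile <- function(pr) {
    stopifnot(all(pr > 0 & pr < 1))
    out <- numeric(length(pr))
    lo <- pr < pL
    hi <- !lo
    out[lo] <- tL * (pr[lo] / pL)^(1 / (gam + 1))
    out[hi] <- stats::qcauchy(stats::pcauchy(tL, loc, sc) +
                                (pr[hi] - pL) / (1 - pL) * A, loc, sc)
    out
  }
  sample <- function(n, ceiling = Inf) {
    x <- quantile(stats::runif(n))
    if (is.finite(ceiling)) x <- pmin(x, ceiling)
    x
  }
  new_calibration_density("trunc_cauchy", pdf, cdf, quantile, sample,
                          list(tL = tL, p = p, c = c_spread, pL = pL))
}

#' Construct the calibration prior for one table row
#'
#' Dispatches on the density family used in the dating sensitivity
#' analyses.
#'
#' @param younger,older Bounds in Ma (older may be `NA` for the Cauchy
#'   families, which only use the minimum).
#' @param family One of `"soft_uniform"`, `"skew_normal"`,
#'   `"trunc_cauchy_short"`, `"trunc_cauchy_long"`.
#' @param ... Passed to the family constructor.
#' @return A `calibration_density`.
#' @export
calibration_density <- function(younger, older = NA,
                                family = c("soft_uniform", "skew_normal",
                                           "trunc_cauchy_short",
                                           "trunc_cauchy_long"), ...) {
  family <- match.arg(family)
  switch(family,
         soft_uniform = soft_uniform_density(younger, older, ...),
         skew_normal = solve_skew_normal(younger, older, ...),
         trunc_cauchy_short = trunc_cauchy_density(younger, c_spread = 0.1,
                                                   ...),
         trunc_cauchy_long = trunc_cauchy_density(younger, c_spread = 10,
                                                  ...))
}

#' Prior quantile table for every clade of a calibration table
#'
#' @param table A `calibration_table` from [read_calibration_table()].
#' @param family Density family (see [calibration_density()]).
#' @param probs Quantile probabilities; default `c(0.025, 0.5, 0.975)`.
#' @param ... Passed to the family constructor.
#' @return Data frame with one row per clade and one column per quantile.
#' @export
prior_quantile_table <- function(table, family = "soft_uniform",
                                 probs = c(0.025, 0.5, 0.975), ...) {
  stopifnot(inherits(table, "calibration_table"))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    d <- calibration_density(table$younger[i], table$older[i],
                             family = family, ...)
    q <- d$quantile(probs)
    stats::setNames(as.data.frame(as.list(q)),
                    paste0("q", format(probs * 100, trim = TRUE)))
  })
  out <- cbind(data.frame(clade = table$clade, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Consistency report for calibrations placed on a tree
#'
#' Report-only guard: flags (i) clades whose maximum bound is below their
#' minimum, (ii) a descendant clade whose younger bound exceeds an ancestor
#' clade's older bound (impossible jointly), and (iii) clades that cannot be
#' resolved to a node of the supplied topology.
#'
#' @param table A `calibration_table`.
#' @param chron Optional [chronogram()] (topology used for placement).
#' @param clade_tips Optional named list mapping clade name to a character
#'   vector of tip labels; required for checks (ii)/(iii) on clades whose
#'   name is not itself a tip label.
#' @return A `calibration_report`: data frame of violations with columns
#'   `type` (`"min_gt_max"`, `"nested_conflict"`, `"unresolvable"`),
#'   `clade`, `detail`. Zero rows means no violations.
#' @export
validate_calibrations <- function(table, chron = NULL, clade_tips = NULL) {
  stopifnot(inherits(table, "calibration_table"))
  viol <- list()
  bad <- which(!is.na(table$older) & !is.na(table$younger) &
                 table$older < table$younger)
  for (i in bad) {
    viol[[length(viol) + 1L]] <-
      data.frame(type = "min_gt_max", clade = table$clade[i],
                 detail = sprintf("min %g > max %g", table$younger[i],
                                  table$older[i]),
                 stringsAsFactors = FALSE)
  }
  if (!is.null(chron)) {
    phy <- chron$phy
    nodes <- rep(NA_integer_, nrow(table))
    for (i in seq_len(nrow(table))) {
      cl <- table$clade[i]
      tips <- if (!is.null(clade_tips) && cl %in% names(clade_tips)) {
        clade_tips[[cl]]
      } else if (cl %in% phy$tip.label) {
        cl
      } else {
        NULL
      }
      if (is.null(tips) || !all(tips %in% phy$tip.label)) {
        viol[[length(viol) + 1L]] <-
          data.frame(type = "unresolvable", clade = cl,
                     detail = "no tip set resolves this clade on the tree",
                     stringsAsFactors = FALSE)
      } else {
        nodes[i] <- mrca_of_tips(phy, tips)
      }
    }
    parent <- node_parents(phy)
    is_ancestor <- function(anc, des) {
      while (des != 0L) {
        if (des == anc) return(TRUE)
        des <- parent[des]
      }
      FALSE
    }
    res <- which(!is.na(nodes))
    for (i in res) {
      for (j in res) {
        if (i == j || nodes[i] == nodes[j]) next
        # j ancestor of i: i's min must not exceed j's max
        if (is_ancestor(nodes[j], nodes[i]) &&
            !is.na(table$younger[i]) && !is.na(table$older[j]) &&
            table$younger[i] > table$older[j]) {
          viol[[length(viol) + 1L]] <-
            data.frame(type = "nested_conflict", clade = table$clade[i],
                       detail = sprintf(
                         "min %g exceeds ancestor '%s' max %g",
                         table$younger[i], table$clade[j], table$older[j]),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(0), clade = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  class(out) <- c("calibration_report", class(out))
  out
}

#' @export
print.calibration_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Calibration report: no violations\n")
  } else {
    cat(sprintf("Calibration report: %d violation(s)\n", nrow(x)))
    NextMethod()
  }
  invisible(x)
}
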