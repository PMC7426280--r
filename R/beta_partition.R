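#' Shared and exclusive components of a site pair
#'
#' For two abundance vectors over a common species universe (absences are
#' zeros or missing names), computes the a/b/c components that all the
#' pairwise beta measures are built from.
#'
#' Incidence mode: `a` = number of species present at both sites, `b` =
#' species exclusive to the first, `c` = exclusive to the second. Abundance
#' mode (the individual-level generalisation): `a` = sum over species of
#' min(x1, x2), `b` = sum of the surplus of site 1, `c` = sum of the
#' surplus of site 2.
#'
#' @param x1,x2 named numeric abundance vectors.
#' @param mode `"incidence"` or `"abundance"`.
#' @return Object of class `shared_exclusive`: list with `a`, `b`, `c`,
#'   `mode`.
#' @export
shared_exclusive <- function(x1, x2, mode = c("incidence", "abundance")) {
  mode <- match.arg(mode)
  al <- align_pair(x1, x2)
  if (sum(al$x1) + sum(al$x2) == 0) stop("both communities are empty")
  if (mode == "incidence") {
    p1 <- al$x1 > 0; p2 <- al$x2 > 0
    out <- list(a = sum(p1 & p2), b = sum(p1 & !p2), c = sum(!p1 & p2))
  } else {
    out <- list(a = sum(pmin(al$x1, al$x2)),
                b = sum(pmax(al$x1 - al$x2, 0)),
                c = sum(pmax(al$x2 - al$x1, 0)))
  }
  structure(c(out, mode = mode), class = "shared_exclusive")
}

# align two abundance vectors on the union of their species names;
# unnamed vectors of equal length are taken as already aligned
align_pair <- function(x1, x2) {
  if (is.null(names(x1)) && is.null(names(x2))) {
    if (length(x1) != length(x2))
      stop("unnamed vectors must have equal length")
    return(list(x1 = x1, x2 = x2))
  }
  if (is.null(names(x1)) || is.null(names(x2)))
    stop("either both or neither vector must be named")
  univ <- union(names(x1), names(x2))
  f <- function(x) {
    y <- stats::setNames(rep(0, length(univ)), univ)
    y[names(x)] <- x
    y
  }
  list(x1 = f(x1), x2 = f(x2))
}

#' Partition total beta diversity into replacement and richness difference
#'
#' Decomposes the Jaccard dissimilarity between two communities,
#' \deqn{\beta_{Tot} = (b + c) / (a + b + c),}
#' into an additive replacement (turnover) component and a richness
#' difference component:
#' \deqn{\beta_{Repl} = 2\min(b, c) / (a + b + c), \qquad
#'       \beta_{Rich} = |b - c| / (a + b + c),}
#' so that \eqn{\beta_{Tot} = \beta_{Repl} + \beta_{Rich}} exactly. The
#' replacement term counts each substitution twice because a substitution
#' involves one species from each site; the richness term is the surplus
#' of exclusive species (or individuals, in abundance mode) of the richer
#' site. Component shares are reported as percentages of the total
#' (both 0 when the total is 0).
#'
#' @param se a [shared_exclusive()] object, or the component `a` given the
#'   three components directly.
#' @param b,c exclusive components when `se` is given as a number.
#' @return Object of class `beta_decomposition`: list with `a`, `b`, `c`,
#'   `mode`, `beta_tot`, `beta_repl`, `beta_rich`, `share_repl`,
#'   `share_rich`.
#' @examples
#' beta_decompose(shared_exclusive(c(A = 3, B = 1), c(B = 2, C = 2)))
#' beta_decompose(4, 28, 0)  # all richness difference
#' @export
beta_decompose <- function(se, b = NULL, c = NULL) {
  if (inherits(se, "shared_exclusive")) {
    a <- se$a; b <- se$b; c <- se$c; mode <- se$mode
  } else {
    a <- se; mode <- NA_character_
    if (is.null(b) || is.null(c)) stop("supply b and c, or a shared_exclusive")
  }
  if (any(c(a, b, c) < 0)) stop("a, b, c must be non-negative")
  denom <- a + b + c
  if (denom == 0) stop("a + b + c must be positive")
  beta_repl <- 2 * min(b, c) / denom
  beta_rich <- abs(b - c) / denom
  beta_tot <- beta_repl + beta_rich
  structure(
    list(a = a, b = b, c = c, mode = mode,
         beta_tot = beta_tot, beta_repl = beta_repl, beta_rich = beta_rich,
         share_repl = if (beta_tot > 0) 100 * beta_repl / beta_tot else 0,
         share_rich = if (beta_tot > 0) 100 * beta_rich / beta_tot else 0),
    class = "beta_decomposition"
  )
}

#' @export
print.beta_decomposition <- function(x, ...) {
  cat(sprintf(
    "a = %g, b = %g, c = %g%s\nbeta_tot = %.3f = repl %.3f (%d%%) + rich %.3f (%d%%)\n",
    x$a, x$b, x$c,
    if (is.na(x$mode)) "" else paste0(" (", x$mode, ")"),
    x$beta_tot, x$beta_repl, round(x$share_repl),
    x$beta_rich, round(x$share_rich)))
  invisible(x)
}

#' Beta decomposition of a site pair from a community matrix
#'
#' Pools each site in the requested stage view and decomposes their
#' dissimilarity.
#'
#' @param m community_matrix.
#' @param site1,site2 site labels.
#' @param stage_view `"total"` or `"adult"`.
#' @param mode `"incidence"` or `"abundance"`.
#' @return A [beta_decompose()] result.
#' @export
beta_pair <- function(m, site1, site2, stage_view = c("total", "adult"),
                      mode = c("incidence", "abundance")) {
  stage_view <- match.arg(stage_view)
  mode <- match.arg(mode)
  beta_decompose(shared_exclusive(pool(m, site1, stage_view),
                                  pool(m, site2, stage_view), mode))
}

#' Grouped beta decompositions (by taxon and status class)
#'
#' Runs the pairwise decomposition for every combination of a taxon filter,
#' a status filter and a mode, on one stage view. Groups with no species at
#' either site are kept in the output flagged `defined = FALSE` rather than
#' dropped.
#'
#' @param m community_matrix.
#' @param site1,site2 site labels.
#' @param stage_view `"total"` or `"adult"`.
#' @param orders taxon filters; `NA` means all species (default
#'   `c(NA, "Araneae", "Coleoptera", "Hemiptera")`).
#' @param statuses status filters; `NA` means all statuses.
#' @param modes subset of `c("incidence", "abundance")`.
#' @return data.frame, one row per (order, status, mode), with a/b/c, the
#'   three beta components, shares and the `defined` flag.
#' @export
grouped_beta <- function(m, site1, site2, stage_view = c("total", "adult"),
                         orders = c(NA, "Araneae", "Coleoptera", "Hemiptera"),
                         statuses = c(NA, "endemic", "native", "introduced"),
                         modes = c("incidence", "abundance")) {
  stage_view <- match.arg(stage_view)
  rows <- list()
  for (ord in orders) for (st in statuses) {
    sub <- subset_species(m,
                          order_name = if (is.na(ord)) NULL else ord,
                          status = if (is.na(st)) NULL else st)
    x1 <- tryCatch(pool(sub, site1, stage_view), error = function(e) numeric(0))
    x2 <- tryCatch(pool(sub, site2, stage_view), error = function(e) numeric(0))
    base <- data.frame(order_name = ifelse(is.na(ord), "all", ord),
                       status = ifelse(is.na(st), "all", st),
                       stage = stage_view, stringsAsFactors = FALSE)
    for (md in modes) {
      if (length(x1) + length(x2) == 0) {
        rows[[length(rows) + 1L]] <- cbind(
          base, data.frame(mode = md, defined = FALSE, a = NA_real_,
                           b = NA_real_, c = NA_real_, beta_tot = NA_real_,
                           beta_repl = NA_real_, beta_rich = NA_real_,
                           share_repl = NA_real_, share_rich = NA_real_))
        next
      }
      d <- beta_decompose(shared_exclusive(x1, x2, md))
      rows[[length(rows) + 1L]] <- cbind(
        base, data.frame(mode = md, defined = TRUE, a = d$a, b = d$b,
                         c = d$c, beta_tot = d$beta_tot,
                         beta_repl = d$beta_repl, beta_rich = d$beta_rich,
                         share_repl = d$share_repl,
                         share_rich = d$share_rich))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
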