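#' Hill-series summary of one pooled community
#'
#' Computes, from a species abundance vector, the observed richness S
#' (Hill number of order 0), the exponential of Shannon entropy
#' (order 1), the inverse Simpson concentration (order 2) and the inverse
#' Berger-Parker dominance (order infinity), together with the rarity
#' figures: singletons F1 (species with exactly one individual), doubletons
#' F2 (exactly two) and the percentage of rare species 100*(F1+F2)/S.
#'
#' With relative abundances \eqn{p_i = x_i / N}:
#' \deqn{\exp H' = \exp(-\sum_i p_i \ln p_i), \quad
#'       1/D = 1 / \sum_i p_i^2, \quad
#'       1/d = N / \max_i x_i.}
#' Shannon entropy uses the natural logarithm; the exponential makes the
#' base immaterial. Simpson is the plug-in concentration \eqn{\sum p_i^2},
#' not the small-sample unbiased form. The Hill numbers decrease with
#' order: \eqn{S \ge \exp H' \ge 1/D \ge 1/d \ge 1}.
#'
#' @param x numeric vector of species abundances (zeros allowed, dropped).
#' @return Object of class `alpha_summary`: list with `N`, `S`, `F1`, `F2`,
#'   `rare_pct`, `expH`, `invD`, `invd`.
#' @examples
#' hill_series(c(8, 2))
#' @export
hill_series <- function(x) {
  x <- check_abundances(x)
  N <- sum(x)
  S <- length(x)
  p <- x / N
  H <- -sum(p * log(p))
  F1 <- sum(x == 1)
  F2 <- sum(x == 2)
  structure(
    list(N = N, S = S, F1 = F1, F2 = F2,
         rare_pct = 100 * (F1 + F2) / S,
         expH = exp(H),
         invD = 1 / sum(p^2),
         invd = N / max(x)),
    class = "alpha_summary"
  )
}

#' @export
print.alpha_summary <- function(x, ...) {
  cat(sprintf(
    "N = %d, S = %d, F1 = %d, F2 = %d, rare%% = %.2f\nexp H' = %.2f, 1/D = %.2f, 1/d = %.2f\n",
    x$N, x$S, x$F1, x$F2, x$rare_pct, x$expH, x$invD, x$invd))
  invisible(x)
}

#' @export
as.data.frame.alpha_summary <- function(x, ...) {
  data.frame(N = x$N, S = x$S, F1 = x$F1, F2 = x$F2,
             rare_pct = x$rare_pct, expH = x$expH,
             invD = x$invD, invd = x$invd)
}

#' Inverse Berger-Parker index
#'
#' N over the abundance of the most abundant species; the Hill number of
#' infinite order. Larger values mean a less dominated, more even
#' community.
#'
#' @param x numeric abundance vector.
#' @return A single number \eqn{\ge 1}.
#' @export
inverse_berger_parker <- function(x) {
  x <- check_abundances(x)
  sum(x) / max(x)
}

#' Dominance ranking and the 50-percent dominant set
#'
#' Ranks species by abundance (ties broken lexicographically by species id)
#' and extracts the minimal prefix of the ranking whose cumulative share of
#' individuals reaches the threshold — by default the set of most common
#' species that together represent at least half of the community.
#' Reaching the threshold exactly qualifies.
#'
#' @param x named numeric abundance vector.
#' @param threshold cumulative share in (0, 1]; default 0.5.
#' @param species_meta optional species metadata (as in a
#'   [community_matrix()]) used to annotate ranks with status and trophic
#'   labels.
#' @return Object of class `dominance_report`: list with `ranking` (a
#'   data.frame of species, abundance, share, `share_pct` as rounded
#'   integer percentage, cumulative share, and `in_dominant_set`),
#'   `dominant_set` (character vector of species ids) and
#'   `dominant_species` (one-row data.frame for rank 1).
#' @export
dominance <- function(x, threshold = 0.5, species_meta = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  x <- check_abundances(x)
  if (is.null(names(x))) names(x) <- sprintf("sp%03d", seq_along(x))
  ord <- order(-x, names(x))
  x <- x[ord]
  N <- sum(x)
  share <- x / N
  cum <- cumsum(share)
  k <- which(cum >= threshold - 1e-12)[1]
  rk <- data.frame(species = names(x),
                   abundance = unname(x),
                   share = unname(share),
                   share_pct = round(unname(share) * 100),
                   cum_share = unname(cum),
                   in_dominant_set = seq_along(x) <= k,
                   stringsAsFactors = FALSE)
  if (!is.null(species_meta)) {
    idx <- match(rk$species, species_meta$species)
    rk$status <- species_meta$status[idx]
    rk$trophic <- species_meta$trophic[idx]
    rk$order_name <- species_meta$order_name[idx]
  }
  structure(
    list(ranking = rk,
         dominant_set = rk$species[rk$in_dominant_set],
         dominant_species = rk[1, , drop = FALSE],
         threshold = threshold, N = N),
    class = "dominance_report"
  )
}

#' @export
print.dominance_report <- function(x, ...) {
  n <- length(x$dominant_set)
  cat(sprintf("dominant set (cumulative share >= %d%%): %d species\n",
              round(100 * x$threshold), n))
  print(utils::head(x$ranking, max(n, 5)), row.names = FALSE)
  invisible(x)
}

# shared input validation: positive total, finite, non-negative
check_abundances <- function(x) {
  if (!is.numeric(x) || length(x) == 0)
    stop("abundance vector must be non-empty numeric")
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundances must be finite and non-negative")
  x <- x[x > 0]
  if (length(x) == 0) stop("community is empty (all abundances zero)")
  x
}

#' Alpha-diversity table for sites and stage views
#'
#' Applies [hill_series()] to each requested (site, stage view)
#' combination of a community matrix and binds the results into one table.
#'
#' @param m community_matrix.
#' @param sites_ site labels (default: all sites).
#' @param stage_views subset of `c("total", "adult")`.
#' @return data.frame with one row per site x stage view.
#' @export
alpha_table <- function(m, sites_ = sites(m),
                        stage_views = c("total", "adult")) {
  rows <- list()
  for (sv in stage_views) for (st in sites_) {
    x <- pool(m, st, sv)
    if (length(x) == 0) next
    rows[[paste(st, sv)]] <-
      cbind(data.frame(site = st, stage = sv, stringsAsFactors = FALSE),
            as.data.frame(hill_series(x)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
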