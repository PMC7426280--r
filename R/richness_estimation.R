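#' Chao1 nonparametric richness estimator
#'
#' Classic (uncorrected) Chao1: \eqn{S + F_1^2 / (2 F_2)}. When no
#' doubletons are present the \eqn{F_1(F_1-1)/2} fallback is used. Accepts
#' fractional singleton/doubleton counts, as produced by averaging over
#' randomized sample orders. The bias-corrected variant
#' \eqn{S + F_1(F_1-1)/(2(F_2+1))} is available via `corrected = TRUE`.
#'
#' @param S observed species richness.
#' @param F1 number of singletons (species with exactly one individual).
#' @param F2 number of doubletons (exactly two individuals).
#' @param corrected use the bias-corrected form.
#' @return Estimated richness, always \eqn{\ge S}.
#' @examples
#' chao1(88, 19, 12)   # 103.04
#' @export
chao1 <- function(S, F1, F2, corrected = FALSE) {
  stopifnot(S >= 0, F1 >= 0, F2 >= 0)
  if (corrected) return(S + F1 * (F1 - 1) / (2 * (F2 + 1)))
  if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
}

#' First-order jackknife richness estimator
#'
#' \eqn{S + Q_1 (m-1)/m}, where \eqn{Q_1} is the number of species
#' occurring in exactly one sample (unique species) and m the number of
#' samples. Fractional order-averaged \eqn{Q_1} is accepted.
#'
#' @param S observed species richness.
#' @param Q1 number of species occurring in exactly one sample.
#' @param m number of samples (\eqn{\ge 1}).
#' @return Estimated richness.
#' @export
jackknife1 <- function(S, Q1, m) {
  stopifnot(S >= 0, Q1 >= 0)
  if (m < 1) stop("m must be >= 1")
  S + Q1 * (m - 1) / m
}

#' Final slope of an accumulation curve
#'
#' The last first-difference of a per-level curve of estimates,
#' \eqn{E(m) - E(m-1)}; values near zero indicate that the inventory has
#' stabilised.
#'
#' @param values numeric vector of estimates at accumulation levels 1..m.
#' @return A single number.
#' @export
final_slope <- function(values) {
  if (length(values) < 2) stop("need at least 2 accumulation levels")
  n <- length(values)
  values[n] - values[n - 1]
}

#' Sample-based species accumulation with randomized sample orders
#'
#' For each of `R` uniformly random orderings of a site's samples, records
#' at every accumulation level the observed richness S, the abundance-based
#' singletons F1 and doubletons F2 of the pooled individuals, and the
#' incidence-based uniques Q1 (species occurring in exactly one of the
#' included samples), then averages over orders. The level-m means are the
#' order-averaged quantities that feed [chao1()] and [jackknife1()];
#' because every ordering ends with the full pool, `mean_S` at the last
#' level equals the observed S exactly, while `mean_F1`/`mean_F2`/`mean_Q1`
#' equal their pooled-community values.
#'
#' @param m community_matrix.
#' @param site site label.
#' @param stage_view `"total"` or `"adult"`.
#' @param R number of random sample orders (default 100).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame of class `accumulation_curve`: columns `level`,
#'   `mean_S`, `mean_F1`, `mean_F2`, `mean_Q1`; attributes `R` and `seed`.
#' @export
accumulate <- function(m, site, stage_view = c("total", "adult"),
                       R = 100, seed = NULL) {
  stage_view <- match.arg(stage_view)
  if (R < 1) stop("R must be >= 1")
  mat <- site_sample_matrix(m, site, stage_view)
  if (ncol(mat) == 0) stop("site has no samples: ", site)
  if (!is.null(seed)) set.seed(seed)
  ns <- ncol(mat)
  sums <- matrix(0, 4, ns)  # accumulators for S, F1, F2, Q1 per level
  for (r in seq_len(R)) {
    ord <- if (ns == 1) 1L else sample.int(ns)
    perm <- mat[, ord, drop = FALSE]
    cum <- row_cumsum(perm)          # cumulative abundance per species
    inc <- row_cumsum(perm > 0)      # cumulative occurrence count
    sums[1, ] <- sums[1, ] + colSums(cum > 0)
    sums[2, ] <- sums[2, ] + colSums(cum == 1)
    sums[3, ] <- sums[3, ] + colSums(cum == 2)
    sums[4, ] <- sums[4, ] + colSums(inc == 1)
  }
  out <- data.frame(level = seq_len(ns),
                    mean_S = sums[1, ] / R,
                    mean_F1 = sums[2, ] / R,
                    mean_F2 = sums[3, ] / R,
                    mean_Q1 = sums[4, ] / R)
  attr(out, "R") <- R
  attr(out, "seed") <- seed
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

# cumulative row sums of a species x samples matrix, safe for 0/1 rows/cols
row_cumsum <- function(mm) {
  mm <- mm * 1  # logical -> numeric
  if (ncol(mm) == 1) return(mm)
  t(apply(mm, 1, cumsum))
}

#' Individual-based rarefaction (expected richness)
#'
#' Expected number of species in a random subsample of n individuals drawn
#' without replacement from the pooled community, via the hypergeometric
#' closed form
#' \deqn{E[S(n)] = \sum_s \left[1 - \binom{N - x_s}{n} / \binom{N}{n}\right]}
#' evaluated with log-binomial coefficients for numerical safety.
#'
#' @param x species abundance vector.
#' @param n number of individuals to rarefy to, \eqn{0 \le n \le N}.
#' @return Expected richness at n individuals.
#' @export
rarefy_individuals <- function(x, n) {
  x <- check_abundances(x)
  N <- sum(x)
  if (n < 0 || n > N) stop("n must be between 0 and N = ", N)
  if (n == 0) return(0)
  # lchoose(N - x, n) is -Inf whenever N - x < n: that species is certain
  sum(1 - exp(lchoose(N - x, n) - lchoose(N, n)))
}

#' Richness estimate with completeness and slope diagnostics
#'
#' Runs the sample-order-averaged accumulation of [accumulate()], builds
#' the per-level estimator curve (Chao1 from mean S/F1/F2 or first-order
#' jackknife from mean Q1), and reports the estimate at full accumulation,
#' the final slope of the estimator curve, and sampling completeness
#' (observed S over estimated S). Optionally also rarefies the pooled
#' community to a reference number of individuals, which is how a
#' larger-sample site is compared against a smaller one.
#'
#' @param m community_matrix.
#' @param site site label.
#' @param stage_view `"total"` or `"adult"`.
#' @param estimator `"chao1"` or `"jackknife1"`.
#' @param R number of sample-order randomizations.
#' @param seed optional integer seed.
#' @param rarefy_to optional number of individuals for rarefied richness.
#' @param corrected use bias-corrected Chao1.
#' @return Object of class `richness_estimate`: list with `estimator`,
#'   `S_obs`, `N`, `value`, `slope`, `completeness`, `rarefied_S`, `curve`
#'   (the estimator values per level) and the accumulation curve.
#' @export
richness_estimate <- function(m, site, stage_view = c("total", "adult"),
                              estimator = c("chao1", "jackknife1"),
                              R = 100, seed = NULL, rarefy_to = NULL,
                              corrected = FALSE) {
  stage_view <- match.arg(stage_view)
  estimator <- match.arg(estimator)
  acc <- accumulate(m, site, stage_view, R = R, seed = seed)
  est_curve <- if (estimator == "chao1") {
    mapply(chao1, acc$mean_S, acc$mean_F1, acc$mean_F2,
           MoreArgs = list(corrected = corrected))
  } else {
    mapply(jackknife1, acc$mean_S, acc$mean_Q1, acc$level)
  }
  nlev <- nrow(acc)
  x <- pool(m, site, stage_view)
  S_obs <- length(x)
  value <- est_curve[nlev]
  structure(
    list(estimator = estimator,
         site = site, stage_view = stage_view,
         N = sum(x), S_obs = S_obs,
         value = value,
         slope = if (nlev >= 2) final_slope(est_curve) else NA_real_,
         completeness = S_obs / value,
         rarefied_S = if (is.null(rarefy_to)) NA_real_
                      else rarefy_individuals(x, rarefy_to),
         curve = est_curve,
         accumulation = acc),
    class = "richness_estimate"
  )
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(
    "%s | %s view: N = %d, S = %d\n%s estimate = %.2f, completeness = %.2f, final slope = %.3f\n",
    x$site, x$stage_view, x$N, x$S_obs, x$estimator, x$value,
    x$completeness, x$slope))
  if (!is.na(x$rarefied_S))
    cat(sprintf("rarefied S = %.2f\n", x$rarefied_S))
  invisible(x)
}
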