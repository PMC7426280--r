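#' Specification for a synthetic paired-site community
#'
#' Describes a two-site arthropod-style survey: how many species the sites
#' share, how many are exclusive to each, the species abundance
#' distribution, the colonisation-status composition, the juvenile
#' fraction, and the number of samples per site. The defaults emulate a
#' two-garden inventory of ten samples per site with a heavy-tailed
#' (log-series) abundance distribution, a moderately large shared-species
#' pool, and an introduced-dominated species mix.
#'
#' @param n_species_shared species present at both sites.
#' @param n_species_only_A,n_species_only_B species exclusive to each site.
#' @param abundance_model list: `list(model = "log_series", theta = p)` with
#'   p in (0,1); `list(model = "lognormal", mu =, sigma =)`; or
#'   `list(model = "uniform", k =)` (discrete uniform on 1..k).
#' @param status_mix named list of proportion vectors over
#'   endemic/native/introduced for the classes `shared`, `only_A`,
#'   `only_B`; each must sum to 1.
#' @param juvenile_fraction probability that an individual is a juvenile.
#' @param n_samples_per_site samples per site (default 10).
#' @param seed integer seed governing all draws.
#' @return Validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_species_shared = 46,
                       n_species_only_A = 42,
                       n_species_only_B = 145,
                       abundance_model = list(model = "log_series",
                                              theta = 0.995),
                       status_mix = list(
                         shared = c(endemic = 0.09, native = 0.30,
                                    introduced = 0.61),
                         only_A = c(endemic = 0.07, native = 0.26,
                                    introduced = 0.67),
                         only_B = c(endemic = 0.02, native = 0.21,
                                    introduced = 0.77)),
                       juvenile_fraction = 0.37,
                       n_samples_per_site = 10,
                       seed = 1L) {
  stopifnot(n_species_shared >= 0, n_species_only_A >= 0,
            n_species_only_B >= 0)
  if (n_species_shared + n_species_only_A + n_species_only_B == 0)
    stop("zero total species")
  if (n_samples_per_site < 1) stop("n_samples_per_site must be >= 1")
  if (juvenile_fraction < 0 || juvenile_fraction > 1)
    stop("juvenile_fraction must be in [0, 1]")
  if (!is.list(abundance_model) || is.null(abundance_model$model) ||
      !abundance_model$model %in% c("log_series", "lognormal", "uniform"))
    stop("abundance_model$model must be log_series, lognormal or uniform")
  for (cls in c("shared", "only_A", "only_B")) {
    p <- status_mix[[cls]]
    if (is.null(p) || !setequal(names(p), c("endemic", "native", "introduced")))
      stop("status_mix$", cls,
           " must be named proportions over endemic/native/introduced")
    if (abs(sum(p) - 1) > 1e-9)
      stop("status_mix$", cls, " must sum to 1")
  }
  structure(list(n_species_shared = as.integer(n_species_shared),
                 n_species_only_A = as.integer(n_species_only_A),
                 n_species_only_B = as.integer(n_species_only_B),
                 abundance_model = abundance_model,
                 status_mix = status_mix,
                 juvenile_fraction = juvenile_fraction,
                 n_samples_per_site = as.integer(n_samples_per_site),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# one draw of per-species site abundance (>= 1, so presence is exact)
draw_abundances <- function(n, model) {
  if (n == 0) return(integer(0))
  switch(model$model,
    log_series = {
      theta <- model$theta
      if (is.null(theta) || theta <= 0 || theta >= 1)
        stop("log_series theta must be in (0, 1)")
      # logarithmic distribution P(k) proportional to theta^k / k on a
      # support truncated where the tail mass is negligible
      kmax <- min(1e5, max(100, ceiling(log(1e-12) / log(theta))))
      k <- seq_len(kmax)
      pr <- theta^k / k
      sample(k, n, replace = TRUE, prob = pr)
    },
    lognormal = {
      pmax(1, round(stats::rlnorm(n, model$mu, model$sigma)))
    },
    uniform = {
      if (is.null(model$k) || model$k < 1) stop("uniform k must be >= 1")
      sample.int(model$k, n, replace = TRUE)
    })
}

# deterministic status assignment by largest remainder, then shuffled
assign_status <- function(n, props) {
  if (n == 0) return(character(0))
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(props * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(props), times = base))
}

#' Generate a synthetic paired-site community matrix
#'
#' Draws a [community_matrix()] from a [synth_spec()]: each species present
#' at a site receives a site abundance of at least one individual from the
#' abundance model, the individuals are scattered multinomially across the
#' site's samples, and each individual is independently a juvenile with the
#' specified probability. Site A and site B are labelled `"A"` and `"B"`;
#' shared species are guaranteed present at both sites, exclusive species
#' at exactly one. The result is bit-identical for a given spec (the seed
#' is part of the spec); per-site sub-seeds are derived from the global
#' seed so the sites have independent reproducible streams.
#'
#' @param spec a [synth_spec()].
#' @return A [community_matrix()] with sites `"A"` and `"B"`.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nS <- spec$n_species_shared + spec$n_species_only_A + spec$n_species_only_B
  ids <- sprintf("sp%03d", seq_len(nS))
  cls <- rep(c("shared", "only_A", "only_B"),
             times = c(spec$n_species_shared, spec$n_species_only_A,
                       spec$n_species_only_B))

  set.seed(spec$seed)
  status <- character(nS)
  for (cl in c("shared", "only_A", "only_B")) {
    idx <- which(cls == cl)
    status[idx] <- assign_status(length(idx), spec$status_mix[[cl]])
  }
  trophic <- sample(c("predator", "herbivore", "saprophage"), nS,
                    replace = TRUE, prob = c(0.4, 0.4, 0.2))
  order_name <- sample(c("Araneae", "Coleoptera", "Hemiptera", "Psocoptera"),
                       nS, replace = TRUE, prob = c(0.25, 0.3, 0.3, 0.15))
  smeta <- data.frame(species = ids, status = status, trophic = trophic,
                      order_name = order_name, stringsAsFactors = FALSE)

  site_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  ns <- spec$n_samples_per_site
  # sampling design mirrors a garden survey: mostly SLAM plus a few active
  # searches; labels only, no method-specific detection model
  methods <- rep(c("SLAM", "AAS", "FBN"), length.out = max(ns, 1))
  methods[seq_len(min(6, ns))] <- "SLAM"

  one_site <- function(site, present, sub_seed) {
    set.seed(sub_seed)
    samp_ids <- sprintf("%s_s%02d", site, seq_len(ns))
    smp <- data.frame(sample = samp_ids, site = site,
                      method = methods[seq_len(ns)],
                      period = sprintf("m%02d", seq_len(ns)),
                      stringsAsFactors = FALSE)
    if (length(present) == 0)
      return(list(counts = data.frame(species = character(0),
                                      sample = character(0),
                                      stage = character(0),
                                      count = numeric(0)),
                  smeta = smp))
    ab <- draw_abundances(length(present), spec$abundance_model)
    rows <- vector("list", length(present))
    for (i in seq_along(present)) {
      per_sample <- as.vector(stats::rmultinom(1, ab[i], rep(1, ns)))
      juv <- stats::rbinom(ns, per_sample, spec$juvenile_fraction)
      rows[[i]] <- data.frame(
        species = present[i],
        sample = rep(samp_ids, 2),
        stage = rep(c("adult", "juvenile"), each = ns),
        count = c(per_sample - juv, juv),
        stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, rows), smeta = smp)
  }

  a <- one_site("A", ids[cls %in% c("shared", "only_A")], site_seeds[1])
  b <- one_site("B", ids[cls %in% c("shared", "only_B")], site_seeds[2])
  community_matrix(rbind(a$counts, b$counts), smeta,
                   rbind(a$smeta, b$smeta))
}

#' Random partition of a pooled community (dominance null model)
#'
#' Splits the individuals of a pooled community at random, without
#' replacement, into two communities of the given sizes — the null model of
#' no dominance difference between sites. Each species' count in the first
#' community is multivariate-hypergeometric.
#'
#' @param n_individuals_A,n_individuals_B sizes of the two communities;
#'   must sum to the pooled total.
#' @param pooled_abundances named abundance vector of the pooled community.
#' @param seed optional integer seed.
#' @return List with named vectors `A` and `B` (zeros retained), summing
#'   per species to the pooled vector.
#' @export
generate_null_pair <- function(n_individuals_A, n_individuals_B,
                               pooled_abundances, seed = NULL) {
  x <- pooled_abundances
  if (any(x < 0) || any(x != floor(x))) stop("pooled abundances must be counts")
  N <- sum(x)
  if (n_individuals_A + n_individuals_B != N)
    stop("n_individuals_A + n_individuals_B must equal the pooled total ", N)
  if (!is.null(seed)) set.seed(seed)
  kA <- partition_counts(as.numeric(x), n_individuals_A, 1L)[, 1]
  A <- stats::setNames(kA, names(x))
  list(A = A, B = x - A)
}

# draw `reps` multivariate hypergeometric splits of pooled counts `x`,
# allocating n1 of sum(x) individuals; returns a species x reps matrix.
# Sequential conditional method: species s gets Hyper(x_s, remaining pool,
# remaining quota) individuals, vectorized across replicates.
partition_counts <- function(x, n1, reps) {
  left <- sum(x)
  quota <- rep(n1, reps)
  out <- matrix(0, length(x), reps)
  for (s in seq_along(x)) {
    left <- left - x[s]
    k <- stats::rhyper(reps, x[s], left, quota)
    out[s, ] <- k
    quota <- quota - k
  }
  out
}
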