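# Small fixtures built in code, shared across test files.

# two sites x two samples, six species with hand-countable totals
toy_matrix <- function() {
  counts <- data.frame(
    species = c("araA", "araA", "araA", "colB", "colB", "hemC", "hemC",
                "araD", "colE", "hemC", "psoF"),
    sample  = c("F1", "F1", "F2", "F1", "F2", "F2", "F2",
                "T1", "T1", "T2", "T2"),
    stage   = c("adult", "juvenile", "adult", "adult", "adult", "adult",
                "juvenile", "adult", "adult", "adult", "juvenile"),
    count   = c(2, 3, 1, 4, 6, 5, 2, 7, 1, 2, 9),
    stringsAsFactors = FALSE)
  species_meta <- data.frame(
    species = c("araA", "colB", "hemC", "araD", "colE", "psoF"),
    status = c("endemic", "introduced", "native", "native", "introduced",
               "undetermined"),
    trophic = c("predator", "predator", "herbivore", "predator",
                "herbivore", "saprophage"),
    order_name = c("Araneae", "Coleoptera", "Hemiptera", "Araneae",
                   "Coleoptera", "Psocoptera"),
    stringsAsFactors = FALSE)
  sample_meta <- data.frame(
    sample = c("F1", "F2", "T1", "T2"),
    site = c("FAI", "FAI", "TER", "TER"),
    method = c("SLAM", "AAS", "SLAM", "FBN"),
    period = c("m01", "m02", "m01", "m02"),
    stringsAsFactors = FALSE)
  community_matrix(counts, species_meta, sample_meta)
}

# a quick small synthetic spec so pipeline-level tests stay fast
small_spec <- function(seed = 11, ...) {
  synth_spec(n_species_shared = 8, n_species_only_A = 5,
             n_species_only_B = 7,
             abundance_model = list(model = "log_series", theta = 0.9),
             n_samples_per_site = 4, seed = seed, ...)
}

# all permutations of 1..n, one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- all_perms(n - 1L)
    cbind(i, matrix(seq_len(n)[-i][rest], nrow(rest)))
  }))
}

# exhaustive sample-order average of S/F1/F2/Q1 for a species x sample
# count matrix: the independent oracle for accumulate()
exhaustive_accumulation <- function(mat) {
  ns <- ncol(mat)
  pm <- all_perms(ns)
  acc <- matrix(0, 4, ns)
  for (r in seq_len(nrow(pm))) {
    perm <- mat[, pm[r, ], drop = FALSE]
    cum <- t(apply(perm, 1, cumsum))
    inc <- t(apply((perm > 0) * 1, 1, cumsum))
    acc[1, ] <- acc[1, ] + colSums(cum > 0)
    acc[2, ] <- acc[2, ] + colSums(cum == 1)
    acc[3, ] <- acc[3, ] + colSums(cum == 2)
    acc[4, ] <- acc[4, ] + colSums(inc == 1)
  }
  acc <- acc / nrow(pm)
  data.frame(level = seq_len(ns), mean_S = acc[1, ], mean_F1 = acc[2, ],
             mean_F2 = acc[3, ], mean_Q1 = acc[4, ])
}

# closed-form expected sample-based richness at each level
closed_form_mean_S <- function(mat) {
  ns <- ncol(mat)
  occ <- rowSums(mat > 0)
  vapply(seq_len(ns), function(l)
    sum(1 - exp(lchoose(ns - occ, l) - lchoose(ns, l))), 0)
}
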