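# Controlled vocabularies for species and sample metadata. Free text is
# rejected at read time so every downstream grouping is well defined.
STATUS_LEVELS  <- c("endemic", "native", "introduced", "undetermined")
TROPHIC_LEVELS <- c("predator", "herbivore", "saprophage", "unknown")
STAGE_LEVELS   <- c("adult", "juvenile")
METHOD_LEVELS  <- c("SLAM", "AAS", "FBN")

#' Construct a community matrix
#'
#' The central data container: long-format counts of individuals per
#' (species, sample, life stage), together with per-species metadata
#' (colonisation status, trophic role, taxonomic order) and per-sample
#' metadata (site, sampling method, period). Counts absent from the table
#' are zero; the adult and juvenile stages are always both representable,
#' a taxon with no juveniles simply has zero juvenile counts.
#'
#' @param counts data.frame with columns `species`, `sample`, `stage`
#'   (`"adult"` or `"juvenile"`) and non-negative integer `count`.
#' @param species_meta data.frame with columns `species`, `status`
#'   (endemic / native / introduced / undetermined), `trophic`
#'   (predator / herbivore / saprophage / unknown) and `order_name`.
#' @param sample_meta data.frame with columns `sample`, `site` and
#'   optionally `method` (SLAM / AAS / FBN) and `period`.
#' @return An object of class `community_matrix`.
#' @seealso [read_occurrences()], [pool()], [filter_status()], [apply_merge()]
#' @export
community_matrix <- function(counts, species_meta, sample_meta) {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  species_meta <- as.data.frame(species_meta, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)

  need <- c("species", "sample", "stage", "count")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  if (!all(c("species", "status", "trophic", "order_name") %in% names(species_meta)))
    stop("species_meta must have columns species, status, trophic, order_name")
  if (!all(c("sample", "site") %in% names(sample_meta)))
    stop("sample_meta must have columns sample, site")
  if (!"method" %in% names(sample_meta)) sample_meta$method <- NA_character_
  if (!"period" %in% names(sample_meta)) sample_meta$period <- NA_character_

  counts$count <- as.numeric(counts$count)
  if (anyNA(counts$count) || any(counts$count < 0) ||
      any(counts$count != floor(counts$count)))
    stop("counts must be non-negative integers")
  bad <- setdiff(unique(counts$stage), STAGE_LEVELS)
  if (length(bad))
    stop("unknown life_stage value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(species_meta$status), STATUS_LEVELS)
  if (length(bad))
    stop("unknown status value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(species_meta$trophic), TROPHIC_LEVELS)
  if (length(bad))
    stop("unknown trophic value(s): ", paste(bad, collapse = ", "))
  mth <- sample_meta$method
  bad <- setdiff(unique(mth[!is.na(mth)]), METHOD_LEVELS)
  if (length(bad))
    stop("unknown method value(s): ", paste(bad, collapse = ", "))

  if (anyDuplicated(species_meta$species))
    stop("duplicate species in species_meta")
  if (anyDuplicated(sample_meta$sample))
    stop("duplicate sample ids in sample_meta")
  orphan <- setdiff(unique(counts$species), species_meta$species)
  if (length(orphan))
    stop("count rows reference species missing from species_meta: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  orphan <- setdiff(unique(counts$sample), sample_meta$sample)
  if (length(orphan))
    stop("count rows reference samples missing from sample_meta: ",
         paste(utils::head(orphan, 5), collapse = ", "))

  # collapse duplicate (species, sample, stage) keys by summation
  key <- interaction(counts$species, counts$sample, counts$stage, drop = TRUE)
  if (anyDuplicated(key)) {
    counts <- stats::aggregate(count ~ species + sample + stage, counts, sum)
  }
  counts <- counts[counts$count > 0, need, drop = FALSE]
  counts <- counts[order(counts$species, counts$sample, counts$stage), ,
                   drop = FALSE]
  species_meta <- species_meta[order(species_meta$species), , drop = FALSE]
  sample_meta <- sample_meta[order(sample_meta$sample), , drop = FALSE]
  rownames(counts) <- NULL
  rownames(species_meta) <- NULL
  rownames(sample_meta) <- NULL

  structure(
    list(counts = counts,
         species_meta = species_meta,
         sample_meta = sample_meta),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix:",
      nrow(x$species_meta), "species,",
      nrow(x$sample_meta), "samples,",
      sum(x$counts$count), "individuals\n")
  cat("sites:", paste(sort(unique(x$sample_meta$site)), collapse = ", "), "\n")
  invisible(x)
}

#' List the sites of a community matrix
#' @param m community_matrix.
#' @return Character vector of site labels.
#' @export
sites <- function(m) sort(unique(m$sample_meta$site))

#' Read a long-format occurrence table
#'
#' Ingests a delimited text file with header
#' `species,site,sample,life_stage,count,status,trophic,order`
#' (optionally also `method` and `period`). The delimiter is auto-detected
#' from the extension (`.tsv`/`.txt` = tab, otherwise comma) unless given.
#' Duplicate (species, sample, stage) rows are summed; the number of rows
#' read and merged is reported via [message()].
#'
#' @param path path to a CSV/TSV occurrence file.
#' @param sep field delimiter; `NULL` (default) auto-detects from extension.
#' @return A [community_matrix()].
#' @export
read_occurrences <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  need <- c("species", "site", "sample", "life_stage", "count",
            "status", "trophic", "order")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("occurrence file lacks column(s): ",
         paste(missing_cols, collapse = ", "))

  # row-addressed validation so a bad token can be located in the source file
  check_enum <- function(values, levels, what) {
    bad <- which(!values %in% levels)
    if (length(bad))
      stop("invalid ", what, " value ", shQuote(values[bad[1]]),
           " at data row ", bad[1],
           if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more rows)"),
           call. = FALSE)
  }
  check_enum(raw$life_stage, STAGE_LEVELS, "life_stage")
  check_enum(raw$status, STATUS_LEVELS, "status")
  check_enum(raw$trophic, TROPHIC_LEVELS, "trophic")
  cnt <- suppressWarnings(as.numeric(raw$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad))
    stop("count not a non-negative integer at data row ", bad[1], call. = FALSE)

  smeta <- unique(raw[, c("species", "status", "trophic", "order")])
  names(smeta)[4] <- "order_name"
  if (anyDuplicated(smeta$species)) {
    dup <- smeta$species[duplicated(smeta$species)][1]
    stop("species ", shQuote(dup), " has conflicting metadata rows")
  }
  keep <- c("sample", "site",
            intersect(c("method", "period"), names(raw)))
  mmeta <- unique(raw[, keep, drop = FALSE])
  if (anyDuplicated(mmeta$sample)) {
    dup <- mmeta$sample[duplicated(mmeta$sample)][1]
    stop("sample ", shQuote(dup), " has conflicting metadata rows")
  }

  counts <- data.frame(species = raw$species, sample = raw$sample,
                       stage = raw$life_stage, count = cnt,
                       stringsAsFactors = FALSE)
  n_in <- nrow(counts)
  m <- community_matrix(counts, smeta, mmeta)
  message("read_occurrences: ", n_in, " rows read, ",
          n_in - nrow(m$counts), " merged/empty")
  m
}

#' Write a community matrix as a long-format occurrence table
#'
#' Inverse of [read_occurrences()]: emits one row per stored
#' (species, sample, stage) count with the species and sample metadata
#' repeated, so `read_occurrences(write_occurrences(m, f))` is the identity
#' on the data model.
#'
#' @param m community_matrix.
#' @param path output path; delimiter chosen from extension as in
#'   [read_occurrences()].
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(m, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- merge(m$counts, m$species_meta, by = "species")
  out <- merge(out, m$sample_meta, by = "sample")
  out <- data.frame(species = out$species, site = out$site,
                    sample = out$sample, life_stage = out$stage,
                    count = out$count, status = out$status,
                    trophic = out$trophic, order = out$order_name,
                    method = out$method, period = out$period,
                    stringsAsFactors = FALSE)
  out <- out[order(out$species, out$sample, out$life_stage), ]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge species under canonical identifiers
#'
#' Collapses morphologically indistinguishable species into a single
#' canonical unit (the classic case: two *Scymnus* species kept as
#' *Scymnus* sp.1), summing their counts per (sample, stage). Applying the
#' map is idempotent: canonical ids never map onward.
#'
#' @param m community_matrix.
#' @param merges data.frame with columns `raw_id`, `canonical_id`, or a named
#'   character vector `c(raw_id = canonical_id)`.
#' @param canonical_status status to assign when the merged species disagree
#'   and the canonical id is not already present with its own status.
#' @return A new community_matrix with the merged species.
#' @export
apply_merge <- function(m, merges, canonical_status = NULL) {
  if (is.character(merges) && !is.null(names(merges))) {
    merges <- data.frame(raw_id = names(merges), canonical_id = unname(merges),
                         stringsAsFactors = FALSE)
  }
  merges <- as.data.frame(merges, stringsAsFactors = FALSE)
  if (nrow(merges) == 0) return(m)
  if (!all(c("raw_id", "canonical_id") %in% names(merges)))
    stop("merges must have columns raw_id, canonical_id")
  if (any(merges$canonical_id %in% merges$raw_id))
    stop("merge map is not idempotent: a canonical_id also appears as raw_id")
  if (anyDuplicated(merges$raw_id))
    stop("raw_id mapped more than once")

  map <- stats::setNames(merges$canonical_id, merges$raw_id)
  sm <- m$species_meta
  translate <- function(ids) ifelse(ids %in% names(map), map[ids], ids)

  # resolve metadata for each canonical id
  new_meta <- sm
  new_meta$species <- translate(sm$species)
  resolved <- lapply(split(new_meta, new_meta$species), function(g) {
    if (nrow(g) == 1) return(g)
    canon <- g$species[1]
    own <- sm[sm$species == canon, , drop = FALSE]  # canonical existed already
    status <- if (nrow(own) == 1) {
      own$status
    } else if (length(unique(g$status)) == 1) {
      g$status[1]
    } else if (!is.null(canonical_status)) {
      canonical_status
    } else {
      stop("merge into ", shQuote(canon), " spans conflicting statuses (",
           paste(unique(g$status), collapse = ", "),
           "); supply canonical_status", call. = FALSE)
    }
    data.frame(species = canon, status = status,
               trophic = if (nrow(own) == 1) own$trophic else g$trophic[1],
               order_name = if (nrow(own) == 1) own$order_name else g$order_name[1],
               stringsAsFactors = FALSE)
  })
  smeta <- do.call(rbind, resolved)

  counts <- m$counts
  counts$species <- translate(counts$species)
  community_matrix(counts, smeta, m$sample_meta)
}

#' Drop species by colonisation status
#'
#' Removes whole species from the matrix by status class. The default
#' reproduces the curation rule of dropping species whose colonisation
#' status could not be determined, so that every reported metric is over
#' the endemic/native/introduced community only.
#'
#' @param m community_matrix.
#' @param drop character vector of statuses to remove
#'   (default `"undetermined"`). Empty vector returns `m` unchanged.
#' @return A community_matrix without the dropped species.
#' @export
filter_status <- function(m, drop = "undetermined") {
  if (length(drop) == 0) return(m)
  bad <- setdiff(drop, STATUS_LEVELS)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  keep <- m$species_meta$species[!m$species_meta$status %in% drop]
  smeta <- m$species_meta[m$species_meta$species %in% keep, , drop = FALSE]
  counts <- m$counts[m$counts$species %in% keep, , drop = FALSE]
  community_matrix(counts, smeta, m$sample_meta)
}

#' Restrict a community matrix to a taxonomic order or status class
#'
#' Convenience subsetter used by the grouped analyses; species not matching
#' the filters are removed entirely (samples are kept even if emptied).
#'
#' @param m community_matrix.
#' @param order_name keep only species of this taxonomic order (NULL = all).
#' @param status keep only species with these statuses (NULL = all).
#' @return A community_matrix.
#' @export
subset_species <- function(m, order_name = NULL, status = NULL) {
  keep <- rep(TRUE, nrow(m$species_meta))
  if (!is.null(order_name)) keep <- keep & m$species_meta$order_name %in% order_name
  if (!is.null(status)) keep <- keep & m$species_meta$status %in% status
  ids <- m$species_meta$species[keep]
  community_matrix(m$counts[m$counts$species %in% ids, , drop = FALSE],
                   m$species_meta[keep, , drop = FALSE],
                   m$sample_meta)
}

#' Pool a site into a species abundance vector
#'
#' Sums counts over all samples of one site, in the requested life-stage
#' view: `"total"` adds adults and juveniles, `"adult"` keeps adults only.
#' Species with zero abundance at the site are excluded by default (they do
#' not count towards observed richness S) but can be retained as named
#' zeros with `keep_zeros = TRUE`.
#'
#' @param m community_matrix.
#' @param site site label present in the sample metadata.
#' @param stage_view `"total"` (default) or `"adult"`.
#' @param keep_zeros keep species absent from the site as zeros.
#' @return Named numeric vector of abundances (names = species ids).
#' @export
pool <- function(m, site, stage_view = c("total", "adult"),
                 keep_zeros = FALSE) {
  stage_view <- match.arg(stage_view)
  samp <- m$sample_meta$sample[m$sample_meta$site == site]
  if (length(samp) == 0) stop("unknown site (or site has no samples): ", site)
  cnt <- m$counts[m$counts$sample %in% samp, , drop = FALSE]
  if (stage_view == "adult") cnt <- cnt[cnt$stage == "adult", , drop = FALSE]
  x <- stats::setNames(rep(0, nrow(m$species_meta)), m$species_meta$species)
  if (nrow(cnt)) {
    agg <- tapply(cnt$count, cnt$species, sum)
    x[names(agg)] <- agg
  }
  if (!keep_zeros) x <- x[x > 0]
  x
}

#' Species-by-sample count matrix for one site
#'
#' @param m community_matrix.
#' @param site site label.
#' @param stage_view `"total"` or `"adult"`.
#' @return Integer matrix, species in rows (only species present at the
#'   site), samples in columns (all samples of the site).
#' @export
site_sample_matrix <- function(m, site, stage_view = c("total", "adult")) {
  stage_view <- match.arg(stage_view)
  samp <- m$sample_meta$sample[m$sample_meta$site == site]
  if (length(samp) == 0) stop("unknown site (or site has no samples): ", site)
  cnt <- m$counts[m$counts$sample %in% samp, , drop = FALSE]
  if (stage_view == "adult") cnt <- cnt[cnt$stage == "adult", , drop = FALSE]
  if (nrow(cnt) == 0)
    return(matrix(0, 0, length(samp), dimnames = list(NULL, samp)))
  tab <- tapply(cnt$count, list(cnt$species, cnt$sample), sum, default = 0)
  out <- matrix(0, nrow(tab), length(samp),
                dimnames = list(rownames(tab), samp))
  out[, colnames(tab)] <- tab
  out[rowSums(out) > 0, , drop = FALSE]
}

#' Read a two-column merge map
#'
#' @param path CSV with header `raw_id,canonical_id`.
#' @return data.frame usable by [apply_merge()].
#' @export
read_merge_map <- function(path) {
  mm <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raw_id", "canonical_id") %in% names(mm)))
    stop("merge map must have columns raw_id, canonical_id")
  mm
}
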