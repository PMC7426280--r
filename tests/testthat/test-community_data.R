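test_that("reading an occurrence file sums duplicate keys and validates enums", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species,site,sample,life_stage,count,status,trophic,order",
    "sp1,A,A_s1,adult,2,native,predator,Araneae",
    "sp1,A,A_s1,adult,3,native,predator,Araneae",
    "sp2,A,A_s1,juvenile,4,endemic,herbivore,Hemiptera"), f)
  m <- suppressMessages(read_occurrences(f))
  expect_equal(m$counts$count[m$counts$species == "sp1"], 5)
  expect_equal(unname(pool(m, "A")), c(5, 4))

  writeLines(c(
    "species,site,sample,life_stage,count,status,trophic,order",
    "sp1,A,A_s1,adult,2,exotic,predator,Araneae"), f)
  expect_error(suppressMessages(read_occurrences(f)), "status.*row 1")

  writeLines(c(
    "species,site,sample,life_stage,count,status,trophic,order",
    "sp1,A,A_s1,adult,-2,native,predator,Araneae"), f)
  expect_error(suppressMessages(read_occurrences(f)), "count.*row 1")
})

test_that("write then read round-trips the data model", {
  m <- generate_community(small_spec(seed = 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_occurrences(m, f)
  m2 <- suppressMessages(read_occurrences(f))
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$species_meta, m$species_meta)
  expect_equal(m2$sample_meta, m$sample_meta)
})

test_that("apply_merge sums counts, drops ids, and guards statuses", {
  m <- toy_matrix()
  # merge two Coleoptera (introduced + introduced): additive, S drops by 1
  merged <- apply_merge(m, c(colE = "colB"))
  expect_equal(nrow(merged$species_meta), 5)
  expect_equal(sum(pool(merged, "FAI")["colB"], pool(merged, "TER")["colB"]),
               4 + 6 + 1)
  # empty map is the identity
  expect_equal(apply_merge(m, data.frame(raw_id = character(0),
                                         canonical_id = character(0))), m)
  # conflicting statuses need an explicit canonical status
  expect_error(apply_merge(m, c(araA = "newsp", araD = "newsp")),
               "conflicting statuses")
  ok <- apply_merge(m, c(araA = "newsp", araD = "newsp"),
                    canonical_status = "native")
  expect_equal(ok$species_meta$status[ok$species_meta$species == "newsp"],
               "native")
  # merging into an existing species keeps that species' own status
  ok2 <- apply_merge(m, c(araA = "araD"))
  expect_equal(ok2$species_meta$status[ok2$species_meta$species == "araD"],
               "native")
  # non-idempotent chains are rejected
  expect_error(apply_merge(m, c(araA = "araD", araD = "colB")),
               "idempotent")
})

test_that("filter_status drops whole species; empty drop set is identity", {
  m <- toy_matrix()
  kept <- filter_status(m)  # default drops undetermined
  expect_equal(nrow(kept$species_meta), 5)
  expect_false("psoF" %in% kept$counts$species)
  expect_equal(filter_status(m, character(0)), m)
  none <- filter_status(m, c("endemic", "native", "introduced",
                             "undetermined"))
  expect_equal(nrow(none$species_meta), 0)
  expect_equal(nrow(none$counts), 0)
})

test_that("a synthetic excluded-morphospecies fixture loses exactly them", {
  # 93 species, 5 of undetermined status, mimicking a curation step that
  # removes species whose colonisation status is unknown
  sm <- data.frame(species = sprintf("s%03d", 1:93),
                   status = c(rep("introduced", 50), rep("native", 30),
                              rep("endemic", 8), rep("undetermined", 5)),
                   trophic = "unknown", order_name = "Coleoptera",
                   stringsAsFactors = FALSE)
  cnt <- data.frame(species = sm$species, sample = "A_s1", stage = "adult",
                    count = 1, stringsAsFactors = FALSE)
  m <- community_matrix(cnt, sm, data.frame(sample = "A_s1", site = "A"))
  expect_equal(length(pool(filter_status(m), "A")), 88)
})

test_that("pool respects stage views, conserves totals, errors on bad site", {
  m <- toy_matrix()
  # araA at FAI: adults 2 + 1, juveniles 3
  expect_equal(pool(m, "FAI")[["araA"]], 6)
  expect_equal(pool(m, "FAI", "adult")[["araA"]], 3)
  expect_error(pool(m, "nowhere"), "unknown site")

  # conservation: site pools add up to the grand total of counts
  expect_equal(sum(pool(m, "FAI")) + sum(pool(m, "TER")),
               sum(m$counts$count))
  # adult view never exceeds the total view
  for (s in sites(m)) {
    tot <- pool(m, s, "total", keep_zeros = TRUE)
    adu <- pool(m, s, "adult", keep_zeros = TRUE)
    expect_true(all(adu <= tot))
  }
  # brute force over raw rows for one site
  raw <- m$counts[m$counts$sample %in% c("T1", "T2"), ]
  expect_equal(sum(pool(m, "TER")), sum(raw$count))
})

test_that("zero-abundance species are excluded from S but available as zeros", {
  m <- toy_matrix()
  x <- pool(m, "FAI")
  expect_false("araD" %in% names(x))
  xz <- pool(m, "FAI", keep_zeros = TRUE)
  expect_equal(xz[["araD"]], 0)
  expect_equal(length(xz), 6)
})

test_that("the shipped example occurrence file supports the curation workflow", {
  path <- system.file("extdata", "example_occurrences.csv",
                      package = "gardendiv")
  m <- suppressMessages(read_occurrences(path))
  expect_equal(sort(sites(m)), c("GARDEN1", "GARDEN2"))
  cur <- filter_status(apply_merge(m, c(scymnus_morph2 = "scymnus_morph1")))
  expect_false("morphosp_x" %in% cur$species_meta$species)
  expect_equal(cur$counts$count[cur$counts$species == "scymnus_morph1"], 5)
  expect_true(all(pool(cur, "GARDEN1", "adult", keep_zeros = TRUE) <=
                    pool(cur, "GARDEN1", "total", keep_zeros = TRUE)))
})
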