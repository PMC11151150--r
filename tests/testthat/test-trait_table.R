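test_that("unit conversion maps every accepted token to centimetres", {
  expect_equal(to_cm(45.72, "m"), 4572)
  expect_equal(to_cm(1, "cm"), 1)
  expect_equal(to_cm(195, "um"), 0.0195)
  expect_equal(to_cm(7.5, "mm"), 0.75)
  expect_equal(to_cm(c(1, 2), c("m", "MM")), c(100, 0.2))
  expect_error(to_cm(1, "inch"), "accepted tokens")
})

test_that("ingest keeps every verbatim row and validates schema", {
  path <- write_fixture_csv(c(
    "species_name,aphia_id,size_value,size_unit,source_id",
    "Syrinx aruanus,211227,91.4,cm,srcA",
    "Syrinx aruanus,211227,72.2,cm,srcB",
    "Praya dubia,135478,45.72,m,srcC"
  ))
  rec <- read_measurements(path)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$aphia_id == 211227), 2)
  expect_equal(rec$size_cm[3], 4572)

  empty <- write_fixture_csv("species_name,aphia_id,size_value,size_unit,source_id")
  expect_equal(nrow(read_measurements(empty)), 0)

  neg <- write_fixture_csv(c(
    "species_name,aphia_id,size_value,size_unit,source_id",
    "X y,1,-3,cm,s"))
  expect_error(read_measurements(neg), "row")

  nocol <- write_fixture_csv(c("species_name,aphia_id,size_value,source_id",
                               "X y,1,3,s"))
  expect_error(read_measurements(nocol), "size_unit")

  badunit <- write_fixture_csv(c(
    "species_name,aphia_id,size_value,size_unit,source_id",
    "X y,1,3,furlong,s"))
  expect_error(read_measurements(badunit), "furlong")
})

test_that("per-species summaries implement the log10 range statistic", {
  rec <- tibble::tibble(
    aphia_id = c(1L, 1L, 2L, 2L, 2L, 3L, 3L),
    species_name = c("a", "a", "b", "b", "b", "c", "c"),
    size_cm = c(91.4, 72.2, 5, 5, 5, 0.1, 10)
  )
  s <- summarize_species(rec)
  expect_equal(s$maxsize_smallest[1], 72.2)
  expect_equal(s$maxsize_largest[1], 91.4)
  # direct logarithm evaluation is the oracle for the range
  expect_equal(s$maxsize_range[1], log10(91.4) - log10(72.2), tolerance = 1e-12)
  expect_identical(s$maxsize_range[2], 0)
  expect_equal(s$count[2], 3L)
  expect_equal(as.character(s$count_class[2]), "c3")
  expect_equal(s$maxsize_range[3], 2)
})

test_that("singleton species are excluded with a warning", {
  rec <- tibble::tibble(aphia_id = c(1L, 1L, 2L), species_name = c("a", "a", "b"),
                        size_cm = c(1, 2, 3))
  expect_warning(s <- summarize_species(rec), "excluded")
  expect_equal(nrow(s), 1)
})

test_that("summary statistics are ordered, permutation-invariant and unit-invariant", {
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    sizes <- 10^stats::runif(k, -2, 3)
    rec <- tibble::tibble(aphia_id = 1L, species_name = "sp", size_cm = sizes)
    s <- summarize_species(rec)
    expect_lte(s$maxsize_smallest, s$maxsize_mean)
    expect_lte(s$maxsize_mean, s$maxsize_largest)
    expect_gte(s$maxsize_range, 0)

    perm <- rec[sample(k), ]
    expect_equal(summarize_species(perm), s)

    scaled <- rec
    scaled$size_cm <- scaled$size_cm * 37.3
    expect_equal(summarize_species(scaled)$maxsize_range, s$maxsize_range,
                 tolerance = 1e-12)

    extra <- dplyr::bind_rows(rec, tibble::tibble(
      aphia_id = 1L, species_name = "sp", size_cm = 10^stats::runif(1, -2, 3)))
    expect_gte(summarize_species(extra)$maxsize_range, s$maxsize_range - 1e-12)
  }
})

test_that("mean modes give geometric vs arithmetic means", {
  rec <- tibble::tibble(aphia_id = 1L, species_name = "a", size_cm = c(1, 100))
  expect_equal(summarize_species(rec)$maxsize_mean, 10)
  expect_equal(summarize_species(rec, mean_mode = "raw_arithmetic")$maxsize_mean, 50.5)
})

test_that("count categorization has the documented boundaries", {
  expect_equal(as.character(assign_count_class(c(2, 3, 4, 5, 6, 1000))),
               c("c2", "c3", "c4_5", "c4_5", "c6plus", "c6plus"))
  expect_error(assign_count_class(1), ">= 2")
})

test_that("phylum filter retains only well-sampled phyla and tallies them", {
  smry <- tibble::tibble(aphia_id = 1:200, species_name = as.character(1:200),
                         count = 2L,
                         count_class = assign_count_class(rep(2, 200)),
                         maxsize_smallest = 1, maxsize_largest = 1,
                         maxsize_mean = 1, log10_smallest = 0,
                         log10_largest = 0, log10_mean = 0, maxsize_range = 0)
  ann <- tibble::tibble(aphia_id = 1:200,
                        phylum = rep(c("Mollusca", "Ctenophora"), c(120, 80)),
                        habitat = "benthic", skeleton = "none")
  res <- filter_phyla(smry, ann, min_species = 100)
  expect_equal(unique(res$summaries$phylum), "Mollusca")
  expect_equal(nrow(res$summaries), 120)
  expect_equal(sort(res$phylum_tally$n_species), c(80, 120))

  res2 <- filter_phyla(smry[1:80, ], ann[1:80, ], min_species = 100)
  expect_equal(nrow(res2$summaries), 0)
})

test_that("magnitude bins are disjoint with the stated boundary conventions", {
  r <- c(0, 0.2, 0.5, 0.99, 1, 2, 2.0001, 2.5)
  expect_equal(as.character(classify_range_magnitude(r)),
               c("zero", "lt_half", "half_to_one", "half_to_one",
                 "one_to_two", "one_to_two", "gt_two", "gt_two"))
  expect_error(classify_range_magnitude(-0.1), "non-negative")

  tal <- magnitude_tallies(r)
  expect_equal(sum(tal$disjoint$n), length(r))
  expect_equal(tal$cumulative$n, c(sum(r > 0.5), sum(r > 1), sum(r > 2)))
})

test_that("summary CSV round-trips at full precision", {
  tr <- small_truth(n = 80)
  s <- simulate_species_table(tr)$summaries
  path <- tempfile(fileext = ".csv")
  write_summaries(s, path)
  back <- read_summaries(path)
  expect_equal(back$maxsize_range, s$maxsize_range, tolerance = 1e-15)
  expect_equal(back$maxsize_smallest, s$maxsize_smallest, tolerance = 1e-15)
  expect_identical(back$count_class, s$count_class)
})

test_that("annotation ingest normalizes habitat and derives the invertebrate flag", {
  path <- write_fixture_csv(c(
    "aphia_id,phylum,habitat,skeleton",
    "1,Mollusca,BENTHIC,exoskeleton",
    "2,Chordata,,endoskeleton",
    "3,Cnidaria,unknown,none"
  ))
  ann <- read_annotations(path)
  expect_equal(ann$habitat, c("benthic", "unspecified", "unspecified"))
  expect_equal(ann$invertebrate, c(TRUE, FALSE, TRUE))
})
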