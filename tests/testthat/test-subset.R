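test_that("sample selection uses union semantics on the three-table fixture", {
  ms <- three_table_fixture()
  sub <- select_samples(ms, c("A", "C"))
  expect_identical(get_sample_names(sub),
                   list(t1 = "A", t2 = c("A", "C"), t3 = c("A", "C")))
  # identity when selecting everything
  expect_same_content(select_samples(ms, c("A", "B", "C")), ms)
  # absent ids keep every dataset, with zero samples
  empty <- select_samples(ms, "Z")
  expect_identical(dataset_names(empty), dataset_names(ms))
  expect_true(all(vapply(get_sample_names(empty), length, integer(1)) == 0L))
})

test_that("union law: each dataset keeps exactly its own intersection, in order", {
  for (seed in 1:40) {
    ms <- random_container(seed)
    S <- withr::with_seed(seed + 1000, sample(LETTERS[1:8], sample(0:6, 1)))
    sub <- select_samples(ms, S)
    for (k in dataset_names(ms)) {
      expected <- get_sample_names(ms, k)[get_sample_names(ms, k) %in% S]
      expect_identical(get_sample_names(sub, k), expected)
      # retained cells are bit-identical, addressed by id
      m0 <- get_assays(ms, k)[[1]]
      m1 <- get_assays(sub, k)[[1]]
      expect_identical(m1, m0[, expected, drop = FALSE])
    }
  }
})

test_that("select_samples is idempotent", {
  ms <- random_container(7)
  once <- select_samples(ms, c("A", "D", "F"))
  expect_same_content(select_samples(once, c("A", "D", "F")), once)
})

test_that("dataset selection keeps stored order and validates keys", {
  ms <- three_table_fixture()
  expect_same_content(select_datasets(ms, dataset_names(ms)), ms)
  one <- select_datasets(ms, "t2")
  expect_identical(dataset_names(one), "t2")
  expect_identical(get_assays(one, "t2"), get_assays(ms, "t2"))
  # requested out of order -> stored order
  two <- select_datasets(ms, c("t3", "t1"))
  expect_identical(dataset_names(two), c("t1", "t3"))
  expect_error(select_datasets(ms, "t9"), class = "omicstack_key_error")
})

test_that("extract returns the original-class bundle for a single dataset", {
  ms <- generate_fixture(fixture_spec(2, tables = NULL, snp = NULL,
                                      proteome = NULL, metabolome = NULL))
  b <- extract(ms, "expression")
  expect_s3_class(b, "ingest_bundle")
  expect_identical(b$declared_class, "expression-set")
  expect_identical(b$assays, get_assays(ms, "expression"))
  sub <- select_samples(ms, get_sample_names(ms, "expression")[1:3])
  b2 <- extract(sub, "expression")
  expect_identical(ncol(b2$assays[[1]]), 3L)
})

test_that("genomic-range subsetting discards unranged sets and keeps touching intervals", {
  m <- make_matrix(3, 2)
  rng <- tibble::tibble(id = rownames(m), chromosome = "chr1",
                        start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L),
                        strand = "*")
  ms <- new_multiset() |>
    add_ranged(ingest_bundle(m, ranges = rng), tag = "expression") |>
    add_generic(ingest_bundle(make_matrix(4, 2)), tag = "metabolome")

  sub <- select_range(ms, data.frame(chromosome = "chr1", start = 200, end = 300))
  expect_identical(dataset_names(sub), "expression")  # metabolome discarded
  # closed-interval touch at 200 retains the first feature
  expect_identical(get_feature_annotation(sub, "expression")$id, "f01")

  # no features on the queried chromosome: dataset retained, empty
  none <- select_range(ms, data.frame(chromosome = "chr7", start = 1, end = 1e6))
  expect_identical(dataset_names(none), "expression")
  expect_identical(nrow(get_feature_annotation(none, "expression")), 0L)

  expect_error(select_range(ms, data.frame(chromosome = "chr1", start = 10, end = 5)),
               class = "omicstack_validation_error")
})

test_that("select_range matches the brute-force overlap oracle on random instances", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      nf <- sample(10:60, 1)
      nq <- sample(1:10, 1)
      m <- make_matrix(nf, 3)
      start <- sample.int(5000, nf, replace = TRUE)
      rng <- tibble::tibble(
        id = rownames(m),
        chromosome = sample(c("chr1", "chr2"), nf, TRUE),
        start = as.integer(start),
        end = as.integer(start + sample.int(300, nf, TRUE)),
        strand = sample(c("+", "-", "*"), nf, TRUE)
      )
      qs <- sample.int(5000, nq, replace = TRUE)
      query <- tibble::tibble(
        chromosome = sample(c("chr1", "chr2", "chr3"), nq, TRUE),
        start = as.integer(qs),
        end = as.integer(qs + sample.int(400, nq, TRUE)),
        strand = sample(c("+", "-", "*"), nq, TRUE, prob = c(0.15, 0.15, 0.7))
      )
      ms <- add_ranged(new_multiset(), ingest_bundle(m, ranges = rng), "expression")
      got <- get_feature_annotation(select_range(ms, query), "expression")$id
      expect_identical(got, oracle_overlap_ids(rng, query))
    })
  }
})

test_that("select_range is idempotent for a fixed query", {
  ms <- generate_fixture(fixture_spec(5, tables = NULL, proteome = NULL))
  q <- data.frame(chromosome = "chr1", start = 1, end = 3e7)
  once <- select_range(ms, q)
  expect_same_content(select_range(once, q), once)
})

test_that("feature predicates filter applicable datasets and pass others through", {
  m1 <- make_matrix(4, 2)
  f1 <- tibble::tibble(id = rownames(m1), gene = c("TP53", "TP53", "TP53", "MYC"))
  m2 <- make_matrix(3, 2)
  ms <- new_multiset() |>
    add_generic(ingest_bundle(m1, features = f1), tag = "t1") |>
    add_generic(ingest_bundle(m2), tag = "t3")

  expect_warning(sub <- subset_features(ms, 'gene == "TP53"'), "t3")
  expect_identical(nrow(get_feature_annotation(sub, "t1")), 3L)
  expect_identical(get_feature_annotation(sub, "t3"),
                   get_feature_annotation(ms, "t3"))  # unchanged

  # tautology leaves content equal
  taut <- subset_features(select_datasets(ms, "t1"), 'gene == gene')
  expect_same_content(taut, select_datasets(ms, "t1"))
})

test_that("phenotype predicates filter samples per dataset", {
  m <- make_matrix(4, 4)
  ph <- tibble::tibble(id = colnames(m),
                       sex = c("male", "female", "male", "female"),
                       age = c(10, 20, 30, 40))
  ms <- add_generic(new_multiset(), ingest_bundle(m, samples = ph), "t1")
  sub <- subset_phenotype(ms, 'sex == "male"')
  expect_identical(get_sample_names(sub, "t1"), c("s01", "s03"))
  sub2 <- subset_phenotype(ms, ~ age > 10 & sex == "female")
  expect_identical(get_sample_names(sub2, "t1"), c("s02", "s04"))
})

test_that("predicates outside the safe grammar are rejected", {
  ms <- three_table_fixture()
  expect_error(subset_features(ms, 'system("touch /tmp/x")'),
               class = "omicstack_parse_error")
  expect_error(subset_phenotype(ms, "age > "), class = "omicstack_parse_error")
  expect_error(subset_features(ms, 'gene %in% c("TP53"); 1'),
               class = "omicstack_parse_error")
})

test_that("common_samples forces the intersection in the first dataset's order", {
  ms <- three_table_fixture()
  cs <- common_samples(ms)
  expect_identical(get_sample_names(cs), list(t1 = "A", t2 = "A", t3 = "A"))

  # identical sample sets: content-equal up to reordering
  m <- make_matrix(3, 3)
  ms2 <- new_multiset() |>
    add_generic(ingest_bundle(m), tag = "a") |>
    add_generic(ingest_bundle(m[, c(3, 1, 2)]), tag = "b")
  cs2 <- common_samples(ms2)
  expect_identical(get_sample_names(cs2, "b"), get_sample_names(cs2, "a"))
  expect_identical(get_assays(cs2, "b")[[1]], m)

  # disjoint sets: all datasets kept with zero samples
  ms3 <- new_multiset() |>
    add_generic(ingest_bundle(make_matrix(2, 2, sprefix = "x")), tag = "a") |>
    add_generic(ingest_bundle(make_matrix(2, 2, sprefix = "y")), tag = "b")
  cs3 <- common_samples(ms3)
  expect_true(all(vapply(get_sample_names(cs3), length, integer(1)) == 0L))

  # idempotence
  expect_same_content(common_samples(cs), cs)
})

test_that("common_samples commutes with select_samples when S covers the intersection", {
  for (seed in 1:15) {
    ms <- random_container(seed)
    inter <- Reduce(intersect, get_sample_names(ms))
    S <- union(inter, withr::with_seed(seed, sample(LETTERS[1:8], 3)))
    a <- common_samples(select_samples(ms, S))
    b <- select_samples(common_samples(ms), S)
    expect_same_content(a, b)
  }
})

test_that("as_matrix_list exports aligned matrices and honours layer choice", {
  ms <- three_table_fixture()
  mats <- as_matrix_list(common_samples(ms))
  expect_named(mats, c("t1", "t2", "t3"))
  expect_true(all(vapply(mats, function(m) identical(colnames(m), "A"), logical(1))))

  expect_identical(as_matrix_list(new_multiset()), list())

  snp_ms <- generate_fixture(fixture_spec(4, tables = NULL, methexpr = NULL,
                                          proteome = NULL, metabolome = NULL))
  probs <- as_matrix_list(snp_ms, layer_choice = c(snp = "probability"))
  expect_identical(probs$snp, get_assays(snp_ms, "snp")$probability)
  expect_error(as_matrix_list(snp_ms, layer_choice = c(snp = "nope")),
               class = "omicstack_key_error")
})
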