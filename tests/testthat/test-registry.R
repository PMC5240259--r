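test_that("add_generic validates layer and annotation dimensions", {
  m <- make_matrix(10, 4)
  short_samples <- tibble::tibble(id = paste0("s", 1:3))
  expect_error(
    add_generic(new_multiset(), ingest_bundle(m, samples = short_samples), "expr2"),
    "sample annotation has 3 rows",
    class = "omicstack_validation_error"
  )
  bad_layers <- list(a = m, b = make_matrix(9, 4))
  expect_error(add_generic(new_multiset(), ingest_bundle(bad_layers), "x"),
               class = "omicstack_validation_error")
  expect_error(ingest_bundle(list(m, m)), class = "omicstack_validation_error")
})

test_that("a samples 'id' column overrides assay column names positionally", {
  m <- make_matrix(4, 3, sprefix = "r")
  samples <- tibble::tibble(id = c("s1", "s2", "s3"), age = c(30, 40, 50))
  ms <- add_generic(new_multiset(), ingest_bundle(m, samples = samples), "expr2")
  expect_identical(get_sample_names(ms, "expr2"), c("s1", "s2", "s3"))
  expect_identical(colnames(get_assays(ms, "expr2")[[1]]), c("s1", "s2", "s3"))
})

test_that("duplicate sample ids and duplicate keys are rejected", {
  m <- make_matrix(3, 2)
  dup <- tibble::tibble(id = c("a", "a"))
  expect_error(add_generic(new_multiset(), ingest_bundle(m, samples = dup), "x"),
               class = "omicstack_validation_error")
  ms <- add_generic(new_multiset(), ingest_bundle(m), "x")
  expect_error(add_generic(ms, ingest_bundle(m), "x"),
               class = "omicstack_conflict_error")
  expect_warning(add_generic(ms, ingest_bundle(m), "x", overwrite = TRUE),
                 "overwriting")
})

test_that("add_ranged requires explicit, exactly aligned, well-formed ranges", {
  m <- make_matrix(5, 3)
  rng <- make_ranges(rownames(m))
  ms <- add_ranged(new_multiset(), ingest_bundle(m, ranges = rng), "expression")
  expect_identical(ranged_dataset_names(ms), "expression")

  expect_error(add_ranged(new_multiset(), ingest_bundle(m), "expression"),
               class = "omicstack_validation_error")
  expect_error(
    add_ranged(new_multiset(), ingest_bundle(m, ranges = rng[1:4, ]), "expression"),
    class = "omicstack_validation_error"
  )
  bad <- rng
  bad$end[2] <- bad$start[2] - 5L
  expect_error(add_ranged(new_multiset(), ingest_bundle(m, ranges = bad), "expression"),
               "start must be <= end", class = "omicstack_validation_error")
  bad2 <- rng
  bad2$start[1] <- 0L
  expect_error(add_ranged(new_multiset(), ingest_bundle(m, ranges = bad2), "expression"),
               class = "omicstack_validation_error")
})

test_that("add_generic builds ranges from recognised coordinate columns", {
  m <- make_matrix(4, 2)
  feats <- tibble::tibble(id = rownames(m), CHR = "chr3",
                          Position = c(10, 20, 30, 40))
  ms <- add_generic(new_multiset(), ingest_bundle(m, features = feats), "meth2")
  rng <- get_ranges(ms, "meth2")
  expect_identical(rng$chromosome, rep("chr3", 4))
  expect_identical(rng$start, c(10L, 20L, 30L, 40L))
  expect_identical(rng$end, rng$start)  # missing end defaults to start
})

test_that("typed adders enforce their schemas", {
  m <- make_matrix(4, 3)
  # expression requires coordinates
  expect_error(add_expression(new_multiset(), ingest_bundle(m)),
               "chromosome", class = "omicstack_schema_error")
  feats <- tibble::tibble(id = rownames(m), chromosome = "chr1",
                          start = 1:4 * 100L, end = 1:4 * 100L + 50L)
  ms <- add_expression(new_multiset(), ingest_bundle(m, features = feats))
  expect_identical(ranged_dataset_names(ms), "expression")
  expect_identical(ms$recipes$expression$declared_class, "expression-set")

  # methylation beta domain
  beta <- make_matrix(4, 3, seed_values = stats::runif(12))
  beta[2, 2] <- 1.7
  mf <- tibble::tibble(id = rownames(beta), chromosome = "chr1", position = 1:4 * 10L)
  expect_error(add_methylation(new_multiset(), ingest_bundle(beta, features = mf)),
               "1.7", class = "omicstack_domain_error")
  beta[2, 2] <- 0.5
  ms2 <- add_methylation(new_multiset(), ingest_bundle(beta, features = mf))
  expect_identical(dataset_names(ms2), "methylation")

  # snp needs a call layer with codes {0,1,2,NA}
  calls <- make_matrix(4, 3, seed_values = sample(0:2, 12, TRUE))
  prob <- make_matrix(4, 3, seed_values = stats::runif(12))
  sf <- tibble::tibble(id = rownames(calls), chromosome = "chr2", position = 1:4 * 7L)
  expect_error(
    add_snp(new_multiset(), ingest_bundle(list(probability = prob), features = sf)),
    "call", class = "omicstack_schema_error"
  )
  bad_calls <- calls
  bad_calls[1, 1] <- 5
  expect_error(
    add_snp(new_multiset(),
            ingest_bundle(list(call = bad_calls, probability = prob), features = sf)),
    class = "omicstack_domain_error"
  )
  ms3 <- add_snp(new_multiset(),
                 ingest_bundle(list(call = calls, probability = prob), features = sf))
  expect_named(get_assays(ms3, "snp"), c("call", "probability"))
})

test_that("reconstruct returns what was ingested, restricted by later subsetting", {
  m <- make_matrix(5, 4)
  samples <- tibble::tibble(id = colnames(m), age = c(31, 42, 53, 64))
  features <- tibble::tibble(id = rownames(m), gene = letters[1:5])
  ms <- add_generic(new_multiset(), ingest_bundle(m, samples, features), "expr2")

  b <- reconstruct(ms, "expr2")
  expect_identical(b$assays$exprs, m)
  expect_identical(b$samples, samples)
  expect_identical(b$features, features)
  expect_identical(b$declared_class, "matrix-set")

  sub <- select_samples(ms, "s01")
  b2 <- reconstruct(sub, "expr2")
  expect_identical(b2$assays$exprs, m[, "s01", drop = FALSE])
  expect_identical(b2$samples, samples[1, ])

  expect_error(reconstruct(ms, "absent"), class = "omicstack_key_error")
})

test_that("round-trip law holds for randomized bundles", {
  for (seed in 1:25) {
    ranged <- seed %% 2 == 0
    b <- random_bundle(seed, ranged = ranged)
    key <- render_key("set", "r")
    ms1 <- if (ranged) add_ranged(new_multiset(), b, "set", "r")
           else add_generic(new_multiset(), b, "set", "r")
    b2 <- reconstruct(ms1, key)
    expect_identical(b2$assays, ms1$assays[[key]])
    expect_identical(b2$declared_class, "random-set")
    ms2 <- if (ranged) add_ranged(new_multiset(), b2, "set", "r")
           else add_generic(new_multiset(), b2, "set", "r")
    expect_same_content(ms1, ms2)
  }
})

test_that("adding a dataset never mutates the ones already stored", {
  ms <- random_container(11)
  snapshot <- list(assays = get_assays(ms), samples = get_sample_annotation(ms),
                   features = get_feature_annotation(ms), ranges = get_ranges(ms))
  ms2 <- add_generic(ms, random_bundle(99), tag = "late")
  expect_identical(get_assays(ms2)[names(snapshot$assays)], snapshot$assays)
  expect_identical(get_sample_annotation(ms2)[names(snapshot$samples)], snapshot$samples)
  expect_identical(get_feature_annotation(ms2)[names(snapshot$features)], snapshot$features)
  expect_identical(get_ranges(ms2)[names(snapshot$ranges)], snapshot$ranges)
  # and the original binding is untouched (functional update)
  expect_identical(get_assays(ms), snapshot$assays)
})
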