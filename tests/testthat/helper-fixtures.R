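# Fixture builders and independent brute-force oracles used across the suite.

make_matrix <- function(nf, ns, fprefix = "f", sprefix = "s", seed_values = NULL) {
  vals <- if (is.null(seed_values)) stats::rnorm(nf * ns) else seed_values
  matrix(vals, nf, ns,
         dimnames = list(sprintf("%s%02d", fprefix, seq_len(nf)),
                         sprintf("%s%02d", sprefix, seq_len(ns))))
}

make_ranges <- function(ids, chromosome = "chr1", start = NULL, width = 10L) {
  n <- length(ids)
  if (is.null(start)) start <- sort(sample.int(1e5, n))
  tibble::tibble(id = ids, chromosome = chromosome,
                 start = as.integer(start),
                 end = as.integer(start + width),
                 strand = "*")
}

# three tables on the overlapping sample sets {A,B}, {A,B,C}, {A,C}
three_table_fixture <- function(seed = 1) {
  generate_fixture(fixture_spec_tables(seed))
}

# randomized container: a few datasets over a shared sample pool, some ranged
random_container <- function(seed, n_datasets = 3, pool = LETTERS[1:8]) {
  withr::with_seed(seed, {
    ms <- new_multiset()
    for (i in seq_len(n_datasets)) {
      ids <- sort(sample(pool, sample(2:length(pool), 1)))
      nf <- sample(3:8, 1)
      m <- matrix(stats::rnorm(nf * length(ids)), nf, length(ids),
                  dimnames = list(sprintf("d%d_f%02d", i, seq_len(nf)), ids))
      samples <- tibble::tibble(id = ids,
                                group = sample(c("x", "y"), length(ids), TRUE))
      features <- tibble::tibble(id = rownames(m),
                                 score = round(stats::runif(nf), 3))
      if (i %% 2 == 1) {
        rng <- make_ranges(rownames(m),
                           chromosome = sample(c("chr1", "chr2"), nf, TRUE))
        ms <- add_ranged(ms, ingest_bundle(m, samples, features, ranges = rng),
                         tag = "set", name = as.character(i))
      } else {
        ms <- add_generic(ms, ingest_bundle(m, samples, features),
                          tag = "set", name = as.character(i))
      }
    }
    ms
  })
}

random_bundle <- function(seed, ranged = FALSE) {
  withr::with_seed(seed, {
    nf <- sample(2:10, 1)
    ns <- sample(2:6, 1)
    layers <- list(exprs = make_matrix(nf, ns))
    if (stats::runif(1) < 0.5) layers$weights <- make_matrix(nf, ns)
    samples <- tibble::tibble(id = colnames(layers[[1]]),
                              age = as.double(sample(20:60, ns, TRUE)))
    features <- tibble::tibble(id = rownames(layers[[1]]),
                               gene = sample(c("TP53", "MYC", "EGFR"), nf, TRUE))
    rng <- if (ranged) make_ranges(features$id,
                                   chromosome = sample(c("chr1", "chr2"), nf, TRUE))
    ingest_bundle(layers, samples, features, ranges = rng,
                  declared_class = "random-set")
  })
}

# Brute-force closed-interval overlap scan: O(features x query intervals).
# Strand is ignored unless the query interval is stranded, then it must match.
oracle_overlap_ids <- function(ranges, query) {
  keep <- vapply(seq_len(nrow(ranges)), function(i) {
    any(vapply(seq_len(nrow(query)), function(j) {
      same_chr <- ranges$chromosome[i] == query$chromosome[j]
      touches <- ranges$start[i] <= query$end[j] && ranges$end[i] >= query$start[j]
      strand_ok <- query$strand[j] == "*" || ranges$strand[i] == query$strand[j]
      same_chr && touches && strand_ok
    }, logical(1)))
  }, logical(1))
  ranges$id[keep]
}

# Brute-force Benjamini-Hochberg step-up: adj p_(i) = min over j >= i of
# min(1, n/j * p_(j)) on the sorted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  running <- Inf
  for (i in rev(seq_len(n))) {
    running <- min(running, n / i * sorted[i])
    adj[i] <- min(1, running)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# container content equality over the five collections
expect_same_content <- function(a, b) {
  expect_identical(get_assays(a), get_assays(b))
  expect_identical(get_sample_annotation(a), get_sample_annotation(b))
  expect_identical(get_feature_annotation(a), get_feature_annotation(b))
  expect_identical(get_ranges(a), get_ranges(b))
  expect_identical(a$recipes, b$recipes)
}
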