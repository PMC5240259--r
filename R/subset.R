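# Coordinated subsetting. All verbs are pure: they return a new container and
# never alter stored values -- retained cells are bit-identical to the input.

# Restrict one dataset to row/column index vectors (positions, in kept order).
# The LOD table in the recipe is feature-shaped, so feature subsetting must
# restrict it too.
restrict_entry <- function(ms, key, sample_idx = NULL, feature_idx = NULL) {
  if (!is.null(sample_idx)) {
    ms$assays[[key]] <- lapply(ms$assays[[key]], function(m) m[, sample_idx, drop = FALSE])
    ms$samples[[key]] <- ms$samples[[key]][sample_idx, ]
  }
  if (!is.null(feature_idx)) {
    ms$assays[[key]] <- lapply(ms$assays[[key]], function(m) m[feature_idx, , drop = FALSE])
    ms$features[[key]] <- ms$features[[key]][feature_idx, ]
    if (!is.null(ms$ranges[[key]])) {
      ms$ranges[[key]] <- ms$ranges[[key]][feature_idx, ]
    }
    lod <- ms$recipes[[key]]$extras$lod
    if (!is.null(lod)) {
      ms$recipes[[key]]$extras$lod <- lod[match(ms$features[[key]]$id, lod$id), ]
    }
  }
  ms
}

#' Select samples across all datasets (union semantics)
#'
#' Restricts every dataset to the intersection of `ids` with its own sample
#' set. Datasets are never dropped -- a dataset sharing no requested sample is
#' kept with zero samples -- and the relative sample order within each dataset
#' is preserved. This is union-style subsetting: the result may not contain
#' complete cases; use [common_samples()] for the complete-case intersection.
#'
#' @param ms A `multiset`.
#' @param ids Character vector of sample ids to keep. Ids present nowhere
#'   simply select nothing.
#' @return The restricted container.
#' @export
select_samples <- function(ms, ids) {
  check_multiset(ms)
  ids <- as.character(ids)
  for (key in dataset_names(ms)) {
    idx <- which(ms_sample_ids(ms, key) %in% ids)
    ms <- restrict_entry(ms, key, sample_idx = idx)
  }
  ms
}

#' Select datasets by key
#'
#' Restricts the container to the requested datasets, keeping the stored
#' insertion order. All keys must be present.
#'
#' @param ms A `multiset`.
#' @param keys Character vector of rendered dataset keys.
#' @return The restricted container.
#' @export
select_datasets <- function(ms, keys) {
  check_multiset(ms)
  for (k in keys) check_key(ms, k)
  keep <- dataset_names(ms)[dataset_names(ms) %in% keys]
  ms$assays <- ms$assays[keep]
  ms$samples <- ms$samples[keep]
  ms$features <- ms$features[keep]
  ms$ranges <- ms$ranges[keep]
  ms$recipes <- ms$recipes[keep]
  ms
}

#' Extract a single dataset in its original form
#'
#' Equivalent to [reconstruct()]: selecting one dataset out of the container
#' returns it as a bundle of its original declared class, reflecting any
#' subsetting applied at the container level.
#'
#' @inheritParams reconstruct
#' @return An [ingest_bundle()].
#' @export
extract <- function(ms, key) reconstruct(ms, key)

# Normalise a genomic query to a validated tibble
# (chromosome, start, end, strand), 1-based closed.
as_genomic_query <- function(query) {
  if (methods::is(query, "GRanges")) {
    query <- tibble::tibble(
      chromosome = as.character(GenomicRanges::seqnames(query)),
      start = GenomicRanges::start(query),
      end = GenomicRanges::end(query),
      strand = as.character(GenomicRanges::strand(query))
    )
  }
  if (!is.data.frame(query)) {
    stop_validation("query must be a data frame or GRanges of genomic intervals")
  }
  names(query)[tolower(names(query)) == "chr"] <- "chromosome"
  needed <- c("chromosome", "start", "end")
  missing <- setdiff(needed, names(query))
  if (length(missing) > 0L) {
    stop_validation(sprintf("query lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  query <- tibble::as_tibble(query)
  query$chromosome <- as.character(query$chromosome)
  query$start <- as.integer(query$start)
  query$end <- as.integer(query$end)
  if (!"strand" %in% names(query)) query$strand <- "*"
  query$strand <- as.character(query$strand)
  if (nrow(query) == 0L) stop_validation("query must contain at least one interval")
  if (anyNA(query$start) || anyNA(query$end)) {
    stop_validation("query start/end must be non-missing integers")
  }
  if (any(query$start < 1L)) stop_validation("query start must be >= 1")
  if (any(query$start > query$end)) stop_validation("query start must be <= end")
  if (!all(query$strand %in% c("+", "-", "*"))) {
    stop_validation("query strand must be one of '+', '-', '*'")
  }
  query
}

ranges_to_granges <- function(ranges) {
  GenomicRanges::GRanges(
    seqnames = ranges$chromosome,
    ranges = IRanges::IRanges(start = ranges$start, end = ranges$end),
    strand = ranges$strand
  )
}

#' Subset by genomic range
#'
#' Keeps, in every dataset that carries genomic coordinates, exactly the
#' features whose interval overlaps at least one query interval (closed
#' 1-based intervals on the same chromosome; touching counts as overlap).
#' Datasets without coordinates -- e.g. metabolomics -- are discarded from the
#' result. Samples are untouched. Strand is ignored unless a query interval
#' specifies `+` or `-`, in which case feature strands must match.
#'
#' @param ms A `multiset`.
#' @param query Genomic intervals: a data frame with columns
#'   `chromosome`/`chr`, `start`, `end` and optional `strand`, or a
#'   `GRanges` object.
#' @return The restricted container (ranged datasets only).
#' @export
select_range <- function(ms, query) {
  check_multiset(ms)
  query <- as_genomic_query(query)
  q_gr <- ranges_to_granges(query)
  ms <- select_datasets(ms, ranged_dataset_names(ms))
  for (key in dataset_names(ms)) {
    rng <- ms$ranges[[key]]
    if (nrow(rng) == 0L) next
    # datasets legitimately lack some query chromosomes; the seqlevel
    # mismatch warning would be noise here
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(ranges_to_granges(rng), q_gr,
                                  ignore.strand = TRUE))
    qh <- S4Vectors::subjectHits(hits)
    fh <- S4Vectors::queryHits(hits)
    stranded <- query$strand[qh] != "*"
    ok <- !stranded | rng$strand[fh] == query$strand[qh]
    keep <- sort(unique(fh[ok]))
    ms <- restrict_entry(ms, key, feature_idx = keep)
  }
  ms
}

# ---- safe predicate grammar -------------------------------------------------

# Predicates over annotation columns are restricted to comparisons
# (==, !=, <, <=, >, >=, %in%), logical connectives (&, |, !, &&, ||),
# parentheses and c(...) literals. No other calls are evaluated, so a
# predicate arriving from the command line cannot execute arbitrary code.
PREDICATE_CALLS <- c("==", "!=", "<", "<=", ">", ">=", "%in%",
                     "&", "|", "!", "&&", "||", "(", "c", "-", "+")

compile_predicate <- function(predicate) {
  expr <- if (is.character(predicate)) {
    if (length(predicate) != 1L) stop_parse("predicate must be a single string")
    parsed <- tryCatch(parse(text = predicate, keep.source = FALSE),
                       error = function(e) stop_parse(
                         sprintf("cannot parse predicate: %s", conditionMessage(e))))
    if (length(parsed) != 1L) stop_parse("predicate must be a single expression")
    parsed[[1]]
  } else if (inherits(predicate, "formula")) {
    if (length(predicate) != 2L) stop_parse("predicate formula must be one-sided")
    predicate[[2]]
  } else if (is.call(predicate) || is.name(predicate)) {
    predicate
  } else {
    stop_parse("predicate must be a string, one-sided formula or quoted expression")
  }
  vars <- character()
  walk <- function(e) {
    if (is.name(e)) {
      vars <<- union(vars, as.character(e))
    } else if (is.call(e)) {
      fn <- e[[1]]
      if (!is.name(fn) || !as.character(fn) %in% PREDICATE_CALLS) {
        stop_parse(sprintf(
          "predicate uses disallowed call '%s'; allowed: %s",
          paste(deparse(fn), collapse = ""), paste(PREDICATE_CALLS, collapse = " ")))
      }
      for (arg in as.list(e)[-1]) walk(arg)
    } else if (!is.atomic(e) && !is.null(e)) {
      stop_parse("predicate contains a non-literal, non-column component")
    }
  }
  walk(expr)
  list(expr = expr, vars = vars)
}

apply_predicate <- function(tbl, compiled) {
  keep <- eval(compiled$expr, envir = tbl, enclos = baseenv())
  if (!is.logical(keep) || !length(keep) %in% c(1L, nrow(tbl))) {
    stop_parse("predicate must evaluate to a logical vector over the rows")
  }
  if (length(keep) == 1L) keep <- rep(keep, nrow(tbl))
  which(!is.na(keep) & keep)
}

predicate_subset <- function(ms, predicate, slot) {
  check_multiset(ms)
  compiled <- compile_predicate(predicate)
  for (key in dataset_names(ms)) {
    tbl <- ms[[slot]][[key]]
    absent <- setdiff(compiled$vars, names(tbl))
    if (length(absent) > 0L) {
      warning(sprintf(
        "dataset '%s' lacks column(s) %s referenced by the predicate; left unfiltered",
        key, paste(absent, collapse = ", ")), call. = FALSE)
      next
    }
    idx <- apply_predicate(tbl, compiled)
    ms <- if (slot == "features") restrict_entry(ms, key, feature_idx = idx)
          else restrict_entry(ms, key, sample_idx = idx)
  }
  ms
}

#' Subset by feature or phenotype predicate
#'
#' `subset_features()` filters the features of each dataset whose feature
#' annotation contains every column the predicate references; datasets
#' lacking a referenced column pass through unfiltered (with a warning),
#' mirroring the union philosophy of sample subsetting. `subset_phenotype()`
#' does the same over sample annotation columns, filtering samples.
#'
#' Predicates are restricted to a safe comparison grammar -- column, literal,
#' `==`, `!=`, `<`, `<=`, `>`, `>=`, `%in%`, `&`, `|`, `!`, parentheses and
#' `c(...)` -- and may be given as a string (CLI-friendly), a one-sided
#' formula or a quoted expression.
#'
#' @param ms A `multiset`.
#' @param predicate Predicate over annotation columns, e.g.
#'   `'gene == "TP53"'` or `~ age > 10`.
#' @return The restricted container.
#' @export
subset_features <- function(ms, predicate) predicate_subset(ms, predicate, "features")

#' @rdname subset_features
#' @export
subset_phenotype <- function(ms, predicate) predicate_subset(ms, predicate, "samples")

#' Restrict every dataset to the common samples (complete cases)
#'
#' Computes the intersection of all datasets' sample sets and restricts every
#' dataset to it, reordered to one canonical order (the first stored
#' dataset's sample order) so that downstream matrix consumers see identical
#' columns everywhere. An empty intersection legally yields zero-sample
#' datasets.
#'
#' @param ms A `multiset`.
#' @return The complete-case container.
#' @export
common_samples <- function(ms) {
  check_multiset(ms)
  keys <- dataset_names(ms)
  if (length(keys) == 0L) return(ms)
  common <- Reduce(intersect, lapply(keys, function(k) ms_sample_ids(ms, k)))
  canonical <- ms_sample_ids(ms, keys[[1]])
  common <- canonical[canonical %in% common]
  for (key in keys) {
    idx <- match(common, ms_sample_ids(ms, key))
    ms <- restrict_entry(ms, key, sample_idx = idx)
  }
  ms
}

#' Export assay matrices as a named list
#'
#' One matrix (features x samples) per dataset, named by rendered key. By
#' default the first (primary) layer of each dataset is exported;
#' `layer_choice` overrides per key. Called after [common_samples()], all
#' matrices share identical column ids in identical order -- the input
#' contract of multi-block integration methods (multiple co-inertia analysis,
#' integrative clustering, ...).
#'
#' @param ms A `multiset`.
#' @param layer_choice Optional named character vector mapping dataset key to
#'   layer name.
#' @return Named list of matrices.
#' @export
as_matrix_list <- function(ms, layer_choice = NULL) {
  check_multiset(ms)
  out <- list()
  for (key in dataset_names(ms)) {
    layers <- ms$assays[[key]]
    layer <- if (!is.null(layer_choice) && key %in% names(layer_choice)) {
      layer_choice[[key]]
    } else {
      names(layers)[1]
    }
    if (!layer %in% names(layers)) {
      stop_key_error(sprintf(
        "dataset '%s' has no layer '%s' (layers: %s)",
        key, layer, paste(names(layers), collapse = ", ")))
    }
    out[[key]] <- layers[[layer]]
  }
  out
}
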