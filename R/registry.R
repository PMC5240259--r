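#' Bundle raw tables for ingestion into a multiset
#'
#' An ingest bundle is the pre-validation form of a dataset: one or more
#' assay layers plus optional sample/feature annotation, explicit genomic
#' ranges, and (for proteome data) a limit-of-detection table. Validation
#' happens when the bundle is added to a container, the single choke point
#' through which all datasets enter.
#'
#' @param assays A features x samples matrix, or a named list of such
#'   matrices (layers). A single unnamed matrix becomes layer `"exprs"`.
#' @param samples Optional sample annotation: a data frame keyed by an `id`
#'   column, or by row names matching the assay column names. When an `id`
#'   column is present its values *replace* the assay column names for
#'   alignment everywhere. Defaults to a bare table of assay column names.
#' @param features Optional feature annotation, keyed by an `id` column or by
#'   row names matching the assay row names.
#' @param ranges Optional explicit per-feature genomic ranges: a data frame
#'   with columns `id`, `chromosome` (or `chr`), `start` (or `position`),
#'   optional `end` (defaults to `start`) and optional `strand`. Coordinates
#'   are 1-based closed intervals.
#' @param lod Optional limit-of-detection table for proteome data: columns
#'   `id`, `lower_lod` and optionally `upper_lod`.
#' @param declared_class String recorded in the reconstruction recipe as the
#'   source dataset class (e.g. `"expression-set"`).
#' @return An object of class `ingest_bundle`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
#' b <- ingest_bundle(m)
#' @export
ingest_bundle <- function(assays, samples = NULL, features = NULL,
                          ranges = NULL, lod = NULL,
                          declared_class = "matrix-set") {
  if (is.matrix(assays)) assays <- list(exprs = assays)
  if (!is.list(assays) || length(assays) == 0L) {
    stop_validation("`assays` must be a matrix or a non-empty named list of matrices")
  }
  if (is.null(names(assays)) || any(!nzchar(names(assays))) || anyDuplicated(names(assays))) {
    stop_validation("assay layers must have unique non-empty names")
  }
  structure(
    list(assays = assays, samples = samples, features = features,
         ranges = ranges, lod = lod, declared_class = declared_class),
    class = "ingest_bundle"
  )
}

#' @rdname ingest_bundle
#' @param x Object to test.
#' @export
is_ingest_bundle <- function(x) inherits(x, "ingest_bundle")

#' @export
print.ingest_bundle <- function(x, ...) {
  d <- dim(x$assays[[1]])
  cat(sprintf(
    "<ingest_bundle> [%s] %d features x %d samples, layers: %s%s%s\n",
    x$declared_class, d[1], d[2], paste(names(x$assays), collapse = ", "),
    if (is.null(x$ranges)) "" else ", ranged",
    if (is.null(x$lod)) "" else ", LOD table"
  ))
  invisible(x)
}

# ---- internal normalisation -------------------------------------------------

as_annotation_tibble <- function(tbl, default_ids, what) {
  if (is.null(tbl)) return(tibble::tibble(id = default_ids))
  if (!is.data.frame(tbl)) stop_validation(sprintf("%s annotation must be a data frame", what))
  has_rownames <- !is.null(rownames(tbl)) &&
    !identical(rownames(tbl), as.character(seq_len(nrow(tbl))))
  if (!"id" %in% names(tbl)) {
    ids <- if (has_rownames) rownames(tbl) else default_ids
    if (nrow(tbl) != length(ids)) {
      stop_validation(sprintf(
        "%s annotation has %d rows but the assay has %d %ss",
        what, nrow(tbl), length(default_ids), what))
    }
    tbl <- tibble::as_tibble(tbl)
    tbl <- tibble::add_column(tbl, id = as.character(ids), .before = 1)
  } else {
    tbl <- tibble::as_tibble(tbl)
    tbl$id <- as.character(tbl$id)
    tbl <- dplyr::relocate(tbl, "id")
  }
  tbl[] <- lapply(tbl, function(col) {
    if (is.factor(col)) return(as.character(col))
    if (is.integer(col)) return(as.double(col))  # one numeric type end-to-end
    col
  })
  tbl
}

normalize_layers <- function(layers) {
  layers <- lapply(layers, function(m) {
    if (!is.matrix(m)) stop_validation("every assay layer must be a matrix")
    if (is.integer(m)) storage.mode(m) <- "double"
    m
  })
  ref <- layers[[1]]
  # zero-length dims legitimately have NULL dimnames (R normalises them)
  if ((nrow(ref) > 0L && is.null(rownames(ref))) ||
      (ncol(ref) > 0L && is.null(colnames(ref)))) {
    stop_validation("assay layers must carry feature row names and sample column names")
  }
  for (nm in names(layers)[-1]) {
    m <- layers[[nm]]
    if (!identical(dim(m), dim(ref))) {
      stop_validation(sprintf(
        "layer '%s' is %d x %d but layer '%s' is %d x %d (features x samples must agree)",
        nm, nrow(m), ncol(m), names(layers)[1], nrow(ref), ncol(ref)))
    }
    if (!identical(rownames(m), rownames(ref))) {
      stop_validation(sprintf("layer '%s' feature ids differ from layer '%s'",
                              nm, names(layers)[1]))
    }
    if (!identical(colnames(m), colnames(ref))) {
      stop_validation(sprintf("layer '%s' sample ids differ from layer '%s'",
                              nm, names(layers)[1]))
    }
  }
  layers
}

# Recognised coordinate columns in feature annotation, case-insensitive:
# chromosome|chr, start|position, optional end (defaults to start), optional
# strand. Returns a range tibble or NULL when no coordinates are present.
ranges_from_annotation <- function(features) {
  lower <- tolower(names(features))
  chr_col <- which(lower %in% c("chromosome", "chr"))[1]
  start_col <- which(lower %in% c("start", "position"))[1]
  if (is.na(chr_col) || is.na(start_col)) return(NULL)
  end_col <- which(lower == "end")[1]
  strand_col <- which(lower == "strand")[1]
  start <- as.integer(features[[start_col]])
  tibble::tibble(
    id = features$id,
    chromosome = as.character(features[[chr_col]]),
    start = start,
    end = if (is.na(end_col)) start else as.integer(features[[end_col]]),
    strand = if (is.na(strand_col)) rep("*", nrow(features))
             else as.character(features[[strand_col]])
  )
}

validate_ranges <- function(ranges, feature_ids) {
  if (!is.data.frame(ranges)) stop_validation("ranges must be a data frame")
  lower <- tolower(names(ranges))
  names(ranges)[lower == "chr"] <- "chromosome"
  names(ranges)[tolower(names(ranges)) == "position"] <- "start"
  needed <- c("id", "chromosome", "start")
  missing <- setdiff(needed, names(ranges))
  if (length(missing) > 0L) {
    stop_validation(sprintf("ranges table lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  ranges <- tibble::as_tibble(ranges)
  ranges$id <- as.character(ranges$id)
  ranges$chromosome <- as.character(ranges$chromosome)
  ranges$start <- as.integer(ranges$start)
  ranges$end <- if ("end" %in% names(ranges)) as.integer(ranges$end) else ranges$start
  ranges$strand <- if ("strand" %in% names(ranges)) as.character(ranges$strand)
                   else rep("*", nrow(ranges))
  ranges <- ranges[, c("id", "chromosome", "start", "end", "strand")]
  if (anyDuplicated(ranges$id)) stop_validation("duplicate feature ids in ranges table")
  if (!setequal(ranges$id, feature_ids) || nrow(ranges) != length(feature_ids)) {
    stop_validation(sprintf(
      "ranges cover %d feature id(s) but the dataset has %d; ids must match exactly",
      nrow(ranges), length(feature_ids)))
  }
  ranges <- ranges[match(feature_ids, ranges$id), ]
  if (anyNA(ranges$start) || anyNA(ranges$end)) {
    stop_validation("range start/end must be integer and non-missing")
  }
  if (any(ranges$start < 1L)) stop_validation("range start must be >= 1 (1-based coordinates)")
  if (any(ranges$start > ranges$end)) stop_validation("range start must be <= end")
  if (!all(ranges$strand %in% c("+", "-", "*"))) {
    stop_validation("strand must be one of '+', '-', '*'")
  }
  ranges
}

# Resolve a bundle into a validated dataset entry (the five per-dataset
# pieces). `ranges_source` picks between annotation-derived and explicit
# ranges -- the difference between add_generic() and add_ranged().
resolve_bundle <- function(bundle, ranges_source = c("annotation", "explicit", "none")) {
  ranges_source <- match.arg(ranges_source)
  if (!is_ingest_bundle(bundle)) stop_validation("expected an `ingest_bundle`")
  layers <- normalize_layers(bundle$assays)
  ref <- layers[[1]]

  samples <- as_annotation_tibble(bundle$samples, colnames(ref) %||% character(), "sample")
  if (nrow(samples) != ncol(ref)) {
    stop_validation(sprintf(
      "sample annotation has %d rows but assay layers have %d samples",
      nrow(samples), ncol(ref)))
  }
  if (anyDuplicated(samples$id)) {
    stop_validation(sprintf("duplicate sample id(s): %s",
      paste(unique(samples$id[duplicated(samples$id)]), collapse = ", ")))
  }
  # The `id` column (when supplied) overrides assay column names positionally;
  # otherwise ids default to the assay column names. With row-name-keyed
  # annotation, rows are aligned to the assay column order first.
  if (!is.null(bundle$samples) && !"id" %in% names(bundle$samples)) {
    if (!setequal(samples$id, colnames(ref))) {
      stop_validation("sample annotation row names do not match assay column names")
    }
    samples <- samples[match(colnames(ref), samples$id), ]
  }
  for (nm in names(layers)) colnames(layers[[nm]]) <- samples$id

  features <- as_annotation_tibble(bundle$features, rownames(ref) %||% character(), "feature")
  if (nrow(features) != nrow(ref)) {
    stop_validation(sprintf(
      "feature annotation has %d rows but assay layers have %d features",
      nrow(features), nrow(ref)))
  }
  if (anyDuplicated(features$id)) {
    stop_validation(sprintf("duplicate feature id(s): %s",
      paste(unique(features$id[duplicated(features$id)]), collapse = ", ")))
  }
  if (!identical(features$id, rownames(ref))) {
    if (!setequal(features$id, rownames(ref))) {
      stop_validation("feature annotation ids do not match assay row names")
    }
    features <- features[match(rownames(ref), features$id), ]
  }

  ranges <- if (ranges_source == "explicit") {
    if (is.null(bundle$ranges)) stop_validation("add_ranged() requires explicit `ranges`")
    validate_ranges(bundle$ranges, features$id)
  } else if (ranges_source == "none") {
    NULL
  } else {
    rng <- ranges_from_annotation(features)
    if (is.null(rng)) NULL else validate_ranges(rng, features$id)
  }

  recipe <- list(
    declared_class = bundle$declared_class,
    layers = names(layers),
    ranged = !is.null(ranges),
    extras = list()
  )
  if (!is.null(bundle$lod)) recipe$extras$lod <- validate_lod(bundle$lod, features$id)

  list(assays = layers, samples = samples, features = features,
       ranges = ranges, recipe = recipe)
}

ms_insert <- function(ms, key, entry, overwrite = FALSE) {
  if (key %in% dataset_names(ms)) {
    if (!overwrite) {
      stop_conflict(sprintf(
        "dataset '%s' already present; use overwrite = TRUE to replace it", key))
    }
    warning(sprintf("overwriting existing dataset '%s'", key), call. = FALSE)
  }
  ms$assays[[key]] <- entry$assays
  ms$samples[[key]] <- entry$samples
  ms$features[[key]] <- entry$features
  ms$ranges[key] <- list(entry$ranges)  # keeps NULL entries
  ms$recipes[[key]] <- entry$recipe
  ms
}

# ---- basic add functions ----------------------------------------------------

#' Add a dataset to a multiset
#'
#' `add_generic()` is the basic ingestion entry point: it validates the
#' bundle's internal consistency (layer dimensions, id uniqueness, annotation
#' alignment) and stores it under the rendered key. If the feature annotation
#' carries recognised coordinate columns (`chromosome`/`chr`,
#' `start`/`position`, optional `end`, optional `strand`), a genomic range
#' table is built from them. `add_ranged()` instead takes the ranges
#' explicitly from `bundle$ranges`, which must cover the feature ids exactly.
#'
#' The typed adders ([add_expression()], [add_methylation()], [add_snp()],
#' [add_proteome()]) layer schema checks on top of these two and are the
#' entry points users should normally call; the basic functions are the
#' extension mechanism for new omic types.
#'
#' @param ms A `multiset`.
#' @param bundle An [ingest_bundle()].
#' @param tag Omic-type tag for the dataset key.
#' @param name Optional name qualifying the key (`tag+name`).
#' @param overwrite Replace an existing dataset under the same key? Defaults
#'   to `FALSE`; replacement emits a warning.
#' @return The container with the dataset added (the input is not modified).
#' @export
add_generic <- function(ms, bundle, tag, name = NULL, overwrite = FALSE) {
  check_multiset(ms)
  key <- render_key(tag, name)
  entry <- resolve_bundle(bundle, ranges_source = "annotation")
  ms_insert(ms, key, entry, overwrite = overwrite)
}

#' @rdname add_generic
#' @export
add_ranged <- function(ms, bundle, tag, name = NULL, overwrite = FALSE) {
  check_multiset(ms)
  key <- render_key(tag, name)
  entry <- resolve_bundle(bundle, ranges_source = "explicit")
  ms_insert(ms, key, entry, overwrite = overwrite)
}

# ---- typed (specific) add functions ----------------------------------------

require_coord_columns <- function(bundle, what, need_position_word = FALSE) {
  features <- as_annotation_tibble(bundle$features,
                                   rownames(bundle$assays[[1]]), "feature")
  lower <- tolower(names(features))
  missing <- character()
  if (!any(lower %in% c("chromosome", "chr"))) missing <- c(missing, "chromosome|chr")
  if (!any(lower %in% c("start", "position"))) {
    missing <- c(missing, if (need_position_word) "position|start" else "start|position")
  }
  if (length(missing) > 0L) {
    stop_schema(sprintf(
      "%s feature annotation lacks required column(s): %s",
      what, paste(missing, collapse = ", ")))
  }
  invisible(features)
}

#' Typed ingestion of expression, methylation and SNP datasets
#'
#' The three omic-specific adders shipped natively. Each validates a schema
#' before delegating to the basic [add_generic()]:
#'
#' * `add_expression()` requires genomic coordinates (`chromosome` + `start`,
#'   optional `end`) in the feature annotation, so the dataset supports
#'   range queries; the key tag is fixed to `"expression"`.
#' * `add_methylation()` requires `chromosome` + `position` (or `start`) and
#'   checks that the primary layer holds beta values in \[0, 1\]; tag
#'   `"methylation"`.
#' * `add_snp()` requires a layer named `"call"` with genotype codes in
#'   \{0, 1, 2, NA\} plus coordinates; additional layers (e.g. call
#'   probabilities) are preserved; tag `"snp"`.
#'
#' Only feature-annotated, coordinate-bearing datasets pass a typed adder;
#' anything else must go through the basic functions deliberately. Proteome
#' data has its own extension adder, [add_proteome()].
#'
#' @inheritParams add_generic
#' @return The container with the dataset added.
#' @export
add_expression <- function(ms, bundle, name = NULL, overwrite = FALSE) {
  if (!is_ingest_bundle(bundle)) stop_validation("expected an `ingest_bundle`")
  require_coord_columns(bundle, "expression")
  if (identical(bundle$declared_class, "matrix-set")) {
    bundle$declared_class <- "expression-set"
  }
  add_generic(ms, bundle, tag = "expression", name = name, overwrite = overwrite)
}

#' @rdname add_expression
#' @export
add_methylation <- function(ms, bundle, name = NULL, overwrite = FALSE) {
  if (!is_ingest_bundle(bundle)) stop_validation("expected an `ingest_bundle`")
  require_coord_columns(bundle, "methylation", need_position_word = TRUE)
  primary <- bundle$assays[[1]]
  vals <- primary[!is.na(primary)]
  if (length(vals) > 0L && (any(vals < 0) || any(vals > 1))) {
    bad <- vals[vals < 0 | vals > 1][1]
    stop_domain(sprintf(
      "methylation beta values must lie in [0, 1]; found %g in layer '%s'",
      bad, names(bundle$assays)[1]))
  }
  if (identical(bundle$declared_class, "matrix-set")) {
    bundle$declared_class <- "methylation-set"
  }
  add_generic(ms, bundle, tag = "methylation", name = name, overwrite = overwrite)
}

#' @rdname add_expression
#' @export
add_snp <- function(ms, bundle, name = NULL, overwrite = FALSE) {
  if (!is_ingest_bundle(bundle)) stop_validation("expected an `ingest_bundle`")
  if (!"call" %in% names(bundle$assays)) {
    stop_schema("snp bundle requires an assay layer named 'call'")
  }
  require_coord_columns(bundle, "snp", need_position_word = TRUE)
  calls <- bundle$assays[["call"]]
  vals <- calls[!is.na(calls)]
  if (length(vals) > 0L && !all(vals %in% c(0, 1, 2))) {
    stop_domain("snp 'call' layer must hold genotype codes 0, 1, 2 or NA")
  }
  if (identical(bundle$declared_class, "matrix-set")) {
    bundle$declared_class <- "snp-set"
  }
  add_generic(ms, bundle, tag = "snp", name = name, overwrite = overwrite)
}

#' Recover a dataset in its original form
#'
#' Returns an [ingest_bundle()] equal to what was ingested -- same layers,
#' values, annotations, ranges, ids and order -- restricted to whatever
#' container-level subsetting has been applied since. The bundle's
#' `declared_class` comes from the stored reconstruction recipe.
#'
#' @param ms A `multiset`.
#' @param key Rendered dataset key.
#' @return An `ingest_bundle`.
#' @export
reconstruct <- function(ms, key) {
  check_multiset(ms)
  check_key(ms, key)
  recipe <- ms$recipes[[key]]
  samples <- ms$samples[[key]]
  features <- ms$features[[key]]
  ingest_bundle(
    assays = ms$assays[[key]],
    samples = if (ncol(samples) > 1L) samples else NULL,
    features = if (ncol(features) > 1L) features else NULL,
    ranges = ms$ranges[[key]],
    lod = recipe$extras$lod,
    declared_class = recipe$declared_class
  )
}
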