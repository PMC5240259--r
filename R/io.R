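# Text-based I/O: TSV matrices and annotation tables, BED ranges (0-based
# half-open on disk, 1-based closed in memory; rtracklayer does the boundary
# conversion), and a versioned directory-bundle serialization of a whole
# container. "NA" encodes missing; everything is UTF-8 and diff-able.

MANIFEST_VERSION <- "1.0"
MANIFEST_FILE <- "manifest.yaml"

# Columns are read as text and type-converted with R's own numeric parser:
# the fast multi-threaded TSV parser is off by one ulp on some doubles, and
# the serialization contract here is bit-exact value round-trips.
read_tsv_quiet <- function(path, id_col = "id") {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tbl <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE, na = "NA"),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (!is.null(id_col)) {
    if (!id_col %in% names(tbl)) {
      stop_parse(sprintf("%s lacks the '%s' column", path, id_col))
    }
  }
  for (nm in names(tbl)) {
    if (identical(nm, id_col)) next
    tbl[[nm]] <- utils::type.convert(tbl[[nm]], as.is = TRUE, na.strings = "NA")
    if (is.integer(tbl[[nm]])) tbl[[nm]] <- as.double(tbl[[nm]])
  }
  tbl
}

matrix_to_tsv <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  df <- tibble::add_column(df, id = as.character(rownames(m) %||% character()),
                           .before = 1)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
}

# `mode` pins the storage mode ("double"/"character"); needed because a
# zero-row or zero-column TSV carries no type information of its own.
tsv_to_matrix <- function(path, mode = NULL) {
  tbl <- read_tsv_quiet(path)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$id
  if (!is.null(mode)) {
    storage.mode(m) <- mode
  } else if (is.integer(m) || is.logical(m)) {
    storage.mode(m) <- "double"
  }
  m
}

#' Read and write BED range files
#'
#' BED files are 0-based half-open on disk; in memory ranges are 1-based
#' closed. The name field (column 4) carries the feature id and is required
#' on read.
#'
#' @param path Path to a BED file.
#' @return `read_bed()`: a range tibble with columns `id`, `chromosome`,
#'   `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop_parse(
                   sprintf("cannot parse BED file %s: %s", path, conditionMessage(e))))
  if (length(gr) == 0L) {
    return(tibble::tibble(id = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) {
    stop_parse(sprintf("%s: BED name field (column 4) is required as the feature id", path))
  }
  tibble::tibble(
    id = as.character(nm),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname read_bed
#' @param ranges A range tibble (`id`, `chromosome`, `start`, `end`, `strand`).
#' @export
write_bed <- function(ranges, path) {
  gr <- ranges_to_granges(ranges)
  gr$name <- as.character(ranges$id)
  gr$score <- rep(0L, length(gr))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

coerce_col_types <- function(tbl, types) {
  for (nm in intersect(names(tbl), names(types))) {
    tbl[[nm]] <- switch(types[[nm]],
                        character = as.character(tbl[[nm]]),
                        numeric = as.double(tbl[[nm]]),
                        integer = as.double(tbl[[nm]]),
                        logical = as.logical(tbl[[nm]]),
                        tbl[[nm]])
  }
  tbl
}

#' Read one dataset directory into an ingest bundle
#'
#' Expects tab-delimited tables: one or more assay layers (`assay.tsv` for a
#' single layer named `exprs`, or `assay_<layer>.tsv` per layer; features in
#' rows, first column `id`, remaining column names the sample ids), optional
#' `samples.tsv` and `features.tsv` (first column `id`), optional
#' `ranges.bed` and optional `lod.tsv`.
#'
#' @param path Dataset directory.
#' @param declared_class Class recorded in the bundle (defaults to
#'   `"matrix-set"`).
#' @return An [ingest_bundle()].
#' @export
read_dataset_dir <- function(path, declared_class = "matrix-set") {
  if (!dir.exists(path)) stop_format(sprintf("dataset directory not found: %s", path))
  layer_files <- sort(list.files(path, pattern = "^assay(_[^.]+)?\\.tsv$"))
  if (length(layer_files) == 0L) {
    stop_parse(sprintf("%s: no assay table (assay.tsv or assay_<layer>.tsv)", path))
  }
  layers <- list()
  for (f in layer_files) {
    layer <- if (f == "assay.tsv") "exprs" else sub("^assay_(.+)\\.tsv$", "\\1", f)
    layers[[layer]] <- tsv_to_matrix(file.path(path, f))
  }

  samples <- NULL
  sp <- file.path(path, "samples.tsv")
  if (file.exists(sp)) {
    samples <- read_tsv_quiet(sp)
    assay_samples <- colnames(layers[[1]])
    missing <- setdiff(assay_samples, samples$id)
    if (length(missing) > 0L) {
      stop_parse(sprintf("%s: sample(s) %s present in the assay header but absent from samples.tsv",
                         sp, paste(missing, collapse = ", ")))
    }
    extra <- setdiff(samples$id, assay_samples)
    if (length(extra) > 0L) {
      stop_parse(sprintf("%s: sample(s) %s absent from the assay header",
                         sp, paste(extra, collapse = ", ")))
    }
    samples <- samples[match(assay_samples, samples$id), ]
  }

  features <- NULL
  fp <- file.path(path, "features.tsv")
  if (file.exists(fp)) {
    features <- read_tsv_quiet(fp)
    assay_features <- rownames(layers[[1]])
    if (!setequal(features$id, assay_features) || nrow(features) != length(assay_features)) {
      stop_parse(sprintf("%s: feature ids do not match the assay row ids", fp))
    }
    features <- features[match(assay_features, features$id), ]
  }

  ranges <- NULL
  rp <- file.path(path, "ranges.bed")
  if (file.exists(rp)) ranges <- read_bed(rp)

  lod <- NULL
  lp <- file.path(path, "lod.tsv")
  if (file.exists(lp)) lod <- read_tsv_quiet(lp)

  ingest_bundle(assays = layers, samples = samples, features = features,
                ranges = ranges, lod = lod, declared_class = declared_class)
}

#' Serialize a multiset to a directory bundle
#'
#' Writes one sub-directory per dataset (TSV assay layers, `samples.tsv`,
#' `features.tsv`, `ranges.bed` when ranged, `lod.tsv` when present) plus a
#' versioned `manifest.yaml` tying them together. `read_multiset()` inverts
#' it exactly: write followed by read is the identity on container content.
#'
#' @param ms A `multiset`.
#' @param path Output directory (created if needed).
#' @return `write_multiset()`: the manifest, invisibly. `read_multiset()`:
#'   the restored `multiset`.
#' @export
write_multiset <- function(ms, path) {
  check_multiset(ms)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  keys <- dataset_names(ms)
  entries <- list()
  for (i in seq_along(keys)) {
    key <- keys[[i]]
    dsdir <- sprintf("ds%03d", i)
    dir.create(file.path(path, dsdir), showWarnings = FALSE)
    layer_files <- list()
    for (layer in names(ms$assays[[key]])) {
      f <- sprintf("assay_%s.tsv", layer)
      matrix_to_tsv(ms$assays[[key]][[layer]], file.path(path, dsdir, f))
      layer_files[[layer]] <- f
    }
    readr::write_tsv(ms$samples[[key]], file.path(path, dsdir, "samples.tsv"),
                     na = "NA", progress = FALSE)
    readr::write_tsv(ms$features[[key]], file.path(path, dsdir, "features.tsv"),
                     na = "NA", progress = FALSE)
    ranged <- !is.null(ms$ranges[[key]])
    if (ranged) write_bed(ms$ranges[[key]], file.path(path, dsdir, "ranges.bed"))
    recipe <- ms$recipes[[key]]
    has_lod <- !is.null(recipe$extras$lod)
    if (has_lod) {
      readr::write_tsv(recipe$extras$lod, file.path(path, dsdir, "lod.tsv"),
                       na = "NA", progress = FALSE)
    }
    entries[[i]] <- list(
      key = key,
      declared_class = recipe$declared_class,
      dir = dsdir,
      layers = layer_files,
      layer_types = lapply(ms$assays[[key]], storage.mode),
      sample_col_types = lapply(ms$samples[[key]], function(x) class(x)[1]),
      feature_col_types = lapply(ms$features[[key]], function(x) class(x)[1]),
      ranges = if (ranged) "ranges.bed" else NULL,
      lod = if (has_lod) "lod.tsv" else NULL,
      n_features = nrow(ms$features[[key]]),
      n_samples = nrow(ms$samples[[key]])
    )
  }
  manifest <- list(format = "omicstack-bundle", format_version = MANIFEST_VERSION,
                   datasets = entries)
  yaml::write_yaml(manifest, file.path(path, MANIFEST_FILE))
  invisible(manifest)
}

#' @rdname write_multiset
#' @export
read_multiset <- function(path) {
  mf <- file.path(path, MANIFEST_FILE)
  if (!file.exists(mf)) stop_format(sprintf("no %s in %s", MANIFEST_FILE, path))
  manifest <- tryCatch(yaml::read_yaml(mf),
                       error = function(e) stop_format(
                         sprintf("cannot parse manifest: %s", conditionMessage(e))))
  version <- manifest$format_version
  if (is.null(version) ||
      strsplit(as.character(version), ".", fixed = TRUE)[[1]][1] !=
      strsplit(MANIFEST_VERSION, ".", fixed = TRUE)[[1]][1]) {
    stop_format(sprintf("unsupported bundle format version '%s' (reader supports %s)",
                        version %||% "<missing>", MANIFEST_VERSION))
  }
  ms <- new_multiset()
  for (entry in manifest$datasets) {
    dsdir <- file.path(path, entry$dir)
    layers <- list()
    for (layer in names(entry$layers)) {
      f <- file.path(dsdir, entry$layers[[layer]])
      if (!file.exists(f)) stop_format(sprintf("manifest references missing file: %s", f))
      layers[[layer]] <- tsv_to_matrix(f, mode = entry$layer_types[[layer]])
    }
    samples <- coerce_col_types(read_tsv_quiet(file.path(dsdir, "samples.tsv")),
                                entry$sample_col_types)
    features <- coerce_col_types(read_tsv_quiet(file.path(dsdir, "features.tsv")),
                                 entry$feature_col_types)
    ranges <- if (!is.null(entry$ranges)) {
      f <- file.path(dsdir, entry$ranges)
      if (!file.exists(f)) stop_format(sprintf("manifest references missing file: %s", f))
      read_bed(f)
    }
    lod <- if (!is.null(entry$lod)) read_tsv_quiet(file.path(dsdir, entry$lod))
    bundle <- ingest_bundle(assays = layers, samples = samples, features = features,
                            ranges = ranges, lod = lod,
                            declared_class = entry$declared_class)
    entry_resolved <- resolve_bundle(
      bundle, ranges_source = if (is.null(ranges)) "none" else "explicit")
    ms <- ms_insert(ms, entry$key, entry_resolved)
  }
  ms
}
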