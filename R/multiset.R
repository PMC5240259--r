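#' Create an empty multiset container
#'
#' A multiset holds any number of omic datasets measured on overlapping --
#' but not necessarily identical -- sample sets. Internally it keeps five
#' parallel collections, all keyed by the rendered dataset key:
#'
#' * `assays` -- per dataset, a named list of features x samples matrices,
#' * `samples` -- per dataset, a sample annotation tibble (phenotype and
#'   technical variables; deliberately *not* merged across datasets),
#' * `features` -- per dataset, a feature annotation tibble,
#' * `ranges` -- per dataset, a genomic range tibble, or `NULL` for assays
#'   without genomic coordinates (metabolomics, untargeted proteomics, ...),
#' * `recipes` -- per dataset, the reconstruction recipe recording the
#'   declared source class and layer mapping, so [reconstruct()] can return
#'   the dataset in its original shape after any container-level subsetting.
#'
#' Containers start empty; datasets enter through the ingestion functions
#' ([add_generic()], [add_ranged()] and the typed adders), which are the only
#' code paths that mutate a container. Accessors return plain copies.
#'
#' @return An empty object of class `multiset`.
#' @examples
#' ms <- new_multiset()
#' n_datasets(ms)
#' @export
new_multiset <- function() {
  structure(
    list(
      assays   = list(),
      samples  = list(),
      features = list(),
      ranges   = list(),
      recipes  = list()
    ),
    class = "multiset"
  )
}

#' @rdname new_multiset
#' @param x Object to test.
#' @export
is_multiset <- function(x) inherits(x, "multiset")

# The five top-level collections and the six accessors. These vectors are the
# single source of truth used by describe_structure() and its tests.
MS_COLLECTIONS <- c("assays", "samples", "features", "ranges", "recipes")
MS_ACCESSORS <- c(
  "get_assays", "get_sample_annotation", "get_feature_annotation",
  "get_ranges", "ranged_dataset_names", "get_sample_names"
)

#' Render a dataset key from its tag and optional name
#'
#' The key of a dataset is its omic tag (e.g. `"expression"`), optionally
#' qualified by a name so several datasets of one type can coexist
#' (`"expression+batch1"`). `+` separates tag and name and is therefore
#' forbidden inside either.
#'
#' @param tag Short string naming the omic type.
#' @param name Optional string distinguishing datasets of one tag.
#' @return The rendered key string.
#' @examples
#' render_key("expression")
#' render_key("expression", "batch1")
#' @export
render_key <- function(tag, name = NULL) {
  if (!is.character(tag) || length(tag) != 1L || is.na(tag) || !nzchar(tag)) {
    stop_validation("`tag` must be a single non-empty string")
  }
  if (grepl("+", tag, fixed = TRUE)) {
    stop_validation("`tag` must not contain '+' (reserved as the tag/name separator)")
  }
  if (is.null(name)) return(tag)
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop_validation("`name`, when given, must be a single non-empty string")
  }
  if (grepl("+", name, fixed = TRUE)) {
    stop_validation("`name` must not contain '+' (reserved as the tag/name separator)")
  }
  paste0(tag, "+", name)
}

#' Names and count of the datasets in a container
#'
#' @param ms A `multiset`.
#' @return `dataset_names()`: character vector of rendered keys in insertion
#'   order. `n_datasets()`: integer count.
#' @examples
#' dataset_names(new_multiset())
#' @export
dataset_names <- function(ms) {
  check_multiset(ms)
  names(ms$assays) %||% character()
}

#' @rdname dataset_names
#' @export
n_datasets <- function(ms) length(dataset_names(ms))

check_multiset <- function(ms) {
  if (!is_multiset(ms)) stop_validation("expected a `multiset` object")
  invisible(ms)
}

check_key <- function(ms, key) {
  if (!is.character(key) || length(key) != 1L || is.na(key)) {
    stop_key_error("dataset key must be a single string")
  }
  if (!key %in% dataset_names(ms)) {
    stop_key_error(sprintf(
      "unknown dataset key '%s' (available: %s)",
      key,
      if (n_datasets(ms) == 0L) "<none>" else paste(dataset_names(ms), collapse = ", ")
    ))
  }
  invisible(key)
}

#' Accessors for the five collections of a multiset
#'
#' Six accessors expose the stored information: `get_assays()`,
#' `get_sample_annotation()`, `get_feature_annotation()`, `get_ranges()`,
#' `ranged_dataset_names()` and `get_sample_names()`. With `key = NULL` the
#' first four return a list over all datasets; with a key they return that
#' dataset's entry. `get_ranges()` returns `NULL` for datasets without genomic
#' coordinates -- an *absent* range table, distinct from an empty one.
#'
#' @param ms A `multiset`.
#' @param key Optional rendered dataset key.
#' @return `get_assays()`: named list of matrices (or list thereof);
#'   `get_sample_annotation()`/`get_feature_annotation()`: tibble (or list);
#'   `get_ranges()`: range tibble with columns `id`, `chromosome`, `start`,
#'   `end`, `strand`, or `NULL` when absent; `ranged_dataset_names()`:
#'   character vector; `get_sample_names()`: named list of sample-id vectors.
#' @export
get_assays <- function(ms, key = NULL) {
  check_multiset(ms)
  if (is.null(key)) return(ms$assays)
  check_key(ms, key)
  ms$assays[[key]]
}

#' @rdname get_assays
#' @export
get_sample_annotation <- function(ms, key = NULL) {
  check_multiset(ms)
  if (is.null(key)) return(ms$samples)
  check_key(ms, key)
  ms$samples[[key]]
}

#' @rdname get_assays
#' @export
get_feature_annotation <- function(ms, key = NULL) {
  check_multiset(ms)
  if (is.null(key)) return(ms$features)
  check_key(ms, key)
  ms$features[[key]]
}

#' @rdname get_assays
#' @export
get_ranges <- function(ms, key = NULL) {
  check_multiset(ms)
  if (is.null(key)) return(ms$ranges)
  check_key(ms, key)
  ms$ranges[[key]]
}

#' @rdname get_assays
#' @export
ranged_dataset_names <- function(ms) {
  check_multiset(ms)
  keys <- dataset_names(ms)
  keys[vapply(keys, function(k) !is.null(ms$ranges[[k]]), logical(1))]
}

#' @rdname get_assays
#' @export
get_sample_names <- function(ms, key = NULL) {
  check_multiset(ms)
  if (!is.null(key)) {
    check_key(ms, key)
    return(ms$samples[[key]]$id)
  }
  lapply(ms$samples, function(tbl) tbl$id)
}

ms_sample_ids <- function(ms, key) ms$samples[[key]]$id
ms_feature_ids <- function(ms, key) ms$features[[key]]$id

#' Summarise the structure of a multiset
#'
#' Reports the container's five top-level collections, its six accessors and
#' the per-dataset dimensions (features, samples, layers, presence of genomic
#' ranges, declared source class).
#'
#' @param ms A `multiset`.
#' @return A `multiset_structure` list with elements `collections` (length 5),
#'   `accessors` (length 6) and `datasets` (a tibble with one row per dataset).
#' @examples
#' describe_structure(new_multiset())
#' @export
describe_structure <- function(ms) {
  check_multiset(ms)
  keys <- dataset_names(ms)
  datasets <- tibble::tibble(
    key = keys,
    declared_class = vapply(keys, function(k) ms$recipes[[k]]$declared_class,
                            character(1), USE.NAMES = FALSE),
    n_features = vapply(keys, function(k) nrow(ms$features[[k]]),
                        integer(1), USE.NAMES = FALSE),
    n_samples = vapply(keys, function(k) nrow(ms$samples[[k]]),
                       integer(1), USE.NAMES = FALSE),
    n_layers = vapply(keys, function(k) length(ms$assays[[k]]),
                      integer(1), USE.NAMES = FALSE),
    has_ranges = vapply(keys, function(k) !is.null(ms$ranges[[k]]),
                        logical(1), USE.NAMES = FALSE)
  )
  structure(
    list(collections = MS_COLLECTIONS, accessors = MS_ACCESSORS, datasets = datasets),
    class = "multiset_structure"
  )
}

#' @export
print.multiset_structure <- function(x, ...) {
  cat("multiset structure\n")
  cat("  collections (", length(x$collections), "): ",
      paste(x$collections, collapse = ", "), "\n", sep = "")
  cat("  accessors   (", length(x$accessors), "): ",
      paste(x$accessors, collapse = ", "), "\n", sep = "")
  cat("  datasets    (", nrow(x$datasets), "):\n", sep = "")
  if (nrow(x$datasets) > 0L) print(x$datasets, n = Inf)
  invisible(x)
}

#' @export
print.multiset <- function(x, ...) {
  keys <- dataset_names(x)
  cat("<multiset> ", length(keys), " dataset(s)\n", sep = "")
  for (k in keys) {
    cat(sprintf(
      "  %s [%s]: %d features x %d samples, layers: %s%s\n",
      k, x$recipes[[k]]$declared_class,
      nrow(x$features[[k]]), nrow(x$samples[[k]]),
      paste(names(x$assays[[k]]), collapse = ", "),
      if (is.null(x$ranges[[k]])) "" else ", ranged"
    ))
  }
  invisible(x)
}

#' Plot sample membership across datasets
#'
#' Tile plot of which samples are present in which dataset -- the overlap
#' structure that drives union subsetting and [common_samples()].
#'
#' @param object A `multiset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multiset <- function(object, ...) {
  check_multiset(object)
  membership <- purrr::imap_dfr(
    get_sample_names(object),
    function(ids, key) tibble::tibble(dataset = key, sample = ids)
  )
  if (nrow(membership) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty multiset"))
  }
  membership$dataset <- factor(membership$dataset, levels = dataset_names(object))
  ggplot2::ggplot(membership, ggplot2::aes(x = .data$sample, y = .data$dataset)) +
    ggplot2::geom_tile(fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "sample", y = "dataset",
                  title = "Sample membership across datasets") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang %||% .data
NULL
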