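# Limit-of-detection handling for multiplex protein quantification. Detectors
# work inside a dynamic range; reported values outside a protein's detection
# limits are unreliable and are imputed (below the lower limit) or truncated
# (above the upper limit), with the raw values kept untouched alongside.

validate_lod <- function(lod, feature_ids) {
  if (!is.data.frame(lod)) stop_schema("LOD table must be a data frame")
  if (!all(c("id", "lower_lod") %in% names(lod))) {
    stop_schema("LOD table requires columns 'id' and 'lower_lod'")
  }
  lod <- tibble::as_tibble(lod)
  lod$id <- as.character(lod$id)
  lod$lower_lod <- as.numeric(lod$lower_lod)
  lod$upper_lod <- if ("upper_lod" %in% names(lod)) as.numeric(lod$upper_lod)
                   else NA_real_
  lod <- lod[, c("id", "lower_lod", "upper_lod")]
  if (anyDuplicated(lod$id)) stop_schema("LOD table has duplicate protein ids")
  missing <- setdiff(feature_ids, lod$id)
  if (length(missing) > 0L) {
    stop_schema(sprintf("LOD table missing protein(s): %s",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  lod <- lod[match(feature_ids, lod$id), ]
  both <- !is.na(lod$lower_lod) & !is.na(lod$upper_lod)
  if (any(both & lod$lower_lod >= lod$upper_lod)) {
    stop_schema("lower_lod must be strictly below upper_lod")
  }
  lod
}

#' Impute and truncate values outside the limit of detection
#'
#' Cells below a protein's lower limit of detection are replaced according to
#' the imputation rule; cells above the upper limit (when one is defined) are
#' truncated to it; in-range cells (including `NA`s) pass through unchanged.
#' The raw matrix is never modified -- the adjusted matrix is returned
#' together with a mask recording which cells were altered and in which
#' direction. The transform is idempotent: applying it to its own output
#' changes nothing.
#'
#' @param raw Numeric matrix, proteins x samples, with protein row names.
#' @param lod LOD table: columns `id`, `lower_lod`, optional `upper_lod`,
#'   covering every protein in `raw`.
#' @param rule Imputation rule for sub-LOD cells: `"half-lod"` (lower/2, the
#'   default), `"sqrt2-lod"` (lower/sqrt(2)) or `"missing"` (set to `NA`).
#' @return A list with `adjusted` (numeric matrix) and `mask` (character
#'   matrix with values `"in"`, `"below"`, `"above"`).
#' @examples
#' raw <- matrix(c(5, 1, 99), 3, 1, dimnames = list(c("p1", "p2", "p3"), "s1"))
#' lod <- data.frame(id = c("p1", "p2", "p3"), lower_lod = 4,
#'                   upper_lod = c(NA, NA, 50))
#' apply_lod(raw, lod)
#' @export
apply_lod <- function(raw, lod, rule = "half-lod") {
  if (!is.matrix(raw) || !is.numeric(raw)) stop_validation("`raw` must be a numeric matrix")
  if (is.null(rownames(raw))) stop_validation("`raw` must carry protein row names")
  lod <- validate_lod(lod, rownames(raw))
  impute <- switch(rule,
    "half-lod" = function(lower) lower / 2,
    "sqrt2-lod" = function(lower) lower / sqrt(2),
    "missing" = function(lower) NA_real_,
    stop_config(sprintf(
      "unknown LOD rule '%s'; available: half-lod, sqrt2-lod, missing", rule))
  )
  lower <- matrix(lod$lower_lod, nrow(raw), ncol(raw))
  upper <- matrix(lod$upper_lod, nrow(raw), ncol(raw))
  below <- !is.na(raw) & raw < lower
  above <- !is.na(raw) & !is.na(upper) & raw > upper
  adjusted <- raw
  adjusted[below] <- impute(lower[below])
  adjusted[above] <- upper[above]
  mask <- matrix("in", nrow(raw), ncol(raw), dimnames = dimnames(raw))
  mask[below] <- "below"
  mask[above] <- "above"
  list(adjusted = adjusted, mask = mask)
}

#' Add a proteome dataset with LOD adjustment
#'
#' The worked extension pattern: a new omic type enters the container through
#' its own specific adder, layered over the basic [add_generic()]. The bundle
#' must carry a `raw` assay layer and an LOD table covering every protein.
#' The stored dataset holds three layers -- `raw` (untouched), `adjusted`
#' (after [apply_lod()]) and the categorical `lod_mask` -- plus the LOD table
#' in its reconstruction recipe, so [reconstruct()] recovers all of them and
#' every subsetting verb restricts them coherently.
#'
#' @inheritParams add_generic
#' @param bundle An [ingest_bundle()] with a layer named `"raw"` and a `lod`
#'   table.
#' @param rule Imputation rule passed to [apply_lod()].
#' @return The container with the proteome dataset added under key
#'   `"proteome"` (or `"proteome+name"`).
#' @export
add_proteome <- function(ms, bundle, name = NULL, rule = "half-lod",
                         overwrite = FALSE) {
  if (!is_ingest_bundle(bundle)) stop_validation("expected an `ingest_bundle`")
  if (is.null(bundle$lod)) stop_schema("lod table required for proteome data")
  if (!"raw" %in% names(bundle$assays)) {
    stop_schema("proteome bundle requires an assay layer named 'raw'")
  }
  raw <- bundle$assays[["raw"]]
  lod <- validate_lod(bundle$lod, rownames(raw))
  adj <- apply_lod(raw, lod, rule = rule)
  bundle$assays <- c(
    list(raw = raw, adjusted = adj$adjusted, lod_mask = adj$mask),
    bundle$assays[setdiff(names(bundle$assays), "raw")]
  )
  bundle$lod <- lod
  if (identical(bundle$declared_class, "matrix-set")) {
    bundle$declared_class <- "proteome-set"
  }
  add_generic(ms, bundle, tag = "proteome", name = name, overwrite = overwrite)
}

#' Summarise LOD mask counts per protein
#'
#' @param ms A `multiset`.
#' @param key Proteome dataset key (default `"proteome"`).
#' @return Tibble with per-protein counts of in-range, below-LOD and
#'   above-LOD cells.
#' @export
lod_summary <- function(ms, key = "proteome") {
  check_multiset(ms)
  check_key(ms, key)
  mask <- get_assays(ms, key)[["lod_mask"]]
  if (is.null(mask)) stop_schema(sprintf("dataset '%s' has no 'lod_mask' layer", key))
  tibble::tibble(
    id = rownames(mask),
    n_in = unname(rowSums(mask == "in")),
    n_below = unname(rowSums(mask == "below")),
    n_above = unname(rowSums(mask == "above"))
  )
}
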