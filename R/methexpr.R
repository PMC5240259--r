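#' Correlate CpG methylation with nearby gene expression
#'
#' Pairs every CpG with every expression feature whose genomic range, expanded
#' by `flank` base pairs on each side, covers the CpG position, then tests
#' the association of expression with methylation across the samples common
#' to both datasets. The procedure has four steps:
#'
#' 1. *Checking*: both datasets must be present and carry genomic ranges, the
#'    covariate columns must exist in both sample annotations, and at least
#'    `min_samples` samples must be shared. Dataset-internal consistency was
#'    already enforced at ingestion, so only the global structure is checked
#'    here.
#' 2. *Preparation*: the two datasets are restricted to their common samples
#'    via [common_samples()] and the primary assay layers are extracted as
#'    column-aligned matrices.
#' 3. *Association*: for each CpG-gene pair, methylation and expression are
#'    residualised on the covariates (intercept always included), and the
#'    Pearson correlation r and the slope of expression on methylation are
#'    computed from the residuals. The two-sided p-value comes from the t
#'    distribution with n - 2 - k degrees of freedom (k = number of fitted
#'    covariate coefficients beyond the intercept). With no covariates this
#'    reduces exactly to the plain Pearson correlation test.
#' 4. *Formatting*: p-values are Benjamini-Hochberg adjusted across all pairs
#'    and the result is sorted by adjusted p-value, then by decreasing |r|.
#'
#' Pairs with zero variance in either residualised variable are reported with
#' missing statistics rather than dropped. Covariate values are taken from
#' the methylation dataset's sample annotation (sample annotation is stored
#' per dataset; the columns must exist in both, and the methylation copy is
#' the one used).
#'
#' @param ms A `multiset`.
#' @param meth_key Key of the methylation dataset (default `"methylation"`).
#' @param expr_key Key of the expression dataset (default `"expression"`).
#' @param flank Flanking window in bp around each expression feature
#'   (default 250000).
#' @param covariates Character vector of sample-annotation columns to adjust
#'   for (default none).
#' @param min_samples Minimum number of common samples required (default 5).
#' @return A `meth_expr_result` tibble with columns `cpg_id`, `expr_id`,
#'   `distance` (bp from the CpG position to the unexpanded expression range,
#'   0 if inside), `estimate` (slope of expression on methylation),
#'   `correlation` (Pearson r of the residuals), `p_value` and `adj_p_value`.
#' @export
meth_expr_correlation <- function(ms, meth_key = "methylation",
                                  expr_key = "expression",
                                  flank = 250000, covariates = character(),
                                  min_samples = 5) {
  check_multiset(ms)
  check_key(ms, meth_key)
  check_key(ms, expr_key)
  if (!is.numeric(flank) || length(flank) != 1L || is.na(flank) || flank < 0) {
    stop_validation("`flank` must be a single non-negative number")
  }

  # step 1: global structure checks
  for (key in c(meth_key, expr_key)) {
    if (is.null(ms$ranges[[key]])) {
      stop_validation(sprintf(
        "dataset '%s' has no genomic ranges; pairing requires coordinates", key))
    }
    absent <- setdiff(covariates, names(ms$samples[[key]]))
    if (length(absent) > 0L) {
      stop_schema(sprintf(
        "dataset '%s' sample annotation lacks covariate column(s): %s",
        key, paste(absent, collapse = ", ")))
    }
  }

  # step 2: common samples and aligned matrices
  cs <- common_samples(select_datasets(ms, unique(c(meth_key, expr_key))))
  n <- length(get_sample_names(cs, meth_key))
  if (n < min_samples) {
    stop_insufficient_data(sprintf(
      "only %d common sample(s) between '%s' and '%s'; need at least %d",
      n, meth_key, expr_key, min_samples))
  }
  M <- get_assays(cs, meth_key)[[1]]
  E <- get_assays(cs, expr_key)[[1]]
  meth_rng <- get_ranges(cs, meth_key)
  expr_rng <- get_ranges(cs, expr_key)

  # step 3: pairing and residual association
  pos <- meth_rng$start
  cpg_gr <- GenomicRanges::GRanges(meth_rng$chromosome,
                                   IRanges::IRanges(pos, pos))
  flanked <- GenomicRanges::GRanges(
    expr_rng$chromosome,
    IRanges::IRanges(pmax(1L, expr_rng$start - as.integer(flank)),
                     expr_rng$end + as.integer(flank))
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cpg_gr, flanked, ignore.strand = TRUE))
  ci <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)

  X <- if (length(covariates) == 0L) {
    matrix(1, n, 1)
  } else {
    cov_tbl <- get_sample_annotation(cs, meth_key)[, covariates, drop = FALSE]
    stats::model.matrix(~ ., data = as.data.frame(cov_tbl))
  }
  k <- ncol(X) - 1L
  df <- n - 2L - k
  if (df < 1L) {
    stop_insufficient_data(sprintf(
      "%d common samples leave %d degrees of freedom after %d covariate coefficient(s)",
      n, df, k))
  }

  # residual sum-of-squares is "zero" when it is numerically indistinguishable
  # from the rounding noise of residualising a constant vector
  rss_zero <- function(ss, v) {
    ss <= length(v) * (1e-10 * (1 + max(abs(v), 0)))^2
  }

  pair_stats <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < max(min_samples, k + 3L)) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    qrX <- qr(X[ok, , drop = FALSE])
    rx <- qr.resid(qrX, x[ok])
    ry <- qr.resid(qrX, y[ok])
    sxx <- sum(rx^2); syy <- sum(ry^2)
    if (rss_zero(sxx, x[ok]) || rss_zero(syy, y[ok])) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    sxy <- sum(rx * ry)
    r <- max(-1, min(1, sxy / sqrt(sxx * syy)))
    slope <- sxy / sxx
    dfree <- sum(ok) - 2L - k
    tval <- r * sqrt(dfree) / sqrt(max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), dfree)
    c(slope, r, p)
  }

  np <- length(ci)
  est <- cor_r <- pval <- rep(NA_real_, np)
  if (np > 0L) {
    # fast path: residualise whole matrices once when there are no NAs
    if (!anyNA(M) && !anyNA(E)) {
      qrX <- qr(X)
      RM <- t(qr.resid(qrX, t(M)))
      RE <- t(qr.resid(qrX, t(E)))
      for (i in seq_len(np)) {
        rx <- RM[ci[i], ]; ry <- RE[ei[i], ]
        sxx <- sum(rx^2); syy <- sum(ry^2)
        if (rss_zero(sxx, M[ci[i], ]) || rss_zero(syy, E[ei[i], ])) next
        sxy <- sum(rx * ry)
        r <- max(-1, min(1, sxy / sqrt(sxx * syy)))
        est[i] <- sxy / sxx
        cor_r[i] <- r
        tval <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
        pval[i] <- 2 * stats::pt(-abs(tval), df)
      }
    } else {
      for (i in seq_len(np)) {
        s <- pair_stats(M[ci[i], ], E[ei[i], ])
        est[i] <- s[1]; cor_r[i] <- s[2]; pval[i] <- s[3]
      }
    }
  }

  dist <- integer(np)
  if (np > 0L) {
    p0 <- pos[ci]
    s0 <- expr_rng$start[ei]
    e0 <- expr_rng$end[ei]
    dist <- ifelse(p0 >= s0 & p0 <= e0, 0L,
                   pmin(abs(p0 - s0), abs(p0 - e0)))
  }

  # step 4: adjust and sort
  out <- tibble::tibble(
    cpg_id = meth_rng$id[ci],
    expr_id = expr_rng$id[ei],
    distance = as.integer(dist),
    estimate = est,
    correlation = cor_r,
    p_value = pval,
    adj_p_value = stats::p.adjust(pval, method = "BH")
  )
  out <- out[order(out$adj_p_value, -abs(out$correlation), out$cpg_id, out$expr_id), ]
  out <- structure(out, class = c("meth_expr_result", class(tibble::tibble())))
  attr(out, "n_samples") <- n
  attr(out, "flank") <- flank
  attr(out, "covariates") <- covariates
  attr(out, "meth_key") <- meth_key
  attr(out, "expr_key") <- expr_key
  out
}

#' @export
tidy.meth_expr_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "n_samples") <- NULL
  attr(out, "flank") <- NULL
  attr(out, "covariates") <- NULL
  attr(out, "meth_key") <- NULL
  attr(out, "expr_key") <- NULL
  out
}

#' @export
glance.meth_expr_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_samples = attr(x, "n_samples"),
    n_significant = sum(x$adj_p_value < 0.05, na.rm = TRUE),
    flank = attr(x, "flank"),
    n_covariates = length(attr(x, "covariates"))
  )
}

#' Volcano-style plot of CpG-expression associations
#'
#' @param object A `meth_expr_result`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_expr_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$correlation) & !is.na(df$adj_p_value), ]
  df$significant <- df$adj_p_value < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$correlation,
                                   y = -log10(pmax(.data$adj_p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residual Pearson r", y = "-log10 adjusted p",
                  colour = sprintf("adj p < %g", alpha),
                  title = "CpG-expression associations") +
    ggplot2::theme_minimal()
}
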