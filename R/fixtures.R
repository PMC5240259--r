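# Deterministic synthetic fixtures. One seeded spec drives one generator; the
# same spec always yields a byte-identical serialization. The default spec
# realises the study conditions the package is exercised under: three tables
# on sample sets {A,B}, {A,B,C}, {A,C}; a methylation + expression pair with
# planted correlated CpG-gene pairs on shared coordinates; a SNP set with
# call and probability layers; a proteome with known fractions of cells
# outside the detection limits; and an unranged metabolome.

#' Specify a synthetic multi-omic fixture
#'
#' Each component is a sub-spec (or `NULL` to omit it):
#'
#' * `tables` -- three generic tables with the overlapping sample sets
#'   \{A,B\}, \{A,B,C\}, \{A,C\} used throughout the subsetting examples.
#' * `methexpr` -- a methylation + expression dataset pair on `n_samples`
#'   shared samples. Genes are laid out every `gene_spacing` bp;
#'   `n_planted` genes carry a CpG in their body whose methylation drives
#'   expression with slope `slope` plus Gaussian noise `noise_sd`;
#'   `n_null` further genes carry an independent (null) CpG; `n_distal`
#'   CpGs sit far beyond any flanking window.
#' * `snp` -- a genotype dataset with `call` and `probability` layers.
#' * `proteome` -- `n_proteins` x `n_samples` raw intensities with expected
#'   fractions `frac_below`/`frac_above` of cells outside the per-protein
#'   detection limits.
#' * `metabolome` -- an unranged dataset (no genomic coordinates), the case
#'   that genomic-range subsetting must discard.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param tables,methexpr,snp,proteome,metabolome Component sub-specs
#'   (lists); `NULL` omits the component. Supplied values are merged over
#'   the defaults shown above.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         tables = list(),
                         methexpr = list(),
                         snp = list(),
                         proteome = list(),
                         metabolome = list()) {
  merge_spec <- function(defaults, given, what) {
    if (is.null(given)) return(NULL)
    if (!is.list(given)) stop_spec(sprintf("`%s` must be a list or NULL", what))
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0L) {
      stop_spec(sprintf("unknown %s field(s): %s", what, paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, given)
  }
  spec <- list(
    seed = as.integer(seed),
    tables = merge_spec(list(
      samples = list(t1 = c("A", "B"), t2 = c("A", "B", "C"), t3 = c("A", "C")),
      n_features = c(t1 = 6L, t2 = 5L, t3 = 4L)
    ), tables, "tables"),
    methexpr = merge_spec(list(
      n_samples = 50L, n_genes = 130L, n_planted = 5L, n_null = 100L,
      n_distal = 3L, slope = 2, noise_sd = 0.1,
      chromosome = "chr1", gene_spacing = 1e6, gene_width = 2000L
    ), methexpr, "methexpr"),
    snp = merge_spec(list(n_snps = 100L, n_samples = 20L,
                          chromosome = "chr2"), snp, "snp"),
    proteome = merge_spec(list(n_proteins = 40L, n_samples = 25L,
                               frac_below = 0.10, frac_above = 0.05),
                          proteome, "proteome"),
    metabolome = merge_spec(list(n_features = 12L, n_samples = 8L),
                            metabolome, "metabolome")
  )
  me <- spec$methexpr
  if (!is.null(me)) {
    if (me$n_planted + me$n_null > me$n_genes) {
      stop_spec("methexpr: n_planted + n_null must not exceed n_genes")
    }
    if (me$gene_spacing <= me$gene_width) {
      stop_spec("methexpr: gene_spacing must exceed gene_width")
    }
    last_end <- me$n_genes * me$gene_spacing + me$gene_width
    if (last_end >= .Machine$integer.max) {
      stop_spec("methexpr: n_genes * gene_spacing exceeds the 32-bit coordinate range")
    }
  }
  structure(spec, class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
fixture_spec_tables <- function(seed = 1L) {
  fixture_spec(seed, methexpr = NULL, snp = NULL, proteome = NULL, metabolome = NULL)
}

#' @rdname fixture_spec
#' @details `fixture_spec_scale()` is a reduced-scale stress configuration:
#'   a 45,000-feature methylation set, an 80,000-feature SNP set and a
#'   7,000-feature expression set on 20 samples.
#' @export
fixture_spec_scale <- function(seed = 1L) {
  fixture_spec(
    seed,
    tables = NULL, proteome = NULL, metabolome = NULL,
    methexpr = list(n_samples = 20L, n_genes = 7000L, n_planted = 5L,
                    n_null = 0L, n_distal = 45000L - 5L,
                    gene_spacing = 25000, gene_width = 2000L),
    snp = list(n_snps = 80000L, n_samples = 20L)
  )
}

sample_annotation_for <- function(ids) {
  n <- length(ids)
  tibble::tibble(
    id = ids,
    age = sample(20:70, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
}

#' Generate the synthetic fixture described by a spec
#'
#' Deterministic: the same spec (including its seed) always produces a
#' container whose serialization is byte-identical. The planted CpG-gene
#' pairs, if any, are attached as the `"planted"` attribute (a tibble with
#' `cpg_id`, `expr_id`, `slope`, `type` in \{"planted", "null"\}).
#'
#' @param spec A [fixture_spec()].
#' @return A `multiset`.
#' @examples
#' ms <- generate_fixture(fixture_spec_tables(seed = 7))
#' get_sample_names(ms)
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) stop_spec("expected a `fixture_spec`")
  withr::with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  ms <- new_multiset()
  planted <- NULL

  if (!is.null(spec$tables)) {
    tb <- spec$tables
    if (!setequal(names(tb$samples), names(tb$n_features))) {
      stop_spec("tables: `samples` and `n_features` must name the same tables")
    }
    gene_pool <- c("TP53", "BRCA2", "EGFR", "MYC", "KRAS", "PTEN")
    for (tab in names(tb$samples)) {
      ids <- tb$samples[[tab]]
      nf <- tb$n_features[[tab]]
      m <- matrix(round(stats::rnorm(nf * length(ids), 10, 2), 4), nf, length(ids),
                  dimnames = list(sprintf("%s_f%02d", tab, seq_len(nf)), ids))
      feats <- tibble::tibble(id = rownames(m),
                              gene = sample(gene_pool, nf, replace = TRUE))
      ms <- add_generic(ms, ingest_bundle(m, samples = sample_annotation_for(ids),
                                          features = feats), tag = tab)
    }
  }

  if (!is.null(spec$methexpr)) {
    me <- spec$methexpr
    sample_ids <- sprintf("S%03d", seq_len(me$n_samples))
    pheno <- sample_annotation_for(sample_ids)

    gene_ids <- sprintf("gene%05d", seq_len(me$n_genes))
    gene_start <- as.integer(seq_len(me$n_genes) * me$gene_spacing)
    gene_end <- as.integer(gene_start + me$gene_width)
    expr_feats <- tibble::tibble(
      id = gene_ids, chromosome = me$chromosome,
      start = gene_start, end = gene_end,
      symbol = toupper(substr(gene_ids, 1, 8))
    )

    n_cpg <- me$n_planted + me$n_null + me$n_distal
    cpg_ids <- sprintf("cpg%05d", seq_len(n_cpg))
    paired_gene <- seq_len(me$n_planted + me$n_null)  # gene index per paired CpG
    cpg_pos <- integer(n_cpg)
    if (length(paired_gene) > 0L) {
      # one CpG inside each paired gene's body
      cpg_pos[seq_along(paired_gene)] <- as.integer(
        gene_start[paired_gene] +
          sample.int(me$gene_width - 1L, length(paired_gene), replace = TRUE))
    }
    if (me$n_distal > 0L) {
      # far beyond every gene plus any plausible flank
      base <- max(gene_end) + 1e7
      cpg_pos[(length(paired_gene) + 1L):n_cpg] <- as.integer(
        base + seq_len(me$n_distal) * 1000L)
    }
    meth_feats <- tibble::tibble(id = cpg_ids, chromosome = me$chromosome,
                                 position = cpg_pos)

    beta <- matrix(stats::runif(n_cpg * me$n_samples, 0.2, 0.8), n_cpg, me$n_samples,
                   dimnames = list(cpg_ids, sample_ids))
    expr <- matrix(stats::rnorm(me$n_genes * me$n_samples, 7, 1), me$n_genes, me$n_samples,
                   dimnames = list(gene_ids, sample_ids))
    if (me$n_planted > 0L) {
      for (i in seq_len(me$n_planted)) {
        expr[i, ] <- me$slope * beta[i, ] +
          stats::rnorm(me$n_samples, 0, me$noise_sd)
      }
    }
    planted <- tibble::tibble(
      cpg_id = cpg_ids[seq_along(paired_gene)],
      expr_id = gene_ids[paired_gene],
      slope = c(rep(me$slope, me$n_planted), rep(0, me$n_null)),
      type = c(rep("planted", me$n_planted), rep("null", me$n_null))
    )

    ms <- add_expression(ms, ingest_bundle(expr, samples = pheno,
                                           features = expr_feats))
    ms <- add_methylation(ms, ingest_bundle(beta, samples = pheno,
                                            features = meth_feats))
  }

  if (!is.null(spec$snp)) {
    sn <- spec$snp
    ids <- sprintf("S%03d", seq_len(sn$n_samples))
    snp_ids <- sprintf("rs%06d", seq_len(sn$n_snps))
    calls <- matrix(sample(0:2, sn$n_snps * sn$n_samples, replace = TRUE,
                           prob = c(0.49, 0.42, 0.09)),
                    sn$n_snps, sn$n_samples, dimnames = list(snp_ids, ids))
    prob <- matrix(round(stats::runif(sn$n_snps * sn$n_samples, 0.9, 1), 4),
                   sn$n_snps, sn$n_samples, dimnames = list(snp_ids, ids))
    feats <- tibble::tibble(id = snp_ids, chromosome = sn$chromosome,
                            position = sort(sample.int(2e8, sn$n_snps)))
    ms <- add_snp(ms, ingest_bundle(list(call = calls, probability = prob),
                                    samples = sample_annotation_for(ids),
                                    features = feats))
  }

  if (!is.null(spec$proteome)) {
    pr <- spec$proteome
    ids <- sprintf("S%03d", seq_len(pr$n_samples))
    prot_ids <- sprintf("prot%03d", seq_len(pr$n_proteins))
    lower <- round(stats::runif(pr$n_proteins, 2, 6), 3)
    lod <- tibble::tibble(id = prot_ids, lower_lod = lower,
                          upper_lod = round(lower * 10, 3))
    nc <- pr$n_proteins * pr$n_samples
    u <- stats::runif(nc)
    lower_m <- matrix(lod$lower_lod, pr$n_proteins, pr$n_samples)
    upper_m <- matrix(lod$upper_lod, pr$n_proteins, pr$n_samples)
    raw <- matrix(0, pr$n_proteins, pr$n_samples, dimnames = list(prot_ids, ids))
    below <- u < pr$frac_below
    above <- !below & u < pr$frac_below + pr$frac_above
    inside <- !below & !above
    raw[below] <- lower_m[below] * stats::runif(sum(below), 0.1, 0.9)
    raw[above] <- upper_m[above] * stats::runif(sum(above), 1.1, 2)
    raw[inside] <- lower_m[inside] +
      (upper_m[inside] - lower_m[inside]) * stats::runif(sum(inside), 0.05, 0.95)
    raw <- round(raw, 4)
    ms <- add_proteome(ms, ingest_bundle(list(raw = raw),
                                         samples = sample_annotation_for(ids),
                                         lod = lod))
  }

  if (!is.null(spec$metabolome)) {
    mb <- spec$metabolome
    ids <- sprintf("S%03d", seq_len(mb$n_samples))
    met_ids <- sprintf("met%03d", seq_len(mb$n_features))
    m <- matrix(round(stats::rlnorm(mb$n_features * mb$n_samples, 2, 0.5), 4),
                mb$n_features, mb$n_samples, dimnames = list(met_ids, ids))
    feats <- tibble::tibble(id = met_ids,
                            mz = round(stats::runif(mb$n_features, 80, 900), 4))
    ms <- add_generic(ms, ingest_bundle(m, samples = sample_annotation_for(ids),
                                        features = feats,
                                        declared_class = "metabolome-set"),
                      tag = "metabolome")
  }

  attr(ms, "planted") <- planted
  ms
}
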