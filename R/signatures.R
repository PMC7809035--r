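#' Gene set container
#'
#' @param name set name.
#' @param genes character vector of member genes (unique, nonempty).
#' @param provenance one of `"signature"`, `"pathway"`, `"tf_targets"`,
#'   `"ad_gwas"`.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes,
                     provenance = c("signature", "pathway", "tf_targets", "ad_gwas")) {
  provenance <- match.arg(provenance)
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("a gene set cannot be empty", call. = FALSE)
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s], %d genes\n", x$name, x$provenance,
              length(x$genes)))
  invisible(x)
}

#' Derive a cell-type-enriched gene set by fold change
#'
#' A gene enters the set iff its mean expression in the target profile is at
#' least `fold` times the mean in EVERY comparator profile (inclusive at
#' exactly fold x comparator) and strictly exceeds `min_expr`. With a single
#' comparator (bulk tissue) this is the rule defining an aged-microglia
#' signature; with several comparators (other cell types) it gives
#' cell-type-specific sets.
#'
#' @param target named numeric vector of mean FPKM in the target cell type.
#' @param comparators list of named numeric vectors (mean FPKM) sharing the
#'   target's gene universe.
#' @param fold fold-change threshold (default 4).
#' @param min_expr minimum target mean (strict; default 1).
#' @param name set name.
#' @return A [gene_set()] with provenance `"signature"`.
#' @export
derive_enriched_set <- function(target, comparators, fold = 4, min_expr = 1,
                                name = "enriched") {
  if (is.numeric(comparators)) comparators <- list(comparators)
  if (length(comparators) == 0L) stop("need at least one comparator profile", call. = FALSE)
  genes <- names(target)
  if (is.null(genes)) stop("profiles must be named by gene", call. = FALSE)
  ok <- target > min_expr
  for (cmp in comparators) {
    cmp <- cmp[genes]
    if (anyNA(cmp)) stop("comparator profile misses genes of the target universe", call. = FALSE)
    ok <- ok & (target >= fold * cmp)
  }
  if (!any(ok)) stop("no gene satisfies the enrichment rule", call. = FALSE)
  gene_set(name, genes[ok], "signature")
}

#' Hypergeometric enrichment of a module for a gene set
#'
#' Upper-tail hypergeometric test of the overlap between a module and a
#' gene set, both intersected with the background universe first. `p =
#' P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param module_genes character vector of module member genes.
#' @param set a [gene_set()] or character vector.
#' @param background character vector: the gene universe (e.g. all genes
#'   with mean FPKM > 1).
#' @return One-row tibble: `k`, `n`, `K`, `N`, `p`, `overlap_fraction`.
#' @export
hypergeom_enrichment <- function(module_genes, set, background) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  mod <- intersect(module_genes, background)
  hit <- intersect(genes, background)
  n <- length(mod)
  if (n == 0L) stop("module has no genes in the background", call. = FALSE)
  K <- length(hit)
  N <- length(background)
  k <- length(intersect(mod, hit))
  p <- exp(phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
  tibble(k = k, n = n, K = K, N = N, p = p, overlap_fraction = k / n)
}

#' Enrichment of every analysis module for a gene set
#'
#' @param a a [module_assignment()].
#' @param set a [gene_set()].
#' @param background gene universe.
#' @param alpha family-wise level for the Bonferroni threshold column.
#' @return Tibble, one row per analysis module, with the enrichment counts,
#'   p-value and a `significant` flag at the Bonferroni threshold
#'   `alpha / n_modules`.
#' @export
enrich_modules <- function(a, set, background, alpha = 0.05) {
  cat_ <- module_catalog(a)
  res <- purrr::map_dfr(cat_$module, function(k) {
    dplyr::bind_cols(tibble(module = k),
                     hypergeom_enrichment(module_genes(a, k), set, background))
  })
  thr <- alpha / nrow(cat_)
  res |>
    dplyr::mutate(bonferroni_threshold = thr, significant = .data$p < thr) |>
    dplyr::arrange(.data$p)
}

#' Ternary cell-type coordinates
#'
#' Projects each gene onto the simplex spanned by three cell-type mean
#' profiles: each coordinate is the gene's mean in that cell type divided by
#' the sum over the three. Genes with all-zero means are excluded with a
#' warning.
#'
#' @param profiles named list of three named numeric vectors (mean FPKM per
#'   gene) over a common gene universe.
#' @param genes genes to project; default the common universe.
#' @return Tibble: `gene` plus one coordinate column per cell type
#'   (nonnegative, rows sum to 1).
#' @export
ternary_coordinates <- function(profiles, genes = NULL) {
  if (length(profiles) != 3L || is.null(names(profiles))) {
    stop("`profiles` must be a named list of three mean profiles", call. = FALSE)
  }
  universe <- Reduce(intersect, lapply(profiles, names))
  if (is.null(genes)) genes <- universe
  genes <- intersect(genes, universe)
  mat <- sapply(profiles, function(p) p[genes])
  if (any(mat < 0)) stop("profile means must be nonnegative", call. = FALSE)
  tot <- rowSums(mat)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d gene(s) with all-zero means", sum(tot == 0)))
    mat <- mat[tot > 0, , drop = FALSE]
    genes <- genes[tot > 0]
    tot <- tot[tot > 0]
  }
  dplyr::bind_cols(tibble(gene = genes), as_tibble(mat / tot))
}

#' Flag genes proximal to nominally significant GWAS probes
#'
#' A gene is flagged iff at least one probe with `p < alpha` lies within
#' `window` bp up- or downstream of the gene (inclusive at exactly `window`
#' bp from either edge), on the same chromosome. Intervals are 1-based
#' inclusive.
#'
#' @param gene_intervals tibble with columns `gene`, `chrom`, `start`, `end`.
#' @param probes tibble with columns `chrom`, `pos`, `p`.
#' @param window flanking window in bp (default 50000).
#' @param alpha nominal significance threshold (strict; default 0.05).
#' @return A [gene_set()] with provenance `"ad_gwas"` of the flagged genes.
#' @export
gwas_gene_flags <- function(gene_intervals, probes, window = 50000, alpha = 0.05) {
  gene_intervals <- as_tibble(gene_intervals)
  probes <- as_tibble(probes)
  if (nrow(gene_intervals) == 0L) stop("empty gene interval table", call. = FALSE)
  gc_ <- unique(gene_intervals$chrom)
  pc_ <- unique(probes$chrom)
  if (length(intersect(gc_, pc_)) == 0L) {
    stop(sprintf("no common chromosome names; intervals use {%s}, probes use {%s}",
                 paste(gc_, collapse = ","), paste(pc_, collapse = ",")),
         call. = FALSE)
  }
  sig <- probes[probes$p < alpha, , drop = FALSE]
  gr_genes <- GenomicRanges::GRanges(
    seqnames = gene_intervals$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, gene_intervals$start - window),
                              end = gene_intervals$end + window))
  gr_probes <- GenomicRanges::GRanges(
    seqnames = sig$chrom,
    ranges = IRanges::IRanges(start = sig$pos, width = 1L))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_genes, gr_probes))
  hit <- seq_len(nrow(gene_intervals)) %in% S4Vectors::queryHits(ov)
  if (!any(hit)) stop("no gene is flagged at these settings", call. = FALSE)
  gene_set("gwas_proximal", gene_intervals$gene[hit], "ad_gwas")
}
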