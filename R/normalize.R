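#' Median-of-ratios size factors
#'
#' Per-sample scale factors estimated by the median-of-ratios method: for
#' every gene with all-positive counts, each sample's count is divided by the
#' gene's geometric mean across samples; a sample's factor is the median of
#' those ratios. When no gene is positive in every sample the estimator falls
#' back to total-count ratios (relative to their geometric mean), with a
#' warning.
#'
#' @param counts validated count matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- validate_count_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene with all-positive counts; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total count")
    sf <- tot / exp(mean(log(tot)))
    return(sf)
  }
  k <- counts[pos, , drop = FALSE]
  log_geo <- rowMeans(log(k))
  sf <- apply(exp(log(k) - log_geo), 2, stats::median)
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Shifted-log variance-stabilizing transform
#'
#' A documented stand-in for a model-based variance-stabilizing
#' transformation of counts: `log2(count / size_factor + pseudocount)`.
#' Monotone in the counts within each sample; zero counts map to
#' `log2(pseudocount)` (0 at the default pseudocount of 1).
#'
#' @param counts count matrix, genes x samples.
#' @param factors per-sample size factors (default [size_factors()]).
#' @param pseudocount shift keeping zeros finite (default 1).
#' @return Numeric matrix of the same shape, log2-like scale.
#' @export
vst_transform <- function(counts, factors = size_factors(counts),
                          pseudocount = 1) {
  counts <- validate_count_matrix(counts)
  if (length(factors) != ncol(counts)) {
    stop("one size factor per sample required")
  }
  if (any(factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, factors, "/") + pseudocount)
}

# vectorized paired t-test on a genes x patients matrix of differences;
# a zero-variance row gets p = 1 when the mean difference is 0 and p = 0
# otherwise (the paired design is then perfectly consistent)
paired_t_rows <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  p <- rep(NA_real_, nrow(d))
  zero <- s < 1e-12
  p[zero] <- ifelse(abs(m[zero]) < 1e-12, 1, 0)
  tt <- m[!zero] / (s[!zero] / sqrt(n))
  p[!zero] <- 2 * stats::pt(-abs(tt), df = n - 1)
  list(mean_diff = m, p = p)
}

paired_wilcoxon_rows <- function(d) {
  p <- apply(d, 1, function(x) {
    if (all(abs(x) < 1e-12)) return(1)
    suppressWarnings(stats::wilcox.test(x)$p.value)
  })
  list(mean_diff = rowMeans(d), p = p)
}

#' Differential-expression gene filter over matched triplets
#'
#' Defines the gene universe for the pattern analysis. For each of the three
#' contrasts (pre vs normal, post vs normal, post vs pre) a paired test
#' across patients is run on the VST differences (paired t-test by default;
#' the patient pairing absorbs the patient effect that a model covariate
#' would). P-values are Benjamini-Hochberg adjusted per contrast, and the
#' fold change is derived from the mean VST difference (`2^|mean diff|`).
#' A gene is retained if, in **any** contrast, its absolute fold change is
#' strictly above `fc_threshold` and its adjusted p-value is at most `alpha`,
#' and additionally its largest raw count across all samples is at least
#' `min_count`.
#'
#' @param vst VST matrix from [vst_transform()].
#' @param counts the raw count matrix (for the minimum-count gate).
#' @param triplets triplet table from [build_triplets()].
#' @param fc_threshold fold-change threshold, strict (default 2).
#' @param alpha adjusted-p threshold, inclusive (default 0.05).
#' @param min_count minimal raw count required in at least one sample
#'   (default 100).
#' @param test paired test: `"t"` (default) or `"wilcoxon"` (signed-rank).
#' @return List with `retained` (character vector of gene ids) and `results`
#'   (data frame: `gene`, `contrast`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`, `max_count`).
#' @export
de_filter <- function(vst, counts, triplets, fc_threshold = 2, alpha = 0.05,
                      min_count = 100, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (nrow(triplets) < 2) {
    stop("at least 2 complete triplets are required for the paired test")
  }
  genes <- rownames(vst)
  max_count <- apply(counts[genes, , drop = FALSE], 1, max)
  contrasts <- list(
    pre_vs_normal  = vst[, triplets$pre, drop = FALSE] -
      vst[, triplets$normal, drop = FALSE],
    post_vs_normal = vst[, triplets$post, drop = FALSE] -
      vst[, triplets$normal, drop = FALSE],
    post_vs_pre    = vst[, triplets$post, drop = FALSE] -
      vst[, triplets$pre, drop = FALSE]
  )
  res <- lapply(names(contrasts), function(cn) {
    d <- contrasts[[cn]]
    tt <- if (test == "t") paired_t_rows(d) else paired_wilcoxon_rows(d)
    data.frame(gene = genes, contrast = cn,
               log2_fold_change = tt$mean_diff,
               p_value = tt$p,
               adjusted_p = stats::p.adjust(tt$p, method = "BH"),
               max_count = max_count,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  hit <- 2^abs(res$log2_fold_change) > fc_threshold &
    res$adjusted_p <= alpha & res$max_count >= min_count
  retained <- genes[genes %in% unique(res$gene[hit])]
  list(retained = retained, results = res)
}
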