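#' Hypergeometric over-representation analysis of a gene list
#'
#' Upper-tail hypergeometric test of each pathway's overlap with a hit list
#' (e.g. the response-associated genes of one pattern cluster) against a gene
#' universe (the DE genes by default). Gene-set members absent from the
#' universe are intersected out before testing. Q-values are
#' Benjamini-Hochberg across the pathways of the run.
#'
#' @param hits character vector of hit genes; must be a subset of `universe`.
#' @param universe character vector, the background gene universe.
#' @param collection named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param cluster label recorded in the output (e.g. `"P1_P3_P7"`).
#' @param alpha q-value threshold for the `significant` flag (default 0.05).
#' @return Data frame: `pathway`, `cluster`, `overlap`, `pathway_size`
#'   (after universe intersection), `universe_size`, `n_hits`, `p_value`,
#'   `q_value`, `significant`.
#' @export
hypergeom_enrich <- function(hits, universe, collection, cluster = NA_character_,
                             alpha = 0.05) {
  if (anyDuplicated(universe)) universe <- unique(universe)
  if (!all(hits %in% universe)) {
    stop("hit genes outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  }
  n_u <- length(universe)
  n_h <- length(unique(hits))
  rows <- lapply(names(collection), function(pw) {
    members <- intersect(collection[[pw]], universe)
    m <- length(members)
    x <- length(intersect(members, hits))
    p <- if (m == 0) 1 else
      stats::phyper(x - 1, n_h, n_u - n_h, m, lower.tail = FALSE)
    data.frame(pathway = pw, cluster = cluster, overlap = x,
               pathway_size = m, universe_size = n_u, n_hits = n_h,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < alpha
  rownames(res) <- NULL
  res
}

#' Robust pathway list from two enrichment runs
#'
#' Intersects the significant pathways of a full-cohort enrichment run with
#' those of a subtype-restricted run, then adds the `k_top` most significant
#' pathways (by q-value, ties by p-value) unique to each run, collapsing
#' duplicates. This trades subtype bias against patient diversity.
#'
#' @param enrich_full,enrich_subset enrichment tables from
#'   [hypergeom_enrich()] (possibly row-bound over clusters).
#' @param k_top number of top unique pathways added per run (default 5).
#' @param alpha q-value significance threshold (default 0.05).
#' @return Data frame: `pathway`, `origin` (`shared`, `unique_full`,
#'   `unique_subset`).
#' @export
robust_pathway_list <- function(enrich_full, enrich_subset, k_top = 5,
                                alpha = 0.05) {
  sig <- function(e) {
    e <- e[e$q_value < alpha, , drop = FALSE]
    # a pathway significant in any cluster counts once, at its best q
    e <- e[order(e$q_value, e$p_value), , drop = FALSE]
    e[!duplicated(e$pathway), , drop = FALSE]
  }
  full <- sig(enrich_full); subs <- sig(enrich_subset)
  shared <- intersect(full$pathway, subs$pathway)
  top_unique <- function(e, other) {
    u <- e[!(e$pathway %in% other), , drop = FALSE]
    utils::head(u$pathway, k_top)   # already ordered by q, then p
  }
  seg <- function(pw, origin) data.frame(
    pathway = pw, origin = rep(origin, length(pw)), stringsAsFactors = FALSE)
  out <- rbind(
    seg(shared, "shared"),
    seg(top_unique(full, subs$pathway), "unique_full"),
    seg(top_unique(subs, full$pathway), "unique_subset")
  )
  out[!duplicated(out$pathway), , drop = FALSE]
}

#' Bootstrap p-value for an observed resistance score
#'
#' Draws `n_boot` random gene sets of the pathway's (considered) size from
#' the patient's considered-gene universe and computes the fraction of random
#' scores greater than or equal to the observed score. No pseudocount is
#' added, so `p = 0` is possible at resolution `1/n_boot`. A random set's
#' score depends on the draw only through its count of resistance-pattern
#' genes, so the count is drawn directly from the corresponding
#' hypergeometric (without replacement, default) or binomial (with
#' replacement) distribution — distributionally identical to resampling gene
#' sets, and much faster.
#'
#' @param observed_score observed fraction of resistance-pattern genes.
#' @param size number of genes drawn per random set (the pathway's
#'   considered size).
#' @param universe_flags logical vector over the patient's considered-gene
#'   universe: `TRUE` for resistance-pattern genes.
#' @param n_boot number of random sets (default 10000).
#' @param replace sample genes with replacement (default `FALSE`).
#' @return Bootstrap p-value in `[0, 1]`.
#' @export
bootstrap_pvalue <- function(observed_score, size, universe_flags,
                             n_boot = 10000, replace = FALSE) {
  n <- length(universe_flags)
  r <- sum(universe_flags)
  if (size < 1) stop("pathway size must be >= 1")
  if (!replace && size > n) {
    stop("pathway size (", size, ") exceeds the universe (", n, ")")
  }
  k <- if (replace) stats::rbinom(n_boot, size, r / n) else
    stats::rhyper(n_boot, r, n - r, size)
  mean(k / size >= observed_score - 1e-12)
}

#' Per-patient per-pathway resistance scores with bootstrap null
#'
#' For each patient, the considered universe is the set of DE genes with an
#' assigned (non-`UNCLASSIFIED`) pattern in that patient; a pathway's score
#' is the fraction of resistance-pattern genes (P3/P4/P7/P8) among the
#' pathway's considered genes — genes with P1/P2 count as reregulated. The
#' score's p-value comes from [bootstrap_pvalue()] over random same-size
#' gene sets from the patient's universe. Pathways with an empty considered
#' set yield a record with `n_considered = 0` and no score or p-value.
#'
#' @param assignments assignment table from [assign_patterns()].
#' @param collection named list of pathway gene vectors.
#' @param de_genes character vector of differentially expressed genes.
#' @param n_boot bootstrap resamples per (patient, pathway) (default 10000).
#' @param seed optional seed for reproducible bootstrap draws.
#' @param replace passed to [bootstrap_pvalue()].
#' @return Data frame: `patient`, `pathway`, `n_considered`, `n_resistance`,
#'   `score`, `p_boot`, `n_boot`.
#' @export
resistance_scores <- function(assignments, collection, de_genes,
                              n_boot = 10000, seed = NULL, replace = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  a <- assignments[assignments$pattern != "UNCLASSIFIED" &
                     assignments$gene %in% de_genes, , drop = FALSE]
  patients <- sort(unique(assignments$patient))
  rows <- list()
  for (p in patients) {
    sub <- a[a$patient == p, , drop = FALSE]
    flags <- stats::setNames(sub$pattern %in% RESISTANCE_PATTERNS, sub$gene)
    for (pw in names(collection)) {
      considered <- intersect(collection[[pw]], sub$gene)
      nc <- length(considered)
      if (nc == 0) {
        rows[[paste(p, pw)]] <- data.frame(
          patient = p, pathway = pw, n_considered = 0L, n_resistance = 0L,
          score = NA_real_, p_boot = NA_real_, n_boot = n_boot,
          stringsAsFactors = FALSE)
        next
      }
      nr <- sum(flags[considered])
      score <- nr / nc
      pb <- bootstrap_pvalue(score, nc, unname(flags), n_boot = n_boot,
                             replace = replace)
      rows[[paste(p, pw)]] <- data.frame(
        patient = p, pathway = pw, n_considered = nc,
        n_resistance = as.integer(nr), score = score, p_boot = pb,
        n_boot = n_boot, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
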