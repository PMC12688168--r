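# Shared fixtures, built in code. The small cohort is generated once per
# test run and reused by tests that only read it.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 8, n_genes = 300, n_pathways = 6,
         resistant_pathway_ids = c("PW01", "PW02"), seed = 42),
    list(...))
  do.call(synthetic_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_config())
  }
  .fixture_env$cohort
}

small_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    co <- small_cohort()
    sf <- size_factors(co$counts)
    vst <- vst_transform(co$counts, sf)
    triplets <- build_triplets(co$counts, co$samples)
    de <- de_filter(vst, co$counts, triplets)
    assignments <- assign_patterns(vst, triplets, genes = de$retained)
    .fixture_env$analysis <- list(cohort = co, sf = sf, vst = vst,
                                  triplets = triplets, de = de,
                                  assignments = assignments)
  }
  .fixture_env$analysis
}

# independent scalar oracle: Pearson correlation against each template via
# stats::cor, argmax by index
oracle_assign <- function(values) {
  tm <- rbind(P1 = c(0, 1, 0), P2 = c(0, -1, 0), P3 = c(0, 1, 1),
              P4 = c(0, -1, -1), P5 = c(0, 0, -1), P6 = c(0, 0, 1),
              P7 = c(0, 1, 2), P8 = c(0, -1, -2))
  if (stats::sd(values) < 1e-12) return("UNCLASSIFIED")
  r <- apply(tm, 1, function(t) stats::cor(values, t))
  names(r)[which.max(r)]
}

# independent oracle: two-sided rank-sum p by exhaustive enumeration of
# group-label assignments (midranks; symmetric permutation distribution)
oracle_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  mu <- length(x) * (n + 1) / 2
  combos <- utils::combn(n, length(x))
  w <- colSums(matrix(r[combos], nrow = length(x)))
  obs <- sum(r[seq_along(x)])
  mean(abs(w - mu) >= abs(obs - mu) - 1e-9)
}

# independent oracle: Benjamini-Hochberg from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ord == i)  # rank of p[i]
    adj[i] <- min(1, min(m * p[ord][seq(j, m)] / seq(j, m)))
  }
  adj
}
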