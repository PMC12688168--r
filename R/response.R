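#' Two-sample Wilcoxon rank-sum test with an exact small-sample mode
#'
#' Two-sided rank-sum test on midranks. For small samples (combined
#' `n <= exact_max_n`) the p-value is computed exactly by enumerating all
#' group-label assignments, which remains exact in the presence of ties
#' (Miller-Payne grades are heavily tied). Larger samples use the normal
#' approximation with tie correction and continuity correction. The
#' permutation distribution of the rank sum is symmetric, so the two-sided
#' exact p is the probability of a rank sum at least as far from its mean as
#' observed.
#'
#' @param x,y numeric vectors (e.g. Miller-Payne grades of the two groups).
#' @param exact_max_n maximal combined sample size for exact enumeration
#'   (default 20).
#' @return List with `statistic` (rank sum of `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' rank_sum_test(c(4, 4, 3), c(1, 2, 2))
#' @export
rank_sum_test <- function(x, y, exact_max_n = 20) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_max_n && choose(n, nx) <= 5e5) {
    combos <- utils::combn(n, nx)
    wperm <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(wperm - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(statistic = w, p_value = p, method = method)
}

#' Genes with persistent dysregulated patterns across patients
#'
#' A gene qualifies as a persistent resistance gene when the share of its
#' classified patients carrying pattern P3 alone, P3+P7 combined, P4 alone,
#' or P4+P8 combined exceeds `threshold` (strictly more than 50% by
#' default). Shares are computed over patients with a non-`UNCLASSIFIED`
#' assignment.
#'
#' @param assignments assignment table from [assign_patterns()].
#' @param threshold patient-share threshold, exceeded strictly (default 0.5).
#' @return Character vector of gene ids.
#' @export
persistent_resistance_genes <- function(assignments, threshold = 0.5) {
  a <- assignments[assignments$pattern != "UNCLASSIFIED", , drop = FALSE]
  if (!nrow(a)) return(character())
  tab <- table(a$gene, factor(a$pattern, levels = PATTERN_IDS))
  n <- rowSums(tab)
  share <- tab / n
  qual <- share[, "P3"] > threshold |
    (share[, "P3"] + share[, "P7"]) > threshold |
    share[, "P4"] > threshold |
    (share[, "P4"] + share[, "P8"]) > threshold
  sort(rownames(tab)[qual])
}

#' Per-gene Wilcoxon test of pattern association with response
#'
#' For each gene (typically the bimodal genes), compares the Miller-Payne
#' grades of patients in which the gene shows a "good response" pattern with
#' those in which it shows a "poor response" pattern, separately per
#' direction cluster: `up` (P1 vs P3/P7) and `down` (P2 vs P4/P8). Patients
#' whose assignment for the gene is neither (P5/P6 or unclassified) are
#' dropped from that gene's test. Genes with an empty group in a cluster are
#' skipped for that cluster. Raw p-values are the selection criterion
#' (significance at `p < 0.05` as customary for this screen); BH-adjusted
#' values are emitted alongside for transparency.
#'
#' @param assignments assignment table from [assign_patterns()].
#' @param patients patient table with `patient_id` and `mp_score`.
#' @param genes optional gene subset (e.g. bimodal genes); default all.
#' @param subtype optional subtype label; restricts the test to patients with
#'   that `subtype` (e.g. `"HR+"`).
#' @param exact_max_n passed to [rank_sum_test()].
#' @return Data frame: `gene`, `cluster` (`up`/`down`), `n_good`, `n_poor`,
#'   `statistic`, `p_value`, `adjusted_p`.
#' @export
wilcoxon_response <- function(assignments, patients, genes = NULL,
                              subtype = NULL, exact_max_n = 20) {
  if (!is.null(subtype)) {
    keep_pat <- patients$patient_id[patients$subtype %in% subtype]
    if (!length(keep_pat)) {
      stop("no patients with subtype ", paste(subtype, collapse = "/"))
    }
    assignments <- assignments[assignments$patient %in% keep_pat, ,
                               drop = FALSE]
  }
  if (!is.null(genes)) {
    assignments <- assignments[assignments$gene %in% genes, , drop = FALSE]
  }
  mp <- stats::setNames(patients$mp_score, patients$patient_id)
  clusters <- list(up = list(good = "P1", poor = c("P3", "P7")),
                   down = list(good = "P2", poor = c("P4", "P8")))
  rows <- list()
  for (g in unique(assignments$gene)) {
    sub <- assignments[assignments$gene == g, , drop = FALSE]
    for (cl in names(clusters)) {
      good <- mp[sub$patient[sub$pattern %in% clusters[[cl]]$good]]
      poor <- mp[sub$patient[sub$pattern %in% clusters[[cl]]$poor]]
      good <- good[!is.na(good)]; poor <- poor[!is.na(poor)]
      if (!length(good) || !length(poor)) next
      tst <- rank_sum_test(good, poor, exact_max_n = exact_max_n)
      rows[[paste(g, cl)]] <- data.frame(
        gene = g, cluster = cl, n_good = length(good),
        n_poor = length(poor), statistic = tst$statistic,
        p_value = tst$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), cluster = character(),
                      n_good = integer(), n_poor = integer(),
                      statistic = numeric(), p_value = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$adjusted_p <- NA_real_
  for (cl in unique(res$cluster)) {
    idx <- res$cluster == cl
    res$adjusted_p[idx] <- stats::p.adjust(res$p_value[idx], method = "BH")
  }
  res
}

#' Combine the two routes to resistance-associated genes
#'
#' @param persistent gene ids from [persistent_resistance_genes()].
#' @param wilcoxon result table from [wilcoxon_response()].
#' @param alpha raw-p significance threshold for the bimodal route
#'   (default 0.05, strict).
#' @return List with `persistent_genes`, `bimodal_significant_genes`, and
#'   their union `combined`.
#' @export
resistance_gene_list <- function(persistent, wilcoxon, alpha = 0.05) {
  bimodal <- sort(unique(wilcoxon$gene[wilcoxon$p_value < alpha]))
  list(persistent_genes = persistent,
       bimodal_significant_genes = bimodal,
       combined = sort(union(persistent, bimodal)))
}

#' One-way ANOVA of the response ratio across Miller-Payne groups
#'
#' Tests whether the per-patient ratio of reregulated to dysregulated
#' pattern fractions, (P1 + P2) / (P7 + P8), differs across Miller-Payne
#' response groups. Infinite ratios (zero dysregulated fraction) are
#' excluded by default because they are undefined on the real line; `cap`
#' replaces them with the largest finite ratio instead.
#'
#' @param fractions per-patient fraction table from [pattern_fractions()].
#' @param patients patient table with `patient_id` and `mp_score`.
#' @param mp_groups named list mapping group labels to MP grades; default
#'   three groups `{1}, {2}, {3-5}`.
#' @param infinite how to treat infinite ratios: `"exclude"` (default) or
#'   `"cap"`.
#' @return List with `f_statistic`, `p_value`, `groups` (per-patient group
#'   table), `n_excluded`.
#' @export
ratio_anova <- function(fractions, patients,
                        mp_groups = list(`1` = 1, `2` = 2, `3-5` = 3:5),
                        infinite = c("exclude", "cap")) {
  infinite <- match.arg(infinite)
  mp <- stats::setNames(patients$mp_score, patients$patient_id)
  df <- data.frame(patient = fractions$patient,
                   ratio = fractions$ratio,
                   mp = mp[fractions$patient],
                   stringsAsFactors = FALSE)
  df$group <- NA_character_
  for (g in names(mp_groups)) df$group[df$mp %in% mp_groups[[g]]] <- g
  df <- df[!is.na(df$group), , drop = FALSE]
  n_excluded <- 0L
  if (any(is.infinite(df$ratio))) {
    if (infinite == "exclude") {
      n_excluded <- sum(is.infinite(df$ratio))
      message(n_excluded, " patient(s) with infinite ratio excluded from ANOVA")
      df <- df[is.finite(df$ratio), , drop = FALSE]
    } else {
      cap <- max(df$ratio[is.finite(df$ratio)])
      df$ratio[is.infinite(df$ratio)] <- cap
    }
  }
  sizes <- table(df$group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("degenerate MP grouping: need >= 2 groups with >= 2 patients each")
  }
  if (stats::var(df$ratio) < 1e-24) {
    return(list(f_statistic = 0, p_value = 1, groups = df,
                n_excluded = n_excluded))
  }
  fit <- stats::oneway.test(ratio ~ group, data = df, var.equal = TRUE)
  list(f_statistic = unname(fit$statistic), p_value = unname(fit$p.value),
       groups = df, n_excluded = n_excluded)
}

#' Kaplan-Meier / log-rank analysis of the response-ratio dichotomy
#'
#' Stratifies patients by whether their reregulated/dysregulated ratio
#' exceeds `cutoff` (default 5) and compares recurrence-free survival
#' between the strata with the two-group log-rank test. Infinite ratios fall
#' in the high stratum.
#'
#' @param patients patient table with `rfs_years` and `recurrence_event`.
#' @param ratios named numeric vector of per-patient ratios, or the fraction
#'   table from [pattern_fractions()].
#' @param cutoff ratio cutoff (default 5).
#' @return List with `fit` (a [survival::survfit] object), `chisq`,
#'   `p_value`, and the stratum table `strata`.
#' @export
km_logrank <- function(patients, ratios, cutoff = 5) {
  if (is.data.frame(ratios)) {
    ratios <- stats::setNames(ratios$ratio, ratios$patient)
  }
  pts <- patients[patients$patient_id %in% names(ratios), , drop = FALSE]
  if (is.null(pts$rfs_years) || is.null(pts$recurrence_event) ||
      any(is.na(pts$rfs_years)) || any(is.na(pts$recurrence_event))) {
    stop("rfs_years and recurrence_event are required for all patients")
  }
  grp <- ifelse(ratios[pts$patient_id] > cutoff, "high", "low")
  if (length(unique(grp)) < 2) {
    stop("a stratum at ratio cutoff ", cutoff, " is empty")
  }
  if (!any(pts$recurrence_event)) {
    stop("log-rank test undefined: no recurrence events")
  }
  surv <- survival::Surv(pts$rfs_years, pts$recurrence_event)
  sd <- survival::survdiff(surv ~ grp)
  fit <- survival::survfit(surv ~ grp)
  list(fit = fit, chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       strata = table(grp))
}
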