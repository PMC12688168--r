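#' Theoretical temporal expression patterns
#'
#' The eight qualitative trajectories a gene can follow over a matched
#' normal -> pretreatment -> posttreatment triplet, excluding the fully flat
#' trajectory. Each pattern is an ordered triple of reference levels together
#' with its biological scenario:
#'
#' * **P1/P2** (`reregulated`): expression rises/falls in the tumor and
#'   returns to normal levels after treatment.
#' * **P3/P4** (`resistance`): the tumor-acquired change persists after
#'   treatment.
#' * **P5/P6** (`treatment_effect`): expression changes only after treatment.
#' * **P7/P8** (`worsening`): monotone intensification from normal through
#'   pre- to posttreatment.
#'
#' The triples encode the verbal shape descriptions with unit steps
#' (P7/P8 use two equal steps); the pattern assignment uses Pearson
#' correlation, so only the shape matters, not the amplitude.
#'
#' @return A data frame with one row per pattern and columns `id`,
#'   `l_normal`, `l_pre`, `l_post`, `scenario`, `direction`.
#' @examples
#' theoretical_templates()
#' @export
theoretical_templates <- function() {
  data.frame(
    id = paste0("P", 1:8),
    l_normal = rep(0, 8),
    l_pre  = c(1, -1, 1, -1, 0, 0, 1, -1),
    l_post = c(0, 0, 1, -1, -1, 1, 2, -2),
    scenario = rep(c("reregulated", "resistance", "treatment_effect",
                     "worsening"), each = 2),
    direction = c("up", "down", "up", "down", "down", "up", "up", "down"),
    stringsAsFactors = FALSE
  )
}

#' All pattern identifiers, including the non-pattern sentinel
#' @keywords internal
PATTERN_IDS <- paste0("P", 1:8)

#' Patterns interpreted as resistance-associated ("dysregulated")
#' @keywords internal
RESISTANCE_PATTERNS <- c("P3", "P4", "P7", "P8")

#' Patterns interpreted as reregulated (return to normal)
#' @keywords internal
REREGULATED_PATTERNS <- c("P1", "P2")

# 8 x 3 matrix of template levels, rows named by pattern id
template_matrix <- function(templates = theoretical_templates()) {
  m <- as.matrix(templates[, c("l_normal", "l_pre", "l_post")])
  rownames(m) <- templates$id
  m
}

# rows centered and scaled to unit norm; templates all have nonzero variance
.center_unit <- function(m) {
  mc <- m - rowMeans(m)
  nrm <- sqrt(rowSums(mc^2))
  mc / nrm
}

#' Assign a single triplet profile to a theoretical pattern
#'
#' Computes the Pearson correlation of a (normal, pre, post) value triple
#' with each of the eight pattern templates and assigns the pattern of
#' maximal correlation. A triplet with (numerically) zero variance carries
#' no shape information and is returned as `UNCLASSIFIED`. Exact ties on the
#' maximal correlation are broken by the smallest Euclidean distance between
#' the z-scored triplet and the z-scored template, then by lowest pattern
#' index, so the assignment is deterministic.
#'
#' @param values numeric vector of length 3: VST values at
#'   (normal, pre, post).
#' @param templates template table from [theoretical_templates()].
#' @param sd_tol triplets with standard deviation below this tolerance are
#'   declared `UNCLASSIFIED`.
#' @param on correlate the `"levels"` themselves (default, Pearson) or the
#'   `"differences"` between consecutive timepoints (cosine similarity of
#'   the two-step change vector with each template's change vector; Pearson
#'   degenerates to ±1 on two points, so the difference reading uses the
#'   uncentered angle instead). The two readings agree for most profiles but
#'   weight the two transitions differently.
#' @return A list with elements `pattern` (`"P1"`..`"P8"` or
#'   `"UNCLASSIFIED"`) and `correlation` (`NA` when unclassified).
#' @examples
#' assign_pattern(c(0, 2, 0))   # P1, correlation 1
#' assign_pattern(c(5, 5, 5))   # UNCLASSIFIED
#' @export
assign_pattern <- function(values, templates = theoretical_templates(),
                           sd_tol = 1e-12, on = c("levels", "differences")) {
  on <- match.arg(on)
  if (length(values) != 3L || !is.numeric(values)) {
    stop("`values` must be a numeric vector of length 3")
  }
  if (any(!is.finite(values))) {
    stop("triplet contains non-finite values")
  }
  if (stats::sd(values) < sd_tol) {
    return(list(pattern = "UNCLASSIFIED", correlation = NA_real_))
  }
  tm <- template_matrix(templates)
  if (on == "differences") {
    dm <- t(apply(tm, 1, diff))
    dmn <- dm / sqrt(rowSums(dm^2))
    dv <- diff(values)
    dvn <- dv / sqrt(sum(dv^2))
    r <- as.numeric(dmn %*% dvn)
    norm_obs <- matrix(dvn, nrow = 1)
    norm_tpl <- dmn
  } else {
    r <- as.numeric(.center_unit(matrix(values, nrow = 1)) %*%
                      t(.center_unit(tm)))
    norm_obs <- .center_unit(matrix(values, nrow = 1))
    norm_tpl <- .center_unit(tm)
  }
  best <- which(r == max(r))
  if (length(best) > 1L) {
    d <- rowSums((norm_tpl[best, , drop = FALSE] -
                    rep(as.numeric(norm_obs), each = length(best)))^2)
    best <- best[d == min(d)]
  }
  best <- min(best)
  list(pattern = rownames(tm)[best], correlation = r[best])
}

#' Classify all gene-per-patient triplets of a cohort
#'
#' Vectorized pattern assignment for every (gene, patient) pair: for each
#' patient's (normal, pre, post) sample triple, every gene's VST triplet is
#' correlated with the eight theoretical templates and assigned to the one
#' with maximal correlation (ties broken as in [assign_pattern()]).
#'
#' @param vst numeric matrix of variance-stabilized expression,
#'   genes x samples, with dimnames.
#' @param triplets triplet table from [build_triplets()] (columns
#'   `patient_id`, `normal`, `pre`, `post`).
#' @param genes optional character vector restricting the genes classified
#'   (typically the DE-retained universe).
#' @param templates template table from [theoretical_templates()].
#' @param sd_tol zero-variance tolerance, see [assign_pattern()].
#' @param on `"levels"` (default) or `"differences"`, see
#'   [assign_pattern()].
#' @return A data frame with columns `gene`, `patient`, `pattern`,
#'   `correlation`, one row per (gene, patient).
#' @export
assign_patterns <- function(vst, triplets, genes = NULL,
                            templates = theoretical_templates(),
                            sd_tol = 1e-12, on = c("levels", "differences")) {
  on <- match.arg(on)
  if (is.null(rownames(vst)) || is.null(colnames(vst))) {
    stop("`vst` must have gene rownames and sample colnames")
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vst))
    if (length(missing)) {
      stop("genes absent from the VST matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    vst <- vst[genes, , drop = FALSE]
  }
  tm <- template_matrix(templates)
  tmn <- if (on == "levels") .center_unit(tm) else {
    dm <- t(apply(tm, 1, diff))
    dm / sqrt(rowSums(dm^2))
  }
  out <- vector("list", nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    cols <- c(triplets$normal[i], triplets$pre[i], triplets$post[i])
    x <- vst[, cols, drop = FALSE]
    if (any(!is.finite(x))) stop("non-finite VST values for patient ",
                                 triplets$patient_id[i])
    if (on == "levels") {
      obs <- x - rowMeans(x)
    } else {
      obs <- cbind(x[, 2] - x[, 1], x[, 3] - x[, 2])
    }
    ss <- sqrt(rowSums(obs^2))
    flat <- ss / sqrt(2) < sd_tol   # sd of 3 values = ||centered|| / sqrt(2)
    r <- (obs / pmax(ss, .Machine$double.xmin)) %*% t(tmn)
    # max correlation; exact ties share the max, take the lowest index
    # (z-score distance is monotone in the correlation for 3-point profiles,
    #  so the distance tie-break never overrides the index tie-break)
    best <- max.col(r, ties.method = "first")
    pattern <- rownames(tmn)[best]
    correlation <- r[cbind(seq_along(best), best)]
    pattern[flat] <- "UNCLASSIFIED"
    correlation[flat] <- NA_real_
    out[[i]] <- data.frame(
      gene = rownames(vst),
      patient = triplets$patient_id[i],
      pattern = pattern,
      correlation = correlation,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a gene's pattern recurrence across patients
#'
#' Applies the cross-patient classification rules to one gene's per-patient
#' assignments: a gene has one *main* pattern if a single pattern occurs in
#' at least 50% of its classified patients; failing that it is *bimodal* if
#' two patterns each occur in at least 30% of classified patients and each in
#' at least five patients; otherwise it is *unclassified*. Denominators count
#' patients with a non-`UNCLASSIFIED` assignment.
#'
#' @param patterns character vector of per-patient pattern calls for one gene
#'   (`"P1"`..`"P8"` or `"UNCLASSIFIED"`).
#' @param main_threshold minimal patient share for a main pattern (0.5).
#' @param bimodal_threshold minimal patient share for each bimodal pattern
#'   (0.3).
#' @param min_patients minimal absolute patient count for each bimodal
#'   pattern (5).
#' @param strict_main if `TRUE`, the main rule requires a share strictly
#'   above `main_threshold` rather than at least it.
#' @return A one-row data frame with columns `n_classified`, `class`
#'   (`main` / `bimodal` / `unclassified`), `main_patterns` (e.g. `"P3"` or
#'   `"P1+P3"`), and per-pattern patient counts `P1`..`P8`.
#' @export
classify_gene <- function(patterns, main_threshold = 0.5,
                          bimodal_threshold = 0.3, min_patients = 5,
                          strict_main = FALSE) {
  patterns <- patterns[patterns != "UNCLASSIFIED"]
  if (!length(patterns)) stop("no classified patients for this gene")
  counts <- table(factor(patterns, levels = PATTERN_IDS))
  n <- length(patterns)
  shares <- as.numeric(counts) / n
  ord <- order(-as.numeric(counts), seq_along(counts))  # count desc, index asc
  top <- ord[1]; second <- ord[2]
  main_ok <- if (strict_main) shares[top] > main_threshold else
    shares[top] >= main_threshold
  if (main_ok) {
    class <- "main"
    main_patterns <- PATTERN_IDS[top]
  } else if (shares[top] >= bimodal_threshold &&
             shares[second] >= bimodal_threshold &&
             counts[top] >= min_patients && counts[second] >= min_patients) {
    class <- "bimodal"
    main_patterns <- paste(PATTERN_IDS[sort(c(top, second))], collapse = "+")
  } else {
    class <- "unclassified"
    main_patterns <- NA_character_
  }
  out <- data.frame(n_classified = n, class = class,
                    main_patterns = main_patterns, stringsAsFactors = FALSE)
  cbind(out, as.data.frame.matrix(t(as.matrix(counts))))
}

#' Classify every gene's pattern recurrence across patients
#'
#' @param assignments assignment table from [assign_patterns()].
#' @inheritParams classify_gene
#' @return Data frame with one row per gene: `gene`, `n_classified`,
#'   `class`, `main_patterns`, and per-pattern counts.
#' @export
classify_genes <- function(assignments, main_threshold = 0.5,
                           bimodal_threshold = 0.3, min_patients = 5,
                           strict_main = FALSE) {
  keep <- assignments$pattern != "UNCLASSIFIED"
  if (!any(keep)) stop("no classified (gene, patient) pairs")
  a <- assignments[keep, , drop = FALSE]
  split_patterns <- split(a$pattern, a$gene)
  rows <- lapply(split_patterns, classify_gene,
                 main_threshold = main_threshold,
                 bimodal_threshold = bimodal_threshold,
                 min_patients = min_patients, strict_main = strict_main)
  res <- do.call(rbind, rows)
  res <- cbind(gene = names(split_patterns), res)
  rownames(res) <- NULL
  res
}

#' Per-patient pattern fractions and the reregulated/dysregulated ratio
#'
#' For each patient, the fraction of its classified genes assigned to each
#' pattern, plus the response ratio (P1 + P2) / (P7 + P8) of reregulated to
#' dysregulated fractions. The denominator of the fractions is the patient's
#' number of classified (non-`UNCLASSIFIED`) genes. A zero dysregulated
#' fraction yields an infinite ratio, flagged in `ratio_infinite`.
#'
#' @param assignments assignment table from [assign_patterns()].
#' @return Data frame with one row per patient: `patient`, `n_classified`,
#'   fractions `P1`..`P8`, `ratio`, `ratio_infinite`.
#' @export
pattern_fractions <- function(assignments) {
  keep <- assignments$pattern != "UNCLASSIFIED"
  a <- assignments[keep, , drop = FALSE]
  patients <- sort(unique(assignments$patient))
  rows <- lapply(patients, function(p) {
    pat <- a$pattern[a$patient == p]
    if (!length(pat)) stop("patient ", p, " has zero classified genes")
    counts <- table(factor(pat, levels = PATTERN_IDS))
    f <- as.numeric(counts) / length(pat)
    names(f) <- PATTERN_IDS
    num <- f[["P1"]] + f[["P2"]]
    den <- f[["P7"]] + f[["P8"]]
    ratio <- if (den == 0) Inf else num / den
    cbind(data.frame(patient = p, n_classified = length(pat),
                     stringsAsFactors = FALSE),
          as.data.frame(t(f)),
          data.frame(ratio = ratio, ratio_infinite = is.infinite(ratio)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
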