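#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of the simulated neoadjuvant
#' cohort. Defaults emulate the study design the pipeline targets: ~24
#' patients with complete matched triplets, RNA-seq-like negative-binomial
#' counts, a majority of flat (non-differential) genes, and a minority of
#' genes planted with one of the eight temporal patterns at a 2-fold-per-step
#' (log2) effect size.
#'
#' @param n_patients number of patients, each contributing a matched
#'   normal/pre/post triplet.
#' @param n_genes number of genes.
#' @param pattern_proportions named numeric vector over `P1`..`P8` and `FLAT`
#'   summing to 1; the prior for each gene's base pattern. `FLAT` genes carry
#'   no planted signal and act as true negatives for the DE filter.
#' @param effect_size log2-scale step magnitude per unit of template level.
#' @param baseline_log_mean_range range (log2 scale) of per-gene baseline
#'   mean counts, drawn uniformly.
#' @param nb_dispersion negative-binomial dispersion `phi`
#'   (variance = mu + phi * mu^2); `0` gives Poisson counts.
#' @param library_size_range range of per-sample library scaling factors,
#'   drawn log-uniformly.
#' @param mp_coupling strength with which a patient's planted dysregulated
#'   gene fraction lowers its Miller-Payne grade; `0` decouples them.
#' @param flip_range range of per-patient probabilities that a reregulated
#'   base gene (P1/P2) is instead dysregulated (P3/P4) in that patient; this
#'   is what creates bimodal genes and inter-patient response heterogeneity.
#' @param mp_range integer range of generated Miller-Payne grades; defaults
#'   to 1-4, the range observed in cohorts of partial responders (complete
#'   responders, grade 5, leave no residual tumor to sample).
#' @param n_pathways,pathway_size_range,resistant_pathway_ids,resistance_enrichment
#'   gene-set collection parameters: number of sets, their size range, which
#'   set ids are seeded with resistance-pattern genes, and the fraction of a
#'   resistant set drawn from planted resistance hubs (default 0.7).
#' @param seed integer random seed; identical configs give byte-identical
#'   cohorts.
#' @return A validated list of class `chemo_config`.
#' @export
synthetic_config <- function(n_patients = 24,
                             n_genes = 2000,
                             pattern_proportions = c(
                               P1 = 0.06, P2 = 0.06, P3 = 0.05, P4 = 0.05,
                               P5 = 0.04, P6 = 0.04, P7 = 0.05, P8 = 0.05,
                               FLAT = 0.60),
                             effect_size = 2,
                             baseline_log_mean_range = c(5, 10),
                             nb_dispersion = 0.05,
                             library_size_range = c(0.5, 2),
                             mp_coupling = 1,
                             flip_range = c(0.1, 0.9),
                             mp_range = c(1L, 4L),
                             n_pathways = 25,
                             pathway_size_range = c(10, 30),
                             resistant_pathway_ids = c("PW01", "PW02", "PW03"),
                             resistance_enrichment = 0.7,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              pattern_proportions = pattern_proportions,
              effect_size = effect_size,
              baseline_log_mean_range = baseline_log_mean_range,
              nb_dispersion = nb_dispersion,
              library_size_range = library_size_range,
              mp_coupling = mp_coupling,
              flip_range = flip_range,
              mp_range = as.integer(mp_range),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              resistant_pathway_ids = resistant_pathway_ids,
              resistance_enrichment = resistance_enrichment,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "chemo_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_patients < 2) stop("configuration error: n_patients must be >= 2")
  if (cfg$n_genes < 1) stop("configuration error: n_genes must be positive")
  pp <- cfg$pattern_proportions
  wanted <- c(PATTERN_IDS, "FLAT")
  if (!setequal(names(pp), wanted)) {
    stop("configuration error: pattern_proportions must be named P1..P8, FLAT")
  }
  if (abs(sum(pp) - 1) > 1e-9) {
    stop("configuration error: pattern_proportions must sum to 1")
  }
  if (any(pp < 0)) stop("configuration error: negative pattern proportion")
  if (cfg$nb_dispersion < 0) stop("configuration error: nb_dispersion < 0")
  for (fld in c("baseline_log_mean_range", "library_size_range",
                "flip_range", "mp_range", "pathway_size_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop("configuration error: ", fld, " must be an ordered (low, high) pair")
    }
  }
  if (any(cfg$library_size_range <= 0)) {
    stop("configuration error: library sizes must be positive")
  }
  if (cfg$mp_range[1] < 1 || cfg$mp_range[2] > 5) {
    stop("configuration error: mp_range must lie within 1..5")
  }
  invisible(cfg)
}

# negative-binomial draw parameterized by mean and dispersion phi
# (variance = mu + phi mu^2); phi = 0 degenerates to Poisson
rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Simulates a matched-triplet neoadjuvant cohort: for each gene a base
#' temporal pattern is drawn from `pattern_proportions`; reregulated base
#' genes (P1/P2) are flipped, per patient, to their persistent dysregulated
#' counterpart (P3/P4) with a patient-specific probability, creating bimodal
#' genes whose pattern distinguishes responders. Counts are drawn
#' negative-binomially around pattern-defined log2 means
#' (`baseline + effect_size * template level`), scaled by log-uniform
#' per-sample library factors. Each patient's Miller-Payne grade decreases
#' stochastically with its planted dysregulated gene fraction, with strength
#' `mp_coupling`. Recurrence-free survival is drawn with a hazard increasing
#' in the same fraction.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `chemo_cohort` with elements:
#' \describe{
#'   \item{counts}{integer matrix, genes x samples.}
#'   \item{samples}{sample table: `sample_id`, `patient_id`, `timepoint`,
#'     `cellularity`.}
#'   \item{patients}{patient table: `patient_id`, `mp_score`, `rcb_class`,
#'     `subtype`, `regimen`, `rfs_years`, `recurrence_event`.}
#'   \item{gene_sets}{named list of gene-id vectors (see
#'     [generate_pathway_collection()]).}
#'   \item{truth}{ground truth: `planted_pattern` (genes x patients character
#'     matrix), `planted_mp`, `dysregulated_fraction`, `library_sizes`,
#'     `flip_probability`, `planted_resistant_pathways`, `hub_genes`.}
#' }
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 4, n_genes = 50,
#'                                            n_pathways = 3, seed = 7))
#' dim(cohort$counts)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  validate_config(config)
  set.seed(config$seed)
  np <- config$n_patients
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  patients <- sprintf("PT%02d", seq_len(np))
  timepoints <- c("normal", "pre", "post")
  samples <- as.vector(t(outer(patients, timepoints, paste, sep = "_")))

  baseline <- stats::runif(ng, config$baseline_log_mean_range[1],
                           config$baseline_log_mean_range[2])
  base_pattern <- sample(names(config$pattern_proportions), ng, replace = TRUE,
                         prob = config$pattern_proportions)
  flip_prob <- stats::runif(np, config$flip_range[1], config$flip_range[2])
  names(flip_prob) <- patients

  # planted pattern per (gene, patient): P1 -> P3 and P2 -> P4 flips with
  # patient-specific probability; everything else is patient-invariant
  planted <- matrix(rep(base_pattern, np), nrow = ng,
                    dimnames = list(genes, patients))
  for (p in seq_len(np)) {
    rereg <- which(base_pattern %in% REREGULATED_PATTERNS)
    if (length(rereg)) {
      flip <- rereg[stats::runif(length(rereg)) < flip_prob[p]]
      planted[flip, p] <- ifelse(base_pattern[flip] == "P1", "P3", "P4")
    }
  }

  lib <- exp(stats::runif(3 * np, log(config$library_size_range[1]),
                          log(config$library_size_range[2])))
  names(lib) <- samples

  tm <- template_matrix()
  levels_for <- function(pat) {
    out <- matrix(0, length(pat), 3)
    idx <- pat != "FLAT"
    out[idx, ] <- tm[pat[idx], , drop = FALSE]
    out
  }
  counts <- matrix(0L, ng, 3 * np, dimnames = list(genes, samples))
  for (p in seq_len(np)) {
    lev <- levels_for(planted[, p])                       # genes x 3
    log_mu <- baseline + config$effect_size * lev         # recycled by column
    for (tp in 1:3) {
      s <- (p - 1) * 3 + tp
      mu <- 2^log_mu[, tp] * lib[s]
      counts[, s] <- rnb(ng, mu, config$nb_dispersion)
    }
  }
  storage.mode(counts) <- "integer"

  dys_frac <- colMeans(matrix(planted %in% RESISTANCE_PATTERNS, ng, np))
  names(dys_frac) <- patients

  mp_lo <- config$mp_range[1]; mp_hi <- config$mp_range[2]
  if (config$mp_coupling > 0) {
    spread <- diff(range(dys_frac))
    z <- if (spread > 0) (dys_frac - min(dys_frac)) / spread else
      rep(0.5, np)
    latent <- mp_lo + (mp_hi - mp_lo + 0.9) * (1 - z) - 0.45 +
      stats::rnorm(np, sd = 0.6 / config$mp_coupling)
    mp <- pmin(mp_hi, pmax(mp_lo, round(latent)))
  } else {
    mp <- sample(seq(mp_lo, mp_hi), np, replace = TRUE)
  }
  mp <- as.integer(mp)
  names(mp) <- patients

  subtype <- sample(c("TNBC", "HR+", "TP"), np, replace = TRUE,
                    prob = c(0.10, 0.55, 0.35))
  regimen <- ifelse(subtype == "TP", "AC-TH", "AC-T")
  rcb <- c("RCB-III", "RCB-III", "RCB-II", "RCB-II", "RCB-I")[mp]
  # recurrence hazard rises with the dysregulated fraction; admin. censoring
  z_haz <- (dys_frac - mean(dys_frac)) / max(stats::sd(dys_frac), 1e-9)
  event_time <- stats::rexp(np, rate = 0.08 * exp(0.8 * z_haz))
  censor_time <- stats::runif(np, 4, 11)
  rfs_years <- round(pmin(event_time, censor_time), 2)
  recurrence_event <- event_time <= censor_time

  sample_tab <- data.frame(
    sample_id = samples,
    patient_id = rep(patients, each = 3),
    timepoint = rep(timepoints, np),
    cellularity = ifelse(rep(timepoints, np) == "normal", NA_real_,
                         round(stats::runif(3 * np, 0.4, 0.9), 2)),
    stringsAsFactors = FALSE
  )
  patient_tab <- data.frame(
    patient_id = patients, mp_score = mp, rcb_class = rcb,
    subtype = subtype, regimen = regimen, rfs_years = rfs_years,
    recurrence_event = recurrence_event, stringsAsFactors = FALSE
  )
  rownames(patient_tab) <- NULL

  truth <- list(
    planted_pattern = planted,
    planted_mp = mp,
    dysregulated_fraction = dys_frac,
    library_sizes = lib,
    flip_probability = flip_prob,
    planted_resistant_pathways = config$resistant_pathway_ids,
    hub_genes = genes[rowMeans(matrix(planted %in% RESISTANCE_PATTERNS,
                                      ng, np)) > 0.5]
  )
  gene_sets <- generate_pathway_collection(config, truth, genes)

  structure(list(counts = counts, samples = sample_tab,
                 patients = patient_tab, gene_sets = gene_sets,
                 truth = truth),
            class = "chemo_cohort")
}

#' Generate a synthetic gene-set collection with planted resistant pathways
#'
#' Pathways named in `config$resistant_pathway_ids` are enriched (default
#' 70%) in resistance hubs — genes whose planted pattern is dysregulated
#' (P3/P4/P7/P8) in a majority of patients; the remaining pathways are
#' uniform random draws from the gene universe.
#'
#' @param config a [synthetic_config()].
#' @param truth ground-truth list from [generate_cohort()] (needs
#'   `hub_genes`).
#' @param genes the gene universe (character vector).
#' @return Named list of gene-id vectors with a `description` attribute
#'   (named character vector) suitable for [write_gmt()].
#' @export
generate_pathway_collection <- function(config, truth, genes) {
  if (max(config$pathway_size_range) > length(genes)) {
    stop("pathway size exceeds the gene universe")
  }
  ids <- sprintf("PW%02d", seq_len(config$n_pathways))
  unknown <- setdiff(config$resistant_pathway_ids, ids)
  if (length(unknown)) {
    stop("resistant_pathway_ids outside the generated collection: ",
         paste(unknown, collapse = ", "))
  }
  hubs <- intersect(truth$hub_genes, genes)
  non_hubs <- setdiff(genes, hubs)
  sets <- vector("list", length(ids))
  names(sets) <- ids
  desc <- character(length(ids))
  names(desc) <- ids
  for (id in ids) {
    k <- if (config$pathway_size_range[1] == config$pathway_size_range[2])
      config$pathway_size_range[1] else
        sample(seq(config$pathway_size_range[1],
                   config$pathway_size_range[2]), 1)
    if (id %in% config$resistant_pathway_ids && length(hubs)) {
      n_res <- min(ceiling(config$resistance_enrichment * k), length(hubs))
      picked <- c(sample(hubs, n_res),
                  sample(non_hubs, k - n_res))
      desc[id] <- "synthetic resistant pathway"
    } else {
      picked <- sample(genes, k)
      desc[id] <- "synthetic random pathway"
    }
    sets[[id]] <- sort(picked)
  }
  attr(sets, "description") <- desc
  sets
}
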