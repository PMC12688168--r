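#' Run the full chemoresistome pipeline
#'
#' Orchestrates every stage end-to-end: simulate (or accept) a cohort,
#' normalize, apply the DE gene filter, classify gene-per-patient patterns,
#' associate patterns with response (per-gene Wilcoxon screen, persistent
#' gene list, ratio ANOVA, Kaplan-Meier log-rank), run per-cluster pathway
#' enrichment on the full cohort and a subtype-restricted subset, build the
#' robust pathway list, compute resistance scores with their bootstrap null,
#' and compute the pathway deregulation score matrix. All stage outputs are
#' written as plain tables under `outdir` together with a JSON manifest
#' (parameters, per-stage row counts, file checksums). Reruns with the same
#' configuration reproduce identical tables.
#'
#' @param cohort a `chemo_cohort` (from [generate_cohort()] or assembled from
#'   files); `NULL` simulates one from `config`.
#' @param config [synthetic_config()] used when `cohort` is `NULL`.
#' @param outdir output directory (created if missing); `NULL` for a
#'   tempdir.
#' @param fc_threshold,alpha,min_count DE filter parameters (defaults
#'   2 / 0.05 / 100).
#' @param main_threshold,bimodal_threshold,min_patients gene classification
#'   thresholds (defaults 0.5 / 0.3 / 5).
#' @param subtype subtype label for the restricted reruns (default `"HR+"`).
#' @param mp_groups MP grouping for the ratio ANOVA.
#' @param km_cutoff ratio cutoff for the survival dichotomy (default 5).
#' @param n_boot bootstrap resamples per (patient, pathway) (default 10000).
#' @param seed seed for the bootstrap stage (the cohort seed lives in
#'   `config`).
#' @return Invisibly, a list with all in-memory stage results plus `outdir`
#'   and `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, config = synthetic_config(),
                         outdir = NULL, fc_threshold = 2, alpha = 0.05,
                         min_count = 100, main_threshold = 0.5,
                         bimodal_threshold = 0.3, min_patients = 5,
                         subtype = "HR+",
                         mp_groups = list(`1` = 1, `2` = 2, `3-5` = 3:5),
                         km_cutoff = 5, n_boot = 10000, seed = 1) {
  if (is.null(outdir)) outdir <- tempfile("chemoresistome_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(stage, n) {
    message("[", stage, "] ", n, " rows")
    stages[[stage]] <<- n
  }
  fail <- function(stage, e) {
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  if (is.null(cohort)) {
    cohort <- tryCatch(generate_cohort(config), error = function(e)
      fail("simulate", e))
  }
  note("simulate", ncol(cohort$counts))
  write_counts(cohort$counts, file.path(outdir, "counts.tsv"))
  write_sample_table(cohort$samples, file.path(outdir, "samples.tsv"))
  write_patient_table(cohort$patients, file.path(outdir, "patients.tsv"))
  write_gmt(cohort$gene_sets, file.path(outdir, "gene_sets.gmt"))
  if (!is.null(cohort$truth)) {
    write_json_file(cohort$truth, file.path(outdir, "ground_truth.json"))
  }

  sf <- tryCatch(size_factors(cohort$counts), error = function(e)
    fail("normalize", e))
  vst <- vst_transform(cohort$counts, sf)
  note("normalize", length(sf))
  utils::write.table(data.frame(sample = names(sf), size_factor = sf),
                     file.path(outdir, "size_factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  triplets <- build_triplets(cohort$counts, cohort$samples)
  de <- tryCatch(
    de_filter(vst, cohort$counts, triplets, fc_threshold = fc_threshold,
              alpha = alpha, min_count = min_count),
    error = function(e) fail("de-filter", e))
  note("de-filter", length(de$retained))
  utils::write.table(de$results, file.path(outdir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(de$retained, file.path(outdir, "retained_genes.txt"))
  if (length(de$retained) < 2) fail("de-filter", simpleError(
    "fewer than 2 genes retained; nothing to classify"))

  assignments <- tryCatch(
    assign_patterns(vst, triplets, genes = de$retained),
    error = function(e) fail("classify", e))
  classifications <- classify_genes(assignments,
                                    main_threshold = main_threshold,
                                    bimodal_threshold = bimodal_threshold,
                                    min_patients = min_patients)
  fractions <- pattern_fractions(assignments)
  note("classify", nrow(assignments))
  utils::write.table(assignments, file.path(outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(classifications,
                     file.path(outdir, "gene_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fractions, file.path(outdir, "patient_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  assoc <- tryCatch({
    bimodal_genes <- classifications$gene[classifications$class == "bimodal"]
    persistent <- persistent_resistance_genes(assignments)
    wil_full <- wilcoxon_response(assignments, cohort$patients,
                                  genes = bimodal_genes)
    wil_sub <- wilcoxon_response(assignments, cohort$patients,
                                 genes = bimodal_genes, subtype = subtype)
    genes_list <- resistance_gene_list(persistent, wil_full, alpha = alpha)
    anova <- ratio_anova(fractions, cohort$patients, mp_groups = mp_groups)
    km <- tryCatch(km_logrank(cohort$patients, fractions,
                              cutoff = km_cutoff),
                   error = function(e) {
                     message("log-rank skipped: ", conditionMessage(e))
                     NULL
                   })
    list(persistent = persistent, wilcoxon_full = wil_full,
         wilcoxon_subtype = wil_sub, genes = genes_list, anova = anova,
         km = km)
  }, error = function(e) fail("associate", e))
  note("associate", nrow(assoc$wilcoxon_full))
  utils::write.table(assoc$wilcoxon_full,
                     file.path(outdir, "response_wilcoxon.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_json_file(list(
    persistent = assoc$genes$persistent_genes,
    bimodal = assoc$genes$bimodal_significant_genes,
    combined = assoc$genes$combined,
    anova = assoc$anova[c("f_statistic", "p_value", "n_excluded")],
    logrank = if (is.null(assoc$km)) NULL else
      assoc$km[c("chisq", "p_value")]),
    file.path(outdir, "response_summary.json"))

  enr <- tryCatch({
    hits_by_cluster <- function(wil) {
      list(P1_P3_P7 = unique(wil$gene[wil$cluster == "up" &
                                        wil$p_value < alpha]),
           P2_P4_P8 = unique(wil$gene[wil$cluster == "down" &
                                        wil$p_value < alpha]))
    }
    universe <- de$retained
    run_enrich <- function(wil) {
      hb <- hits_by_cluster(wil)
      do.call(rbind, lapply(names(hb), function(cl) {
        hits <- union(intersect(hb[[cl]], universe),
                      character())
        if (!length(hits)) return(NULL)
        hypergeom_enrich(hits, universe, cohort$gene_sets, cluster = cl,
                         alpha = alpha)
      }))
    }
    e_full <- run_enrich(assoc$wilcoxon_full)
    e_sub <- run_enrich(assoc$wilcoxon_subtype)
    robust <- if (!is.null(e_full) && !is.null(e_sub))
      robust_pathway_list(e_full, e_sub) else
        data.frame(pathway = character(), origin = character())
    list(full = e_full, subset = e_sub, robust = robust)
  }, error = function(e) fail("enrich", e))
  note("enrich", if (is.null(enr$full)) 0L else nrow(enr$full))
  if (!is.null(enr$full)) {
    utils::write.table(enr$full, file.path(outdir, "enrichment_full.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(enr$subset)) {
    utils::write.table(enr$subset,
                       file.path(outdir, "enrichment_subtype.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(enr$robust, file.path(outdir, "robust_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scores <- tryCatch(
    resistance_scores(assignments, cohort$gene_sets, de$retained,
                      n_boot = n_boot, seed = seed),
    error = function(e) fail("score", e))
  note("score", nrow(scores))
  utils::write.table(scores, file.path(outdir, "resistance_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pds <- tryCatch({
    normals <- cohort$samples$sample_id[cohort$samples$timepoint == "normal"]
    pds_matrix(vst, cohort$gene_sets, normals)
  }, error = function(e) fail("pds", e))
  note("pds", nrow(pds))
  utils::write.table(
    data.frame(pathway = rownames(pds), pds, check.names = FALSE),
    file.path(outdir, "pds_matrix.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  note("report", length(list.files(outdir)))
  manifest <- list(
    package = "chemoresistome",
    version = as.character(utils::packageVersion("chemoresistome")),
    seed = seed,
    parameters = list(fc_threshold = fc_threshold, alpha = alpha,
                      min_count = min_count,
                      main_threshold = main_threshold,
                      bimodal_threshold = bimodal_threshold,
                      min_patients = min_patients, subtype = subtype,
                      km_cutoff = km_cutoff, n_boot = n_boot),
    stage_rows = stages,
    files = as.list(tools::md5sum(list.files(outdir, full.names = TRUE)))
  )
  names(manifest$files) <- basename(names(manifest$files))
  write_json_file(manifest, file.path(outdir, "manifest.json"))

  invisible(list(cohort = cohort, size_factors = sf, vst = vst,
                 triplets = triplets, de = de, assignments = assignments,
                 classifications = classifications, fractions = fractions,
                 association = assoc, enrichment = enr, scores = scores,
                 pds = pds, outdir = outdir, manifest = manifest))
}

# p-value color band used in the report figures
p_band <- function(p) {
  cut(p, breaks = c(-Inf, 0.01, 0.05, 0.1, Inf),
      labels = c("<0.01", "<0.05", "<0.1", ">=0.1"))
}

#' Render the summary figures of a pipeline run
#'
#' Builds the figures behind the run's main views, each with a 1:1 companion
#' data table: per-patient pattern-fraction stacked bars, the balloon plot of
#' resistance scores (pathways x patients; circle size = score, color =
#' bootstrap p band), per-patient circular chemoresistome maps, and the PDS
#' heatmap. Figures are ggplot objects; with `dir` given they are also saved
#' as PDF next to their tables.
#'
#' @param result list returned by [run_pipeline()].
#' @param dir optional directory for saved figures and tables.
#' @param map_patients patients to draw circular maps for (default: all).
#' @return List of `ggplot` objects (`fractions`, `balloon`, `maps`,
#'   `pds_heatmap`) and their `tables`.
#' @export
render_reports <- function(result, dir = NULL, map_patients = NULL) {
  frac <- result$fractions
  frac_long <- do.call(rbind, lapply(PATTERN_IDS, function(pp) {
    data.frame(patient = frac$patient, pattern = pp, fraction = frac[[pp]],
               stringsAsFactors = FALSE)
  }))
  g_frac <- ggplot2::ggplot(frac_long,
                            ggplot2::aes(x = .data$patient,
                                         y = .data$fraction,
                                         fill = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of classified genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))

  sc <- result$scores[!is.na(result$scores$score), , drop = FALSE]
  robust <- result$enrichment$robust$pathway
  balloon_tab <- if (length(robust))
    sc[sc$pathway %in% robust, , drop = FALSE] else sc
  balloon_tab$p_band <- p_band(balloon_tab$p_boot)
  g_balloon <- ggplot2::ggplot(balloon_tab,
                               ggplot2::aes(x = .data$patient,
                                            y = .data$pathway,
                                            size = .data$score,
                                            color = .data$p_band)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = NULL, y = NULL, size = "resistance score",
                  color = "bootstrap p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))

  if (is.null(map_patients)) map_patients <- unique(sc$patient)
  map_tab <- sc[sc$patient %in% map_patients, , drop = FALSE]
  map_tab$p_band <- p_band(map_tab$p_boot)
  g_maps <- ggplot2::ggplot(map_tab,
                            ggplot2::aes(x = .data$pathway,
                                         y = .data$score,
                                         fill = .data$p_band)) +
    ggplot2::geom_col() +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~patient) +
    ggplot2::labs(x = NULL, y = "resistance score", fill = "bootstrap p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())

  pds_long <- data.frame(
    pathway = rep(rownames(result$pds), ncol(result$pds)),
    sample = rep(colnames(result$pds), each = nrow(result$pds)),
    pds = as.vector(result$pds), stringsAsFactors = FALSE)
  g_pds <- ggplot2::ggplot(pds_long,
                           ggplot2::aes(x = .data$sample, y = .data$pathway,
                                        fill = .data$pds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166AC", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PDS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())

  tables <- list(fractions = frac_long, balloon = balloon_tab,
                 maps = map_tab, pds = pds_long)
  plots <- list(fractions = g_frac, balloon = g_balloon, maps = g_maps,
                pds_heatmap = g_pds)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.table(tables[[nm]],
                         file.path(dir, paste0("figure_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ggplot2::ggsave(file.path(dir, paste0("figure_", nm, ".pdf")),
                      plots[[nm]], width = 9, height = 6)
    }
  }
  list(plots = plots, tables = tables)
}
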