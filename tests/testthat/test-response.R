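mk_assign <- function(gene, patients, patterns) {
  data.frame(gene = gene, patient = patients, pattern = patterns,
             correlation = 1, stringsAsFactors = FALSE)
}

test_that("the persistent-pattern rule follows the share arithmetic", {
  pats <- sprintf("p%02d", 1:20)
  # P3 in 40% + P7 in 15% -> combined 55% > 50% -> qualifies
  a <- mk_assign("gA", pats, c(rep("P3", 8), rep("P7", 3), rep("P1", 9)))
  expect_equal(persistent_resistance_genes(a), "gA")
  # P3 45%, P4 45%: no route exceeds 50%
  a <- mk_assign("gB", pats, c(rep("P3", 9), rep("P4", 9), rep("P1", 2)))
  expect_equal(persistent_resistance_genes(a), character(0))
  # exactly 50% does not qualify (strictly more than half)
  a <- mk_assign("gC", pats, c(rep("P4", 10), rep("P1", 10)))
  expect_equal(persistent_resistance_genes(a), character(0))
  # UNCLASSIFIED patients shrink the denominator
  a <- mk_assign("gD", pats, c(rep("P3", 6), rep("UNCLASSIFIED", 14)))
  expect_equal(persistent_resistance_genes(a), "gD")
})

test_that("a gene planted P3 in all patients qualifies as persistent", {
  an <- small_analysis()
  co <- an$cohort
  all_p3 <- names(which(rowSums(co$truth$planted_pattern == "P3") ==
                          ncol(co$truth$planted_pattern)))
  all_p3 <- intersect(all_p3, an$de$retained)
  expect_gt(length(all_p3), 0)
  persistent <- persistent_resistance_genes(an$assignments)
  expect_gt(mean(all_p3 %in% persistent), 0.9)
})

test_that("the rank-sum test matches exhaustive permutation enumeration", {
  # frozen exact example: good MP {4,4,3} vs poor {1,2,2}
  tst <- rank_sum_test(c(4, 4, 3), c(1, 2, 2))
  expect_equal(tst$method, "exact")
  expect_equal(tst$statistic, 15)
  expect_equal(tst$p_value, 0.1)

  # identical multisets are perfectly exchangeable
  expect_equal(rank_sum_test(c(1, 2, 3), c(3, 2, 1))$p_value, 1)

  # all tied instances with combined n <= 8, including heavy ties
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    nx <- sample(seq_len(n - 1), 1)
    vals <- sample(1:4, n, replace = TRUE)
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 info = paste("instance", i))
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("the per-gene response screen groups patients by pattern cluster", {
  pats <- sprintf("p%02d", 1:10)
  patients <- data.frame(patient_id = pats,
                         mp_score = c(4, 4, 3, 3, 4, 1, 2, 2, 1, 1),
                         subtype = c(rep("HR+", 8), "TNBC", "TNBC"),
                         stringsAsFactors = FALSE)
  # gene with P1 in good responders and P3/P7 in poor responders
  a <- mk_assign("gU", pats, c(rep("P1", 5), rep("P3", 3), rep("P7", 2)))
  res <- wilcoxon_response(a, patients)
  expect_equal(nrow(res), 1)
  expect_equal(res$cluster, "up")
  expect_equal(res$n_good, 5)
  expect_equal(res$n_poor, 5)
  expect_equal(res$p_value,
               oracle_ranksum_p(c(4, 4, 3, 3, 4), c(1, 2, 2, 1, 1)))
  # P5/P6 and UNCLASSIFIED patients are dropped from the test
  a2 <- mk_assign("gU", pats, c(rep("P1", 4), "P5", rep("P3", 3),
                                "UNCLASSIFIED", "P7"))
  res2 <- wilcoxon_response(a2, patients)
  expect_equal(res2$n_good + res2$n_poor, 8)
  # empty group: gene skipped
  a3 <- mk_assign("gU", pats, rep("P1", 10))
  expect_equal(nrow(wilcoxon_response(a3, patients)), 0)
  # subtype restriction drops non-matching patients
  res4 <- wilcoxon_response(a, patients, subtype = "HR+")
  expect_equal(res4$n_good + res4$n_poor, 8)
  expect_error(wilcoxon_response(a, patients, subtype = "LUMINAL"),
               "no patients")
})

test_that("resistance gene list combines the two routes", {
  wil <- data.frame(gene = c("g1", "g2", "g3"), cluster = "up",
                    n_good = 5, n_poor = 5, statistic = 1,
                    p_value = c(0.01, 0.2, 0.04), stringsAsFactors = FALSE)
  out <- resistance_gene_list(c("g4", "g1"), wil)
  expect_equal(out$bimodal_significant_genes, c("g1", "g3"))
  expect_equal(out$combined, c("g1", "g3", "g4"))
})

test_that("ratio ANOVA handles degenerate and separated groups", {
  pats <- sprintf("p%d", 1:9)
  patients <- data.frame(patient_id = pats,
                         mp_score = rep(c(1, 2, 3), each = 3),
                         stringsAsFactors = FALSE)
  fr <- data.frame(patient = pats, ratio = rep(2, 9),
                   stringsAsFactors = FALSE)
  out <- ratio_anova(fr, patients)
  expect_equal(out$f_statistic, 0)
  expect_equal(out$p_value, 1)

  fr$ratio <- c(1, 1, 1, 9, 9, 9, 9.5, 8.5, 9)
  out <- ratio_anova(fr, patients)
  expect_lt(out$p_value, 0.01)

  # two groups: F equals the square of the pooled t statistic
  patients2 <- data.frame(patient_id = pats,
                          mp_score = c(rep(1, 4), rep(3, 5)),
                          stringsAsFactors = FALSE)
  fr2 <- data.frame(patient = pats,
                    ratio = c(1.2, 0.8, 1.1, 0.9, 2.4, 2.2, 2.8, 2.0, 2.6),
                    stringsAsFactors = FALSE)
  out2 <- ratio_anova(fr2, patients2,
                      mp_groups = list(low = 1, high = 3))
  tt <- t.test(fr2$ratio[1:4], fr2$ratio[5:9], var.equal = TRUE)
  expect_equal(out2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out2$p_value, tt$p.value, tolerance = 1e-10)

  # infinite ratios are excluded by default, capped on request
  fr$ratio[1] <- Inf
  expect_message(out3 <- ratio_anova(fr, patients), "infinite")
  expect_equal(out3$n_excluded, 1L)
  out4 <- ratio_anova(fr, patients, infinite = "cap")
  expect_equal(nrow(out4$groups), 9)

  expect_error(ratio_anova(fr[1:3, ], patients), "degenerate")
})

test_that("ratio ANOVA detects the planted response association", {
  an <- small_analysis()
  fr <- pattern_fractions(an$assignments)
  out <- ratio_anova(fr, an$cohort$patients,
                     mp_groups = list(`1` = 1, `2` = 2, `3-5` = 3:5))
  expect_lt(out$p_value, 0.05)
})

test_that("log-rank on the ratio dichotomy matches a hand computation", {
  patients <- data.frame(
    patient_id = sprintf("p%d", 1:6),
    mp_score = rep(2, 6),
    rfs_years = c(1, 2, 3, 4, 5, 6),
    recurrence_event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  ratios <- setNames(c(8, 1, 9, 2, 10, 1), patients$patient_id)
  out <- km_logrank(patients, ratios, cutoff = 5)

  # independent oracle: observed-minus-expected over event times
  grp <- ratios > 5
  times <- sort(unique(patients$rfs_years[patients$recurrence_event]))
  o_minus_e <- 0; v <- 0
  for (tm in times) {
    at_risk <- patients$rfs_years >= tm
    n <- sum(at_risk); n1 <- sum(at_risk & grp)
    d <- sum(patients$rfs_years == tm & patients$recurrence_event)
    d1 <- sum(patients$rfs_years == tm & patients$recurrence_event & grp)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_oracle <- o_minus_e^2 / v
  expect_equal(out$chisq, chisq_oracle, tolerance = 1e-10)

  # identical survival in both strata: statistic 0, p 1
  dup <- rbind(patients, transform(patients,
                                   patient_id = sprintf("q%d", 1:6)))
  ratios2 <- setNames(rep(c(8, 1), each = 6), dup$patient_id)
  dup$rfs_years <- rep(patients$rfs_years, 2)
  out2 <- km_logrank(dup, ratios2, cutoff = 5)
  expect_equal(out2$chisq, 0, tolerance = 1e-12)
  expect_equal(out2$p_value, 1)

  # degenerate inputs
  no_ev <- transform(patients, recurrence_event = FALSE)
  expect_error(km_logrank(no_ev, ratios), "no recurrence events")
  expect_error(km_logrank(patients, ratios, cutoff = 100), "cutoff 100")
})

test_that("null calibration: decoupled MP gives ~5% significant genes", {
  # with mp_coupling = 0 the MP grades are independent of every gene's
  # pattern, so the per-gene screen should reject at its nominal rate
  hits <- 0; total <- 0
  for (s in 1:20) {
    co <- generate_cohort(synthetic_config(
      n_patients = 24, n_genes = 150, mp_coupling = 0,
      pattern_proportions = c(P1 = 0.5, P2 = 0.5, P3 = 0, P4 = 0, P5 = 0,
                              P6 = 0, P7 = 0, P8 = 0, FLAT = 0),
      n_pathways = 2, resistant_pathway_ids = character(0), seed = 100 + s))
    a <- data.frame(
      gene = rep(rownames(co$truth$planted_pattern), ncol(co$truth$planted_pattern)),
      patient = rep(colnames(co$truth$planted_pattern),
                    each = nrow(co$truth$planted_pattern)),
      pattern = as.vector(co$truth$planted_pattern),
      stringsAsFactors = FALSE)
    res <- wilcoxon_response(a, co$patients)
    hits <- hits + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  rate <- hits / total
  expect_gt(total, 1000)
  expect_lt(abs(rate - 0.05), 0.03)
})
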