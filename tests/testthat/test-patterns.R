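test_that("the template taxonomy has the expected structure", {
  tpl <- theoretical_templates()
  expect_equal(nrow(tpl), 8)
  expect_equal(tpl$id, paste0("P", 1:8))
  expect_equal(tpl$scenario[tpl$id %in% c("P1", "P2")],
               rep("reregulated", 2))
  expect_equal(tpl$scenario[tpl$id %in% c("P3", "P4")],
               rep("resistance", 2))
  expect_equal(tpl$scenario[tpl$id %in% c("P5", "P6")],
               rep("treatment_effect", 2))
  expect_equal(tpl$scenario[tpl$id %in% c("P7", "P8")],
               rep("worsening", 2))

  m <- as.matrix(tpl[, c("l_normal", "l_pre", "l_post")])
  # opposite-direction pairs are elementwise negations
  for (pair in list(1:2, 3:4, 5:6, 7:8)) {
    expect_equal(m[pair[1], ], -m[pair[2], ], ignore_attr = TRUE)
  }
  # no two templates are perfectly correlated
  cors <- stats::cor(t(m))
  diag(cors) <- 0
  expect_true(all(cors < 1 - 1e-12))
  # none is flat
  expect_true(all(apply(m, 1, stats::sd) > 0))
})

test_that("single-triplet assignment matches the template shapes", {
  expect_equal(assign_pattern(c(0, 2, 0)),
               list(pattern = "P1", correlation = 1))
  expect_equal(assign_pattern(c(5, 5, 5))$pattern, "UNCLASSIFIED")
  expect_true(is.na(assign_pattern(c(5, 5, 5))$correlation))
  # frozen oracle: brute-force Pearson argmax for (1, 3, 2.9) is P3
  # with correlation 0.999015
  a <- assign_pattern(c(1, 3, 2.9))
  expect_equal(a$pattern, "P3")
  expect_equal(a$correlation, 0.999015, tolerance = 1e-6)
  expect_error(assign_pattern(c(1, NA, 2)), "non-finite")
  expect_error(assign_pattern(c(1, 2)), "length 3")
})

test_that("assignment is invariant to positive affine maps and flips under negation", {
  set.seed(7)
  negation <- c(P1 = "P2", P2 = "P1", P3 = "P4", P4 = "P3",
                P5 = "P6", P6 = "P5", P7 = "P8", P8 = "P7")
  for (i in 1:200) {
    v <- rnorm(3)
    if (sd(v) < 1e-8) next
    base <- assign_pattern(v)$pattern
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 5)
    expect_identical(assign_pattern(a * v + b)$pattern, base)
    expect_identical(assign_pattern(-v)$pattern, unname(negation[base]))
  }
})

test_that("vectorized assignment equals the scalar brute-force oracle", {
  set.seed(11)
  n <- 2000
  vals <- matrix(rnorm(3 * n), ncol = 3)
  vals[1, ] <- c(3, 3, 3)   # force one flat triplet
  vstm <- vals
  rownames(vstm) <- sprintf("g%04d", seq_len(n))
  colnames(vstm) <- c("s_n", "s_pre", "s_post")
  triplets <- data.frame(patient_id = "p1", normal = "s_n", pre = "s_pre",
                         post = "s_post", stringsAsFactors = FALSE)
  res <- assign_patterns(vstm, triplets)
  oracle <- apply(vals, 1, oracle_assign)
  expect_identical(res$pattern, unname(oracle))
})

test_that("the difference-based reading agrees with a cosine oracle", {
  # oracle: cosine similarity of the two-step change vector with each
  # template's change vector, computed directly
  tm <- rbind(P1 = c(0, 1, 0), P2 = c(0, -1, 0), P3 = c(0, 1, 1),
              P4 = c(0, -1, -1), P5 = c(0, 0, -1), P6 = c(0, 0, 1),
              P7 = c(0, 1, 2), P8 = c(0, -1, -2))
  oracle_diff <- function(v) {
    dv <- diff(v)
    r <- apply(tm, 1, function(t) {
      dt <- diff(t)
      sum(dv * dt) / sqrt(sum(dv^2) * sum(dt^2))
    })
    names(r)[which.max(r)]
  }
  set.seed(17)
  for (i in 1:300) {
    v <- rnorm(3)
    expect_identical(assign_pattern(v, on = "differences")$pattern,
                     oracle_diff(v))
  }
  # exact template shapes are recovered under both readings
  for (p in rownames(tm)) {
    expect_equal(assign_pattern(tm[p, ], on = "differences")$pattern, p)
    expect_equal(assign_pattern(tm[p, ], on = "levels")$pattern, p)
  }
  # vectorized differences path equals the scalar one
  vals <- matrix(rnorm(600), ncol = 3)
  vstm <- vals
  rownames(vstm) <- sprintf("g%03d", seq_len(nrow(vals)))
  colnames(vstm) <- c("s_n", "s_pre", "s_post")
  tri <- data.frame(patient_id = "p1", normal = "s_n", pre = "s_pre",
                    post = "s_post", stringsAsFactors = FALSE)
  vec <- assign_patterns(vstm, tri, on = "differences")$pattern
  sc <- apply(vals, 1, function(v) assign_pattern(v, on = "differences")$pattern)
  expect_identical(vec, unname(sc))
})

test_that("cross-patient gene classification applies main, bimodal and floor rules", {
  # main: 60% >= 50%
  g <- classify_gene(c(rep("P3", 12), rep("P1", 5), rep("P5", 3)))
  expect_equal(g$class, "main")
  expect_equal(g$main_patterns, "P3")
  # bimodal: 40% and 35%, both >= 5 patients
  g <- classify_gene(c(rep("P1", 8), rep("P3", 7), rep("P5", 5)))
  expect_equal(g$class, "bimodal")
  expect_equal(g$main_patterns, "P1+P3")
  # 5-patient floor blocks bimodal at 40% of 10
  g <- classify_gene(c(rep("P1", 4), rep("P3", 4), rep("P5", 2)))
  expect_equal(g$class, "unclassified")
  # UNCLASSIFIED patients are excluded from the denominator
  g <- classify_gene(c(rep("P3", 3), rep("UNCLASSIFIED", 7)))
  expect_equal(g$class, "main")
  expect_equal(g$n_classified, 3)
  # strict threshold flips an exact 50% main call
  pat <- c(rep("P2", 5), rep("P4", 5))
  expect_equal(classify_gene(pat)$class, "main")
  expect_equal(classify_gene(pat, strict_main = TRUE)$class, "bimodal")
  expect_error(classify_gene(rep("UNCLASSIFIED", 3)), "no classified")
})

test_that("classification classes partition the gene list", {
  an <- small_analysis()
  cl <- classify_genes(an$assignments)
  expect_setequal(cl$gene, unique(an$assignments$gene))
  expect_true(all(cl$class %in% c("main", "bimodal", "unclassified")))
  expect_equal(anyDuplicated(cl$gene), 0L)
})

test_that("pattern fractions and the response ratio behave as specified", {
  mk <- function(patient, patterns) data.frame(
    gene = sprintf("g%03d", seq_along(patterns)), patient = patient,
    pattern = patterns, correlation = 1, stringsAsFactors = FALSE)
  a <- mk("p1", c(rep("P1", 30), rep("P2", 20), rep("P7", 5), rep("P8", 5),
                  rep("P5", 40)))
  fr <- pattern_fractions(a)
  expect_equal(fr$ratio, 5)
  expect_false(fr$ratio_infinite)
  expect_equal(fr$P1, 0.30)
  # degenerate denominator: all genes P1
  fr <- pattern_fractions(mk("p1", rep("P1", 10)))
  expect_true(is.infinite(fr$ratio))
  expect_true(fr$ratio_infinite)
  # fractions exclude UNCLASSIFIED from the denominator and sum to <= 1
  a <- mk("p1", c(rep("P1", 4), rep("UNCLASSIFIED", 6)))
  fr <- pattern_fractions(a)
  expect_equal(fr$n_classified, 4)
  expect_equal(fr$P1, 1)
})

test_that("patients with more planted dysregulation have lower ratios", {
  an <- small_analysis()
  fr <- pattern_fractions(an$assignments)
  dys <- an$cohort$truth$dysregulated_fraction[fr$patient]
  rho <- suppressWarnings(cor(fr$ratio, dys, method = "spearman"))
  expect_lt(rho, 0)
})
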