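# hand-built measures table: two genotypes, two eyes each, known values
fake_measures <- function(wt_b = c(100, 110), mut_b = c(80, 88),
                          genotype = "mdx") {
  strengths <- da_flash_strengths()
  rows <- list()
  for (f in strengths) {
    for (i in seq_along(wt_b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = paste0("w", i), eye_id = paste0("w", i, "e"),
        genotype = "WT", adaptation = "DA", flash_strength = f,
        baseline_uv = 0, a_amp_uv = NA_real_, a_it_ms = NA_real_,
        b_amp_uv = wt_b[i] * (1 + f / 10), b_it_ms = 100 + f * 10,
        op_amp_uv = wt_b[i] / 10, flags = "")
    }
    for (i in seq_along(mut_b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = paste0("m", i), eye_id = paste0("m", i, "e"),
        genotype = genotype, adaptation = "DA", flash_strength = f,
        baseline_uv = 0, a_amp_uv = NA_real_, a_it_ms = NA_real_,
        b_amp_uv = mut_b[i] * (1 + f / 10), b_it_ms = 105 + f * 10,
        op_amp_uv = mut_b[i] / 10, flags = "")
    }
  }
  do.call(rbind, rows)
}

test_that("WT self-normalization is exactly 100 percent / 0 ms", {
  m <- fake_measures()
  amp <- normalize_to_wt(m, "b_amp")
  wt_pool <- amp$pooled[amp$pooled$genotype == "WT", ]
  expect_equal(wt_pool$pooled, 100)
  per_stratum <- aggregate(norm ~ flash_strength,
                           data = amp$values[amp$values$genotype == "WT", ],
                           FUN = mean)
  expect_equal(per_stratum$norm, rep(100, 5))
  tm <- normalize_to_wt(m, "b_it")
  expect_equal(tm$pooled[tm$pooled$genotype == "WT", "pooled"], 0)
})

test_that("normalization recovers exact constructed effects", {
  # mutant at exactly 0.8 x WT mean at every strength -> pooled 80 %
  m <- fake_measures(wt_b = c(100, 110), mut_b = c(84, 84))
  amp <- normalize_to_wt(m, "b_amp")
  expect_equal(amp$pooled[amp$pooled$genotype == "mdx", "pooled"], 80)
  expect_equal(pooled_effect(m, "b_amp", "mdx"), 80)
  # uniform +5 ms shift -> pooled +5 ms
  tm <- normalize_to_wt(m, "b_it")
  expect_equal(tm$pooled[tm$pooled$genotype == "mdx", "pooled"], 5)
  # degenerate WT amplitude names the stratum
  bad <- fake_measures()
  bad$b_amp_uv[bad$genotype == "WT" & bad$flash_strength == -2.7] <- 0
  expect_error(normalize_to_wt(bad, "b_amp"), "-2.7")
})

test_that("pooling is linear in the stated sense", {
  m <- fake_measures(wt_b = c(100, 120), mut_b = c(70, 90))
  base_amp <- pooled_effect(m, "b_amp", "mdx")
  base_it <- pooled_effect(m, "b_it", "mdx")
  m2 <- m
  m2$b_amp_uv <- m2$b_amp_uv * 3          # common gain cancels in the ratio
  expect_equal(pooled_effect(m2, "b_amp", "mdx"), base_amp)
  m3 <- m
  m3$b_it_ms[m3$genotype == "mdx"] <- m3$b_it_ms[m3$genotype == "mdx"] + 2.5
  expect_equal(pooled_effect(m3, "b_it", "mdx"), base_it + 2.5)
})

test_that("eye and animal units agree on group means within sampling noise", {
  arm <- fix_small_arm("mdx2Cv", seed = 9L, n_mutant = 6L, n_wt = 6L)
  meas <- arm_measures(arm)
  by_eye <- pooled_effect(meas, "b_amp", "mdx2Cv", unit = "eye")
  by_animal <- pooled_effect(meas, "b_amp", "mdx2Cv", unit = "animal")
  expect_lt(abs(by_eye - by_animal), 2)
})

test_that("model summary table is ordered, WT-free and monotone", {
  cfg <- fix_config()
  arms <- list(
    mdx = rbind(quantify_cohort(fix_noise_free_eye("mdx"), cfg),
                quantify_cohort(fix_noise_free_eye("WT"), cfg)),
    mdx2Cv = rbind(quantify_cohort(fix_noise_free_eye("mdx2Cv"), cfg),
                   quantify_cohort(fix_noise_free_eye("WT"), cfg)),
    dmd_null = rbind(quantify_cohort(fix_noise_free_eye("dmd_null"), cfg),
                     quantify_cohort(fix_noise_free_eye("WT"), cfg)))
  tab <- summarize_models(arms, parameters = c("b_amp", "b_it"))
  expect_false("WT" %in% tab$genotype)
  expect_equal(as.character(unique(tab$genotype)),
               c("mdx", "mdx2Cv", "dmd_null"))
  b <- tab[tab$parameter == "b_amp", ]
  # progressive worsening of the pooled DA b-wave along the severity order
  expect_false(is.unsorted(rev(b$pooled)))
  # single genotype in -> single row
  one <- summarize_models(arms["mdx"], parameters = "b_amp")
  expect_equal(nrow(one), 1L)
})

test_that("two-way mixed ANOVA takes the documented decision tree", {
  # identical groups relabeled: genotype effect is null by construction
  cfg <- fix_config()
  wt <- quantify_cohort(generate_cohort(
    cohort_spec("WT", 6L, seed = 3L)), cfg)
  relab <- wt
  relab$genotype <- "mdx"
  relab$animal_id <- paste0("r", relab$animal_id)
  relab$eye_id <- paste0("r", relab$eye_id)
  null_cmp <- compare_groups_da(rbind(wt, relab), "b_amp")
  expect_gt(null_cmp$p_genotype, 0.5)
  expect_equal(null_cmp$design, "two_way_mixed")
  # real contrast: strong genotype and flash-strength effects, recorded trail
  arm <- fix_small_arm("dmd_null", seed = 5L, n_mutant = 8L, n_wt = 8L)
  cmp <- compare_groups_da(arm_measures(arm), "b_amp", unit = "animal")
  expect_lt(cmp$p_genotype, 0.001)
  expect_lt(cmp$p_within, 0.001)
  expect_true(cmp$correction %in% c("none", "greenhouse_geisser",
                                    "huynh_feldt"))
  if (cmp$correction != "none") {
    expect_lt(cmp$sphericity_p, 0.05)
    expect_equal(cmp$posthoc_method, "bonferroni")
  }
  expect_true(all(c(cmp$p_genotype, cmp$p_within, cmp$p_interaction) >= 0 &
                    c(cmp$p_genotype, cmp$p_within, cmp$p_interaction) <= 1))
  # incomplete within-subject series raise, never imputed
  broken <- arm_measures(arm)
  drop_row <- which(broken$adaptation == "DA" &
                      broken$flash_strength == -0.7)[1]
  expect_error(compare_groups_da(broken[-drop_row, ], "b_amp"),
               "incomplete")
})

test_that("one-way LA comparison routes through Levene correctly", {
  set.seed(33)
  base <- data.frame(
    animal_id = sprintf("a%02d", 1:40), eye_id = sprintf("e%02d", 1:40),
    genotype = rep(c("WT", "mdx"), each = 20), adaptation = "LA",
    flash_strength = 0.3, baseline_uv = 0, a_amp_uv = NA_real_,
    a_it_ms = NA_real_, b_it_ms = 30, op_amp_uv = NA_real_, flags = "")
  # equal variances, equal means: plain ANOVA path, Tukey, p > 0.05
  base$b_amp_uv <- 100 + rnorm(40, sd = 5)
  eq <- compare_groups_la(base, "la_b_amp")
  expect_equal(eq$correction, "none")
  expect_equal(eq$posthoc_method, "tukey")
  expect_gt(eq$p_genotype, 0.05)
  # one group with ~10x the SD: Welch + Games-Howell path
  het <- base
  het$b_amp_uv[het$genotype == "mdx"] <- 100 + rnorm(20, sd = 50)
  wl <- compare_groups_la(het, "la_b_amp")
  expect_equal(wl$correction, "welch")
  expect_equal(wl$posthoc_method, "games_howell")
  expect_lt(wl$levene_p, 0.05)
  expect_true(all(wl$posthoc$p >= 0 & wl$posthoc$p <= 1))
})

test_that("Games-Howell agrees with Welch t for two groups", {
  set.seed(8)
  x <- rnorm(12, 0, 1)
  y <- rnorm(20, 1.2, 4)
  gh <- games_howell(c(x, y), rep(c("A", "B"), c(12L, 20L)))
  wt <- t.test(x, y)  # Welch
  # for k = 2 the studentized-range p equals the two-sided Welch t p
  expect_equal(gh$p, wt$p.value, tolerance = 1e-10)
})
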