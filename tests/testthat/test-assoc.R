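test_that("association fits recover exact linear structure", {
  set.seed(3)
  d <- tibble::tibble(
    cvr = rnorm(50, 0.2, 0.05),
    age = rnorm(50, 75, 4),
    sex = sample(c("female", "male"), 50, replace = TRUE)
  )
  d$y <- 2 * d$cvr
  # effect sizes are undefined at R^2 = 1 (cohens_f2 errors there by design)
  fit <- suppressWarnings(
    fit_association(d, "y", "cvr", c("age", "sex"), effect_sizes = FALSE)
  )
  co <- coef(fit$model)
  expect_equal(co[["cvr"]], 2, tolerance = 1e-9)
  expect_equal(co[["age"]], 0, tolerance = 1e-9)
  row <- suppressWarnings(association_row(fit)) # perfect-fit summary warning
  expect_true(row$conf_low <= row$beta && row$beta <= row$conf_high)
  expect_error(fit_association(d, "y", "cvr", c("cvr", "age")),
               "cannot also be a covariate")
  expect_error(fit_association(d[1:3, ], "y", "cvr", c("age", "sex")),
               "Too few complete cases")
})

test_that("association CIs and p-values match the lm/confint oracle", {
  coh <- simulate_cohort(cohort_spec(n_participants = 80), seed = 21)
  d <- wave2_frame(coh)
  fit <- fit_association(d, "fa_fornix", "cvr_left_hippocampus",
                         c("age_wave2", "sex"))
  ref <- lm(fa_fornix ~ cvr_left_hippocampus + age_wave2 + sex, data = d)
  row <- association_row(fit)
  expect_equal(row$beta, unname(coef(ref)["cvr_left_hippocampus"]))
  expect_equal(c(row$conf_low, row$conf_high),
               unname(confint(ref)["cvr_left_hippocampus", ]))
  expect_equal(row$p,
               summary(ref)$coefficients["cvr_left_hippocampus", 4])
  sw <- shapiro.test(residuals(ref))
  expect_equal(row$shapiro_w, unname(sw$statistic))
  expect_equal(row$shapiro_p, sw$p.value)
})

test_that("Cohen's f2 follows the R-squared formulas", {
  expect_equal(cohens_f2(0.5), 1)
  expect_equal(cohens_f2(0), 0)
  expect_equal(cohens_f2(0.20, 0.17), 0.03 / 0.8, tolerance = 1e-12)
  expect_error(cohens_f2(1), "\\[0, 1\\)")
  expect_error(cohens_f2(0.3, 0.4), "r2_full")

  # per-predictor f2 equals the overall f2 for a single-predictor model
  set.seed(4)
  d <- tibble::tibble(x = rnorm(40), y = rnorm(40) + 0.5 * rnorm(40))
  d$y <- 0.8 * d$x + rnorm(40)
  fit <- fit_association(d, "y", "x")
  expect_equal(fit$f2_predictors$f2[fit$f2_predictors$term == "x"],
               fit$f2_overall, tolerance = 1e-12)
})

test_that("bh_adjust implements the step-up rule", {
  # equal p-values are a fixed point
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # adjusted >= raw, capped at 1
  set.seed(5)
  p <- runif(10)
  a <- bh_adjust(p)
  expect_true(all(a >= p - 1e-12))
  expect_true(all(a <= 1))
  # agreement with the independent stats oracle
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
  # monotone: raising a raw p never lowers any adjusted p
  p <- c(0.01, 0.04, 0.3, 0.8)
  a1 <- bh_adjust(p)
  p2 <- p; p2[2] <- 0.2
  a2 <- bh_adjust(p2)
  expect_true(all(a2 >= a1 - 1e-12))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  # ties share identical adjusted values
  a3 <- bh_adjust(c(0.02, 0.02, 0.5))
  expect_equal(a3[1], a3[2])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the association suite has the published table structure", {
  coh <- simulate_cohort(cohort_spec(n_participants = 60), seed = 30)
  res <- run_association_suite(coh, design = "cross_sectional")
  expect_equal(nrow(res), 19) # 2 GMV + 16 tract + 1 WMH
  expect_equal(sum(res$domain == "wm"), 16)
  # GMV and WMH rows carry no adjusted p (single tests)
  expect_true(all(is.na(res$p_corr[res$domain %in% c("gmv", "wmh")])))
  # within-family correction matches bh_adjust on those four p-values
  for (fam in c("fa", "md", "rd", "l1")) {
    rows <- res[res$family %in% fam, ]
    expect_equal(rows$p_corr, bh_adjust(rows$p))
    expect_true(all(rows$p_corr >= rows$p - 1e-12))
  }
  # side-matched exposures for the GMV models, bilateral average elsewhere
  expect_equal(res$exposure[res$outcome == "gmv_left_hippocampus"],
               "cvr_left_hippocampus")
  expect_equal(unique(res$exposure[res$domain == "wm"]), "cvr_hippocampal")
  expect_s3_class(autoplot(res), "ggplot")

  long <- run_association_suite(coh, design = "longitudinal")
  expect_equal(nrow(long), 19)
  expect_true(all(grepl("^delta_", long$outcome)))

  wb <- run_association_suite(coh, design = "cross_sectional",
                              exposure = "whole_brain")
  expect_equal(unique(wb$exposure[wb$domain == "wm"]), "cvr_whole_brain")

  expect_error(run_association_suite(list(participants = coh$participants[, 1:3],
                                          measurements = coh$measurements)),
               "Missing participant columns")
})

test_that("a planted longitudinal effect surfaces in longitudinal rows only", {
  eff <- 6 # annual-change units per (%/mmHg): a large planted effect
  spec <- cohort_spec(
    n_participants = 154,
    longitudinal_effect = c(fa_corpus_callosum = eff * 0.03 / 8.7)
  )
  coh <- simulate_cohort(spec, seed = 77)
  long <- run_association_suite(coh, design = "longitudinal")
  target_long <- long[long$family %in% "fa" &
                        long$tract %in% "corpus_callosum", ]
  expect_lt(target_long$p_corr, 0.05)
  expect_gt(target_long$beta, 0)
  # unaffected longitudinal families stay mostly null
  other <- long[long$domain == "wm" &
                  !(long$family == "fa" & long$tract == "corpus_callosum"), ]
  expect_lt(mean(other$p < 0.05), 0.4)
})
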