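test_that("paired t-test matches the closed-form textbook computation", {
  r <- paired_t_test(c(1, 2, 4), c(2, 2, 5))
  expect_equal(r$mean_diff, -2 / 3, tolerance = 1e-12)
  expect_equal(r$t, -2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  o <- paired_t_oracle(c(1, 2, 4), c(2, 2, 5))
  expect_equal(r$p, o$p, tolerance = 1e-12)

  set.seed(19)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- paired_t_test(a, b)
    want <- paired_t_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$mean_diff, want$mean_diff, tolerance = 1e-12)
  }
})

test_that("degenerate paired inputs are rejected", {
  x <- c(1, 2, 3)
  expect_error(paired_t_test(x, x), class = "anoscore_degenerate_test")
  # constant shift also has zero difference variance
  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)),
               class = "anoscore_degenerate_test")
  expect_error(paired_t_test(c(1, NA), c(2, 3)),
               class = "anoscore_degenerate_test")
  # missing pairs are dropped, not imputed
  r <- paired_t_test(c(1, 2, 4, NA), c(2, 2, 5, 0))
  expect_equal(r$n, 3)
})

test_that("trajectory classification covers its documented patterns", {
  expect_identical(classify_trajectory(5, 3, 1), "decreasing")
  expect_identical(classify_trajectory(1, 3, 5), "increasing")
  expect_identical(classify_trajectory(1, 3, 2), "inc_dec")
  expect_identical(classify_trajectory(3, 1, 2), "dec_inc")
  expect_identical(classify_trajectory(1, 1.05, 1), "flat")
  # exhaustive and mutually exclusive over a grid of inputs
  vals <- c(-0.3, -0.05, 0, 0.05, 0.3)
  for (d1 in vals) for (d2 in vals) {
    got <- classify_trajectory(1, 1 + d1, 1 + d1 + d2, tol = 0.1)
    expect_true(got %in% c("decreasing", "increasing", "inc_dec", "dec_inc",
                           "flat"))
  }
})

test_that("the mixed model recovers a noise-free cohort exactly", {
  truth <- c(intercept = -2.39, days = 0.004, recon_expander = 2.223,
             frac_hypo = 0.485, frac_hypo_x_days = -0.001,
             mast_nsm_ssm = -0.309, scl = 1.094, imn = -0.229, boost = 0.909,
             plan_imrt = -0.186, complication = 0.077, age = 0.073,
             bmi_gt23 = 0.570)
  co <- generate_cohort(cohort_gen_spec(n_patients = 80, fixed_effects = truth,
                                        random_intercept_sd = 0,
                                        residual_sd = 0, seed = 4))
  fit <- fit_lme(co)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[names(truth)], truth, tolerance = 1e-6)
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$estimate))
  expect_true(all(fit$coefficients$estimate <= fit$coefficients$ci_high))
})

test_that("the mixed model requires repeated measures on several patients", {
  co <- generate_cohort(cohort_gen_spec(n_patients = 5, seed = 2))
  single <- co[co$patient_id == "pt_0001", ]
  expect_error(fit_lme(single), class = "anoscore_insufficient_data")
})

test_that("rank-deficient designs are rejected naming the collinear term", {
  co <- generate_cohort(cohort_gen_spec(n_patients = 30, seed = 6))
  co$scl <- co$imn  # perfectly collinear covariates
  expect_error(fit_lme(co), class = "anoscore_rank_deficient")
  expect_error(fit_lme(co), "imn|scl")
})

test_that("days-after-RT recovery across replicate cohorts is unbiased", {
  rec <- run_recovery(truth = c(days = 0.004), n_patients = 100, n_reps = 8,
                      random_intercept_sd = 1, residual_sd = 0.5, seed = 21)
  s <- rec$summary[rec$summary$term == "days", ]
  expect_lt(abs(s$mean_estimate - 0.004), 2 * s$mc_se)
})

test_that("contrast prediction follows the delta-method arithmetic", {
  terms <- c("recon_expander", "recon_expander_x_days")
  fit <- structure(list(
    coefficients = data.frame(term = terms, estimate = c(2.0, 0.001),
                              std_error = c(0.5, 0.0005),
                              ci_low = NA, ci_high = NA, p_value = NA),
    vcov = matrix(c(0.25, 0, 0, 2.5e-7), 2, 2, dimnames = list(terms, terms)),
    converged = TRUE), class = "lme_fit")
  got <- predict_contrasts(fit, c(0, 500))
  # at day 0 the interaction vanishes: estimate equals the main effect
  expect_identical(got$estimate[1], 2.0)
  expect_equal(got$estimate[2], 2.5, tolerance = 1e-12)
  expect_true(all(got$ci_low <= got$estimate & got$estimate <= got$ci_high))
  # zero interaction: the contrast is constant over days
  fit0 <- fit
  fit0$coefficients$estimate[2] <- 0
  flat <- predict_contrasts(fit0, c(0, 180, 720))
  expect_true(all(flat$estimate == flat$estimate[1]))
  expect_error(predict_contrasts(fit, 0, contrast = c("recon_expander", "absent")),
               class = "anoscore_missing_term")
})

test_that("run_analysis produces the full bundle and is byte-deterministic", {
  co <- generate_cohort(cohort_gen_spec(
    n_patients = 60,
    fixed_effects = c(intercept = 1, days = 0.004, recon_expander = 2.2),
    seed = 14))
  d1 <- file.path(tempdir(), "an1"); d2 <- file.path(tempdir(), "an2")
  b <- run_analysis(co, out_dir = d1)
  run_analysis(co, out_dir = d2)
  for (f in c("pairwise_tests.csv", "trajectories.csv", "contrasts.csv",
              "lme_fit.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
  expect_s3_class(b$lme, "lme_fit")
  expect_true(all(c("overall", "complication", "recon_type") %in%
                    b$pairwise$stratum))
  expect_equal(nrow(b$trajectories), 60)
  expect_true(all(b$contrasts$contrast %in%
                    c("recon_expander_vs_autologous", "hypo_vs_conventional")))
  # a strong expander effect shows up in the stratified means at every visit
  for (v in c("pre_rt", "post_1y", "post_2y")) {
    m_exp <- mean(co$as_value[co$visit == v & co$recon_type == "expander"])
    m_aut <- mean(co$as_value[co$visit == v & co$recon_type == "autologous"])
    expect_gt(m_exp, m_aut)
  }
})

test_that("an all-identical cohort reports degenerate paired tests rather than failing", {
  co <- generate_cohort(cohort_gen_spec(n_patients = 20,
                                        fixed_effects = c(intercept = 2),
                                        random_intercept_sd = 0.5,
                                        residual_sd = 0, seed = 3))
  # residual_sd = 0: within-patient differences are exactly zero
  wide_diffs_zero <- all(tapply(co$as_value, co$patient_id, function(x) sd(x) == 0))
  expect_true(wide_diffs_zero)
  pw <- anoscore:::pairwise_block(
    data.frame(patient_id = unique(co$patient_id),
               pre_rt = co$as_value[co$visit == "pre_rt"],
               post_1y = co$as_value[co$visit == "post_1y"],
               post_2y = co$as_value[co$visit == "post_2y"]),
    "overall", "all")
  expect_true(all(is.na(pw$p_value)))
  expect_true(all(nzchar(pw$note)))
})
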