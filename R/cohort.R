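# canonical fixed-effect names of the longitudinal model
lme_terms <- function() {
  c("intercept", "days", "recon_expander", "recon_expander_x_days",
    "frac_hypo", "frac_hypo_x_days", "mast_nsm_ssm", "scl", "imn", "boost",
    "plan_imrt", "complication", "age", "bmi_gt23")
}

# reported cohort marginals used as simulation defaults: tissue expander
# 23.0%, hypofractionation 13.1%, NSM/SSM 36.0%, boost 19.7%, IMRT 21.3%,
# major complication 16.4%, BMI > 23 47.5%; nodal-irradiation covariates are
# not tabulated and default to 0.5
default_marginals <- function() {
  list(expander = 0.23, hypo = 0.131, nsm_ssm = 0.36, scl = 0.5, imn = 0.5,
       boost = 0.197, imrt = 0.213, complication = 0.164, bmi_gt23 = 0.475)
}

#' Specification for a simulated longitudinal cohort
#'
#' Describes the generating random-intercept linear model for anomaly-score
#' trajectories: per-patient covariates drawn from marginal probabilities,
#' visit days drawn from the follow-up timing distribution (1-year CT
#' uniform over days 343--512, 2-year CT uniform over days 741--951 --- the
#' reported interquartile ranges), age uniform over 30--70 years (centred at
#' 50 in the linear predictor), a patient random intercept
#' `b_i ~ N(0, random_intercept_sd^2)` and residual
#' `e_ij ~ N(0, residual_sd^2)`.
#'
#' @param n_patients number of patients (3 visits each).
#' @param fixed_effects named numeric vector/list of generating coefficients;
#'   names must come from the model's covariate set (see
#'   [fit_lme()]); unspecified coefficients are 0.
#' @param random_intercept_sd SD of the patient random intercept (AS units).
#' @param residual_sd SD of the visit-level residual (AS units).
#' @param visit_day_sampler list with `post_1y` and `post_2y` ranges
#'   (uniform sampling bounds in days).
#' @param covariate_marginals named list of Bernoulli probabilities for the
#'   binary covariates (defaults follow the reported cohort).
#' @param seed integer seed.
#' @return An object of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_patients = 61,
                            fixed_effects = c(intercept = -2.390, days = 0.004,
                                              recon_expander = 2.223,
                                              frac_hypo = 0.485,
                                              frac_hypo_x_days = -0.001,
                                              mast_nsm_ssm = -0.309,
                                              scl = 1.094, imn = -0.229,
                                              boost = 0.909, plan_imrt = -0.186,
                                              complication = 0.077,
                                              age = 0.073, bmi_gt23 = 0.570),
                            random_intercept_sd = 1.5,
                            residual_sd = 1.0,
                            visit_day_sampler = list(post_1y = c(343, 512),
                                                     post_2y = c(741, 951)),
                            covariate_marginals = default_marginals(),
                            seed = 1L) {
  stopifnot(is_count(n_patients, 1),
            random_intercept_sd >= 0, residual_sd >= 0)
  fe <- unlist(fixed_effects)
  bad <- setdiff(names(fe), lme_terms())
  if (length(bad)) {
    stop_named("anoscore_unknown_coefficient",
               "unknown coefficient name(s): ", paste(bad, collapse = ", "),
               "; valid names: ", paste(lme_terms(), collapse = ", "))
  }
  cm <- utils::modifyList(default_marginals(), as.list(covariate_marginals))
  pr <- unlist(cm)
  if (any(pr < 0 | pr > 1)) {
    stop("covariate marginals must be probabilities in [0, 1]")
  }
  stopifnot(visit_day_sampler$post_1y[1] > 0,
            visit_day_sampler$post_2y[1] >= visit_day_sampler$post_1y[2])
  beta <- stats::setNames(numeric(length(lme_terms())), lme_terms())
  beta[names(fe)] <- fe
  structure(list(n_patients = as.integer(n_patients), fixed_effects = beta,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd,
                 visit_day_sampler = visit_day_sampler,
                 covariate_marginals = cm, seed = as.integer(seed)),
            class = "cohort_gen_spec")
}

#' Simulate a longitudinal anomaly-score cohort
#'
#' Generates three rows per patient (visits `pre_rt` at day 0, `post_1y`,
#' `post_2y`) with
#' `AS_ij = intercept + sum_k beta_k x_ijk + b_i + e_ij`. Age enters the
#' linear predictor centred at 50 years. The simulated random intercepts are
#' attached as `attr(, "random_intercepts")`.
#'
#' @param spec a [cohort_gen_spec()].
#' @return A data.frame cohort table (class `cohort_table`): one row per
#'   (patient, visit) with columns `patient_id`, `visit`, `day`,
#'   `recon_type`, `fractionation`, `mastectomy`, `scl`, `imn`, `boost`,
#'   `plan`, `complication`, `age`, `bmi_gt23`, `as_value`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  n <- spec$n_patients
  beta <- spec$fixed_effects
  cm <- spec$covariate_marginals
  with_seed(spec$seed, {
    recon <- ifelse(stats::runif(n) < cm$expander, "expander", "autologous")
    frac <- ifelse(stats::runif(n) < cm$hypo, "hypo", "conventional")
    mast <- ifelse(stats::runif(n) < cm$nsm_ssm, "nsm_ssm", "total_radical")
    scl <- as.integer(stats::runif(n) < cm$scl)
    imn <- as.integer(stats::runif(n) < cm$imn)
    boost <- as.integer(stats::runif(n) < cm$boost)
    plan <- ifelse(stats::runif(n) < cm$imrt, "imrt", "3d")
    compl <- as.integer(stats::runif(n) < cm$complication)
    age <- stats::runif(n, 30, 70)
    bmi <- as.integer(stats::runif(n) < cm$bmi_gt23)
    d1 <- stats::runif(n, spec$visit_day_sampler$post_1y[1],
                       spec$visit_day_sampler$post_1y[2])
    d2 <- stats::runif(n, spec$visit_day_sampler$post_2y[1],
                       spec$visit_day_sampler$post_2y[2])
    b_i <- stats::rnorm(n, 0, spec$random_intercept_sd)

    visit <- rep(c("pre_rt", "post_1y", "post_2y"), times = n)
    pid <- rep(sprintf("pt_%04d", seq_len(n)), each = 3)
    day <- as.vector(rbind(0, d1, d2))
    idx <- rep(seq_len(n), each = 3)

    x_exp <- as.integer(recon[idx] == "expander")
    x_hypo <- as.integer(frac[idx] == "hypo")
    mu <- beta["intercept"] +
      beta["days"] * day +
      beta["recon_expander"] * x_exp +
      beta["recon_expander_x_days"] * x_exp * day +
      beta["frac_hypo"] * x_hypo +
      beta["frac_hypo_x_days"] * x_hypo * day +
      beta["mast_nsm_ssm"] * as.integer(mast[idx] == "nsm_ssm") +
      beta["scl"] * scl[idx] +
      beta["imn"] * imn[idx] +
      beta["boost"] * boost[idx] +
      beta["plan_imrt"] * as.integer(plan[idx] == "imrt") +
      beta["complication"] * compl[idx] +
      beta["age"] * (age[idx] - 50) +
      beta["bmi_gt23"] * bmi[idx]
    eps <- stats::rnorm(3L * n, 0, spec$residual_sd)
    as_value <- as.numeric(mu + b_i[idx] + eps)

    out <- data.frame(patient_id = pid, visit = visit, day = day,
                      recon_type = recon[idx], fractionation = frac[idx],
                      mastectomy = mast[idx], scl = scl[idx], imn = imn[idx],
                      boost = boost[idx], plan = plan[idx],
                      complication = compl[idx], age = age[idx],
                      bmi_gt23 = bmi[idx], as_value = as_value,
                      stringsAsFactors = FALSE)
    attr(out, "random_intercepts") <- b_i
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a cohort table.
#' @param path CSV path.
#' @return `read_cohort_csv` returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
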