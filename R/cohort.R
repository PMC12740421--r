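#' Specify a synthetic case-control cohort
#'
#' Builds the parameter object for [generate_cohort()]. Defaults reproduce the
#' sample-characteristics table of a 358-case / 200-control COPD cohort:
#' group-conditional Gaussians for age, FEV1/FVC, smoking years, PM2.5 and
#' exposure years (mean, sd), and Bernoulli prevalences for sex, smoking and
#' a binary SERPINA1-variant susceptibility flag.
#'
#' Disease-stage structure is injected by construction: among cases a
#' `stage_mix` multinomial assigns mild/moderate/severe, and `fev1_stage_shift`
#' moves FEV1/FVC by stage. The default shifts are mean-zero under the default
#' stage mix, and the within-stage sd is shrunk so the marginal COPD-group
#' mean and sd still match the group parameters. Per-modality signal can be
#' restricted to a subgroup (`image_signal_group`, `env_signal_group`) or
#' switched off (`lungfunc_signal`) to build cohorts for gating-recovery
#' experiments.
#'
#' @param n_copd,n_control Group sizes (non-negative integers).
#' @param age_copd,age_control,fev1_fvc_copd,fev1_fvc_control,smoking_years_copd,smoking_years_control,pm25_copd,pm25_control,exposure_years_copd,exposure_years_control
#'   Length-2 numeric `c(mean, sd)` per group. Units: years, %, ug/m3.
#' @param male_frac_copd,male_frac_control,smoking_prev_copd,smoking_prev_control,gene_prev_copd,gene_prev_control
#'   Fractions in `[0, 1]`.
#' @param stage_mix Named proportions over mild/moderate/severe; must sum to 1.
#' @param pm25_smoker_shift Additive shift (ug/m3) of the PM2.5 mean for
#'   smokers in both groups; exposure tracks smoking in realistic cohorts,
#'   and a nonzero shift makes the clinical condition genuinely predictive
#'   of the environmental variables (which conditional imputation relies
#'   on).
#' @param fev1_stage_shift Named additive FEV1/FVC offsets (%) per stage.
#' @param image_signal_group,env_signal_group Which patients carry the
#'   modality's disease signal: `"all"`, `"smoker"`, `"nonsmoker"` or `"none"`.
#' @param lungfunc_signal If `FALSE`, FEV1/FVC is drawn from the control
#'   distribution for every patient (lung function carries no label signal).
#' @param env_missing_rate Fraction of records whose environmental variables
#'   are masked at generation time (missing completely at random).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [mask_environment()]
#' @export
cohort_spec <- function(n_copd = 358L, n_control = 200L,
                        age_copd = c(65.3, 8.7), age_control = c(63.1, 7.9),
                        male_frac_copd = 214 / 358, male_frac_control = 112 / 200,
                        fev1_fvc_copd = c(58.4, 6.2), fev1_fvc_control = c(75.6, 4.8),
                        smoking_prev_copd = 0.788, smoking_prev_control = 0.225,
                        smoking_years_copd = c(35.2, 18.5), smoking_years_control = c(4.5, 2.1),
                        pm25_copd = c(42.5, 11.3), pm25_control = c(28.6, 8.7),
                        exposure_years_copd = c(15.4, 5.2), exposure_years_control = c(10.1, 4.8),
                        gene_prev_copd = 0.249, gene_prev_control = 0.060,
                        stage_mix = c(mild = 0.4, moderate = 0.4, severe = 0.2),
                        fev1_stage_shift = c(mild = 4, moderate = 0, severe = -8),
                        pm25_smoker_shift = 0,
                        image_signal_group = "all",
                        env_signal_group = "all",
                        lungfunc_signal = TRUE,
                        env_missing_rate = 0,
                        seed = 20177L) {
  spec <- list(
    n_copd = n_copd, n_control = n_control,
    age_copd = age_copd, age_control = age_control,
    male_frac_copd = male_frac_copd, male_frac_control = male_frac_control,
    fev1_fvc_copd = fev1_fvc_copd, fev1_fvc_control = fev1_fvc_control,
    smoking_prev_copd = smoking_prev_copd, smoking_prev_control = smoking_prev_control,
    smoking_years_copd = smoking_years_copd, smoking_years_control = smoking_years_control,
    pm25_copd = pm25_copd, pm25_control = pm25_control,
    exposure_years_copd = exposure_years_copd, exposure_years_control = exposure_years_control,
    gene_prev_copd = gene_prev_copd, gene_prev_control = gene_prev_control,
    stage_mix = stage_mix, fev1_stage_shift = fev1_stage_shift,
    pm25_smoker_shift = pm25_smoker_shift,
    image_signal_group = image_signal_group,
    env_signal_group = env_signal_group,
    lungfunc_signal = isTRUE(lungfunc_signal),
    env_missing_rate = env_missing_rate,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != round(x))
      stop("`", nm, "` must be a single non-negative integer", call. = FALSE)
  }
  chk_count(spec$n_copd, "n_copd")
  chk_count(spec$n_control, "n_control")
  for (nm in c("age_copd", "age_control", "fev1_fvc_copd", "fev1_fvc_control",
               "smoking_years_copd", "smoking_years_control",
               "pm25_copd", "pm25_control",
               "exposure_years_copd", "exposure_years_control")) {
    v <- spec[[nm]]
    if (length(v) != 2L || any(!is.finite(v)))
      stop("`", nm, "` must be c(mean, sd)", call. = FALSE)
    if (v[2] <= 0) stop("`", nm, "` sd must be > 0", call. = FALSE)
  }
  for (nm in c("male_frac_copd", "male_frac_control", "smoking_prev_copd",
               "smoking_prev_control", "gene_prev_copd", "gene_prev_control",
               "env_missing_rate")) {
    v <- spec[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a fraction in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(spec$stage_mix), c("mild", "moderate", "severe")))
    stop("`stage_mix` must be named mild/moderate/severe", call. = FALSE)
  if (any(spec$stage_mix < 0) || abs(sum(spec$stage_mix) - 1) > 1e-8)
    stop("`stage_mix` must be non-negative and sum to 1", call. = FALSE)
  if (!setequal(names(spec$fev1_stage_shift), c("mild", "moderate", "severe")))
    stop("`fev1_stage_shift` must be named mild/moderate/severe", call. = FALSE)
  for (nm in c("image_signal_group", "env_signal_group")) {
    if (!spec[[nm]] %in% c("all", "smoker", "nonsmoker", "none"))
      stop("`", nm, "` must be one of all/smoker/nonsmoker/none", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_copd, " COPD / ", x$n_control, " control, seed ",
      x$seed, "\n", sep = "")
  cat("  FEV1/FVC: ", x$fev1_fvc_copd[1], "+/-", x$fev1_fvc_copd[2], " vs ",
      x$fev1_fvc_control[1], "+/-", x$fev1_fvc_control[2], " %\n", sep = "")
  cat("  PM2.5:    ", x$pm25_copd[1], "+/-", x$pm25_copd[2], " vs ",
      x$pm25_control[1], "+/-", x$pm25_control[2], " ug/m3\n", sep = "")
  invisible(x)
}

# Inverse-CDF truncated-normal draw; exact and vectorized, so the cohort is
# byte-reproducible from the seed without rejection loops.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

stage_levels <- c("none", "mild", "moderate", "severe")

#' Generate a synthetic multimodal COPD cohort
#'
#' Draws one patient record per row from the group-conditional distributions
#' in a [cohort_spec()]: binary COPD/control label, disease stage among cases,
#' demographics, smoking history, FEV1/FVC (%), PM2.5 exposure and exposure
#' years, and a binary gene-variant flag. Continuous physiologic variables are
#' truncated Gaussians (FEV1/FVC to (0, 100], non-negative variables to
#' [0, Inf)); binary traits are Bernoulli. The same spec (which carries its
#' seed) always yields an identical tibble.
#'
#' Columns `image_informative` / `env_informative` record whether that
#' patient's image texture, respectively environmental exposure, carries the
#' disease signal (controlled by the spec's signal-group switches); the image
#' renderer and downstream experiments honour them.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; if given, `cohort.csv` (and nothing else) is
#'   written there via [write_cohort()].
#' @return A tibble with one row per patient and class `lungfuse_cohort`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_copd = 20, n_control = 10, seed = 1))
#' dplyr::count(coh, label, stage)
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  set.seed(spec$seed)

  n <- spec$n_copd + spec$n_control
  label <- rep(c("COPD", "control"), c(spec$n_copd, spec$n_control))
  is_case <- label == "COPD"

  draw_group <- function(par_case, par_ctrl, lower = -Inf, upper = Inf) {
    m <- ifelse(is_case, par_case[1], par_ctrl[1])
    s <- ifelse(is_case, par_case[2], par_ctrl[2])
    rtruncnorm(n, m, s, lower, upper)
  }

  stage <- rep("none", n)
  if (spec$n_copd > 0) {
    stage[is_case] <- sample(names(spec$stage_mix), spec$n_copd,
                             replace = TRUE, prob = spec$stage_mix)
  }

  age <- draw_group(spec$age_copd, spec$age_control, lower = 18)
  sex <- ifelse(stats::runif(n) < ifelse(is_case, spec$male_frac_copd,
                                         spec$male_frac_control),
                "male", "female")
  smoker <- stats::runif(n) < ifelse(is_case, spec$smoking_prev_copd,
                                     spec$smoking_prev_control)
  smoking_years <- ifelse(
    smoker,
    draw_group(spec$smoking_years_copd, spec$smoking_years_control, lower = 0),
    0
  )

  # FEV1/FVC: stage shifts are applied within the COPD group with the
  # within-stage sd deflated so the marginal group moments still match the
  # spec's (mean, sd). If the shifts' variance under the mix exceeds the
  # group variance the shifts are used as-is with the full sd.
  fev_par_case <- if (spec$lungfunc_signal) spec$fev1_fvc_copd else spec$fev1_fvc_control
  shift <- spec$fev1_stage_shift[stage]
  shift[is.na(shift)] <- 0
  if (spec$lungfunc_signal && spec$n_copd > 0) {
    mix <- spec$stage_mix
    sh <- spec$fev1_stage_shift[names(mix)]
    mu_b <- sum(mix * sh)
    var_b <- sum(mix * (sh - mu_b)^2)
    sd_within <- sqrt(max(fev_par_case[2]^2 - var_b, 1e-6))
  } else {
    sd_within <- fev_par_case[2]
    shift[] <- 0
  }
  fev_mean <- ifelse(is_case, fev_par_case[1] + shift, spec$fev1_fvc_control[1])
  fev_sd <- ifelse(is_case, sd_within, spec$fev1_fvc_control[2])
  fev1_fvc <- rtruncnorm(n, fev_mean, fev_sd, lower = 1e-6, upper = 100)

  in_group <- function(which) switch(which,
    all = rep(TRUE, n), smoker = smoker, nonsmoker = !smoker,
    none = rep(FALSE, n))
  env_informative <- in_group(spec$env_signal_group)
  image_informative <- in_group(spec$image_signal_group)

  # Non-informative env records are drawn from the pooled (midpoint)
  # distribution so PM2.5 carries no label signal for them.
  pm_pool <- (spec$pm25_copd + spec$pm25_control) / 2
  ey_pool <- (spec$exposure_years_copd + spec$exposure_years_control) / 2
  pm_mean <- ifelse(env_informative,
                    ifelse(is_case, spec$pm25_copd[1], spec$pm25_control[1]),
                    pm_pool[1])
  pm_sd <- ifelse(env_informative,
                  ifelse(is_case, spec$pm25_copd[2], spec$pm25_control[2]),
                  pm_pool[2])
  shift_pm <- spec$pm25_smoker_shift %||% 0
  pm25 <- rtruncnorm(n, pm_mean + shift_pm * smoker, pm_sd, lower = 0)
  ey_mean <- ifelse(env_informative,
                    ifelse(is_case, spec$exposure_years_copd[1],
                           spec$exposure_years_control[1]),
                    ey_pool[1])
  ey_sd <- ifelse(env_informative,
                  ifelse(is_case, spec$exposure_years_copd[2],
                         spec$exposure_years_control[2]),
                  ey_pool[2])
  exposure_years <- rtruncnorm(n, ey_mean, ey_sd, lower = 0)

  gene_variant <- stats::runif(n) < ifelse(is_case, spec$gene_prev_copd,
                                           spec$gene_prev_control)

  cohort <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    label = factor(label, levels = c("control", "COPD")),
    stage = factor(stage, levels = stage_levels),
    age = age,
    sex = factor(sex, levels = c("female", "male")),
    smoker = smoker,
    smoking_years = smoking_years,
    fev1_fvc = fev1_fvc,
    pm25 = pm25,
    exposure_years = exposure_years,
    gene_variant = gene_variant,
    env_missing = FALSE,
    image_informative = image_informative,
    env_informative = env_informative,
    image_path = NA_character_
  )
  class(cohort) <- c("lungfuse_cohort", class(cohort))
  attr(cohort, "spec") <- spec

  if (spec$env_missing_rate > 0) {
    cohort <- mask_environment(cohort, spec$env_missing_rate,
                               seed = spec$seed + 1L)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_cohort(cohort, file.path(dir, "cohort.csv"))
  }
  cohort
}

#' Mask environmental exposure for a fraction of records
#'
#' Marks exactly `round(rate * n)` records as missing their environmental
#' exposure variables (PM2.5 and exposure years set to `NA`, `env_missing`
#' flag raised). By default masking is completely at random given the seed;
#' with `by = "smoker"` it is covariate-dependent — smokers carry
#' `by_weight`-fold the selection weight of nonsmokers (sampled without
#' replacement, total count unchanged), emulating exposure histories that go
#' unrecorded more often for high-risk patients. Records left observed are
#' returned untouched.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param rate Fraction in `[0, 1]` of records to mask.
#' @param seed Integer seed for the mask draw.
#' @param by `NULL` (completely at random) or `"smoker"`.
#' @param by_weight Relative selection weight of the `by` group.
#' @return The cohort with masked environmental fields.
#' @export
mask_environment <- function(cohort, rate, seed = 1L, by = NULL,
                             by_weight = 3) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("`rate` must be a single number in [0, 1]", call. = FALSE)
  if (!is.null(by) && !identical(by, "smoker"))
    stop("`by` must be NULL or \"smoker\"", call. = FALSE)
  n <- nrow(cohort)
  k <- round(rate * n)
  if (k > 0) {
    set.seed(as.integer(seed))
    w <- if (identical(by, "smoker")) {
      ifelse(cohort$smoker, by_weight, 1)
    } else rep(1, n)
    idx <- sample.int(n, k, prob = w)
    cohort$pm25[idx] <- NA_real_
    cohort$exposure_years[idx] <- NA_real_
    cohort$env_missing[idx] <- TRUE
  }
  cohort
}

#' Write / read a cohort table
#'
#' The cohort CSV has a header row, one row per patient, missing values as
#' empty fields, UTF-8 encoding. `read_cohort()` restores column types and
#' factor levels.
#'
#' @param cohort A cohort tibble.
#' @param path File path for the CSV.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$label <- as.character(df$label)
  df$stage <- as.character(df$stage)
  df$sex <- as.character(df$sex)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  cohort <- tibble::as_tibble(df)
  cohort$label <- factor(cohort$label, levels = c("control", "COPD"))
  cohort$stage <- factor(cohort$stage, levels = stage_levels)
  cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  for (nm in c("smoker", "gene_variant", "env_missing",
               "image_informative", "env_informative")) {
    if (nm %in% names(cohort)) cohort[[nm]] <- as.logical(cohort[[nm]])
  }
  if (!"image_path" %in% names(cohort)) cohort$image_path <- NA_character_
  cohort$image_path <- as.character(cohort$image_path)
  class(cohort) <- c("lungfuse_cohort", class(cohort))
  cohort
}
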