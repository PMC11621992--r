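#' Configuration for the synthetic study generator
#'
#' Defaults emulate the marginal structure of the multicentre occupational
#' brain-tumour case-control study the package models: 1819 glioma and 1758
#' meningioma cases against 5227 controls, interviewed 2000-2004; a JEM of
#' 468 four-digit ISCO88 codes of which 62% are occupationally exposed;
#' job-level exposure prevalence drawn from a Beta(0.8, 12) (median about
#' 5%); skewed lognormal intensities with E- and H-field levels coupled
#' through a latent normal with correlation 0.93 (Spearman about 0.9);
#' careers of 27.6 +/- 12 years split over about 3 jobs. Participant-level
#' source reports are noisy observations of true job-level exposure with
#' configurable sensitivity/specificity, which drives the Method-3
#' attribution. Case status is assigned by a stratified logistic disease
#' model with configurable log odds ratios per exposure category of a
#' target metric, so parameter recovery is well-posed.
#'
#' @param ... Overrides of any default listed above (see the returned list
#'   for names).
#' @return A list of class `rfjem_synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_glioma = 1819L, n_meningioma = 1758L, n_controls = 5227L,
    n_isco_codes = 468L, frac_exposed_codes = 0.62,
    prevalence_shape1 = 0.8, prevalence_shape2 = 12,
    intensity_meanlog = 0, intensity_sdlog = 1.2,
    eh_latent_cor = 0.93,
    mean_career_years = 27.6, sd_career_years = 12,
    mean_jobs = 3,
    interview_years = 2000:2004,
    age_groups = c("<35", "35-39", "40-44", "45-49", "50-54", "55-59",
                   "60-64", "65-69", "70+"),
    age_group_probs = c(401, 443, 604, 713, 930, 972, 488, 416, 260) / 5227,
    sex_probs = c(F = 0.558, M = 0.442),
    regions = c("Australia", "Canada", "France", "Germany", "Israel",
                "NewZealand", "UK"),
    region_probs = c(633, 613, 456, 1478, 898, 136, 1013) / 5227,
    education_levels = c("high_school_or_less", "medium_technical", "university"),
    education_probs = c(2818, 978, 1431) / 5227,
    proxy_rate = 0.03, preexisting_rate = 0.01,
    nonstandard_rate = 0.08, unknown_code_rate = 0.03,
    overlap_rate = 0.1, mean_gap_years = 0.3,
    source_report_sensitivity = 0.9, source_report_specificity = 0.99,
    true_log_or = c(0, 0, 0, 0),
    target = list(field = "E", method = "M1", metric = "cumulative",
                  label = "lag1"),
    stratum_intercept_sd = 0.2,
    diagnosis_gap_probs = c(`0` = 0.3, `1` = 0.45, `2` = 0.25),
    exclusion_rates = c(source_info = 0, missing_education = 0,
                        chronology = 0, nonstandard_only = 0,
                        unknown_occupation = 0)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$frac_exposed_codes >= 0, cfg$frac_exposed_codes <= 1,
            length(cfg$true_log_or) == 4)
  structure(cfg, class = c("rfjem_synth_config", "list"))
}

#' Generate a synthetic job-exposure matrix
#'
#' Draws `n_isco_codes` occupation codes; each is exposed with probability
#' `frac_exposed_codes`. Exposed codes receive a prevalence from the
#' configured Beta distribution (shared between fields: the same workers
#' are exposed to both components) and lognormal E and H intensities whose
#' latent normals are correlated. Unexposed codes get intensity and
#' prevalence 0.
#'
#' @param cfg An `rfjem_synth_config`.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @return An `rfjem_jem`.
#' @export
generate_jem <- function(cfg, seed) {
  set.seed(seed)
  n <- cfg$n_isco_codes
  codes <- sprintf("%04d", sample(1000:9999, n))
  exposed <- stats::rbinom(n, 1, cfg$frac_exposed_codes) == 1
  prev <- ifelse(exposed,
                 stats::rbeta(n, cfg$prevalence_shape1, cfg$prevalence_shape2), 0)
  zE <- stats::rnorm(n)
  zH <- cfg$eh_latent_cor * zE +
    sqrt(1 - cfg$eh_latent_cor^2) * stats::rnorm(n)
  iE <- ifelse(exposed, exp(cfg$intensity_meanlog + cfg$intensity_sdlog * zE), 0)
  iH <- ifelse(exposed, exp(cfg$intensity_meanlog + cfg$intensity_sdlog * zH), 0)
  nb <- 1L + stats::rpois(n, 19)
  jem(data.frame(
    isco88 = c(codes, codes),
    field_kind = rep(c("E", "H"), each = n),
    intensity = c(iE, iH),
    prevalence = c(prev, prev),
    n_basis = c(nb, nb)))
}

band_age <- function(age_group) {
  lo <- suppressWarnings(as.integer(sub("[-+<].*$|\\+", "", sub("^<", "", age_group))))
  ifelse(age_group == "<35", 25L, ifelse(age_group == "70+", 70L, lo))
}

#' Generate a synthetic case-control cohort with known truth
#'
#' Places job histories on the calendar, computes the target exposure
#' metric through the package's own exposure machinery (Method 1 over all
#' participants at a provisional reference of interview year minus 1),
#' categorizes it by percentile cut-points of the exposed pool, assigns
#' case status by a stratified logistic model with the configured
#' `true_log_or` per category, and finally injects the configured rates of
#' exclusion-triggering defects. The returned truth record carries the
#' category, metric value and cut-points the disease model actually used.
#'
#' @param cfg An `rfjem_synth_config`.
#' @param jm An `rfjem_jem`, typically from [generate_jem()].
#' @param seed Integer seed.
#' @param n_total Optional total cohort size override; the glioma /
#'   meningioma / control mix keeps the configured proportions.
#' @return list with `participants`, `jobs` (load_cohort-compatible
#'   data.frames) and `truth` (category, value, cut-points, true_log_or,
#'   target, seed).
#' @export
generate_cohort <- function(cfg, jm, seed, n_total = NULL) {
  set.seed(seed + 1L)
  n_cases <- cfg$n_glioma + cfg$n_meningioma
  N <- if (is.null(n_total)) n_cases + cfg$n_controls else as.integer(n_total)
  case_frac <- n_cases / (n_cases + cfg$n_controls)

  pid <- sprintf("P%06d", seq_len(N))
  age_group <- sample(cfg$age_groups, N, replace = TRUE, prob = cfg$age_group_probs)
  sex <- sample(names(cfg$sex_probs), N, replace = TRUE, prob = cfg$sex_probs)
  region <- sample(cfg$regions, N, replace = TRUE, prob = cfg$region_probs)
  education <- sample(cfg$education_levels, N, replace = TRUE,
                      prob = cfg$education_probs)
  interview_year <- sample(cfg$interview_years, N, replace = TRUE)
  proxy <- stats::rbinom(N, 1, cfg$proxy_rate) == 1
  preexisting <- stats::rbinom(N, 1, cfg$preexisting_rate) == 1
  age <- band_age(age_group) + sample(0:4, N, replace = TRUE)

  career <- pmin(pmax(round(stats::rnorm(N, cfg$mean_career_years,
                                         cfg$sd_career_years)), 1L), age - 17L)
  career <- pmax(career, 1L)
  delay <- ifelse(stats::runif(N) < 0.7, 0L, sample(1:4, N, replace = TRUE))
  career_end <- interview_year - delay
  career_start <- career_end - career + 1L

  # job spells: split each career into k segments with small gaps/overlaps
  k <- 1L + stats::rpois(N, max(cfg$mean_jobs - 1, 0))
  M <- sum(k)
  pix <- rep.int(seq_len(N), k)
  g <- stats::rgamma(M, shape = 1.5)
  sg <- rowsum(g, pix)[, 1]
  dur <- pmax(1L, as.integer(round(career[pix] * g / sg[pix])))
  gap <- c(0L, stats::rpois(M - 1, cfg$mean_gap_years))
  first <- !duplicated(pix)
  gap[first] <- 0L
  blk <- dur + gap
  cum_end <- stats::ave(blk, pix, FUN = cumsum)
  start <- career_start[pix] + cum_end - dur
  shift <- !first & stats::runif(M) < cfg$overlap_rate
  start[shift] <- pmax(start[shift] - sample(1:3, sum(shift), replace = TRUE),
                       career_start[pix][shift])
  end <- start + dur - 1L

  jem_codes <- unique(jm$isco88)
  isco <- sample(jem_codes, M, replace = TRUE)
  off_jem <- stats::runif(M) < cfg$unknown_code_rate
  isco[off_jem] <- sprintf("%04d", sample(100:999, sum(off_jem), replace = TRUE))
  nonstandard <- stats::rbinom(M, 1, cfg$nonstandard_rate) == 1
  isco[nonstandard] <- "0000"

  prev_spell <- jem_lookup(jm, isco, "E")$prevalence
  truly_exposed <- !nonstandard & stats::runif(M) < prev_spell
  source_reported <- ifelse(truly_exposed,
                            stats::runif(M) < cfg$source_report_sensitivity,
                            stats::runif(M) < 1 - cfg$source_report_specificity)
  source_reported[nonstandard] <- FALSE

  participants <- data.frame(
    pid = pid, status = "control", diagnosis_year = NA_integer_,
    interview_year = interview_year, age_group = age_group, sex = sex,
    region = region, education = education, proxy = proxy,
    grade = "n/a", preexisting_condition = preexisting,
    stringsAsFactors = FALSE)
  jobs <- data.frame(
    pid = pid[pix], start_year = start, end_year = end, isco88 = isco,
    nonstandard = nonstandard, source_reported = source_reported,
    source_uncertain = FALSE, stringsAsFactors = FALSE)

  # disease model on the target metric at a provisional reference date
  tg <- cfg$target
  prov_ref <- interview_year - 1L
  thr <- if (tg$method == "M2")
    stats::setNames(list(median_prevalence_threshold(jm, tg$field)), tg$field)
  else NULL
  prof <- exposure_profiles(participants, jobs, jm, prov_ref,
                            methods = tg$method, fields = tg$field,
                            labels = tg$label, thresholds = thr)
  value <- if (tg$metric == "twa") prof$twa else prof$cumulative
  exposed <- prof$exposed
  if (!any(exposed))
    stop("inestimable synthetic design: no exposed participants ",
         "(is frac_exposed_codes 0?)")
  cp <- exposure_cutpoints(value[exposed])
  category <- assign_category(value, exposed, cp)

  lp <- c(0, cfg$true_log_or)[as.integer(category)]
  # stratum levels in deterministic (appearance) order, independent of the
  # session locale, so a fixed seed reproduces the cohort bit-for-bit
  stratum <- paste(age_group, sex, region, sep = "|")
  slev <- unique(stratum)
  alpha_s <- stats::rnorm(length(slev), 0, cfg$stratum_intercept_sd)
  alpha <- stats::qlogis(case_frac) - mean(lp)
  p_case <- stats::plogis(alpha + alpha_s[match(stratum, slev)] + lp)
  is_case <- stats::runif(N) < p_case
  tumor <- ifelse(stats::runif(N) < cfg$n_glioma / n_cases, "glioma", "meningioma")
  participants$status[is_case] <- tumor[is_case]
  gap_dx <- as.integer(sample(names(cfg$diagnosis_gap_probs), N, replace = TRUE,
                              prob = cfg$diagnosis_gap_probs))
  participants$diagnosis_year[is_case] <- interview_year[is_case] - gap_dx[is_case]
  glioma <- participants$status == "glioma"
  participants$grade[glioma] <- sample(c("low", "high"), sum(glioma),
                                       replace = TRUE, prob = c(0.4, 0.6))

  res <- inject_exclusion_defects(participants, jobs, cfg$exclusion_rates)
  truth <- list(category = as.integer(as.character(category)), value = value,
                cutpoints = cp, true_log_or = cfg$true_log_or, target = tg,
                stratum = stratum, seed = seed)
  list(participants = res$participants, jobs = res$jobs, truth = truth)
}

inject_exclusion_defects <- function(participants, jobs, rates) {
  if (all(rates == 0)) return(list(participants = participants, jobs = jobs))
  N <- nrow(participants)
  pool <- sample(participants$pid)  # disjoint assignment, random order
  take <- function(n) {
    out <- utils::head(pool, n)
    pool <<- utils::tail(pool, length(pool) - length(out))
    out
  }
  first_spell <- !duplicated(jobs$pid)
  pick <- list(
    source_info = function(p) jobs$source_uncertain[first_spell & jobs$pid %in% p] <<- TRUE,
    missing_education = function(p)
      participants$education[participants$pid %in% p] <<- "missing",
    chronology = function(p) jobs$start_year[first_spell & jobs$pid %in% p] <<- NA_integer_,
    nonstandard_only = function(p) {
      sel <- jobs$pid %in% p
      jobs$nonstandard[sel] <<- TRUE
      jobs$isco88[sel] <<- "0000"
    },
    unknown_occupation = function(p)
      jobs$isco88[first_spell & jobs$pid %in% p] <<- "UNKNOWN"
  )
  for (nm in names(pick)) {
    r <- rates[[nm]]
    if (is.null(r) || r <= 0) next
    pick[[nm]](take(stats::rbinom(1, N, r)))
  }
  list(participants = participants, jobs = jobs)
}

#' Write a synthetic study to disk
#'
#' Emits `jem.csv`, `participants.csv`, `jobs.csv` and `truth.json` in the
#' load_cohort / load_jem schemas, so generator output round-trips through
#' the package's own readers.
#'
#' @param synth list from [generate_cohort()].
#' @param jm The `rfjem_jem` used to generate it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, jm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_jem(jm, file.path(dir, "jem.csv"))
  utils::write.csv(synth$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(synth$jobs, file.path(dir, "jobs.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- synth$truth
  tr$cutpoints <- list(q = tr$cutpoints$q, probs = tr$cutpoints$probs,
                       n = tr$cutpoints$n)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
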