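# Published marginal structure of the multicentre occupational RF-EMF
# brain-tumour case-control population that the synthetic generator
# emulates. These counts are inputs: fixture cohorts realized from them let
# the accounting operations (exclusion ledger, sociodemographic summary) be
# checked against the printed margins without access to the original data.

#' Reference sociodemographic margins
#'
#' Marginal counts of included participants by age group, sex, country and
#' education for the glioma (n = 1819), meningioma (n = 1758) and control
#' (n = 5227) groups of the study population the package targets.
#'
#' @return Named list of data.frames (`age_group`, `sex`, `region`,
#'   `education`), each with columns `level,glioma,meningioma,control`.
#' @export
reference_margins <- function() {
  list(
    age_group = data.frame(
      level = c("<35", "35-39", "40-44", "45-49", "50-54", "55-59",
                "60-64", "65-69", "70+"),
      glioma = c(200, 169, 204, 224, 324, 286, 180, 127, 105),
      meningioma = c(76, 96, 163, 261, 354, 303, 174, 156, 175),
      control = c(401, 443, 604, 713, 930, 972, 488, 416, 260)),
    sex = data.frame(
      level = c("F", "M"),
      glioma = c(715, 1104), meningioma = c(1287, 471),
      control = c(2917, 2310)),
    region = data.frame(
      level = c("Australia", "Canada", "France", "Germany", "Israel",
                "NewZealand", "UK"),
      glioma = c(257, 154, 89, 346, 377, 60, 536),
      meningioma = c(239, 90, 138, 364, 647, 48, 232),
      control = c(633, 613, 456, 1478, 898, 136, 1013)),
    education = data.frame(
      level = c("high_school_or_less", "medium_technical", "university"),
      glioma = c(954, 351, 514), meningioma = c(1040, 344, 374),
      control = c(2818, 978, 1431)))
}

#' Reference exclusion accounting
#'
#' Initial group sizes and counts excluded by each of the five ordered
#' criteria, per status group, for the study population the package
#' targets: source information, missing education, chronological issues,
#' nonstandard-only histories, unknown occupation codes.
#'
#' @return list with `initial` (named vector) and `excluded` (matrix
#'   criteria x group).
#' @export
reference_exclusion_counts <- function() {
  excl <- rbind(source_info = c(137, 115, 260),
                missing_education = c(14, 7, 11),
                chronology = c(47, 15, 29),
                nonstandard_only = c(12, 20, 32),
                unknown_occupation = c(25, 9, 42))
  colnames(excl) <- c("glioma", "meningioma", "control")
  final <- c(glioma = 1819, meningioma = 1758, control = 5227)
  list(initial = final + colSums(excl), excluded = excl, final = final)
}

#' Build a cohort realizing the reference margins
#'
#' Expands the marginal counts of [reference_margins()] into a participant
#' table: within each status group the age, sex, region and education
#' labels are laid out independently to their marginal counts (the joint
#' distribution is not published and is irrelevant to marginal summaries).
#'
#' @param margins list as returned by [reference_margins()].
#' @return Participant data.frame in the [load_cohort()] schema.
#' @export
make_margins_cohort <- function(margins = reference_margins()) {
  groups <- c("glioma", "meningioma", "control")
  do.call(rbind, lapply(groups, function(g) {
    n <- sum(margins$age_group[[g]])
    df <- data.frame(
      pid = sprintf("%s%05d", toupper(substr(g, 1, 1)), seq_len(n)),
      status = g,
      diagnosis_year = if (g == "control") NA_integer_ else 2001L,
      interview_year = 2002L,
      age_group = rep(margins$age_group$level, margins$age_group[[g]]),
      sex = rep(margins$sex$level, margins$sex[[g]]),
      region = rep(margins$region$level, margins$region[[g]]),
      education = rep(margins$education$level, margins$education[[g]]),
      proxy = FALSE, grade = if (g == "glioma") "low" else "n/a",
      preexisting_condition = FALSE, stringsAsFactors = FALSE)
    df
  }))
}

#' Build a cohort realizing the reference exclusion accounting
#'
#' Engineers a participant and job-spell table in which exactly the
#' reference numbers of participants per status group trip each exclusion
#' criterion (and only that criterion), so that [apply_exclusions()] must
#' reproduce the printed final sample sizes and exclusion percentages.
#'
#' @param counts list as returned by [reference_exclusion_counts()].
#' @return list with `participants` and `jobs` data.frames.
#' @export
make_exclusion_cohort <- function(counts = reference_exclusion_counts()) {
  groups <- colnames(counts$excluded)
  built <- lapply(groups, function(g) {
    n_inc <- counts$final[[g]]
    n_exc <- counts$excluded[, g]
    kinds <- c(rep("ok", n_inc), rep(rownames(counts$excluded), n_exc))
    n <- length(kinds)
    pid <- sprintf("%s%05d", toupper(substr(g, 1, 1)), seq_len(n))
    pt <- data.frame(
      pid = pid, status = g,
      diagnosis_year = if (g == "control") NA_integer_ else 2001L,
      interview_year = 2002L, age_group = "50-54",
      sex = rep_len(c("F", "M"), n), region = "Germany",
      education = ifelse(kinds == "missing_education", "missing",
                         "university"),
      proxy = FALSE, grade = "n/a", preexisting_condition = FALSE,
      stringsAsFactors = FALSE)
    jb <- data.frame(
      pid = pid, start_year = 1980L, end_year = 2000L, isco88 = "3114",
      nonstandard = FALSE, source_reported = FALSE,
      source_uncertain = FALSE, stringsAsFactors = FALSE)
    jb$source_uncertain[kinds == "source_info"] <- TRUE
    jb$end_year[kinds == "chronology"] <- 1979L
    sel <- kinds == "nonstandard_only"
    jb$nonstandard[sel] <- TRUE
    jb$isco88[sel] <- "0000"
    extra <- data.frame(
      pid = pid[kinds == "unknown_occupation"], start_year = 2001L,
      end_year = 2001L, isco88 = "UNKNOWN", nonstandard = FALSE,
      source_reported = FALSE, source_uncertain = FALSE,
      stringsAsFactors = FALSE)
    list(pt = pt, jb = rbind(jb, extra))
  })
  list(participants = do.call(rbind, lapply(built, `[[`, "pt")),
       jobs = do.call(rbind, lapply(built, `[[`, "jb")))
}
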