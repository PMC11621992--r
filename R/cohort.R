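participant_cols <- c("pid", "status", "diagnosis_year", "interview_year",
                      "age_group", "sex", "region", "education", "proxy",
                      "grade", "preexisting_condition")
job_cols <- c("pid", "start_year", "end_year", "isco88", "nonstandard",
              "source_reported", "source_uncertain")

#' Load participants and job histories
#'
#' Reads the two study tables and returns typed records. Rows that cannot be
#' parsed are collected into a rejects report rather than silently dropped;
#' job spells referring to a pid absent from the participant table abort.
#'
#' Chronological problems (unknown years, end before start) are NOT errors
#' at load time: they are captured and dealt with by [apply_exclusions()].
#'
#' @param participants_path CSV with columns
#'   `pid,status,diagnosis_year,interview_year,age_group,sex,region,education,proxy,grade,preexisting_condition`.
#' @param jobs_path CSV with columns
#'   `pid,start_year,end_year,isco88,nonstandard,source_reported,source_uncertain`
#'   (empty year fields mean unknown).
#' @return list with elements `participants`, `jobs` (data.frames) and
#'   `rejects` (data.frame of unparseable rows with a reason column).
#' @export
load_cohort <- function(participants_path, jobs_path) {
  pt <- utils::read.csv(participants_path, stringsAsFactors = FALSE,
                        colClasses = c(pid = "character"))
  jb <- utils::read.csv(jobs_path, stringsAsFactors = FALSE,
                        colClasses = c(pid = "character", isco88 = "character"))
  miss_p <- setdiff(participant_cols, names(pt))
  if (length(miss_p))
    stop("participants schema error: missing column(s) ",
         paste(miss_p, collapse = ", "))
  miss_j <- setdiff(job_cols, names(jb))
  if (length(miss_j))
    stop("jobs schema error: missing column(s) ", paste(miss_j, collapse = ", "))

  rejects <- data.frame(file = character(), row = integer(), reason = character())
  note <- function(file, rows, reason) {
    if (length(rows))
      rejects <<- rbind(rejects,
                        data.frame(file = file, row = rows, reason = reason))
  }

  pt$diagnosis_year <- suppressWarnings(as.integer(pt$diagnosis_year))
  pt$interview_year <- suppressWarnings(as.integer(pt$interview_year))
  for (col in c("proxy", "preexisting_condition")) pt[[col]] <- as.logical(pt[[col]])
  bad_status <- which(!pt$status %in% c("glioma", "meningioma", "control"))
  note("participants", bad_status, "unknown status")
  bad_case <- which(pt$status != "control" &
                    (is.na(pt$diagnosis_year) | is.na(pt$interview_year) |
                     pt$diagnosis_year > pt$interview_year))
  note("participants", bad_case, "case without coherent diagnosis/interview years")
  bad_ctrl <- which(pt$status == "control" & !is.na(pt$diagnosis_year))
  note("participants", bad_ctrl, "control with a diagnosis year")
  drop_p <- unique(c(bad_status, bad_case, bad_ctrl))
  if (length(drop_p)) pt <- pt[-drop_p, ]

  jb$start_year <- suppressWarnings(as.integer(jb$start_year))
  jb$end_year <- suppressWarnings(as.integer(jb$end_year))
  for (col in c("nonstandard", "source_reported", "source_uncertain"))
    jb[[col]] <- as.logical(jb[[col]])
  orphan <- setdiff(jb$pid, pt$pid)
  if (length(orphan))
    stop("orphan-spell error: job history references unknown pid(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "))

  rownames(pt) <- rownames(jb) <- NULL
  list(participants = pt, jobs = jb, rejects = rejects)
}

#' Apply the study's ordered exclusion rules
#'
#' Participants are excluded, in this order, for: (1) uncertain/unknown
#' RF-EMF source information or an absent occupational history; (2) missing
#' education; (3) chronological issues in the job history (unknown start or
#' end years, end before start); (4) an occupational history consisting
#' exclusively of nonstandard occupations (housewife/husband, pensioner,
#' training, imprisonment); (5) any unknown occupation code. A participant
#' matching several criteria is counted only under the first. Nonstandard
#' spells reported alongside real jobs are retained as unexposed periods.
#'
#' @param cohort list as returned by [load_cohort()] (elements
#'   `participants` and `jobs`).
#' @return list with `participants` and `jobs` restricted to included
#'   participants, and `ledger`, an `rfjem_ledger` recording per-status
#'   initial counts, per-criterion exclusions (with percentages of the
#'   initial group) and final counts. Conservation
#'   (initial = final + sum(excluded)) is asserted on every run.
#' @export
apply_exclusions <- function(cohort) {
  pt <- cohort$participants
  jb <- cohort$jobs
  has_spell <- pt$pid %in% jb$pid
  agg <- function(cond) pt$pid %in% unique(jb$pid[cond])

  crit <- list(
    source_info = agg(jb$source_uncertain) | !has_spell,
    missing_education = is.na(pt$education) | pt$education == "" |
      pt$education == "missing",
    chronology = agg(is.na(jb$start_year) | is.na(jb$end_year) |
                     (jb$end_year < jb$start_year)),
    nonstandard_only = {
      std <- tapply(!jb$nonstandard, jb$pid, any)
      has_spell & !pt$pid %in% names(std)[is.na(std) | std]
    },
    unknown_occupation = agg(!jb$nonstandard & (is.na(jb$isco88) |
                             jb$isco88 == "" | toupper(jb$isco88) == "UNKNOWN"))
  )

  assigned <- rep(NA_character_, nrow(pt))
  for (nm in names(crit)) assigned[is.na(assigned) & crit[[nm]]] <- nm

  groups <- c("glioma", "meningioma", "control")
  initial <- vapply(groups, function(g) sum(pt$status == g), integer(1))
  counts <- sapply(groups, function(g)
    vapply(names(crit), function(nm)
      sum(pt$status == g & !is.na(assigned) & assigned == nm, na.rm = TRUE),
      integer(1)))
  final <- vapply(groups, function(g)
    sum(pt$status == g & is.na(assigned)), integer(1))
  stopifnot(all(initial == final + colSums(counts)))

  ledger <- structure(list(criteria = names(crit), initial = initial,
                           excluded = counts,
                           pct = sweep(counts, 2, initial, "/") * 100,
                           final = final),
                      class = "rfjem_ledger")
  keep <- is.na(assigned)
  list(participants = pt[keep, , drop = FALSE],
       jobs = jb[jb$pid %in% pt$pid[keep], , drop = FALSE],
       ledger = ledger)
}

#' @export
print.rfjem_ledger <- function(x, ...) {
  cat("Exclusion ledger (participants counted once, first matching criterion)\n")
  hdr <- sprintf("%-22s %10s %12s %10s", "", "glioma", "meningioma", "control")
  cat(hdr, "\n")
  cat(sprintf("%-22s %10d %12d %10d\n", "initial",
              x$initial[1], x$initial[2], x$initial[3]))
  for (i in seq_along(x$criteria))
    cat(sprintf("%-22s %6d (%.1f%%) %7d (%.1f%%) %6d (%.1f%%)\n",
                x$criteria[i],
                x$excluded[i, 1], x$pct[i, 1],
                x$excluded[i, 2], x$pct[i, 2],
                x$excluded[i, 3], x$pct[i, 3]))
  cat(sprintf("%-22s %10d %12d %10d\n", "included",
              x$final[1], x$final[2], x$final[3]))
  invisible(x)
}

#' Convert an exclusion ledger to a data.frame
#'
#' @param x An `rfjem_ledger`.
#' @param ... unused.
#' @return Long data.frame with columns `criterion,status,excluded,pct`.
#' @export
as.data.frame.rfjem_ledger <- function(x, ...) {
  groups <- colnames(x$excluded)
  out <- expand.grid(criterion = x$criteria, status = groups,
                     stringsAsFactors = FALSE)
  out$excluded <- as.vector(x$excluded)
  out$pct <- as.vector(x$pct)
  out
}

#' Median gap between diagnosis and interview among cases
#'
#' Used to place the reference date of controls: a control's reference year
#' is the interview year minus this median, so that controls and cases are
#' evaluated at comparable calendar depths.
#'
#' @param participants data.frame of participants; only cases (status other
#'   than "control") with both years observed contribute.
#' @return Median of (interview_year - diagnosis_year), in years.
#' @export
median_dx_interview_gap <- function(participants) {
  cases <- participants[participants$status != "control", ]
  gaps <- cases$interview_year - cases$diagnosis_year
  gaps <- gaps[!is.na(gaps)]
  if (!length(gaps)) stop("undefined gap: no cases with diagnosis and interview years")
  stats::median(gaps)
}

#' Reference year per participant
#'
#' Cases anchor at the diagnosis year; controls at the interview year minus
#' the cases' median diagnosis-to-interview gap, rounded half-up to a whole
#' year (exposure is resolved at year granularity throughout).
#'
#' @param participants data.frame of participants.
#' @param median_gap Non-negative gap in years (see
#'   [median_dx_interview_gap()]).
#' @return Integer vector of reference years, aligned with the rows.
#' @export
reference_years <- function(participants, median_gap) {
  stopifnot(median_gap >= 0)
  is_case <- participants$status != "control"
  if (any(is_case & is.na(participants$diagnosis_year)))
    stop("data error: case without diagnosis year")
  ifelse(is_case, participants$diagnosis_year,
         participants$interview_year - as.integer(floor(median_gap + 0.5)))
}

#' Sociodemographic summary of a cohort
#'
#' Counts and within-status percentages by age group, sex, region and
#' education, per status group — the standard "Table 1" margins of a
#' case-control report.
#'
#' @param participants data.frame of participants.
#' @return data.frame with columns `status,variable,level,n,pct`.
#' @export
cohort_summary <- function(participants) {
  vars <- c("age_group", "sex", "region", "education")
  out <- do.call(rbind, lapply(split(participants, participants$status),
    function(sub) {
      do.call(rbind, lapply(vars, function(v) {
        tab <- table(sub[[v]])
        data.frame(status = sub$status[1], variable = v,
                   level = names(tab), n = as.integer(tab),
                   pct = 100 * as.integer(tab) / nrow(sub))
      }))
    }))
  rownames(out) <- NULL
  out
}
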