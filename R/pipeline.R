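#' Configuration of a full analysis run
#'
#' Defines the analysis grid (outcomes x fields x methods x metrics x
#' lag/window labels), the reference group, and the sensitivity switches.
#' The primary grid uses lags 1/5/10 and windows 1-4/5-9; the
#' longer-latency labels are enabled with `extended_labels = TRUE`.
#'
#' @param outcomes Subset of c("glioma", "meningioma").
#' @param fields Subset of c("E", "H").
#' @param methods Subset of c("M1", "M2", "M3").
#' @param metrics Subset of c("cumulative", "twa").
#' @param labels Labels from [exposure_labels()].
#' @param reference "unexposed" (primary) or "low_exposed" (sensitivity:
#'   category 1 as reference, see [rebase_reference()]).
#' @param extended_labels Add the 15/20/25-year lags and 10-14/15-19/20-24
#'   windows.
#' @param full_employment Restrict to subjects who worked all 4 calendar
#'   years in the 1-4-year window before their reference date.
#' @param exclude_proxy Drop proxy respondents.
#' @param exclude_over60 Drop subjects over 60 at interview (age groups
#'   60-64, 65-69, 70+).
#' @param exclude_preexisting Drop subjects with qualifying pre-existing
#'   conditions.
#' @param trim_p99 Drop subjects above the 99th percentile of the exposed
#'   controls' distribution of each analysed metric.
#' @param sex_restrict NULL, "F" or "M".
#' @param grade_restrict NULL, "low" or "high" (glioma grade subset).
#' @param likelihood "exact" or "breslow" conditional likelihood.
#' @return list of class `rfjem_run_config`.
#' @export
run_config <- function(outcomes = c("glioma", "meningioma"),
                       fields = c("E", "H"),
                       methods = c("M1", "M2", "M3"),
                       metrics = c("cumulative", "twa"),
                       labels = NULL, reference = c("unexposed", "low_exposed"),
                       extended_labels = FALSE,
                       full_employment = FALSE, exclude_proxy = FALSE,
                       exclude_over60 = FALSE, exclude_preexisting = FALSE,
                       trim_p99 = FALSE, sex_restrict = NULL,
                       grade_restrict = NULL,
                       likelihood = c("exact", "breslow")) {
  if (is.null(labels)) labels <- exposure_labels(extended_labels)
  stopifnot(length(outcomes) >= 1, length(fields) >= 1,
            length(methods) >= 1, length(metrics) >= 1, length(labels) >= 1)
  lapply(labels, parse_label)  # validate
  structure(list(outcomes = outcomes, fields = fields, methods = methods,
                 metrics = metrics, labels = labels,
                 reference = match.arg(reference),
                 full_employment = full_employment,
                 exclude_proxy = exclude_proxy,
                 exclude_over60 = exclude_over60,
                 exclude_preexisting = exclude_preexisting,
                 trim_p99 = trim_p99, sex_restrict = sex_restrict,
                 grade_restrict = grade_restrict,
                 likelihood = match.arg(likelihood)),
            class = c("rfjem_run_config", "list"))
}

#' Cohort-level sensitivity filters
#'
#' Applies the enabled subject-level predicates: full employment through
#' the 1-4-year window (worked all 4 calendar years in
#' \[ref - 4, ref - 1\]), proxy-response exclusion, age over 60 at
#' interview, pre-existing conditions, sex restriction and glioma-grade
#' restriction. With no switches enabled this is the identity.
#' Percentile trimming is value-dependent and is applied inside
#' [run_analysis()], per analysis cell, after these filters.
#'
#' @param participants Included participants.
#' @param profiles Exposure profiles of those participants
#'   ([exposure_profiles()]), needed for the full-employment predicate.
#' @param config An `rfjem_run_config`.
#' @return Logical vector: keep each participant row?
#' @export
sensitivity_filter <- function(participants, profiles, config) {
  keep <- rep(TRUE, nrow(participants))
  if (config$full_employment) {
    w14 <- profiles[profiles$label == "win1_4" &
                    profiles$field_kind == profiles$field_kind[1] &
                    profiles$method == profiles$method[1], ]
    full <- w14$pid[w14$years_worked == 4L]
    keep <- keep & participants$pid %in% full
  }
  if (config$exclude_proxy) keep <- keep & !participants$proxy
  if (config$exclude_over60)
    keep <- keep & !participants$age_group %in% c("60-64", "65-69", "70+")
  if (config$exclude_preexisting) keep <- keep & !participants$preexisting_condition
  if (!is.null(config$sex_restrict))
    keep <- keep & participants$sex == config$sex_restrict
  if (!is.null(config$grade_restrict))
    keep <- keep & (participants$status == "control" |
                    participants$grade == config$grade_restrict)
  if (!any(keep))
    stop("inestimable run: sensitivity filters removed every participant")
  keep
}

#' Run the full analysis grid
#'
#' End-to-end orchestration: exclusions, reference dates (per-outcome
#' median diagnosis-interview gap), exposure profiles under every requested
#' method/field/label, sensitivity filters, control-based percentile
#' cut-points (recomputed from the controls actually included in each run),
#' category assignment, stratified conditional logistic fits (strata =
#' age group x sex x region, adjusted for education), odds ratios per
#' category and a Wald trend test per cell. Inestimable cells (no exposed
#' controls, empty categories, non-convergence) yield a flagged row and the
#' run continues. Deterministic given inputs and configuration.
#'
#' @param participants,jobs Cohort tables ([load_cohort()] schema).
#' @param jm An `rfjem_jem`.
#' @param config An `rfjem_run_config`.
#' @return list with `results` (one row per analysis cell x category),
#'   `cutpoints`, `profiles`, `ledger`, and `log` (character vector of
#'   stage-by-stage counts).
#' @export
run_analysis <- function(participants, jobs, jm, config = run_config()) {
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("loaded: %d participants, %d job spells", nrow(participants), nrow(jobs))

  exc <- apply_exclusions(list(participants = participants, jobs = jobs))
  led <- exc$ledger
  for (i in seq_along(led$criteria))
    say("excluded (%s): glioma %d, meningioma %d, control %d",
        led$criteria[i], led$excluded[i, 1], led$excluded[i, 2],
        led$excluded[i, 3])
  say("included: glioma %d, meningioma %d, control %d",
      led$final[1], led$final[2], led$final[3])

  thresholds <- sapply(config$fields, function(f)
    if ("M2" %in% config$methods) median_prevalence_threshold(jm, f)
    else NA_real_, simplify = FALSE)
  if ("M2" %in% config$methods)
    for (f in config$fields)
      say("Method-2 prevalence threshold (%s): %.4f", f, thresholds[[f]])

  results <- list(); cps <- list(); prof_all <- list()
  for (outcome in config$outcomes) {
    sub <- exc$participants[exc$participants$status %in% c(outcome, "control"), ]
    gap <- median_dx_interview_gap(sub)
    refs <- reference_years(sub, gap)
    say("[%s] median diagnosis-interview gap: %g year(s)", outcome, gap)

    prof <- exposure_profiles(sub, exc$jobs, jm, refs,
                              methods = config$methods,
                              fields = config$fields,
                              labels = config$labels,
                              thresholds = thresholds)
    keep <- sensitivity_filter(sub, prof, config)
    sub <- sub[keep, ]; refs <- refs[keep]
    prof <- prof[prof$pid %in% sub$pid, ]
    say("[%s] after sensitivity filters: %d cases, %d controls", outcome,
        sum(sub$status == outcome), sum(sub$status == "control"))
    prof$outcome <- outcome
    prof_all[[outcome]] <- prof

    y <- as.integer(sub$status == outcome)
    strata <- interaction(sub$age_group, sub$sex, sub$region, drop = TRUE)
    edu <- factor(sub$education,
                  levels = c("high_school_or_less", "medium_technical",
                             "university"))
    Xedu <- category_design(edu, prefix = "edu_")

    cell <- function(field, method, metric, label) {
      pr <- prof[prof$field_kind == field & prof$method == method &
                 prof$label == label, ]
      pr <- pr[match(sub$pid, pr$pid), ]
      value <- if (metric == "twa") pr$twa else pr$cumulative
      exposed <- pr$exposed
      is_ctrl <- y == 0L
      flag_row <- function(status_flag) data.frame(
        outcome = outcome, field_kind = field, method = method,
        metric = metric, label = label, category = NA_character_,
        n_cases = sum(y), n_controls = sum(is_ctrl), OR = NA_real_,
        CI_low = NA_real_, CI_high = NA_real_, p_trend = NA_real_,
        n_informative_strata = NA_integer_, converged = FALSE,
        status_flag = status_flag)
      if (!any(exposed & is_ctrl)) return(list(rows = flag_row("no_exposed_controls"),
                                               cp = NULL))
      keep_cell <- rep(TRUE, nrow(sub))
      if (config$trim_p99) {
        p99 <- stats::quantile(value[exposed & is_ctrl], 0.99, names = FALSE)
        keep_cell <- value <= p99
        if (!any(keep_cell & y == 1L) || !any(keep_cell & is_ctrl))
          return(list(rows = flag_row("trim_removed_a_group"), cp = NULL))
      }
      v <- value[keep_cell]; ex <- exposed[keep_cell]
      yk <- y[keep_cell]; stk <- droplevels(strata[keep_cell])
      cp <- exposure_cutpoints(v[ex & yk == 0L])
      cats <- assign_category(v, ex, cp)
      if (config$reference == "low_exposed") cats <- rebase_reference(cats)
      cats <- droplevels(cats)
      if (nlevels(cats) < 2) return(list(rows = flag_row("single_category"),
                                         cp = NULL))
      X <- cbind(category_design(cats), Xedu[keep_cell, , drop = FALSE])
      fit <- tryCatch(
        fit_condlogit(X, yk, stk, likelihood = config$likelihood),
        error = function(e) NULL)
      tt <- trend_test(as.numeric(as.character(cats)), yk, stk,
                       adjust = Xedu[keep_cell, , drop = FALSE],
                       likelihood = config$likelihood)
      cat_tab <- table(category = cats, case = yk)
      lev <- levels(cats)[-1]
      if (is.null(fit) || !fit$converged) {
        rows <- flag_row(if (is.null(fit)) "fit_error" else "not_converged")
      } else {
        ors <- odds_ratios(fit)
        ors <- ors[match(paste0("cat", lev), ors$term), ]
        rows <- data.frame(
          outcome = outcome, field_kind = field, method = method,
          metric = metric, label = label, category = lev,
          n_cases = as.integer(cat_tab[lev, "1"]),
          n_controls = as.integer(cat_tab[lev, "0"]),
          OR = ors$OR, CI_low = ors$CI_low, CI_high = ors$CI_high,
          p_trend = tt$p, n_informative_strata = fit$n_informative_strata,
          converged = TRUE, status_flag = "ok")
        say("[%s] %s/%s %s %s: %d informative strata, converged in %d iter",
            outcome, field, method, metric, label,
            fit$n_informative_strata, fit$iterations)
      }
      list(rows = rows,
           cp = data.frame(label = label, field_kind = field, method = method,
                           metric = metric, p50 = cp$q[1], p75 = cp$q[2],
                           p90 = cp$q[3], n_exposed_controls = cp$n))
    }

    for (field in config$fields)
      for (method in config$methods)
        for (metric in config$metrics)
          for (label in config$labels) {
            res <- cell(field, method, metric, label)
            results[[length(results) + 1L]] <- res$rows
            if (!is.null(res$cp)) {
              res$cp$outcome <- outcome
              cps[[length(cps) + 1L]] <- res$cp
            }
          }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  list(results = results,
       cutpoints = if (length(cps)) do.call(rbind, cps) else NULL,
       profiles = do.call(rbind, prof_all), ledger = led, log = log)
}

#' Write run outputs to a directory
#'
#' Emits `results.csv`, `cutpoints.csv`, `exposure_profiles.csv`,
#' `ledger.csv` and `run.log`.
#'
#' @param run list from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  if (!is.null(run$cutpoints))
    write_cutpoints(run$cutpoints, file.path(dir, "cutpoints.csv"))
  write_profiles(run$profiles, file.path(dir, "exposure_profiles.csv"))
  utils::write.csv(as.data.frame(run$ledger), file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Minimal forest plot of odds ratios
#'
#' Base-graphics forest plot of the OR and 95% CI per category for one
#' analysis cell, on a log scale.
#'
#' @param results data.frame from [run_analysis()] (rows of one cell, or
#'   pre-filtered).
#' @param main Plot title.
#' @return Invisibly, the plotted subset.
#' @export
plot_forest <- function(results, main = "Odds ratios by exposure category") {
  res <- results[!is.na(results$OR), ]
  if (!nrow(res)) stop("nothing to plot: no estimable rows")
  k <- nrow(res)
  lab <- paste(res$label, res$method, "cat", res$category)
  xlim <- range(c(res$CI_low, res$CI_high, 1), na.rm = TRUE)
  graphics::plot(res$OR, k:1, log = "x", xlim = xlim, pch = 15,
                 yaxt = "n", xlab = "Odds ratio (95% CI)", ylab = "",
                 main = main, panel.first = graphics::abline(v = 1, lty = 2))
  graphics::segments(res$CI_low, k:1, res$CI_high, k:1)
  graphics::axis(2, at = k:1, labels = lab, las = 1, cex.axis = 0.7)
  invisible(res)
}
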