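#' Supported lag and time-window labels
#'
#' Lags of 1, 5 and 10 years and the 1-4 and 5-9 year windows before the
#' reference date form the primary grid; longer lags (15/20/25) and windows
#' (10-14/15-19/20-24) probe longer latencies and are off by default in the
#' pipeline. A lag of L years covers all calendar years up to and including
#' reference - L; a window (a, b) covers the years reference - b through
#' reference - a inclusive, so lag 1 partitions exactly into windows 1-4,
#' 5-9 and lag 10.
#'
#' @param extended If TRUE include the longer-latency labels.
#' @return Character vector of labels.
#' @export
exposure_labels <- function(extended = FALSE) {
  main <- c("lag1", "lag5", "lag10", "win1_4", "win5_9")
  extra <- c("lag15", "lag20", "lag25", "win10_14", "win15_19", "win20_24")
  if (extended) c(main, extra) else main
}

parse_label <- function(label) {
  if (grepl("^lag[0-9]+$", label))
    return(list(type = "lag", lag = as.integer(sub("lag", "", label))))
  if (grepl("^win[0-9]+_[0-9]+$", label)) {
    ab <- as.integer(strsplit(sub("win", "", label), "_")[[1]])
    if (ab[1] < 1 || ab[1] > ab[2]) stop("invalid window label: ", label)
    return(list(type = "window", a = ab[1], b = ab[2]))
  }
  stop("unrecognized exposure label: ", label)
}

spell_intensity <- function(jobs, jm, method, field_kind, threshold = NULL) {
  hit <- jem_lookup(jm, jobs$isco88, field_kind)
  val <- ifelse(jobs$nonstandard, 0, hit$intensity)
  if (method == "M2") {
    if (is.null(threshold))
      stop("Method 2 requires the median prevalence threshold")
    val[hit$prevalence < threshold] <- 0
  } else if (method == "M3") {
    val[!jobs$source_reported] <- 0
  } else if (method != "M1") stop("unknown method: ", method)
  val
}

#' Per-year exposure intensity series for one participant
#'
#' Each job spell contributes its JEM intensity for every calendar year from
#' its start to its end year inclusive, gated by the attribution method:
#' under Method 1 every JEM-exposed job contributes; under Method 2 only
#' jobs whose exposure prevalence is at least the median prevalence among
#' exposed occupations (`threshold`); under Method 3 only jobs in which the
#' participant reported using an RF-EMF source. Nonstandard spells and codes
#' absent from the JEM contribute 0. Years covered by several concurrent
#' spells take the arithmetic mean of the concurrent spell intensities,
#' unexposed spells entering as 0.
#'
#' @param jobs data.frame of this participant's job spells (schema of
#'   [load_cohort()]). Unknown or incoherent years are a contract violation:
#'   exclusions must run first.
#' @param jm An `rfjem_jem`.
#' @param method "M1", "M2" or "M3".
#' @param field_kind "E" or "H".
#' @param threshold Prevalence threshold, required for Method 2 only.
#' @return list with integer vector `years` (worked calendar years) and
#'   numeric `values` (mean intensity per worked year, same order).
#' @export
yearly_series <- function(jobs, jm, method = "M1", field_kind = "E",
                          threshold = NULL) {
  if (nrow(jobs) == 0)
    return(list(years = integer(), values = numeric()))
  if (any(is.na(jobs$start_year) | is.na(jobs$end_year) |
          jobs$end_year < jobs$start_year))
    stop("contract violation: chronologically invalid spells reached exposure stage")
  val <- spell_intensity(jobs, jm, method, field_kind, threshold)
  len <- jobs$end_year - jobs$start_year + 1L
  yr <- sequence(len, from = jobs$start_year, by = 1L)
  v <- rep.int(val, len)
  tot <- rowsum(v, yr)
  cnt <- rowsum(rep(1, length(yr)), yr)
  years <- as.integer(rownames(tot))
  ord <- order(years)
  list(years = years[ord], values = (tot / cnt)[ord])
}

#' Cumulative exposure up to a lagged reference date
#'
#' Sum of the yearly intensity over all years up to and including
#' `ref_year - lag`.
#'
#' @param series list from [yearly_series()].
#' @param ref_year Reference calendar year (diagnosis year for cases,
#'   shifted interview year for controls).
#' @param lag Lag in years, >= 1.
#' @return Cumulative exposure; 0 for an empty range.
#' @export
cumulative_exposure <- function(series, ref_year, lag) {
  stopifnot(lag >= 1)
  sum(series$values[series$years <= ref_year - lag])
}

#' Exposure summed over a time window before the reference date
#'
#' @param series list from [yearly_series()].
#' @param ref_year Reference calendar year.
#' @param a,b Window bounds in years before the reference date,
#'   1 <= a <= b; the window covers calendar years `ref_year - b` through
#'   `ref_year - a` inclusive.
#' @return Window exposure; 0 for an empty range.
#' @export
window_exposure <- function(series, ref_year, a, b) {
  stopifnot(a >= 1, a <= b)
  sum(series$values[series$years >= ref_year - b & series$years <= ref_year - a])
}

#' Years worked within a lag or window period
#'
#' Counts calendar years covered by at least one job spell (including
#' retained nonstandard spells, which occupy calendar time as unexposed
#' periods) in the same year range as the corresponding exposure metric.
#' Gap years (unemployment) are not counted.
#'
#' @param series list from [yearly_series()].
#' @param ref_year Reference calendar year.
#' @param label A label such as "lag5" or "win1_4" (see
#'   [exposure_labels()]).
#' @return Integer count of worked years.
#' @export
years_worked <- function(series, ref_year, label) {
  spec <- parse_label(label)
  if (spec$type == "lag")
    sum(series$years <= ref_year - spec$lag)
  else
    sum(series$years >= ref_year - spec$b & series$years <= ref_year - spec$a)
}

#' Time-weighted average exposure
#'
#' Cumulative exposure divided by the number of years worked in the same
#' period; defined as 0 for a participant who did not work in the period
#' (in which case the cumulative exposure must also be 0).
#'
#' @param cumulative Cumulative exposure over a period.
#' @param years Years worked in the same period.
#' @return TWA exposure.
#' @export
twa_exposure <- function(cumulative, years) {
  stopifnot(years >= 0)
  if (years == 0) {
    if (cumulative > 0)
      stop("contract violation: positive exposure with zero worked years")
    return(0)
  }
  cumulative / years
}

#' Exposure profiles for a whole cohort
#'
#' Vectorized computation of cumulative and TWA exposure for every
#' participant under every requested method, field and label. Equivalent to
#' looping [yearly_series()] / [cumulative_exposure()] /
#' [window_exposure()] / [twa_exposure()] per participant (a property the
#' test suite asserts), but runs in a few vectorized passes.
#'
#' @param participants data.frame of included participants.
#' @param jobs data.frame of their job spells (post-exclusion).
#' @param jm An `rfjem_jem`.
#' @param ref_year Integer vector of reference years aligned with
#'   `participants` rows (see [reference_years()]).
#' @param methods Subset of c("M1","M2","M3").
#' @param fields Subset of c("E","H").
#' @param labels Labels from [exposure_labels()].
#' @param thresholds Named list/vector of Method-2 prevalence thresholds per
#'   field; computed from `jm` via [median_prevalence_threshold()] when NULL.
#' @return data.frame with columns
#'   `pid,field_kind,method,label,cumulative,twa,years_worked,exposed`.
#' @export
exposure_profiles <- function(participants, jobs, jm, ref_year,
                              methods = c("M1", "M2", "M3"),
                              fields = c("E", "H"),
                              labels = exposure_labels(),
                              thresholds = NULL) {
  stopifnot(nrow(participants) > 0, length(ref_year) == nrow(participants))
  if (is.null(thresholds))
    thresholds <- sapply(fields, function(f)
      if ("M2" %in% methods) median_prevalence_threshold(jm, f) else NA_real_,
      simplify = FALSE)
  jb <- jobs[jobs$pid %in% participants$pid, , drop = FALSE]
  if (any(is.na(jb$start_year) | is.na(jb$end_year) |
          jb$end_year < jb$start_year))
    stop("contract violation: chronologically invalid spells reached exposure stage")
  if (nrow(jb) == 0) {
    grid <- expand.grid(pid = participants$pid, field_kind = fields,
                        method = methods, label = labels,
                        stringsAsFactors = FALSE)
    grid$cumulative <- 0; grid$twa <- 0
    grid$years_worked <- 0L; grid$exposed <- FALSE
    return(grid)
  }

  # expand spells to (pid, year) once; per-(field, method) values reuse it
  len <- jb$end_year - jb$start_year + 1L
  spell_ix <- rep.int(seq_len(nrow(jb)), len)
  yr <- sequence(len, from = jb$start_year, by = 1L)
  pix <- rep.int(match(jb$pid, participants$pid), len)
  y0 <- min(yr)
  key <- (pix - 1L) * (max(yr) - y0 + 2L) + (yr - y0 + 1L)
  ukey <- sort(unique(key))
  kix <- match(key, ukey)
  n_keys <- length(ukey)
  cnt <- tabulate(kix, n_keys)
  span <- max(yr) - y0 + 2L
  year_of <- (ukey - 1L) %% span + y0
  pid_of <- (ukey - 1L) %/% span + 1L
  rel <- ref_year[pid_of] - year_of  # years before reference

  combos <- expand.grid(field_kind = fields, method = methods,
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos) * length(labels))
  k <- 0L
  n_p <- nrow(participants)
  for (ci in seq_len(nrow(combos))) {
    fk <- combos$field_kind[ci]; me <- combos$method[ci]
    sval <- spell_intensity(jb, jm, me, fk,
                            threshold = thresholds[[fk]])
    tot <- numeric(n_keys)
    tot[] <- rowsum(rep.int(sval, len), kix, reorder = TRUE)
    mean_val <- tot / cnt
    for (lab in labels) {
      spec <- parse_label(lab)
      inwin <- if (spec$type == "lag") rel >= spec$lag
               else rel >= spec$a & rel <= spec$b
      cum <- numeric(n_p)
      wrk <- integer(n_p)
      if (any(inwin)) {
        cs <- rowsum(mean_val[inwin], pid_of[inwin])
        cum[as.integer(rownames(cs))] <- cs
        ws <- rowsum(rep(1L, sum(inwin)), pid_of[inwin])
        wrk[as.integer(rownames(ws))] <- ws
      }
      k <- k + 1L
      out[[k]] <- data.frame(pid = participants$pid, field_kind = fk,
                             method = me, label = lab, cumulative = cum,
                             twa = ifelse(wrk > 0, cum / wrk, 0),
                             years_worked = wrk, exposed = cum > 0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write exposure profiles to CSV
#'
#' @param profiles data.frame from [exposure_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
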