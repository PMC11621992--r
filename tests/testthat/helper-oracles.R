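# Independent oracles and tiny fixtures used across the suite.

# Exact conditional log-likelihood by exhaustive subset enumeration:
# log[ exp(sum of case etas) / sum over all d-subsets of exp(sum eta) ].
enum_cond_loglik <- function(eta, y) {
  d <- sum(y)
  n <- length(eta)
  subs <- matrix(utils::combn(n, d), nrow = d)
  den <- sum(apply(subs, 2, function(ix) exp(sum(eta[ix]))))
  sum(eta[y == 1]) - log(den)
}

# Naive exposure oracle: materializes every (year, spell) pair for one
# participant and aggregates with plain loops. Independent of the
# yearly_series / exposure_profiles implementations.
naive_metric <- function(spells, jm, method, field, threshold, ref, label) {
  hit <- rfjem::jem_lookup(jm, spells$isco88, field)
  base <- ifelse(spells$nonstandard, 0, hit$intensity)
  if (method == "M2") base[hit$prevalence < threshold] <- 0
  if (method == "M3") base[!spells$source_reported] <- 0
  years <- if (nrow(spells)) seq(min(spells$start_year), max(spells$end_year)) else integer()
  spec <- rfjem:::parse_label(label)
  inwin <- if (spec$type == "lag") years <= ref - spec$lag
           else years >= ref - spec$b & years <= ref - spec$a
  cum <- 0; worked <- 0L
  for (y in years[inwin]) {
    cover <- which(spells$start_year <= y & spells$end_year >= y)
    if (!length(cover)) next
    worked <- worked + 1L
    cum <- cum + mean(base[cover])
  }
  c(cumulative = cum, years_worked = worked,
    twa = if (worked > 0) cum / worked else 0)
}

# Small fixed JEM: three exposed codes plus one zero-prevalence code.
tiny_jem <- function() {
  jem(data.frame(
    isco88 = rep(c("1000", "2000", "3000", "4000"), 2),
    field_kind = rep(c("E", "H"), each = 4),
    intensity = c(2, 0.5, 4, 9, 1, 0.25, 2, 9),
    prevalence = c(0.10, 0.03, 0.30, 0, 0.10, 0.03, 0.30, 0),
    n_basis = 10L))
}

# One-participant spell table in the load_cohort jobs schema.
spells_df <- function(pid = "P1", start, end, isco = "1000",
                      nonstandard = FALSE, source_reported = FALSE,
                      source_uncertain = FALSE) {
  data.frame(pid = pid, start_year = start, end_year = end, isco88 = isco,
             nonstandard = nonstandard, source_reported = source_reported,
             source_uncertain = source_uncertain, stringsAsFactors = FALSE)
}

participants_df <- function(pid, status = "control", diagnosis_year = NA,
                            interview_year = 2002L, age_group = "50-54",
                            sex = "F", region = "UK",
                            education = "university") {
  data.frame(pid = pid, status = status,
             diagnosis_year = as.integer(diagnosis_year),
             interview_year = as.integer(interview_year),
             age_group = age_group, sex = sex, region = region,
             education = education, proxy = FALSE, grade = "n/a",
             preexisting_condition = FALSE, stringsAsFactors = FALSE)
}

# Small synthetic study shared by several test files (cached per session).
small_study <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- synth_config()
      jm <- generate_jem(cfg, 424242)
      syn <- generate_cohort(cfg, jm, 424242, n_total = 1000)
      memo <<- list(cfg = cfg, jm = jm, syn = syn)
    }
    memo
  }
})
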