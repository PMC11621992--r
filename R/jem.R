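#' ICNIRP squared ratio of a source measurement
#'
#' Converts a measured arithmetic-mean field strength into a dimensionless
#' intensity by squaring its ratio to the frequency-specific occupational
#' reference level. Above 100 kHz this quantity is proportional to the
#' specific absorption rate (SAR), which makes intensities comparable across
#' sources operating at very different frequencies.
#'
#' @param mean_field Arithmetic mean E-field (V/m) or H-field (A/m) level of
#'   the source at its operating frequency. Must be >= 0.
#' @param reference_level Occupational reference level for the same field
#'   kind and frequency, in the same units. Must be > 0.
#' @return `(mean_field / reference_level)^2`, a dimensionless intensity.
#'   Vectorized over both arguments.
#' @examples
#' icnirp_ratio(10, 20)   # 0.25
#' icnirp_ratio(0, 61)    # 0
#' @export
icnirp_ratio <- function(mean_field, reference_level) {
  if (!is.numeric(mean_field) || !is.numeric(reference_level))
    stop("mean_field and reference_level must be numeric")
  if (any(!is.finite(reference_level)) || any(reference_level <= 0))
    stop("invalid measurement: reference_level must be finite and > 0")
  if (any(!is.finite(mean_field)) || any(mean_field < 0))
    stop("invalid measurement: mean_field must be finite and >= 0")
  (mean_field / reference_level)^2
}

jem_cols <- c("isco88", "field_kind", "intensity", "prevalence", "n_basis")

#' Construct a job-exposure matrix
#'
#' A JEM assigns, to each 4-digit ISCO88 occupation code and field kind
#' (E = electric, H = magnetic), an exposure intensity (a time-weighted
#' average ICNIRP squared ratio) and a prevalence of exposure (the fraction
#' of workers in the occupation considered exposed). Codes absent from the
#' matrix are unexposed by definition: lookups never fail.
#'
#' @param entries data.frame with columns `isco88` (4-character code),
#'   `field_kind` ("E" or "H"), `intensity` (>= 0), `prevalence` (in
#'   \[0, 1\]) and `n_basis` (count of subjects behind the estimate).
#' @return An object of class `rfjem_jem`.
#' @export
jem <- function(entries) {
  if (!is.data.frame(entries)) stop("entries must be a data.frame")
  missing_cols <- setdiff(jem_cols, names(entries))
  if (length(missing_cols))
    stop("JEM schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  entries <- entries[jem_cols]
  entries$isco88 <- formatC(as.character(entries$isco88), width = 4, flag = "0")
  entries$field_kind <- as.character(entries$field_kind)
  entries$intensity <- as.numeric(entries$intensity)
  entries$prevalence <- as.numeric(entries$prevalence)
  entries$n_basis <- as.integer(entries$n_basis)

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("JEM schema error: ", what, " in row(s) ",
           paste(utils::head(rows, 5L), collapse = ", "))
  }
  bad(!entries$field_kind %in% c("E", "H"), "field_kind not in {E, H}")
  bad(is.na(entries$intensity) | entries$intensity < 0, "intensity missing or < 0")
  bad(is.na(entries$prevalence) | entries$prevalence < 0 | entries$prevalence > 1,
      "prevalence outside [0, 1]")
  key <- paste(entries$isco88, entries$field_kind)
  if (anyDuplicated(key))
    stop("JEM duplicate-key error: (isco88, field_kind) repeated: ",
         paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  rownames(entries) <- NULL
  structure(entries, class = c("rfjem_jem", "data.frame"))
}

#' @export
print.rfjem_jem <- function(x, ...) {
  cat("RF-EMF job-exposure matrix:", nrow(x), "entries,",
      length(unique(x$isco88)), "ISCO88 codes\n")
  for (fk in c("E", "H")) {
    sub <- x[x$field_kind == fk, ]
    if (nrow(sub))
      cat(sprintf("  %s fields: %d codes, %d exposed (prevalence > 0)\n",
                  fk, nrow(sub), sum(sub$prevalence > 0)))
  }
  invisible(x)
}

#' Read a job-exposure matrix from CSV
#'
#' @param path CSV file with header `isco88,field_kind,intensity,prevalence,n_basis`.
#' @return An `rfjem_jem` object; rows violating the entry invariants abort
#'   with a row-numbered message.
#' @export
load_jem <- function(path) {
  df <- utils::read.csv(path, colClasses = c(isco88 = "character"),
                        stringsAsFactors = FALSE)
  jem(df)
}

#' Write a job-exposure matrix to CSV
#'
#' Inverse of [load_jem()]: `load_jem(write_jem(jem, path))` reproduces the
#' matrix exactly.
#'
#' @param x An `rfjem_jem` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_jem <- function(x, path) {
  stopifnot(inherits(x, "rfjem_jem"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up JEM intensity and prevalence for occupation codes
#'
#' Absent codes yield intensity 0 and prevalence 0 (unexposed), never an
#' error. Entries with prevalence 0 yield intensity 0 regardless of the
#' stored intensity value.
#'
#' @param x An `rfjem_jem` object.
#' @param isco88 Character vector of 4-digit codes.
#' @param field_kind "E" or "H" (scalar).
#' @return data.frame with columns `intensity` and `prevalence`, one row per
#'   input code.
#' @export
jem_lookup <- function(x, isco88, field_kind) {
  stopifnot(inherits(x, "rfjem_jem"), field_kind %in% c("E", "H"))
  sub <- x[x$field_kind == field_kind, ]
  i <- match(formatC(as.character(isco88), width = 4, flag = "0"), sub$isco88)
  prev <- ifelse(is.na(i), 0, sub$prevalence[i])
  inten <- ifelse(is.na(i) | prev <= 0, 0, sub$intensity[i])
  data.frame(intensity = inten, prevalence = prev)
}

#' Median exposure prevalence among exposed occupations
#'
#' The specificity threshold used by attribution Method 2: occupations whose
#' prevalence of exposure falls below the median prevalence over all exposed
#' occupations (prevalence > 0) are treated as unexposed. An even number of
#' exposed entries gives the mean of the two middle values (standard sample
#' median).
#'
#' @param x An `rfjem_jem` object.
#' @param field_kind "E" or "H".
#' @return The median prevalence (a fraction).
#' @export
median_prevalence_threshold <- function(x, field_kind) {
  stopifnot(inherits(x, "rfjem_jem"))
  p <- x$prevalence[x$field_kind == field_kind & x$prevalence > 0]
  if (!length(p))
    stop("undefined threshold: no exposed entries for field ", field_kind)
  stats::median(p)
}
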