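#' Percentile cut-points from exposed controls
#'
#' The exposure distributions are heavily right-skewed, so categories are
#' anchored at the 50th, 75th and 90th percentiles of the distribution among
#' exposed controls (never-exposed participants form the reference group and
#' do not contribute; cases never influence cut-points). Quantiles use
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param control_values Exposure values of exposed controls (all > 0), or —
#'   with `include_zeros = TRUE`, a robustness variant — all control values.
#' @param probs Percentile probabilities, default c(0.5, 0.75, 0.9).
#' @param include_zeros Keep zeros in the distribution (default FALSE).
#' @return An `rfjem_cutpoints` object: list with `p50`, `p75`, `p90` (or
#'   the requested probs) and `n`, the number of values used.
#' @export
exposure_cutpoints <- function(control_values, probs = c(0.5, 0.75, 0.9),
                               include_zeros = FALSE) {
  v <- control_values[!is.na(control_values)]
  if (!include_zeros) v <- v[v > 0]
  if (!length(v))
    stop("undefined cut-points: no exposed controls")
  q <- stats::quantile(v, probs = probs, names = FALSE, type = 7)
  structure(list(q = q, probs = probs, n = length(v)),
            class = "rfjem_cutpoints")
}

#' @export
print.rfjem_cutpoints <- function(x, ...) {
  cat("Exposure cut-points (n =", x$n, "exposed controls):\n")
  cat(paste(sprintf("  P%g = %.4g", 100 * x$probs, x$q), collapse = "\n"), "\n")
  invisible(x)
}

#' Assign ordered exposure categories
#'
#' Category 0 = never exposed (the reference group of the primary analysis);
#' 1 = (0, P50]; 2 = (P50, P75]; 3 = (P75, P90]; 4 = above P90. A value
#' exactly equal to a cut-point falls in the lower category.
#'
#' @param value Exposure values (>= 0).
#' @param exposed Logical, same length: ever exposed on this metric.
#' @param cp An `rfjem_cutpoints` with three cut-points.
#' @return Factor with levels "0".."4" (category 0 iff not exposed).
#' @export
assign_category <- function(value, exposed, cp) {
  stopifnot(inherits(cp, "rfjem_cutpoints"), length(cp$q) == 3,
            length(value) == length(exposed), all(value >= 0))
  cat <- ifelse(!exposed, 0L,
                1L + (value > cp$q[1]) + (value > cp$q[2]) + (value > cp$q[3]))
  factor(cat, levels = 0:4)
}

#' Move the reference to the low-exposed group
#'
#' Sensitivity analysis: instead of the never-exposed, the low-exposed
#' category (1) serves as reference, and "unexposed" becomes an ordinary
#' non-reference level. Category membership is unchanged — only the factor
#' level order (hence the implied reference in a model matrix) moves.
#'
#' @param categories Factor from [assign_category()].
#' @return The same factor with levels reordered to c("1","0","2","3","4").
#' @export
rebase_reference <- function(categories) {
  stopifnot(is.factor(categories))
  factor(categories, levels = c("1", "0", "2", "3", "4"))
}

#' Indicator design matrix for exposure categories
#'
#' Expands a category factor into 0/1 indicator columns for every
#' non-reference level (the first factor level is the reference).
#'
#' @param categories Factor of categories.
#' @param prefix Column-name prefix.
#' @return Numeric matrix with one column per non-reference level.
#' @export
category_design <- function(categories, prefix = "cat") {
  lev <- levels(categories)[-1]
  X <- vapply(lev, function(l) as.numeric(categories == l),
              numeric(length(categories)))
  colnames(X) <- paste0(prefix, lev)
  X
}

#' Write cut-points to CSV
#'
#' @param df data.frame with columns
#'   `label,field_kind,method,metric,p50,p75,p90,n_exposed_controls`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutpoints <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
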