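#' Match detections to ground truth
#'
#' One-to-one greedy matching by increasing centroid distance: the
#' closest unmatched detection/truth pair is matched repeatedly, and
#' pairs farther apart than `tol_m` stay unmatched.  The default
#' tolerance of 2 m is about one body length of the animals considered.
#'
#' @param detections a `detection_set` (or data frame with `x`, `y`).
#' @param truth ground truth: the `truth` element of [generate_scene()],
#'   or a [point_set()] of true centroids.
#' @param tol_m matching tolerance in meters (> 0).
#' @param area_id label for the resulting counts row.
#' @return An `area_counts` data frame with columns `area_id`,
#'   `reference`, `classified`, `correct`.
#' @export
match_detections <- function(detections, truth, tol_m = 2.0,
                             area_id = "scene") {
  stopifnot(tol_m > 0)
  det <- if (inherits(detections, "detection_set")) detections$detections
         else detections
  tp <- if (!is.null(truth$animals)) truth$animals else truth
  nd <- nrow(det); nt <- nrow(tp)
  correct <- 0L
  if (nd > 0 && nt > 0) {
    D <- outer(det$x, tp$x, "-")^2 + outer(det$y, tp$y, "-")^2
    D <- sqrt(D)
    repeat {
      m <- which.min(D)
      if (!length(m) || D[m] > tol_m) break
      i <- (m - 1) %% nd + 1; j <- (m - 1) %/% nd + 1
      correct <- correct + 1L
      D[i, ] <- Inf; D[, j] <- Inf
      if (!is.finite(min(D))) break
    }
  }
  area_counts(area_id, reference = nt, classified = nd, correct = correct)
}

#' Per-area detection counts
#'
#' @param area_id area label(s).
#' @param reference consensus manual count(s).
#' @param classified automated count(s).
#' @param correct matched detection count(s);
#'   `correct <= min(reference, classified)` is enforced.
#' @param ... further columns (e.g. a grouping variable).
#' @return A data frame of class `area_counts`.
#' @export
area_counts <- function(area_id, reference, classified, correct, ...) {
  stopifnot(all(reference >= 0), all(classified >= 0), all(correct >= 0),
            all(correct <= pmin(reference, classified)))
  df <- data.frame(area_id = area_id, reference = as.integer(reference),
                   classified = as.integer(classified),
                   correct = as.integer(correct), ...,
                   stringsAsFactors = FALSE)
  class(df) <- c("area_counts", "data.frame")
  df
}

#' Count, omission and commission error rates
#'
#' For each row of counts:
#' \itemize{
#'   \item count error = |classified - reference| / reference x 100
#'     (set `signed = TRUE` for the signed variant);
#'   \item omission error = (reference - correct) / reference x 100,
#'     the percentage of true animals missed;
#'   \item commission error = (classified - correct) / classified x 100,
#'     the percentage of detections that are not true animals.
#' }
#' Zero denominators yield `NA` (reported as undefined, not as 0).
#'
#' @param counts an [area_counts()] data frame.
#' @param signed report signed count error.
#' @return The data frame with `count_error_pct`, `omission_pct`,
#'   `commission_pct` columns appended.
#' @export
error_rates <- function(counts, signed = FALSE) {
  ce <- (counts$classified - counts$reference) / counts$reference * 100
  if (!signed) ce <- abs(ce)
  ce[counts$reference == 0] <- NA_real_
  om <- (counts$reference - counts$correct) / counts$reference * 100
  om[counts$reference == 0] <- NA_real_
  co <- (counts$classified - counts$correct) / counts$classified * 100
  co[counts$classified == 0] <- NA_real_
  counts$count_error_pct <- ce
  counts$omission_pct <- om
  counts$commission_pct <- co
  counts
}

#' Aggregate counts across areas
#'
#' Aggregates are computed from summed counts, never by averaging
#' percentages.
#'
#' @param counts an [area_counts()] data frame.
#' @param by optional column name to group by; otherwise one total row.
#' @param area_id label for ungrouped aggregation.
#' @return An [area_counts()] data frame of aggregates.
#' @export
aggregate_counts <- function(counts, by = NULL, area_id = "total") {
  if (is.null(by)) {
    return(area_counts(area_id, sum(counts$reference),
                       sum(counts$classified), sum(counts$correct)))
  }
  agg <- lapply(split(counts, counts[[by]]), function(g) {
    area_counts(g[[by]][1], sum(g$reference), sum(g$classified),
                sum(g$correct))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Chi-square test of error-rate independence between two areas
#'
#' Tests whether an error rate differs between two areas (e.g. a
#' high-density and a low-density pilot area) with Pearson's chi-square
#' on the 2 x 2 table \[error, non-error\] x \[area A, area B\], without
#' continuity correction, df = 1.  Omission errors are counted against
#' the reference totals, commission errors against the classified
#' totals.
#'
#' @param counts_a,counts_b single-row [area_counts()] (or aggregates).
#' @param error_type `"omission"` or `"commission"`.
#' @return A list with `chi2`, `p`, and the underlying `table`.
#' @export
chi2_error_independence <- function(counts_a, counts_b,
                                    error_type = c("omission",
                                                   "commission")) {
  error_type <- match.arg(error_type)
  get_cell <- function(cn) {
    if (error_type == "omission") {
      err <- cn$reference - cn$correct
      tot <- cn$reference
    } else {
      err <- cn$classified - cn$correct
      tot <- cn$classified
    }
    if (tot <= 0) stop("empty margin: zero denominator for ", error_type)
    c(sum(err), sum(tot - err))
  }
  tab <- cbind(get_cell(counts_a), get_cell(counts_b))
  dimnames(tab) <- list(c("error", "non_error"),
                        c(as.character(counts_a$area_id[1]),
                          as.character(counts_b$area_id[1])))
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ht$statistic), p = ht$p.value, table = tab)
}

#' Coefficient of variation of interpreter counts
#'
#' Agreement between independent manual counts of the same area: sample
#' standard deviation over mean, as a percentage.
#'
#' @param counts integer vector, one count per interpreter (>= 2).
#' @return CV in percent.
#' @export
interpreter_cv <- function(counts) {
  if (length(counts) < 2) stop("need at least two interpreter counts")
  m <- mean(counts)
  if (m <= 0) stop("mean count must be positive")
  stats::sd(counts) / m * 100
}
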