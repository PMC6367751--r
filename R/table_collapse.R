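#' Stratified disease-count table
#'
#' Counts of diseased / not-diseased subjects by exposure category within
#' strata of a second exposure — the raw material for the relative-risk
#' demonstration that collapsing exposure categories can manufacture an
#' interaction.
#'
#' @param df A data frame with columns `stratum`, `category`, `diseased`,
#'   `not_diseased`. Counts must be non-negative integers, every
#'   (stratum, category) combination must be present exactly once, and every
#'   cell total must be positive.
#'
#' @return An object of class `"stratified_count_table"` (a validated data
#'   frame with an added `total` column).
#' @examples
#' stratified_count_table(data.frame(
#'   stratum = c(1, 1, 2, 2), category = c(1, 2, 1, 2),
#'   diseased = c(5, 10, 2, 4), not_diseased = c(95, 90, 98, 96)))
#' @export
stratified_count_table <- function(df) {
  req <- c("stratum", "category", "diseased", "not_diseased")
  if (!all(req %in% names(df))) {
    stop("table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[req]
  cnts <- c(df$diseased, df$not_diseased)
  if (any(!is.finite(cnts)) || any(cnts < 0) || any(cnts != round(cnts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  combos <- table(df$stratum, df$category)
  if (any(combos != 1L)) {
    stop("every (stratum, category) combination must appear exactly once",
         call. = FALSE)
  }
  df$total <- df$diseased + df$not_diseased
  if (any(df$total <= 0)) {
    stop("every (stratum, category) cell needs a positive total",
         call. = FALSE)
  }
  df <- df[order(df$stratum, df$category), ]
  rownames(df) <- NULL
  structure(df, class = c("stratified_count_table", "data.frame"))
}

#' Read a stratified count table from CSV
#'
#' Expects the columns of [stratified_count_table()]. Lines starting with `#`
#' are treated as comments. The bundled four-category demonstration table is
#' at `system.file("extdata", "collapse_demo.csv", package = "spurint")`.
#'
#' @param path CSV file path.
#' @return A [stratified_count_table()].
#' @examples
#' read_count_table(system.file("extdata", "collapse_demo.csv",
#'                              package = "spurint"))
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  stratified_count_table(df)
}

#' Per-stratum risks and relative risks
#'
#' Computes the disease risk (diseased / total) in every cell and the relative
#' risk (RR) against the reference category within each stratum. RRs are kept
#' as exact fractions of the counts; rounding is a display matter.
#'
#' @param t A [stratified_count_table()].
#' @param reference Reference category label; defaults to the lowest-sorted
#'   category. Its risk must be positive in every stratum.
#'
#' @return An object of class `"rr_table"`: data frame with `stratum`,
#'   `category`, `diseased`, `total`, `risk`, `rr`, plus attribute
#'   `"reference"`.
#' @examples
#' relative_risks(read_count_table(
#'   system.file("extdata", "collapse_demo.csv", package = "spurint")))
#' @export
relative_risks <- function(t, reference = NULL) {
  stopifnot(inherits(t, "stratified_count_table"))
  cats <- sort(unique(t$category))
  if (is.null(reference)) reference <- cats[1L]
  if (!reference %in% cats) stop("reference category not present", call. = FALSE)
  t$risk <- t$diseased / t$total
  ref_risk <- t$risk[t$category == reference]
  names(ref_risk) <- t$stratum[t$category == reference]
  if (any(ref_risk == 0)) {
    stop("reference category has zero risk in some stratum", call. = FALSE)
  }
  t$rr <- t$risk / ref_risk[as.character(t$stratum)]
  out <- t[c("stratum", "category", "diseased", "total", "risk", "rr")]
  attr(out, "reference") <- reference
  class(out) <- c("rr_table", "data.frame")
  out
}

#' @export
print.rr_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$risk <- round(y$risk, 4)
  y$rr <- round(y$rr, digits)
  cat(sprintf("relative risks (reference category: %s)\n",
              attr(x, "reference")))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Collapse exposure categories
#'
#' Merges categories of the column exposure according to a surjective map and
#' sums the counts within each new category per stratum. Totals are conserved
#' exactly; it is the within-category risk composition that changes, which is
#' how collapsing creates heterogeneous relative risks across strata.
#'
#' @param t A [stratified_count_table()].
#' @param map Named vector or list: `names(map)` are the old category labels,
#'   values the new ones. Every old category must be mapped and at least two
#'   distinct new categories must remain.
#'
#' @return A [stratified_count_table()] on the new categories.
#' @examples
#' t3 <- read_count_table(system.file("extdata", "collapse_demo.csv",
#'                                    package = "spurint"))
#' collapse_table(t3, c(`1` = 1, `2` = 1, `3` = 2, `4` = 2))
#' @export
collapse_table <- function(t, map) {
  stopifnot(inherits(t, "stratified_count_table"))
  map <- unlist(map)
  old <- unique(as.character(t$category))
  if (!all(old %in% names(map))) {
    stop("unmapped categories: ",
         paste(setdiff(old, names(map)), collapse = ", "), call. = FALSE)
  }
  if (length(unique(map[old])) < 2L) {
    stop("collapse must leave at least two categories", call. = FALSE)
  }
  new_cat <- map[as.character(t$category)]
  agg <- stats::aggregate(cbind(diseased, not_diseased) ~ stratum + new_cat,
                          data = transform(as.data.frame(t), new_cat = new_cat),
                          FUN = sum)
  names(agg)[names(agg) == "new_cat"] <- "category"
  stratified_count_table(agg)
}

#' Homogeneity of relative risks across strata
#'
#' For each non-reference category, compares the relative risks across strata
#' by their max/min ratio. Exactly homogeneous RRs mean no interaction between
#' the stratum variable and the exposure on the relative-risk scale; any
#' ratio above `threshold` is flagged. The default threshold reports any
#' inhomogeneity beyond numerical noise; display rounding is two decimals.
#'
#' @param r An [relative_risks()] result.
#' @param threshold Flag ratio strictly above this (default `1 + 1e-9`).
#'
#' @return An object of class `"homogeneity_report"`: data frame with
#'   `category`, `rr_min`, `rr_max`, `ratio`, `flagged`, plus attribute
#'   `"homogeneous"` (TRUE when nothing is flagged; a single-stratum table is
#'   trivially homogeneous).
#' @examples
#' t3 <- read_count_table(system.file("extdata", "collapse_demo.csv",
#'                                    package = "spurint"))
#' interaction_check(relative_risks(t3))   # homogeneous: RRs 1,2,3,4 twice
#' @export
interaction_check <- function(r, threshold = 1 + 1e-9) {
  stopifnot(inherits(r, "rr_table"))
  reference <- attr(r, "reference")
  nonref <- unique(r$category[r$category != reference])
  n_strata <- length(unique(r$stratum))
  rows <- lapply(nonref, function(cc) {
    rrs <- r$rr[r$category == cc]
    data.frame(category = cc, rr_min = min(rrs), rr_max = max(rrs),
               ratio = max(rrs) / min(rrs))
  })
  out <- do.call(rbind, rows)
  out$flagged <- n_strata >= 2L & out$ratio > threshold
  attr(out, "homogeneous") <- !any(out$flagged)
  attr(out, "reference") <- reference
  class(out) <- c("homogeneity_report", "data.frame")
  out
}

#' @export
print.homogeneity_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$rr_min <- round(y$rr_min, digits); y$rr_max <- round(y$rr_max, digits)
  y$ratio <- round(y$ratio, digits + 2)
  print(y, row.names = FALSE)
  cat(if (attr(x, "homogeneous")) {
    "relative risks homogeneous across strata: no interaction on the RR scale\n"
  } else {
    "relative risks differ across strata: interaction on the RR scale\n"
  })
  invisible(x)
}
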