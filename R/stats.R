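#' Descriptive statistics of a trait table
#'
#' Per-trait mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum over all individual nut rows.
#'
#' @param table a trait table (see [read_trait_table()]).
#' @return A data.frame with columns `trait` (display name), `column`,
#'   `mean`, `sd`, `min`, `max`, `n` and `sd_defined` (`FALSE` when n = 1, in
#'   which case `sd` is reported as 0).
#' @export
summarize_traits <- function(table) {
  table <- validate_trait_table(table)
  cols <- trait_columns()
  rows <- lapply(names(cols), function(cn) {
    v <- table[[cn]]
    v <- v[!is.na(v)]
    if (!length(v)) stop("trait column ", cn, " has no data")
    data.frame(trait = cols[[cn]], column = cn, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v), n = length(v),
               sd_defined = length(v) > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations between trait columns and two-sided
#' p-values from the t distribution with n - 2 degrees of freedom. A
#' zero-variance column yields `NA` correlations with a warning (never a
#' silent 0). No multiple-testing correction is applied by default;
#' `adjust = "bonferroni"` corrects the p-values for the number of distinct
#' pairs.
#'
#' @param table a trait table.
#' @param columns trait columns to include (default all fourteen).
#' @param adjust "none" (default) or "bonferroni".
#' @return List with `r` (correlation matrix, unit diagonal), `p` (p-value
#'   matrix, `NA` diagonal) and `n` (rows used).
#' @export
correlation_matrix <- function(table, columns = names(trait_columns()),
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  check_numeric_columns(table, columns)
  x <- as.matrix(table[, columns, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 complete rows for correlations")
  zv <- apply(x, 2, stats::sd) == 0
  if (any(zv))
    warning("zero-variance column(s): ", paste(columns[zv], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(x))
  r[zv, ] <- NA_real_; r[, zv] <- NA_real_
  diag(r)[!zv] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  if (adjust == "bonferroni") {
    m <- ncol(x) * (ncol(x) - 1) / 2
    p <- pmin(1, p * m)
  }
  list(r = r, p = p, n = n)
}

#' Principal component analysis of a trait table
#'
#' Traits are centred and scaled to unit variance before the
#' eigendecomposition. Component signs are fixed deterministically (the
#' largest-magnitude loading of each component is made positive). The
#' squared cosines give, per nut, the quality of representation of each
#' component (scores squared over the row's total squared distance).
#'
#' @param table a trait table.
#' @param columns trait columns to include.
#' @param standardize scale columns to unit variance (default `TRUE`).
#' @return List with `explained_variance_pct` (sums to 100, non-increasing),
#'   `loadings`, `scores`, `squared_cosines` and `sdev`.
#' @export
run_pca <- function(table, columns = names(trait_columns()),
                    standardize = TRUE) {
  check_numeric_columns(table, columns)
  x <- as.matrix(table[, columns, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete rows for PCA")
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant trait column(s): ",
         paste(columns[apply(x, 2, stats::sd) == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  cos2 <- pc$x^2 / rowSums(pc$x^2)
  list(explained_variance_pct = 100 * ev / sum(ev),
       loadings = pc$rotation, scores = pc$x, squared_cosines = cos2,
       sdev = pc$sdev)
}

#' Rank accessions by a trait
#'
#' Per-accession mean and standard deviation of one trait, sorted in the
#' requested direction; used to shortlist superior genotypes (e.g. thinnest
#' shells, highest kernel filling ratio).
#'
#' @param table a trait table.
#' @param trait a trait column name (e.g. `"T_mm"`) or display name
#'   (e.g. `"Shell thickness"`).
#' @param direction "asc" (smallest first) or "desc".
#' @param n number of accessions returned.
#' @return Data.frame with `accession_id`, `mean`, `sd`, `n_nuts`, ordered.
#' @export
top_accessions <- function(table, trait, direction = c("asc", "desc"),
                           n = 10L) {
  direction <- match.arg(direction)
  if (!"accession_id" %in% names(table))
    stop("table has no accession_id column")
  cols <- trait_columns()
  cn <- if (trait %in% names(cols)) trait else names(cols)[match(trait, cols)]
  if (is.na(cn) || !cn %in% names(table))
    stop("unknown trait: '", trait, "' (use one of: ",
         paste(names(cols), collapse = ", "), " or the display ",
         "names in trait_columns())")
  v <- table[[cn]]
  ok <- !is.na(v)
  agg <- aggregate(v[ok], by = list(accession_id = table$accession_id[ok]),
                   FUN = function(z) c(mean = mean(z),
                                       sd = if (length(z) > 1) stats::sd(z) else 0,
                                       n = length(z)))
  out <- data.frame(accession_id = agg$accession_id,
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n_nuts = as.integer(agg$x[, "n"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean, decreasing = direction == "desc"), ]
  utils::head(out, n)
}

check_numeric_columns <- function(table, columns) {
  missing <- setdiff(columns, names(table))
  if (length(missing))
    stop("column(s) not in table: ", paste(missing, collapse = ", "))
  bad <- columns[!vapply(table[columns], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric column(s): ", paste(bad, collapse = ", "))
  invisible(table)
}
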