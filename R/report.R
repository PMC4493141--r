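# Variant tables, mutation bookkeeping, and correlation of predicted local
# stability with experimental melting temperatures.

#' Expand an incremental mutation list
#'
#' Variant tables state mutations incrementally ("4D3 + M134E, M137P,
#' S163P"); this resolves the base references recursively to a flat list.
#' When a position is mutated more than once along the chain of bases, the
#' most-derived entry wins. Cyclic references are an error.
#'
#' @param variant variant name present in `table`.
#' @param table a data frame with columns `variant` and `mutations` (see
#'   [table1_fixture()]); `-` or empty means no mutations.
#' @return character vector of mutations (`A15S` style), ordered by
#'   position.
#' @examples
#' expand_mutations("6B", table1_fixture())
#' @export
expand_mutations <- function(variant, table = table1_fixture()) {
  .expand_mutations(variant, table, visiting = character(0))
}

.expand_mutations <- function(variant, table, visiting) {
  if (variant %in% visiting)
    stop("cyclic mutation reference involving ", variant)
  row <- which(table$variant == variant)
  if (length(row) != 1) stop("unknown variant: ", variant)
  mut_spec <- trimws(table$mutations[row])
  if (mut_spec %in% c("-", "", NA)) return(character(0))

  parts <- trimws(strsplit(mut_spec, "\\+")[[1]])
  base_muts <- character(0)
  if (length(parts) == 2 && parts[1] %in% table$variant) {
    base_muts <- .expand_mutations(parts[1], table, c(visiting, variant))
    mut_spec <- parts[2]
  } else if (length(parts) > 1) {
    stop("cannot parse mutation list: ", table$mutations[row])
  }
  own <- trimws(strsplit(mut_spec, ",")[[1]])
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", own)
  if (!all(ok)) stop("malformed mutation token(s): ",
                     paste(own[!ok], collapse = ", "))
  pos <- function(m) as.integer(gsub("[^0-9]", "", m))
  merged <- c(base_muts, own)
  # most-derived entry wins on duplicate positions
  keep <- !duplicated(vapply(rev(merged), pos, integer(1)))
  merged <- rev(rev(merged)[keep])
  merged[order(vapply(merged, pos, integer(1)))]
}

#' Sequence identity of a variant to the wild type
#'
#' @param variant variant name (or a character vector of mutations).
#' @param length sequence length (181 for the lipase).
#' @param table variant table for name lookup.
#' @return percent identity.
#' @export
sequence_identity <- function(variant, length = 181, table = table1_fixture()) {
  muts <- if (is.character(variant) && length(variant) == 1 &&
              variant %in% table$variant)
    expand_mutations(variant, table) else variant
  n_mut <- length(unique(gsub("[^0-9]", "", muts)))
  if (n_mut > length) stop("more mutations than residues")
  100 * (length - n_mut) / length
}

#' Ordinary least-squares fit with correlation statistics
#'
#' Fits `y` on `x` and reports the coefficient of determination, Pearson r,
#' slope, intercept, and the two-sided p-value of the correlation (t
#' distribution with n - 2 degrees of freedom).
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return object of class `cna_correlation`: list with `n`, `r`,
#'   `r_squared`, `slope`, `intercept`, `p_value`.
#' @examples
#' fit <- linear_fit_r2(1:5, 2 * (1:5) + 1)
#' fit$r_squared
#' @export
linear_fit_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate variance: correlation undefined")
  r <- cor(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  fit <- lm(y ~ x)
  structure(list(n = n, r = r, r_squared = r^2,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = 2 * pt(-abs(tstat), df = n - 2)),
            class = "cna_correlation")
}

#' @export
print.cna_correlation <- function(x, ...) {
  cat(sprintf("n = %d, R^2 = %.3f (r = %.3f), slope = %.3f, p = %.4g\n",
              x$n, x$r_squared, x$r, x$slope, x$p_value))
  invisible(x)
}

#' Assemble the variant report
#'
#' Joins predicted stabilities onto the variant table and computes the
#' standard correlation subsets against experimental melting temperatures:
#' the wild type plus all thermodynamically characterized mutants, the same
#' set with the wild-type value replaced by its multi-crystal-structure
#' average, the crystal-structure rows only, and the side-chain-modeled
#' rows only.
#'
#' @param records variant table (defaults to the packaged one).
#' @param predictions optional data frame with `variant` and
#'   `rc_median_K` (and optionally `t_p`) columns; when omitted the printed
#'   `rc_median_K` column of `records` is used, which reproduces the
#'   published-table analysis.
#' @return list with `table` (the joined data frame), `correlations` (list
#'   of `cna_correlation` for subsets `all`, `averaged_wt`, `xray`,
#'   `modeled`), and `missing` (variants without predictions).
#' @export
build_report <- function(records = table1_fixture(), predictions = NULL) {
  tab <- records
  if (!is.null(predictions)) {
    stopifnot(all(c("variant", "rc_median_K") %in% names(predictions)))
    idx <- match(tab$variant, predictions$variant)
    tab$predicted_rc_K <- predictions$rc_median_K[idx]
    if ("t_p" %in% names(predictions)) tab$predicted_t_p <- predictions$t_p[idx]
    missing <- tab$variant[is.na(idx)]
  } else {
    tab$predicted_rc_K <- tab$rc_median_K
    missing <- character(0)
  }

  thermo <- tab$source %in% c("wild_type", "rao") & !is.na(tab$t_m)
  # subsets with too few joined predictions yield NULL rather than failing
  corr <- function(rows, rc = tab$predicted_rc_K)
    tryCatch(linear_fit_r2(tab$t_m[rows], rc[rows]),
             error = function(e) NULL)

  rc_avg <- tab$predicted_rc_K
  wt <- which(tab$source == "wild_type")
  if (length(wt) == 1 && !is.na(tab$rc_median_avg_K[wt]) && is.null(predictions))
    rc_avg[wt] <- tab$rc_median_avg_K[wt]

  correlations <- list(
    all = corr(which(thermo)),
    averaged_wt = corr(which(thermo), rc_avg),
    xray = corr(which(thermo & tab$is_xray)),
    modeled = corr(which(thermo & tab$is_modeled))
  )
  list(table = tab, correlations = correlations, missing = missing)
}
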