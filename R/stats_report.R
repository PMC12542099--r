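#' Univariate statistics and feature-importance reporting
#'
#' Group comparisons between pCR and non-pCR patients (Mann-Whitney U for
#' continuous variables; Chi-square or Fisher's exact for categorical,
#' decided by expected cell counts), Spearman rank correlations of
#' features with residual infiltration size (pCR patients carry RIS 0),
#' and ranked favorable/adverse LASSO-weight reports. All tests are
#' two-sided; significance is declared at P < 0.05 and no multiple-testing
#' correction is applied (the number of tests run is reported alongside).
#'
#' @name stats_report
NULL

#' Compare one variable between two outcome groups
#'
#' Continuous variables use the two-sided Mann-Whitney U test (exact when
#' both groups have at most 20 members and no ties; otherwise the
#' tie-corrected normal approximation). Categorical and ordinal variables
#' use Fisher's exact test unless every expected cell count exceeds 5
#' (the Chi-square large-sample approximation needs all expected counts
#' safely above the small-count regime).
#'
#' @param values Variable values.
#' @param groups Two-level grouping vector (e.g. pCR indicator).
#' @param kind `"continuous"`, `"categorical"` or `"ordinal"`.
#' @return List `test`, `statistic`, `p_value`, `significant`,
#'   `group_medians` (continuous only).
#' @export
compare_groups <- function(values, groups,
                           kind = c("continuous", "categorical",
                                    "ordinal")) {
  kind <- match.arg(kind)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  if (kind == "continuous") {
    x <- values[g == levels(g)[1L]]
    y <- values[g == levels(g)[2L]]
    has_ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- length(x) <= 20L && length(y) <= 20L && !has_ties
    ht <- stats::wilcox.test(x, y, exact = use_exact,
                             correct = !use_exact)
    res <- list(test = "mann_whitney",
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                group_medians = stats::setNames(
                  c(stats::median(x), stats::median(y)), levels(g)))
  } else {
    tab <- table(factor(values), g)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L) ||
        nrow(tab) < 2L)
      stop("degenerate contingency table (a margin of zeros)")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected <= 5)) {
      ht <- stats::fisher.test(tab)
      res <- list(test = "fisher_exact", statistic = NA_real_,
                  p_value = ht$p.value)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res <- list(test = "chi_square",
                  statistic = unname(ht$statistic),
                  p_value = ht$p.value)
    }
  }
  res$significant <- res$p_value < 0.05
  res
}

#' Spearman correlation of a feature with residual infiltration size
#'
#' Residual infiltration size is 0 for every pCR patient, so the RIS
#' vector typically contains a block of ties; ties are handled by
#' midranks, and the two-sided P value comes from the t approximation on
#' the midrank correlation.
#'
#' @param feature Numeric feature values.
#' @param ris Residual infiltration sizes (cm), paired with `feature`.
#' @return List `test`, `rho`, `p_value`, `significant`.
#' @export
spearman_vs_ris <- function(feature, ris) {
  if (length(feature) != length(ris)) stop("inputs must be paired")
  if (length(feature) < 3L) stop("at least 3 pairs are required")
  if (stats::sd(feature) == 0 || stats::sd(ris) == 0) {
    return(list(test = "spearman", rho = NA_real_, p_value = NA_real_,
                significant = NA, degenerate = TRUE))
  }
  ht <- suppressWarnings(stats::cor.test(feature, ris,
                                         method = "spearman",
                                         exact = FALSE))
  list(test = "spearman", rho = unname(ht$estimate),
       p_value = ht$p.value, significant = ht$p.value < 0.05,
       degenerate = FALSE)
}

#' Ranked favorable / adverse feature report from LASSO weights
#'
#' Features are sorted by signed weight; the top three positive weights
#' are reported as favorable for pCR and the top three negative weights as
#' adverse. Zero-weight features are dropped.
#'
#' @param weights Named numeric vector of selected-feature weights.
#' @param n_top How many features per direction; default 3.
#' @return List `favorable`, `adverse` (character vectors), `table` (data
#'   frame of feature, weight, direction, sorted by weight).
#' @export
importance_report <- function(weights, n_top = 3L) {
  if (length(weights) == 0L) stop("empty weight set")
  w <- weights[weights != 0]
  w <- sort(w, decreasing = TRUE)
  pos <- names(w)[w > 0]
  neg <- rev(names(w)[w < 0])
  tab <- data.frame(feature = names(w), weight = unname(w),
                    direction = ifelse(w > 0, "favorable", "adverse"),
                    stringsAsFactors = FALSE)
  list(favorable = utils::head(pos, n_top),
       adverse = utils::head(neg, n_top),
       table = tab)
}

#' Univariate screen of a cohort table
#'
#' Runs [compare_groups()] for each feature against the outcome and
#' [spearman_vs_ris()] against residual infiltration size.
#'
#' @param df Cohort table with `pcr` and `ris_cm` columns.
#' @param features Feature column names; default every numeric feature
#'   column.
#' @param kinds Optional named character vector of variable kinds;
#'   defaults to `"continuous"`, with 0/1 columns treated as categorical.
#' @return Data frame: `feature`, `test`, `statistic`, `p_value`,
#'   `significant`, `rho_ris`, `p_ris`; attribute `n_tests` records how
#'   many hypotheses were tested (no correction applied).
#' @export
univariate_table <- function(df, features = NULL, kinds = NULL) {
  if (is.null(features))
    features <- setdiff(colnames(df)[vapply(df, is.numeric, TRUE)],
                        c("pcr", "ris_cm"))
  rows <- lapply(features, function(f) {
    v <- df[[f]]
    kind <- if (!is.null(kinds) && f %in% names(kinds)) kinds[[f]]
            else if (all(v %in% c(0, 1), na.rm = TRUE)) "categorical"
            else "continuous"
    cg <- tryCatch(compare_groups(v, df$pcr, kind),
                   error = function(e) list(test = NA_character_,
                                            statistic = NA_real_,
                                            p_value = NA_real_,
                                            significant = NA))
    sp <- tryCatch(spearman_vs_ris(v, df$ris_cm),
                   error = function(e) list(rho = NA_real_,
                                            p_value = NA_real_))
    data.frame(feature = f, test = cg$test,
               statistic = if (is.null(cg$statistic)) NA_real_
                           else cg$statistic,
               p_value = cg$p_value, significant = cg$significant,
               rho_ris = sp$rho, p_ris = sp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- 2L * length(features)
  out
}
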