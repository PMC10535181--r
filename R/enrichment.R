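# Chemical-class set enrichment driven by the Bayesian outputs: the
# probability of direction plays the role of the p-value, the posterior
# median that of the effect size, and each class is tested for an excess of
# small p-analogs with a one-sided Kolmogorov-Smirnov test against
# Uniform(0, 1).

#' Convert probability of direction to a p-value analog
#'
#' \code{p = 2 (1 - pd)}, so that pd = 0.975 maps to 0.05 — the same
#' boundary at which a 95\% credible interval starts excluding zero.
#'
#' @param pd numeric vector in [0.5, 1].
#' @return p-analogs in [0, 1].
#' @export
pd_to_p <- function(pd) {
  if (anyNA(pd) || any(pd < 0.5 | pd > 1))
    stop("pd must lie in [0.5, 1]")
  2 * (1 - pd)
}

#' One-sided KS enrichment test for one class
#'
#' Tests whether the class's p-analogs are left-shifted relative to
#' Uniform(0, 1), i.e. carry an excess of small values. The statistic is
#' D+ = max_i (i/n - p_(i)); anti-enrichment (a right shift) scores near
#' zero by construction.
#'
#' @param p_analogs p-value analogs of the class members.
#' @param min_size minimum class size (default 3); smaller classes return
#'   \code{NULL} (skipped, not an error).
#' @return list \code{ks_stat}, \code{p_value}, \code{n}; or \code{NULL}.
#' @export
ks_enrich <- function(p_analogs, min_size = 3) {
  n <- length(p_analogs)
  if (n < min_size) return(NULL)
  if (any(p_analogs < 0 | p_analogs > 1)) stop("p-analogs must lie in [0, 1]")
  kt <- suppressWarnings(
    ks.test(p_analogs, "punif", alternative = "greater"))
  list(ks_stat = unname(kt$statistic), p_value = unname(kt$p.value), n = n)
}

#' Chemical-class enrichment from a Bayesian result table
#'
#' Groups compounds by their annotated chemical class, tests each class of
#' at least \code{min_class_size} members with \code{\link{ks_enrich}},
#' adjusts across classes by Benjamini-Hochberg, and classifies each
#' class's direction from the posterior medians of all its members
#' (up if every median is positive, down if every one is negative,
#' otherwise mixed). Compounds without a class label, or labeled
#' "Unknown", are excluded.
#'
#' @param results \code{\link{run_bayes}} table (needs compound_id, pd,
#'   posterior_median).
#' @param annotations compound annotation data.frame (compound_id,
#'   chem_class).
#' @param min_class_size smallest class tested (default 3).
#' @return data.frame: chem_class, n_members, ks_stat, p_value,
#'   p_adjusted, fraction_up, direction; attribute \code{skipped_classes}
#'   lists classes below the size threshold.
#' @export
run_enrichment <- function(results, annotations, min_class_size = 3) {
  stopifnot(all(c("compound_id", "pd", "posterior_median") %in%
                  names(results)))
  ann <- annotations[, c("compound_id", "chem_class")]
  df <- merge(results, ann, by = "compound_id")
  df <- df[!is.na(df$chem_class) & !(df$chem_class %in% c("", "Unknown")), ,
           drop = FALSE]
  if (nrow(df) == 0) stop("no compounds carry a usable chemical class")
  classes <- split(df, df$chem_class)
  skipped <- character(0)
  rows <- list()
  for (cl in names(classes)) {
    sub <- classes[[cl]]
    kt <- ks_enrich(pd_to_p(sub$pd), min_size = min_class_size)
    if (is.null(kt)) { skipped <- c(skipped, cl); next }
    fu <- mean(sub$posterior_median > 0)
    rows[[cl]] <- data.frame(
      chem_class = cl, n_members = kt$n,
      ks_stat = kt$ks_stat, p_value = kt$p_value,
      fraction_up = fu,
      direction = if (fu == 1) "up" else if (fu == 0) "down" else "mixed",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no chemical class reaches min_class_size = ", min_class_size)
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_adjusted, out$p_value), c("chem_class", "n_members",
             "ks_stat", "p_value", "p_adjusted", "fraction_up", "direction")]
  rownames(out) <- NULL
  attr(out, "skipped_classes") <- skipped
  out
}
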