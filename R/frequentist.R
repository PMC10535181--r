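# Classic comparator: per-compound OLS with covariates, two-sided t test on
# the group coefficient, Benjamini-Hochberg FDR across compounds.

#' Ordinary least-squares fit of one compound
#'
#' Classical OLS of the autoscaled abundance on the group indicator plus
#' encoded covariates; the reported coefficient is the group effect on the
#' autoscaled-log scale, with a two-sided t test on n - k residual degrees
#' of freedom.
#'
#' @param y numeric response vector (one compound, autoscaled).
#' @param design model matrix from \code{\link{encode_design}} (must
#'   contain a \code{group} column).
#' @return list: \code{beta_p}, \code{se}, \code{t}, \code{p_value},
#'   \code{df}.
#' @export
fit_ols <- function(y, design) {
  res <- .ols_matrix(matrix(y, ncol = 1), design)
  list(beta_p = unname(res$beta[1]), se = unname(res$se[1]),
       t = unname(res$t[1]), p_value = unname(res$p[1]), df = res$df)
}

# Vectorized OLS across compounds sharing one design matrix (QR once).
.ols_matrix <- function(Y, X) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more samples than design columns (n = ", n,
                   ", k = ", k, ")")
  gi <- match("group", colnames(X))
  if (is.na(gi)) stop("design matrix lacks a 'group' column")
  qr_ <- qr(X)
  if (qr_$rank < k)
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[qr_$pivot[(qr_$rank + 1):k]], collapse = ", "))
  B <- qr.coef(qr_, Y)                       # k x m
  XtX_inv <- chol2inv(qr.R(qr_))             # in pivoted column order
  unpiv <- order(qr_$pivot)
  XtX_inv <- XtX_inv[unpiv, unpiv, drop = FALSE]
  resid <- Y - X %*% B
  df <- n - k
  s2 <- colSums(resid^2) / df                # residual variance per compound
  se <- sqrt(outer(diag(XtX_inv), s2))       # k x m
  tval <- B / se
  list(beta = B[gi, ], se = se[gi, ], t = tval[gi, ],
       p = 2 * pt(-abs(tval[gi, ]), df), df = df)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across a vector of p-values, returned in the
#' original order.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no missing entries")
  p.adjust(p_values, method = "BH")
}

#' Frequentist differential-abundance analysis of one cohort
#'
#' Fits each compound by OLS with covariate adjustment, applies BH across
#' compounds and flags significance at the configured FDR threshold.
#'
#' @param d a preprocessed (autoscaled) \code{cohort_dataset}.
#' @param fdr_threshold FDR cut-off for the significance flag (default 0.10).
#' @param covariates covariate columns to adjust for; \code{NULL} = all.
#' @return data.frame: compound_id, beta_p, se, p_value, p_adjusted,
#'   significant.
#' @export
run_frequentist <- function(d, fdr_threshold = 0.10, covariates = NULL) {
  stopifnot(inherits(d, "cohort_dataset"))
  if (ncol(d$abundance) == 0) stop("no compounds to analyze")
  if (d$stage != "autoscaled")
    stop("dataset must be preprocessed (autoscaled) first")
  X <- encode_design(d$samples, covariates)
  res <- .ols_matrix(d$abundance, X)
  padj <- bh_adjust(res$p)
  data.frame(compound_id = colnames(d$abundance),
             beta_p = unname(res$beta),
             se = unname(res$se),
             p_value = unname(res$p),
             p_adjusted = unname(padj),
             significant = unname(padj < fdr_threshold),
             stringsAsFactors = FALSE)
}

#' @importFrom stats qr.coef
NULL
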