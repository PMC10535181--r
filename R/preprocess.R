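# Preprocessing chain for left-censored LC-MS intensities:
# presence filter -> half-minimum imputation -> log -> autoscale.

#' Remove compounds observed in too few samples
#'
#' A compound is retained when its observed (non-missing) fraction is at
#' least \code{min_presence}; the boundary is inclusive, so a compound seen
#' in exactly half of the samples survives the default 50\% filter.
#' Compound order is preserved.
#'
#' @param d a raw-stage \code{cohort_dataset}.
#' @param min_presence required observed fraction, in (0, 1].
#' @return list with \code{data} (filtered \code{cohort_dataset}) and
#'   \code{report}: counts in/removed, per-compound missing fraction and
#'   the maximum missing fraction among retained compounds.
#' @export
filter_by_presence <- function(d, min_presence = 0.5) {
  stopifnot(inherits(d, "cohort_dataset"))
  if (!(min_presence > 0 && min_presence <= 1))
    stop("min_presence must lie in (0, 1]")
  obs_frac <- colMeans(!is.na(d$abundance))
  keep <- obs_frac >= min_presence
  if (!any(keep))
    stop("all ", length(keep), " compounds fall below min_presence = ",
         min_presence, "; review the threshold")
  out <- cohort_dataset(d$abundance[, keep, drop = FALSE],
                        d$samples,
                        d$compounds[keep, , drop = FALSE],
                        provenance = d$provenance, stage = d$stage)
  report <- list(n_compounds_in = length(keep),
                 n_removed_by_filter = sum(!keep),
                 n_retained = sum(keep),
                 missing_fraction = setNames(1 - obs_frac, names(obs_frac)),
                 max_missing_retained = max(1 - obs_frac[keep]),
                 removed_ids = d$compounds$compound_id[!keep])
  list(data = out, report = report)
}

#' Impute missing intensities with per-compound half-minimum values
#'
#' Each missing cell is replaced by half the smallest observed intensity of
#' its compound, on the raw scale — the standard convention for values
#' below the limit of detection. Observed cells are untouched.
#'
#' @param d a \code{cohort_dataset}; every compound needs at least one
#'   observed value (guaranteed after \code{\link{filter_by_presence}}).
#' @return the imputed \code{cohort_dataset} (stage \code{"imputed"}) with
#'   attribute \code{imputation_values}: the value used per compound
#'   (\code{NA} for compounds that had nothing to impute).
#' @export
impute_half_min <- function(d) {
  stopifnot(inherits(d, "cohort_dataset"))
  m <- d$abundance
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0))
    stop("compound(s) with zero observed values: ",
         paste(colnames(m)[n_obs == 0], collapse = ", "))
  imp <- rep(NA_real_, ncol(m))
  names(imp) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) {
      imp[j] <- min(m[, j], na.rm = TRUE) / 2
      m[miss, j] <- imp[j]
    }
  }
  out <- cohort_dataset(m, d$samples, d$compounds,
                        provenance = d$provenance, stage = "imputed")
  attr(out, "imputation_values") <- imp
  out
}

#' Log-transform and autoscale each compound
#'
#' Natural log followed by per-compound standardization to mean 0 and
#' sample standard deviation 1 (n - 1 denominator). The log base is
#' immaterial: autoscaling removes any multiplicative constant.
#'
#' @param d a fully imputed \code{cohort_dataset} (all values > 0).
#' @return autoscaled \code{cohort_dataset} (stage \code{"autoscaled"}).
#' @export
log_autoscale <- function(d) {
  stopifnot(inherits(d, "cohort_dataset"))
  m <- d$abundance
  if (anyNA(m)) stop("missing values remain; impute before autoscaling")
  if (any(m <= 0)) stop("non-positive intensities; autoscaling needs positives")
  lm_ <- log(m)
  sds <- apply(lm_, 2, sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var))
    stop("zero variance after log transform for compound(s): ",
         paste(colnames(m)[zero_var], collapse = ", "))
  scaled <- scale(lm_, center = TRUE, scale = TRUE)
  out <- matrix(as.numeric(scaled), nrow = nrow(m), dimnames = dimnames(m))
  cohort_dataset(out, d$samples, d$compounds,
                 provenance = d$provenance, stage = "autoscaled")
}

#' Run the full preprocessing chain
#'
#' Presence filter, half-minimum imputation, natural-log transform and
#' autoscaling, in that order, each applied within one cohort only.
#'
#' @param d a raw \code{cohort_dataset}.
#' @param min_presence presence threshold for \code{\link{filter_by_presence}}.
#' @return list with \code{data} (autoscaled \code{cohort_dataset}) and
#'   \code{report} (filter report plus imputation values).
#' @export
preprocess <- function(d, min_presence = 0.5) {
  flt <- filter_by_presence(d, min_presence)
  imp <- impute_half_min(flt$data)
  rep <- flt$report
  rep$imputation_values <- attr(imp, "imputation_values")
  list(data = log_autoscale(imp), report = rep)
}
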