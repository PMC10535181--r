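# Design-matrix construction shared by the frequentist and Bayesian fits.

#' Encode the regression design from sample metadata
#'
#' Builds the model matrix \code{~ group + covariates}. Categorical
#' covariates (character columns) are dummy-encoded with the
#' lexicographically first level as the reference; numeric covariates enter
#' on their raw scale. The group indicator column is named \code{group}.
#'
#' @param samples sample metadata data.frame (\code{sample_id},
#'   \code{group}, covariates).
#' @param covariates character vector of covariate column names to adjust
#'   for; \code{NULL} (default) uses every column beyond sample_id/group.
#' @return numeric model matrix with an \code{(Intercept)} column; full
#'   rank is enforced.
#' @export
encode_design <- function(samples, covariates = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(samples), c("sample_id", "group"))
  missing_cv <- setdiff(covariates, names(samples))
  if (length(missing_cv))
    stop("covariate(s) not in metadata: ", paste(missing_cv, collapse = ", "))
  df <- samples[, c("group", covariates), drop = FALSE]
  for (cv in covariates)
    if (!is.numeric(df[[cv]]))
      df[[cv]] <- factor(df[[cv]], levels = sort(unique(as.character(df[[cv]]))))
  fml <- if (length(covariates))
    as.formula(paste("~ group +", paste(sprintf("`%s`", covariates), collapse = " + ")))
  else ~ group
  X <- model.matrix(fml, data = df)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    dropped <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  rownames(X) <- samples$sample_id
  X
}

#' @importFrom stats as.formula
NULL
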