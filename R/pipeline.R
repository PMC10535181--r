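# End-to-end orchestration: preprocess -> frequentist -> Bayes (unchained)
# -> chained Bayes -> enrichment, plus comparison summaries and plot-ready
# tables.  All outputs are plain TSV/JSON and deterministic under a fixed
# master seed.

#' Compare frequentist and Bayesian decisions on one cohort
#'
#' @param freq \code{\link{run_frequentist}} table.
#' @param bayes \code{\link{run_bayes}} table over the same compounds.
#' @return list: per-method counts, intersection and difference compound
#'   lists, and the sign-agreement rate between the OLS coefficient and
#'   the posterior median.
#' @export
comparison_summary <- function(freq, bayes) {
  if (!setequal(freq$compound_id, bayes$compound_id))
    stop("frequentist and Bayesian tables cover different compound sets")
  bayes <- bayes[match(freq$compound_id, bayes$compound_id), ]
  sig <- freq$compound_id[freq$significant]
  alt <- bayes$compound_id[bayes$altered]
  list(n_frequentist_significant = length(sig),
       n_bayes_altered = length(alt),
       both = sort(intersect(sig, alt)),
       frequentist_only = sort(setdiff(sig, alt)),
       bayes_only = sort(setdiff(alt, sig)),
       sign_agreement = mean(sign(freq$beta_p) ==
                               sign(bayes$posterior_median)))
}

#' Run the full sequential workflow over an ordered list of cohorts
#'
#' Preprocesses every cohort, runs the frequentist baseline and the
#' unchained Bayesian analysis per cohort, chains posteriors forward in
#' the given order, runs chemical-class enrichment on the final chained
#' result, and (optionally) writes the report bundle: per-study TSV
#' tables, plot-ready tables (per-compound effect matrix for heatmaps,
#' Bayes-factor table, forest table of altered compounds, enrichment
#' bubble table) and a JSON manifest with the seed, thresholds and
#' per-study counts.
#'
#' @param studies ordered list of raw \code{cohort_dataset}s (chain order).
#' @param output_dir directory for the report bundle; \code{NULL} skips
#'   writing.
#' @param covariates covariate columns to adjust for; \code{NULL} = all.
#' @param min_presence,fdr_threshold,min_class_size stage thresholds.
#' @param config an \code{mcmc_config}; its seed is the master seed.
#' @param key compound-matching key between consecutive studies.
#' @return list: \code{preprocess} reports, \code{frequentist},
#'   \code{bayes_unchained}, \code{bayes_chained} tables,
#'   \code{chain_manifest}, \code{enrichment}, \code{comparisons}.
#' @export
run_all <- function(studies, output_dir = NULL, covariates = NULL,
                    min_presence = 0.5, fdr_threshold = 0.10,
                    min_class_size = 3, config = mcmc_config(),
                    key = "inchikey") {
  stopifnot(length(studies) >= 1)
  labels <- make.unique(vapply(studies, function(s) s$provenance, ""),
                        sep = "_")

  pp <- lapply(studies, preprocess, min_presence = min_presence)
  proc <- lapply(pp, `[[`, "data")
  reports <- lapply(pp, `[[`, "report")

  freq <- lapply(proc, run_frequentist, fdr_threshold = fdr_threshold,
                 covariates = covariates)
  unchained <- lapply(proc, run_bayes, priors = NULL, config = config,
                      covariates = covariates)

  chained <- NULL; chain_manifest <- NULL
  if (length(studies) >= 2) {
    ch <- run_chain(proc, config = config, covariates = covariates,
                    key = key)
    chained <- ch$results
    chain_manifest <- ch$manifest
  }

  final_bayes <- if (!is.null(chained)) chained[[length(chained)]]
                 else unchained[[1]]
  final_ann <- proc[[length(proc)]]$compounds
  enr <- tryCatch(
    run_enrichment(final_bayes, final_ann, min_class_size = min_class_size),
    error = function(e) { warning("enrichment skipped: ", conditionMessage(e));
                          NULL })

  comparisons <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    cmp_bayes <- if (!is.null(chained)) chained[[i]] else unchained[[i]]
    comparisons[[i]] <- list(
      study = labels[i],
      unchained = comparison_summary(freq[[i]], unchained[[i]]),
      chained = if (i > 1) comparison_summary(freq[[i]], cmp_bayes) else NULL)
  }

  out <- list(studies = labels, preprocess = reports, frequentist = freq,
              bayes_unchained = unchained, bayes_chained = chained,
              chain_manifest = chain_manifest, enrichment = enr,
              comparisons = comparisons, config = config)

  if (!is.null(output_dir)) .write_bundle(out, proc, output_dir)
  out
}

.write_bundle <- function(out, proc, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) write_results(tbl, file.path(output_dir, name))
  for (i in seq_along(out$studies)) {
    lab <- out$studies[i]
    w(out$frequentist[[i]], sprintf("frequentist_%s.tsv", lab))
    w(out$bayes_unchained[[i]], sprintf("bayes_unchained_%s.tsv", lab))
    if (!is.null(out$bayes_chained))
      w(out$bayes_chained[[i]], sprintf("bayes_chained_%s.tsv", lab))
  }
  final <- if (!is.null(out$bayes_chained))
    out$bayes_chained[[length(out$bayes_chained)]] else
    out$bayes_unchained[[1]]

  # plot-ready tables
  eff <- data.frame(compound_id = final$compound_id,
                    posterior_median = final$posterior_median,
                    stringsAsFactors = FALSE)
  w(eff, "plot_heatmap_effects.tsv")
  w(data.frame(compound_id = final$compound_id, bf10 = final$bf10,
               log10_bf10 = log10(final$bf10)), "plot_bf_scatter.tsv")
  forest <- final[final$altered,
                  c("compound_id", "posterior_median", "ci_low", "ci_high",
                    "direction")]
  if (nrow(forest)) w(forest, "plot_forest_altered.tsv")
  if (!is.null(out$enrichment)) {
    w(out$enrichment, "enrichment.tsv")
    w(data.frame(chem_class = out$enrichment$chem_class,
                 neg_log10_p = -log10(pmax(out$enrichment$p_value, 1e-300)),
                 n_members = out$enrichment$n_members,
                 fraction_up = out$enrichment$fraction_up),
      "plot_enrichment_bubbles.tsv")
  }

  written <- sort(list.files(output_dir, pattern = "\\.tsv$"))
  manifest <- list(
    seed = out$config$seed,
    mcmc = out$config[c("n_chains", "n_iter", "n_burnin")],
    file_md5 = as.list(setNames(
      unname(tools::md5sum(file.path(output_dir, written))), written)),
    studies = out$studies,
    n_compounds = vapply(out$frequentist, nrow, 0L),
    chain = out$chain_manifest,
    comparisons = lapply(out$comparisons, function(cc) list(
      study = cc$study,
      n_frequentist_significant = cc$unchained$n_frequentist_significant,
      n_bayes_altered_unchained = cc$unchained$n_bayes_altered,
      n_bayes_altered_chained =
        if (!is.null(cc$chained)) cc$chained$n_bayes_altered else NULL)))
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}
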