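# Fixtures are built in code; nothing is stored on disk beyond tempfiles.

# Write a small cohort as the three standard tables; returns the paths.
# 3 samples x 2 compounds, one empty cell and one literal zero by default.
write_toy_cohort_files <- function(dir = tempfile("cohort"),
                                   abundance_lines = c(
                                     "compound_id,S1,S2,S3",
                                     "C1,4.0,,9.0",
                                     "C2,1.5,2.5,3.5")) {
  dir.create(dir, showWarnings = FALSE)
  ab <- file.path(dir, "abundance.csv")
  md <- file.path(dir, "metadata.csv")
  an <- file.path(dir, "annotations.csv")
  writeLines(abundance_lines, ab)
  writeLines(c("sample_id,group,age",
               "S1,1,40", "S2,0,50", "S3,1,60"), md)
  writeLines(c("compound_id,name,inchikey,chem_class",
               "C1,alanine,QNAYBMKLOCPYGJ-REOHCLBHSA-N,Amino acids",
               "C2,glucose,WQZGKKKJIJFFOK-GASJEMHNSA-N,Sugars"), an)
  list(abundance = ab, metadata = md, annotations = an)
}

# Programmatic cohort with chosen intensities (samples x compounds).
make_cohort <- function(m, groups, ids = sprintf("C%d", seq_len(ncol(m))),
                        inchikey = NA, chem_class = NA, stage = "raw",
                        provenance = "toy") {
  rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  colnames(m) <- ids
  cohort_dataset(
    m,
    data.frame(sample_id = rownames(m), group = groups,
               stringsAsFactors = FALSE),
    data.frame(compound_id = ids, name = ids,
               inchikey = if (length(inchikey) == 1 && is.na(inchikey))
                 rep(NA_character_, length(ids)) else inchikey,
               chem_class = if (length(chem_class) == 1 && is.na(chem_class))
                 rep(NA_character_, length(ids)) else chem_class,
               stringsAsFactors = FALSE),
    provenance = provenance, stage = stage)
}

# An already-autoscaled cohort with known standardized group effects.
make_autoscaled <- function(n_per_group = 25, effects = c(0, 1), seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  g <- rep(c(1, 0), each = n_per_group)
  m <- vapply(effects, function(d) {
    y <- d * g + rnorm(n)
    as.numeric(scale(y))
  }, numeric(n))
  make_cohort(m, g, stage = "autoscaled")
}

# Fake posterior_draws object around a given draw vector (for summarize
# tests that need full control of the draws).
fake_posterior <- function(draws, prior_loc = 0, prior_scale = 1,
                           n_chains = 2) {
  d <- matrix(draws, ncol = 1, dimnames = list(NULL, "group"))
  structure(list(
    draws = d, sigma2 = rep(1, length(draws)),
    chain = rep(seq_len(n_chains), length.out = length(draws)),
    prior = prior_spec("group", prior_loc, prior_scale),
    config = mcmc_config(n_chains, 2000, 1000, 1),
    term = "group"), class = "posterior_draws")
}

# Independent brute-force BH step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Direct ECDF-scan oracle for the one-sided KS statistic D+ vs Uniform(0,1).
ks_oracle <- function(p) {
  ps <- sort(p)
  n <- length(ps)
  max(seq_len(n) / n - ps)
}
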