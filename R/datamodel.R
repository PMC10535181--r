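# Core data containers and tabular IO.
#
# A cohort is held as a samples x compounds numeric matrix with NA marking
# missing cells (zero intensities are recoded to NA on load: in LC-MS data a
# zero means no signal, i.e. below the limit of detection, not a measured
# concentration).  Sample metadata and compound annotations ride along as
# data frames keyed by sample_id / compound_id.

.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Construct a cohort dataset
#'
#' Bundles an abundance matrix (samples in rows, compounds in columns,
#' \code{NA} = missing/below detection), per-sample metadata and per-compound
#' annotations into a validated container.
#'
#' @param abundance numeric matrix, samples x compounds; dimnames must carry
#'   sample and compound ids. \code{NA} marks missing cells. All present
#'   values must be strictly positive on the raw intensity scale.
#' @param samples data.frame with columns \code{sample_id}, \code{group}
#'   (0 = control, 1 = case) and one column per covariate. Covariate values
#'   must be complete.
#' @param compounds data.frame with columns \code{compound_id}, \code{name},
#'   \code{inchikey} (27-character standard InChIKey or \code{NA}) and
#'   \code{chem_class} (free-text label or \code{NA}).
#' @param provenance free-text study label.
#' @param stage processing stage; raw intensities are \code{"raw"}.
#' @return an object of class \code{cohort_dataset}.
#' @export
cohort_dataset <- function(abundance, samples, compounds,
                           provenance = "unnamed", stage = "raw") {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have sample row names and compound column names")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)

  req_s <- c("sample_id", "group")
  if (!all(req_s %in% names(samples)))
    stop("samples must contain columns: ", paste(req_s, collapse = ", "))
  req_c <- c("compound_id", "name", "inchikey", "chem_class")
  miss_c <- setdiff(req_c, names(compounds))
  for (m in miss_c) compounds[[m]] <- NA_character_

  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (anyDuplicated(compounds$compound_id))
    stop("duplicate compound_id: ",
         paste(unique(compounds$compound_id[duplicated(compounds$compound_id)]),
               collapse = ", "))
  if (!all(samples$group %in% c(0, 1)))
    stop("group must be coded 0 (control) / 1 (case)")

  if (!setequal(rownames(abundance), samples$sample_id))
    stop("abundance row names do not match samples$sample_id")
  if (!setequal(colnames(abundance), compounds$compound_id))
    stop("abundance column names do not match compounds$compound_id")
  abundance <- abundance[samples$sample_id, compounds$compound_id, drop = FALSE]

  covars <- setdiff(names(samples), req_s)
  for (cv in covars)
    if (anyNA(samples[[cv]]))
      stop("missing covariate values are not allowed (covariate '", cv, "')")

  bad_key <- !is.na(compounds$inchikey) &
    !grepl(.INCHIKEY_RE, compounds$inchikey)
  if (any(bad_key))
    stop("malformed InChIKey for compound(s): ",
         paste(compounds$compound_id[bad_key], collapse = ", "))

  if (stage %in% c("raw", "imputed")) {
    present <- abundance[!is.na(abundance)]
    if (any(present <= 0))
      stop("present intensities must be strictly positive (zeros are missing)")
  }

  structure(list(abundance = abundance, samples = samples,
                 compounds = compounds, provenance = provenance,
                 stage = stage),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset '%s' [%s]: %d samples (%d cases / %d controls), %d compounds, %.1f%% missing\n",
              x$provenance, x$stage, nrow(x$abundance),
              sum(x$samples$group == 1), sum(x$samples$group == 0),
              ncol(x$abundance), 100 * mean(is.na(x$abundance))))
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$abundance)

#' Missing mask of a cohort dataset
#'
#' @param d a \code{cohort_dataset}
#' @return logical matrix, TRUE where the cell is missing.
#' @export
missing_mask <- function(d) is.na(d$abundance)

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character")
}

#' Read a cohort from abundance, metadata and annotation tables
#'
#' The abundance table has compounds in rows (first column
#' \code{compound_id}) and samples in columns; an empty cell or a literal
#' \code{0} is recorded as missing. Metadata columns are \code{sample_id},
#' \code{group}, then covariates. Annotation columns are
#' \code{compound_id}, \code{name}, \code{inchikey}, \code{chem_class}.
#' CSV and TSV are both accepted (sniffed from the header line).
#'
#' @param abundance_path,metadata_path,annotation_path file paths.
#' @param provenance study label recorded on the dataset.
#' @return a validated \code{cohort_dataset}.
#' @export
read_cohort <- function(abundance_path, metadata_path, annotation_path,
                        provenance = basename(abundance_path)) {
  ab <- .read_table(abundance_path)
  md <- .read_table(metadata_path)
  an <- .read_table(annotation_path)

  if (names(ab)[1] != "compound_id")
    stop("abundance table must start with a compound_id column")
  compound_ids <- ab$compound_id
  sample_ids <- names(ab)[-1]

  extra_s <- setdiff(sample_ids, md$sample_id)
  if (length(extra_s))
    stop("sample(s) in abundance header absent from metadata: ",
         paste(extra_s, collapse = ", "))
  extra_c <- setdiff(compound_ids, an$compound_id)
  if (length(extra_c))
    stop("compound(s) in abundance table absent from annotations: ",
         paste(extra_c, collapse = ", "))

  m <- matrix(NA_real_, nrow = length(sample_ids), ncol = length(compound_ids),
              dimnames = list(sample_ids, compound_ids))
  for (s in seq_along(sample_ids)) {
    raw <- ab[[s + 1L]]                 # one sample's intensities over compounds
    raw[is.na(raw) | trimws(raw) == ""] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric intensity '%s' at compound row %d ('%s'), sample column '%s'",
                   raw[bad[1]], bad[1], compound_ids[bad[1]], sample_ids[s]))
    num[!is.na(num) & num == 0] <- NA   # zero = below limit of detection
    m[s, ] <- num
  }

  md <- md[match(sample_ids, md$sample_id), , drop = FALSE]
  md$group <- as.numeric(md$group)
  for (cv in setdiff(names(md), c("sample_id", "group"))) {
    num <- suppressWarnings(as.numeric(md[[cv]]))
    if (!anyNA(num)) md[[cv]] <- num
  }
  an <- an[match(compound_ids, an$compound_id), , drop = FALSE]
  an$inchikey[!is.na(an$inchikey) & trimws(an$inchikey) == ""] <- NA
  an$chem_class[!is.na(an$chem_class) & trimws(an$chem_class) == ""] <- NA

  cohort_dataset(m, md, an, provenance = provenance)
}

#' Match compounds between two cohorts by chemical identity
#'
#' Pairs compounds by exact, case-sensitive match of the chosen key:
#' the full 27-character InChIKey (default), the compound name, or a
#' user-supplied two-column mapping table (ids in \code{a} -> ids in
#' \code{b}) for cross-assay harmonization. A key that occurs more than
#' once within one dataset is ambiguous and raises an error rather than
#' pairing arbitrarily.
#'
#' @param a,b \code{cohort_dataset}s.
#' @param key one of \code{"inchikey"}, \code{"name"}, \code{"mapping"}.
#' @param mapping for \code{key = "mapping"}: data.frame whose first column
#'   holds compound ids of \code{a} and second column ids of \code{b}.
#' @return list with \code{pairs} (data.frame \code{compound_id_a},
#'   \code{compound_id_b}), \code{unmatched_a}, \code{unmatched_b}.
#' @export
match_compounds <- function(a, b, key = c("inchikey", "name", "mapping"),
                            mapping = NULL) {
  key <- match.arg(key)
  stopifnot(inherits(a, "cohort_dataset"), inherits(b, "cohort_dataset"))

  if (key == "mapping") {
    if (is.null(mapping) || ncol(mapping) < 2)
      stop("key = 'mapping' requires a two-column mapping table")
    map <- data.frame(ida = as.character(mapping[[1]]),
                      idb = as.character(mapping[[2]]),
                      stringsAsFactors = FALSE)
    map <- map[map$ida %in% a$compounds$compound_id &
               map$idb %in% b$compounds$compound_id, , drop = FALSE]
    if (anyDuplicated(map$ida) || anyDuplicated(map$idb))
      stop("ambiguous mapping: duplicated ids: ",
           paste(unique(c(map$ida[duplicated(map$ida)],
                          map$idb[duplicated(map$idb)])), collapse = ", "))
    pairs <- data.frame(compound_id_a = map$ida, compound_id_b = map$idb,
                        stringsAsFactors = FALSE)
  } else {
    ka <- a$compounds[[key]]
    kb <- b$compounds[[key]]
    keyed_a <- !is.na(ka)
    keyed_b <- !is.na(kb)
    if (!any(keyed_a) || !any(keyed_b))
      stop("key '", key, "' is absent from every compound in one dataset")
    dup_a <- unique(ka[keyed_a][duplicated(ka[keyed_a])])
    dup_b <- unique(kb[keyed_b][duplicated(kb[keyed_b])])
    if (length(dup_a) || length(dup_b))
      stop("ambiguous ", key, " (duplicated within one dataset): ",
           paste(unique(c(dup_a, dup_b)), collapse = ", "))
    common <- intersect(ka[keyed_a], kb[keyed_b])
    pairs <- data.frame(
      compound_id_a = a$compounds$compound_id[match(common, ka)],
      compound_id_b = b$compounds$compound_id[match(common, kb)],
      stringsAsFactors = FALSE)
  }

  list(pairs = pairs,
       unmatched_a = setdiff(a$compounds$compound_id, pairs$compound_id_a),
       unmatched_b = setdiff(b$compounds$compound_id, pairs$compound_id_b))
}

#' Write a result table as TSV
#'
#' Columns are written in their existing order; numeric values keep full
#' double precision so a write/read round trip reproduces them to at least
#' 12 significant digits.
#'
#' @param results non-empty data.frame.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0) stop("refusing to write an empty result table")
  num <- vapply(results, is.numeric, logical(1))
  out <- results
  for (j in which(num)) out[[j]] <- sprintf("%.15g", results[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by \code{write_results}
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  df
}

#' Write a cohort as the three standard TSV tables
#'
#' Writes \code{abundance.tsv} (compounds in rows, samples in columns,
#' missing cells empty), \code{metadata.tsv} and \code{annotations.tsv}
#' into a directory. Intensities are written with 17 significant digits,
#' so \code{\link{read_cohort}} reproduces the matrix and the missing
#' mask exactly.
#'
#' Note that only raw-stage tables round-trip through
#' \code{\link{read_cohort}}, whose validation requires positive
#' intensities; autoscaled tables are terminal outputs.
#'
#' @param d a \code{cohort_dataset}.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(d, dir) {
  stopifnot(inherits(d, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- t(d$abundance)                       # compounds x samples
  cells <- ifelse(is.na(m), "", sprintf("%.17g", m))
  ab <- data.frame(compound_id = rownames(m), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(ab) <- c("compound_id", colnames(m))
  write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_results(d$samples, file.path(dir, "metadata.tsv"))
  write_results(d$compounds, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
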