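#' Construct an expression cohort
#'
#' Container for a log2 gene x sample expression matrix plus per-sample
#' clinical outcome metadata (survival time in years, event indicator,
#' endpoint, age, T-stage, nodal status, tumour purity, chemotherapy flag,
#' TNBC/HER2 flag).
#'
#' @param values Numeric gene x sample matrix with unique row (gene) and
#'   column (sample) names; log2 abundance.
#' @param clinical Data frame with a `sample` column and (optionally) the
#'   metadata columns above; samples absent from it get NA metadata and are
#'   recorded in the `missing_clinical` attribute.
#' @param cohort_id Cohort label.
#' @param role `"discovery"` or `"validation"`.
#' @param is_normal Logical per-sample flag (default all tumour).
#' @param standardized Whether rows are already per-gene z-scores.
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, clinical = NULL,
                              cohort_id = "cohort",
                              role = c("discovery", "validation"),
                              is_normal = rep(FALSE, ncol(values)),
                              standardized = FALSE) {
  role <- match.arg(role)
  stopifnot(is.matrix(values), is.numeric(values))
  genes <- rownames(values); samples <- colnames(values)
  if (is.null(genes) || any(genes == "") || anyNA(genes))
    stop("expression matrix must have complete gene row names")
  if (anyDuplicated(genes))
    stop(sprintf("duplicated gene identifier: %s",
                 genes[duplicated(genes)][1]))
  if (is.null(samples) || anyDuplicated(samples))
    stop("expression matrix must have unique sample column names")
  if (length(is_normal) != length(samples))
    stop("is_normal must have one entry per sample")

  meta_cols <- c("time", "event", "endpoint", "age", "t_stage", "nodal",
                 "purity", "chemo", "tnbc_or_her2")
  clin <- data.frame(sample = samples, stringsAsFactors = FALSE)
  missing_clinical <- character(0)
  if (!is.null(clinical)) {
    if (!"sample" %in% names(clinical))
      stop("clinical table needs a 'sample' column")
    idx <- match(samples, clinical$sample)
    missing_clinical <- samples[is.na(idx)]
    for (col in intersect(meta_cols, names(clinical)))
      clin[[col]] <- clinical[[col]][idx]
  }
  for (col in setdiff(meta_cols, names(clin))) clin[[col]] <- NA
  if (any(!is.na(clin$time) & clin$time < 0))
    stop("negative survival times")
  if (any(is.na(clin$time) & !is.na(clin$event)))
    stop("time must be present wherever event is present")
  rownames(clin) <- samples

  structure(list(cohort_id = cohort_id, genes = genes, samples = samples,
                 values = values, standardized = standardized,
                 is_normal = is_normal, role = role, clinical = clin),
            missing_clinical = missing_clinical,
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort '%s' (%s): %d genes x %d samples (%d normal)%s\n",
              x$cohort_id, x$role, length(x$genes), length(x$samples),
              sum(x$is_normal), if (x$standardized) ", z-scored" else ""))
  ev <- x$clinical$event
  if (any(!is.na(ev)))
    cat(sprintf("  outcomes: %d samples with follow-up, %d events\n",
                sum(!is.na(ev)), sum(ev, na.rm = TRUE)))
  invisible(x)
}

#' Subset an expression cohort by sample
#'
#' @param cohort An [expression_cohort].
#' @param samples Sample identifiers or logical/integer index.
#' @return The subsetted cohort.
#' @export
subset_samples <- function(cohort, samples) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (is.character(samples)) samples <- match(samples, cohort$samples)
  if (is.logical(samples)) samples <- which(samples)
  if (anyNA(samples)) stop("unknown sample identifiers")
  expression_cohort(cohort$values[, samples, drop = FALSE],
                    clinical = cbind(sample = cohort$samples[samples],
                                     cohort$clinical[samples, -1,
                                                     drop = FALSE]),
                    cohort_id = cohort$cohort_id, role = cohort$role,
                    is_normal = cohort$is_normal[samples],
                    standardized = cohort$standardized)
}

#' Split a cohort into tumour and normal sub-cohorts
#'
#' @param cohort An [expression_cohort].
#' @return List with elements `tumour` and `normal` (NULL when absent).
#' @export
split_tumour_normal <- function(cohort) {
  list(tumour = if (any(!cohort$is_normal))
         subset_samples(cohort, !cohort$is_normal) else NULL,
       normal = if (any(cohort$is_normal))
         subset_samples(cohort, cohort$is_normal) else NULL)
}

#' Write an expression cohort to TSV files
#'
#' Expression TSV: genes as rows, first column `gene_id`, one column per
#' sample. Clinical TSV: one row per sample with the metadata columns plus
#' an `is_normal` flag.
#'
#' @param cohort An [expression_cohort].
#' @param expr_path,clinical_path Output file paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, expr_path, clinical_path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  expr <- data.frame(gene_id = cohort$genes, cohort$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- cohort$clinical
  clin$is_normal <- cohort$is_normal
  utils::write.table(clin, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cohort)
}

#' Load an expression cohort from TSV files
#'
#' Reads a gene x sample expression TSV (first column `gene_id`) and a
#' per-sample clinical TSV. Samples present in the expression matrix but
#' absent from the clinical table are loaded with unknown metadata and a
#' warning; duplicated gene rows or non-numeric cells are errors. De-novo
#' metastatic records (time = 0 with an event) are excluded by default.
#'
#' @param expr_path,clinical_path Input file paths (`clinical_path` may be
#'   NULL).
#' @param cohort_id,role Passed to [expression_cohort()].
#' @param drop_denovo_metastatic Drop samples with `time == 0 & event == 1`.
#' @return An [expression_cohort].
#' @export
load_expression <- function(expr_path, clinical_path = NULL,
                            cohort_id = "cohort",
                            role = c("discovery", "validation"),
                            drop_denovo_metastatic = TRUE) {
  role <- match.arg(role)
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(expr)[1] != "gene_id")
    stop("first column of the expression TSV must be 'gene_id'")
  genes <- as.character(expr$gene_id)
  if (anyDuplicated(genes))
    stop(sprintf("duplicated gene identifier: %s",
                 genes[duplicated(genes)][1]))
  mat <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(mat), nrow(mat)))) & !is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1]], colnames(mat)[bad[2]]))
  }
  rownames(mat) <- genes

  clinical <- NULL; is_normal <- rep(FALSE, ncol(mat))
  if (!is.null(clinical_path)) {
    clinical <- utils::read.delim(clinical_path, check.names = FALSE,
                                  stringsAsFactors = FALSE)
    missing <- setdiff(colnames(mat), clinical$sample)
    if (length(missing))
      warning(sprintf("%d sample(s) missing from the clinical table: %s",
                      length(missing),
                      paste(utils::head(missing, 5), collapse = ", ")))
    if ("is_normal" %in% names(clinical)) {
      idx <- match(colnames(mat), clinical$sample)
      is_normal <- ifelse(is.na(idx), FALSE,
                          as.logical(clinical$is_normal[idx]))
    }
  }
  cohort <- expression_cohort(mat, clinical = clinical,
                              cohort_id = cohort_id, role = role,
                              is_normal = is_normal)
  if (drop_denovo_metastatic) {
    denovo <- !is.na(cohort$clinical$time) & cohort$clinical$time == 0 &
      !is.na(cohort$clinical$event) & cohort$clinical$event == 1
    if (any(denovo)) {
      warning(sprintf("excluding %d de-novo metastatic sample(s) (time = 0, event = 1)",
                      sum(denovo)))
      cohort <- subset_samples(cohort, !denovo)
    }
  }
  cohort
}

#' Load gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description (discarded), then gene
#' identifiers. Duplicate genes within a set are collapsed; duplicate set
#' names are an error.
#'
#' @param path GMT file path.
#' @param source Source label stored on the database.
#' @return A `pathway_db` (named list of unique gene vectors).
#' @export
load_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file; returning an empty pathway database")
    return(structure(stats::setNames(list(), character(0)),
                     source = source, class = "pathway_db"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1]))
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop(sprintf("duplicated pathway name: %s", nm[duplicated(nm)][1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  structure(sets, source = source, class = "pathway_db")
}

#' Write gene sets to a GMT file
#'
#' @param db A `pathway_db`.
#' @param path Output path.
#' @param description Description column value (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(db, path, description = "na") {
  lines <- vapply(seq_along(db), function(i)
    paste(c(names(db)[i], description, db[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Remove genes below an expression floor in both cohorts
#'
#' The floor is the median, over a reference gene set assumed inactive in
#' this tissue (e.g. Y-chromosome genes in a female breast cohort), of
#' per-gene mean expression computed on the pooled tumour + normal samples.
#' Genes whose mean expression falls below the floor in both the tumour and
#' the normal cohort are declared unexpressed and dropped from both.
#'
#' @param tumour,normal [expression_cohort] objects over the same genes.
#' @param reference_genes Character vector of reference (inactive) genes; a
#'   subset of the measured genes.
#' @return List with filtered `tumour`, `normal`, and the `floor` used
#'   (log2 units).
#' @export
filter_unexpressed <- function(tumour, normal, reference_genes) {
  stopifnot(inherits(tumour, "expression_cohort"),
            inherits(normal, "expression_cohort"))
  if (!length(reference_genes)) stop("reference gene set is empty")
  if (!all(reference_genes %in% tumour$genes))
    stop("reference_genes must be a subset of the measured genes")
  if (!identical(tumour$genes, normal$genes))
    stop("tumour and normal cohorts must share the same gene list")
  pooled <- cbind(tumour$values, normal$values)
  floor_val <- stats::median(rowMeans(pooled[reference_genes, , drop = FALSE]))
  mean_t <- rowMeans(tumour$values)
  mean_n <- rowMeans(normal$values)
  drop <- mean_t < floor_val & mean_n < floor_val
  keep <- which(!drop)
  sub_genes <- function(co) {
    co$values <- co$values[keep, , drop = FALSE]
    co$genes <- co$genes[keep]
    co
  }
  list(tumour = sub_genes(tumour), normal = sub_genes(normal),
       floor = floor_val)
}

#' Remove genes with too many zero counts
#'
#' @param counts Non-negative numeric matrix (genes x samples).
#' @param max_zero_fraction Rows whose zero fraction strictly exceeds this
#'   are removed (default 0.75, i.e. ">75% of samples have zero counts").
#' @return The filtered matrix.
#' @export
filter_zero_fraction <- function(counts, max_zero_fraction = 0.75) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  zf <- rowMeans(counts == 0)
  counts[zf <= max_zero_fraction, , drop = FALSE]
}

#' Transform a cohort to per-gene z-scores
#'
#' Each gene row is centred and scaled to sample mean 0 and sample SD 1
#' (n - 1 denominator) within the given cohort. Constant genes are dropped
#' with a warning.
#'
#' @param cohort An unstandardized [expression_cohort] with >= 2 samples.
#' @return The standardized cohort (`standardized = TRUE`).
#' @export
zscore_genes <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (cohort$standardized) stop("cohort is already standardized")
  if (length(cohort$samples) < 2)
    stop("need at least 2 samples to z-score")
  v <- row_vars(cohort$values)
  const <- v == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant gene(s) before z-scoring",
                    sum(const)))
    cohort$values <- cohort$values[!const, , drop = FALSE]
    cohort$genes <- cohort$genes[!const]
    v <- v[!const]
  }
  cohort$values <- (cohort$values - rowMeans(cohort$values)) / sqrt(v)
  cohort$standardized <- TRUE
  cohort
}

#' Truncate survival follow-up at a horizon
#'
#' Samples with follow-up strictly beyond the horizon are administratively
#' censored at the horizon; an event exactly at the horizon is kept as an
#' event.
#'
#' @param cohort An [expression_cohort].
#' @param horizon Truncation time in years (> 0).
#' @return The cohort with truncated `time`/`event` and attribute
#'   `truncated_at`.
#' @export
truncate_survival <- function(cohort, horizon = 10) {
  stopifnot(inherits(cohort, "expression_cohort"), horizon > 0)
  tm <- cohort$clinical$time
  if (any(!is.na(tm) & tm < 0)) stop("negative survival times")
  over <- !is.na(tm) & tm > horizon
  cohort$clinical$time[over] <- horizon
  cohort$clinical$event[over] <- 0L
  attr(cohort, "truncated_at") <- horizon
  cohort
}
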