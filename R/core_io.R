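#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `scale` attribute that records whether values are on
#' the TPM scale or already log2(TPM+1)-transformed. Downstream scoring
#' functions require the log scale and refuse to double-transform.
#'
#' @param values Numeric matrix with unique rownames (gene identifiers) and
#'   unique colnames (sample identifiers).
#' @param scale Either `"TPM"` or `"LOG2_TPM1"`.
#' @return A matrix of class `expr_matrix` with a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("TPM", "LOG2_TPM1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at gene '", rownames(values)[bad[1]],
         "', sample '", colnames(values)[bad[2]], "'")
  }
  if (scale == "TPM" && any(values < 0))
    stop("negative values are not valid on the TPM scale")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' Scale of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"TPM"` or `"LOG2_TPM1"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "TPM" else s
}

#' @export
as.matrix.expr_matrix <- function(x, ...) {
  attr(x, "scale") <- NULL
  class(x) <- NULL
  x
}

# subsetting keeps the scale attribute (drop is forced off so the object
# stays a matrix)
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  s <- attr(x, "scale")
  y <- NextMethod(drop = FALSE)
  structure(y, scale = s, class = c("expr_matrix", "matrix", "array"))
}

#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated text file whose first column holds gene identifiers
#' and whose header row holds sample identifiers. Duplicate gene rows are
#' collapsed by the per-cell maximum (with a warning), preserving detection of
#' the most expressed duplicate row. Missing or non-numeric cells are errors.
#'
#' @param path Path to the TSV file.
#' @param scale Declared scale of the values, `"TPM"` (default) or
#'   `"LOG2_TPM1"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("TPM", "LOG2_TPM1")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a gene column plus >=1 sample")
  genes <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s' (value '%s')",
                 genes[bad[1]], samples[bad[2]], vals[bad[1], bad[2]]))
  }
  rownames(num) <- genes
  colnames(num) <- samples
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene row(s) by maximum: ",
            paste(utils::head(dup, 5), collapse = ", "))
    num <- do.call(rbind, lapply(split(seq_along(genes), genes)[unique(genes)],
                                 function(idx) apply(num[idx, , drop = FALSE], 2, max)))
    rownames(num) <- unique(genes)
  }
  expression_matrix(num, scale)
}

#' Write an expression matrix as TSV
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @param id_col Name of the gene-identifier column in the header.
#' @export
write_expression <- function(x, path, id_col = "gene_id") {
  df <- data.frame(rownames(x), as.matrix(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes. Repeated genes within a set are dropped
#' with a warning; an empty set or a duplicated set name is an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of class `gene_sets`; the
#'   `provenance` attribute holds the per-set description field.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- vector("list", length(fields))
  prov <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("gene set '", nms[i], "' has zero genes")
    if (anyDuplicated(genes)) {
      warning("gene set '", nms[i], "': dropping repeated genes")
      genes <- unique(genes)
    }
    sets[[i]] <- genes
    prov[i] <- if (length(f) >= 2) f[2] else ""
  }
  names(sets) <- nms
  gene_set_collection(sets, prov)
}

#' Construct a gene-set collection
#' @param sets Named list of character vectors (unique, non-empty).
#' @param provenance Optional character vector of per-set free-text notes.
#' @return A `gene_sets` object.
#' @export
gene_set_collection <- function(sets, provenance = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set needs a name")
    if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
    for (nm in names(sets)) {
      g <- sets[[nm]]
      if (length(g) == 0) stop("gene set '", nm, "' has zero genes")
      if (anyDuplicated(g)) stop("gene set '", nm, "' has duplicate genes")
    }
  }
  if (is.null(provenance)) provenance <- rep("", length(sets))
  structure(sets, provenance = provenance, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10))
    cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]])))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param sets A `gene_sets` object.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  prov <- attr(sets, "provenance")
  if (is.null(prov)) prov <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], prov[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Keep genes expressed in more than a given fraction of samples
#'
#' Retains genes with TPM strictly greater than zero in strictly more than
#' `min_prop` of the samples; the inequality is strict on both sides, so a
#' gene positive in exactly half the samples is removed at the default.
#'
#' @param x An `expr_matrix` on the TPM scale.
#' @param min_prop Minimum fraction of samples with positive expression.
#' @return The filtered `expr_matrix`.
#' @export
filter_expressed_genes <- function(x, min_prop = 0.5) {
  if (expr_scale(x) != "TPM")
    stop("expression filtering is defined on the TPM scale")
  keep <- rowMeans(as.matrix(x) > 0) > min_prop
  if (!any(keep)) stop("no gene passes the expression filter")
  x[keep, , drop = FALSE]
}

#' Log-transform a TPM matrix
#'
#' Applies log2(TPM + 1) cell-wise and flips the scale flag. Calling it on an
#' already-transformed matrix is an error, guarding against double
#' transformation.
#'
#' @param x An `expr_matrix` on the TPM scale.
#' @return An `expr_matrix` on the LOG2_TPM1 scale.
#' @export
log_transform <- function(x) {
  if (expr_scale(x) != "TPM")
    stop("matrix is already log2(TPM+1)-transformed")
  y <- log2(as.matrix(x) + 1)
  dimnames(y) <- dimnames(x)
  expression_matrix(y, "LOG2_TPM1")
}

#' Read a survival table
#'
#' Tab-separated file with required columns `sample_id`, `time_days`,
#' `event`; any further columns are kept as categorical covariates. Times
#' must be positive and events coded 0/1.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with validated columns.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_survival(df)
}

#' Validate a survival data frame
#' @param df Data frame with `sample_id`, `time_days`, `event` columns.
#' @return The validated data frame.
#' @export
validate_survival <- function(df) {
  need <- c("sample_id", "time_days", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("survival table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(df$time_days) || !is.numeric(df$time_days))
    stop("time_days must be numeric with no missing values")
  if (any(df$time_days <= 0))
    stop("non-positive survival time for sample(s): ",
         paste(df$sample_id[df$time_days <= 0], collapse = ", "))
  if (!all(df$event %in% c(0, 1)))
    stop("event must be coded 0/1")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in survival table")
  df
}

#' Default non-silent MAF variant classes
#'
#' The standard nonsynonymous classes used for tumor-mutational-burden
#' counting from MAF-style tables.
#' @return Character vector of class names.
#' @export
maf_nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Read a simplified mutation table
#'
#' Tab-separated, MAF-style. Required columns (renameable through
#' `column_map`): `sample_id`, `gene`, `variant_class`. Variant classes
#' outside `vocabulary` are kept but flagged in the `known_class` column.
#'
#' @param path Path to the TSV file.
#' @param vocabulary Declared variant-class vocabulary.
#' @param column_map Named character vector mapping required names to the
#'   file's actual column names, e.g.
#'   `c(sample_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol", variant_class = "Variant_Classification")`.
#' @return Data frame with columns `sample_id`, `gene`, `variant_class`,
#'   `known_class`.
#' @export
read_mutations <- function(path,
                           vocabulary = c(maf_nonsilent_classes(),
                                          "Silent", "Intron", "3'UTR", "5'UTR",
                                          "IGR", "RNA"),
                           column_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "variant_class")
  if (!is.null(column_map)) {
    for (nm in intersect(names(column_map), need)) {
      if (!column_map[[nm]] %in% colnames(df))
        stop("mapped column '", column_map[[nm]], "' not found")
      colnames(df)[colnames(df) == column_map[[nm]]] <- nm
    }
  }
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  df$known_class <- df$variant_class %in% vocabulary
  if (!all(df$known_class))
    warning("unknown variant class(es): ",
            paste(unique(df$variant_class[!df$known_class]), collapse = ", "))
  df
}
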