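#' Expression matrix with a unit tag
#'
#' A light container for gene-by-sample abundance data: a numeric matrix with
#' unique gene row names, unique sample column names and a `unit` attribute
#' recording the abundance scale (`"FPKM"`, `"TPM"` or `"LOG2"`).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames set.
#' @param unit one of `"FPKM"`, `"TPM"`, `"LOG2"`.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, unit = c("TPM", "FPKM", "LOG2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (unit %in% c("FPKM", "TPM") && any(values < 0))
    stop("negative values are not allowed on the ", unit, " scale")
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("object carries no unit tag")
  u
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "unit") <- attr(x, "unit")
    class(out) <- class(x)
  }
  out
}

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Duplicate gene rows are collapsed by taking the per-sample maximum (with a
#' warning); duplicate sample columns are an error.
#'
#' @param path file path.
#' @param unit abundance unit of the stored values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, unit = c("TPM", "FPKM", "LOG2")) {
  unit <- match.arg(unit)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >= 1 sample")
  genes <- as.character(raw[[1]])
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(raw[[bad + 1]]))))[1]
    stop(sprintf("non-numeric value at gene row %d, sample column '%s'",
                 badrow, samples[bad]))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup),
            " duplicated gene row(s) by per-sample maximum: ",
            paste(utils::head(dup, 5), collapse = ", "))
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes), function(ii) {
      apply(vals[ii, , drop = FALSE], 2, max)
    }))
    vals <- vals[order(match(rownames(vals), unique(genes))), , drop = FALSE]
  } else {
    rownames(vals) <- genes
  }
  colnames(vals) <- samples
  expression_matrix(vals, unit)
}

#' Write an expression matrix as TSV
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert FPKM to TPM by within-sample renormalisation
#'
#' TPM_gs = FPKM_gs / sum_g FPKM_gs * 1e6, so every sample column sums to one
#' million.
#'
#' @param x an [expression_matrix()] with unit `"FPKM"`.
#' @return the matrix on the TPM scale.
#' @export
fpkm_to_tpm <- function(x) {
  if (expr_unit(x) != "FPKM") stop("input unit must be FPKM")
  cs <- colSums(x)
  if (any(cs == 0))
    stop("sample(s) with all-zero expression: ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  out <- sweep(unclass(x), 2, cs, "/") * 1e6
  expression_matrix(out, "TPM")
}

#' log2(x + pseudocount) transform
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (!expr_unit(x) %in% c("FPKM", "TPM"))
    stop("input unit must be FPKM or TPM")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  expression_matrix(log2(unclass(x) + pseudocount), "LOG2")
}

#' Read a clinical table TSV
#'
#' Required columns: `sample_id`, `os_time` (days, > 0), `os_event` (0/1).
#' Optional: `age`, `sex`, `stage`, `msi`, `cohort` and any `ips_*` columns.
#' Missing values stay missing; nothing is imputed.
#'
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  bad <- which(!is.finite(df$os_time) | df$os_time <= 0)
  if (length(bad))
    stop("os_time must be > 0; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  if ("msi" %in% colnames(df)) {
    ok <- is.na(df$msi) | df$msi %in% c("MSS", "MSI-L", "MSI-H")
    if (!all(ok)) stop("msi must be one of MSS, MSI-L, MSI-H")
  }
  df
}

#' @export
write_clinical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file (Broad dialect)
#'
#' Each line: set name, description, then tab-separated member genes.
#'
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  empty <- lengths(sets) == 0
  if (any(empty)) stop("empty gene set(s): ", paste(nm[empty], collapse = ", "))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(
    vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)), nm)
  sets
}

#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions))
      descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-lite mutation table
#'
#' TSV with columns `sample_id`, `gene`, `variant_class`. Fully duplicated
#' rows are rejected.
#'
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "variant_class")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df[need]))
    stop("fully duplicated mutation row(s) present")
  df
}

#' @export
write_mutations <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Inner-join two cohorts on shared genes
#'
#' Utility for merging platforms on shared gene symbols (case-sensitive, no
#' aliasing). Units must match.
#'
#' @export
merge_cohorts <- function(x, y) {
  if (expr_unit(x) != expr_unit(y)) stop("units differ")
  shared <- intersect(rownames(x), rownames(y))
  if (length(shared) < 2) stop("fewer than 2 shared genes")
  if (length(intersect(colnames(x), colnames(y))))
    stop("sample ids overlap between cohorts")
  expression_matrix(cbind(unclass(x)[shared, , drop = FALSE],
                          unclass(y)[shared, , drop = FALSE]),
                    expr_unit(x))
}
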