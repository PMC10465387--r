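#' Read a regulator catalog TSV
#'
#' A regulator catalog maps each RNA-modification regulator gene to its
#' modification mark (m6A, m5C or m1A) and enzymatic role (writer deposits
#' the mark, reader recognises it, eraser removes it). File format: TSV with
#' columns `gene`, `modification`, `role`.
#'
#' @param path file path.
#' @return data.frame of class `regulator_catalog`.
#' @export
read_regulator_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "modification", "role")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene))
    stop("duplicate gene id(s) in catalog: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  if (!all(df$modification %in% c("m6A", "m5C", "m1A")))
    stop("modification must be one of m6A, m5C, m1A")
  if (!all(df$role %in% c("writer", "reader", "eraser")))
    stop("role must be one of writer, reader, eraser")
  if (any(is.na(df$gene)) || any(!nzchar(df$gene)))
    stop("empty gene id in catalog")
  class(df) <- c("regulator_catalog", "data.frame")
  df
}

#' The packaged synthetic 48-regulator panel
#'
#' A synthetic stand-in panel of 48 RNA-modification regulators (23 m6A,
#' 15 m5C, 10 m1A) assembled from gene symbols standard in the field. Each
#' gene appears once, under the modification whose panel slot it fills.
#'
#' @return a `regulator_catalog` data.frame with 48 rows.
#' @export
regulator_catalog <- function() {
  path <- system.file("extdata", "regulator_catalog_synthetic.tsv",
                      package = "rnamodsig", mustWork = TRUE)
  read_regulator_catalog(path)
}

#' Count regulators by modification and role
#'
#' @param catalog a `regulator_catalog`.
#' @return list with `total`, `by_modification`, `by_role`.
#' @export
catalog_counts <- function(catalog) {
  list(total = nrow(catalog),
       by_modification = table(factor(catalog$modification,
                                      levels = c("m6A", "m5C", "m1A"))),
       by_role = table(factor(catalog$role,
                              levels = c("writer", "reader", "eraser"))))
}

#' @export
print.regulator_catalog <- function(x, ...) {
  cc <- catalog_counts(x)
  cat(sprintf("<regulator_catalog> %d genes (%s)\n", cc$total,
              paste(sprintf("%s: %d", names(cc$by_modification),
                            as.integer(cc$by_modification)), collapse = ", ")))
  invisible(x)
}
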