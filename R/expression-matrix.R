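#' Expression matrix with sample metadata
#'
#' Genes x samples counts (or TPM) plus a metadata row per sample giving
#' species, time point and replicate.
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample
#'   ids; all values non-negative.
#' @param meta `data.frame` with one row per column of `values` and
#'   columns `sample`, `species`, `time`, `replicate`.
#' @return An object of class `ExpressionMatrix` (list with `values`,
#'   `meta`).
#' @export
expression_matrix <- function(values, meta) {
  values <- as.matrix(values)
  .assert(all(values >= 0), "expression values must be non-negative")
  .assert(nrow(meta) == ncol(values), "one metadata row per sample column is required")
  need <- c("sample", "species", "time", "replicate")
  .assert(all(need %in% names(meta)), "metadata must give sample, species, time, replicate")
  .assert(!anyNA(meta[need]), "metadata must be complete for every sample")
  .assert(identical(as.character(meta$sample), colnames(values)),
          "metadata sample order must match matrix columns")
  structure(list(values = values, meta = meta), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s; t = %s h)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$meta$species), collapse = ","),
              paste(sort(unique(x$meta$time)), collapse = ", ")))
  invisible(x)
}

#' Write / read an expression matrix as TSV with a metadata header block
#'
#' The file starts with comment lines `#meta sample species time
#' replicate` (one per sample) followed by a tab-separated genes x
#' samples table.
#'
#' @param x An `ExpressionMatrix`.
#' @param path File path.
#' @return Invisibly `path`; for the reader, an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x$meta))) {
    writeLines(sprintf("#meta\t%s\t%s\t%s\t%s", x$meta$sample[i], x$meta$species[i],
                       format(x$meta$time[i]), x$meta$replicate[i]), con)
  }
  utils::write.table(data.frame(gene_id = rownames(x$values), x$values,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#meta\t", lines, value = TRUE)
  meta <- do.call(rbind, lapply(strsplit(meta_lines, "\t"), function(x)
    data.frame(sample = x[2], species = x[3], time = as.numeric(x[4]),
               replicate = as.integer(x[5]))))
  tab <- utils::read.delim(textConnection(lines[!startsWith(lines, "#meta")]),
                           check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene_id
  expression_matrix(values, meta)
}
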