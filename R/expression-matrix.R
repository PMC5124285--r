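#' Read an expression matrix from delimited text
#'
#' Reads a genes x conditions real-valued matrix from a delimited text file.
#' The first row must be a header of condition identifiers and the first
#' column must hold gene identifiers; every remaining cell must parse as a
#' real number.  Row and column order are preserved.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, tab by default.
#'
#' @return A numeric matrix with gene identifiers as `rownames` and condition
#'   identifiers as `colnames`.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' write_expression_matrix(m, tf)
#' m2 <- read_expression_matrix(tf)
#' all.equal(m, m2)
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          fill = FALSE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expected at least 2 condition columns after the gene id column")
  gene_ids <- df[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  condition_ids <- colnames(df)[-1]
  dupc <- condition_ids[duplicated(condition_ids)]
  if (length(dupc)) stop("duplicate condition id: ", paste(unique(dupc), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) | is.nan(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing cell at gene '%s', condition '%s' (value '%s')",
                 gene_ids[bad[1, 1]], condition_ids[bad[1, 2]], raw[bad[1, 1], bad[1, 2]]))
  }
  dimnames(values) <- list(gene_ids, condition_ids)
  validate_expression_matrix(values)
  values
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: writes a header row of condition
#' identifiers and one row per gene, first field the gene identifier.
#'
#' @param matrix Numeric matrix with gene rownames and condition colnames.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(matrix, path, delimiter = "\t") {
  validate_expression_matrix(matrix)
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- "gene_id"
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the container invariants assumed throughout the package: a numeric
#' matrix, no missing values, at least one gene and two conditions, and
#' duplicate-free gene/condition identifiers (generated when absent).
#'
#' @param matrix Candidate matrix.
#' @return The matrix, invisibly, with dimnames guaranteed.
#' @export
validate_expression_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix")
  if (nrow(matrix) < 1) stop("expression matrix needs at least one gene")
  if (ncol(matrix) < 2) stop("expression matrix needs at least two conditions")
  if (anyNA(matrix) || any(is.nan(matrix)))
    stop("expression matrix contains missing or NaN entries")
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("g", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("c", seq_len(ncol(matrix)))
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene id: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]), collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate condition id: ",
         paste(unique(colnames(matrix)[duplicated(colnames(matrix))]), collapse = ", "))
  invisible(matrix)
}

#' Normalize each gene profile to unit Euclidean norm
#'
#' Divides every row by the square root of the sum of its squared entries,
#' so that the dot product of two normalized profiles is their cosine
#' similarity.  All-zero rows cannot be normalized; they are left as zeros
#' and reported in the `skip_report` attribute (a data frame of
#' `gene_id`/`reason`), and downstream steps exclude them.
#'
#' @param matrix Numeric genes x conditions matrix.
#' @return The matrix with every nonzero row rescaled to norm 1, carrying a
#'   `skip_report` attribute.
#'
#' @examples
#' l2_normalize(matrix(c(3, 4), 1, 2))  # the 3-4-5 triangle: 0.6, 0.8
#' @export
l2_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) stop("need a numeric matrix")
  nrm <- sqrt(rowSums(matrix^2))
  zero <- nrm == 0
  out <- matrix / ifelse(zero, 1, nrm)
  skip <- data.frame(gene_id = if (is.null(rownames(matrix)))
                       as.character(which(zero)) else rownames(matrix)[zero],
                     reason = rep("zero norm", sum(zero)),
                     stringsAsFactors = FALSE)
  attr(out, "skip_report") <- skip
  out
}
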