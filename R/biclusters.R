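# Bicluster containers and their JSON/TSV serialization.

#' Construct a bicluster
#'
#' A bicluster is a subset of genes together with the subset of conditions in
#' which those genes are coexpressed, optionally annotated with the mean
#' pairwise correlation of its genes, its selection score, and per-gene signs.
#'
#' @param genes Character vector of gene identifiers (nonempty, unique).
#' @param conditions Character vector of condition identifiers (nonempty,
#'   unique).
#' @param correlation Mean pairwise correlation of the member genes, or `NA`.
#' @param score Selection score (`y + log(x)/log(N)`), or `NA`.
#' @param signs Optional integer matrix of \{-1, +1\} signs, genes x
#'   conditions, restricted to `conditions`.
#' @return A `cg_bicluster` object.
#' @export
bicluster <- function(genes, conditions, correlation = NA_real_,
                      score = NA_real_, signs = NULL) {
  genes <- as.character(genes)
  conditions <- as.character(conditions)
  if (length(genes) == 0) stop("bicluster needs at least one gene")
  if (length(conditions) == 0) stop("bicluster needs at least one condition")
  if (anyDuplicated(genes)) stop("duplicate gene in bicluster")
  if (anyDuplicated(conditions)) stop("duplicate condition in bicluster")
  if (!is.na(correlation) && (correlation < -1 - 1e-9 || correlation > 1 + 1e-9))
    stop("correlation outside [-1, 1]")
  structure(list(genes = genes, conditions = conditions,
                 size = length(genes),
                 correlation = as.numeric(correlation),
                 score = as.numeric(score), signs = signs),
            class = "cg_bicluster")
}

#' Construct an ordered collection of biclusters
#'
#' @param biclusters List of [bicluster()] objects (possibly empty).
#' @param source_shape Optional integer pair `c(N, C)`: the dimensions of the
#'   matrix the biclusters refer to.
#' @return A `cg_bicluster_set` object.
#' @export
bicluster_set <- function(biclusters = list(), source_shape = NULL) {
  if (!all(vapply(biclusters, inherits, logical(1), "cg_bicluster")))
    stop("all elements must be cg_bicluster objects")
  structure(list(biclusters = biclusters,
                 source_shape = if (!is.null(source_shape))
                   as.integer(source_shape) else NULL),
            class = "cg_bicluster_set")
}

#' @export
length.cg_bicluster_set <- function(x) length(x$biclusters)

#' @export
print.cg_bicluster <- function(x, ...) {
  cat(sprintf("bicluster: %d gene(s) x %d condition(s)", x$size,
              length(x$conditions)))
  if (!is.na(x$correlation)) cat(sprintf(", correlation %.4f", x$correlation))
  if (!is.na(x$score)) cat(sprintf(", score %.4f", x$score))
  cat("\n")
  invisible(x)
}

#' @export
print.cg_bicluster_set <- function(x, ...) {
  cat(sprintf("bicluster set: %d bicluster(s)\n", length(x$biclusters)))
  if (length(x$biclusters)) {
    sizes <- vapply(x$biclusters, `[[`, 0L, "size")
    ncond <- vapply(x$biclusters, function(b) length(b$conditions), 0L)
    cat(sprintf("  sizes %s x conditions %s\n",
                paste(utils::head(sizes, 10), collapse = ","),
                paste(utils::head(ncond, 10), collapse = ",")))
  }
  invisible(x)
}

cluster_to_bicluster <- function(cl) {
  bicluster(cl$genes, cl$conditions, correlation = cl$correlation,
            score = cl$score)
}

# deterministic ordering: size desc, correlation desc, smallest gene id
sort_biclusters <- function(bl) {
  if (length(bl) < 2) return(bl)
  sizes <- vapply(bl, `[[`, 0L, "size")
  corr <- vapply(bl, `[[`, 0, "correlation")
  corr[is.na(corr)] <- -Inf
  firstgene <- vapply(bl, function(b) min(b$genes), "")
  bl[order(-sizes, -corr, firstgene, method = "radix")]
}

#' Write a bicluster set to JSON or TSV
#'
#' JSON stores, per bicluster, the gene list, condition list, size,
#' correlation and score (`null` when absent).  TSV stores one row per
#' bicluster with semicolon-joined member lists.  [read_biclusters()] inverts
#' both losslessly (up to numeric formatting in TSV).
#'
#' @param set A `cg_bicluster_set`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`; guessed from the file extension when
#'   missing.
#' @return Invisibly, `path`.
#' @export
write_biclusters <- function(set, path, format = c("json", "tsv")) {
  if (!inherits(set, "cg_bicluster_set")) stop("need a cg_bicluster_set")
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (format == "json") {
    payload <- list(
      source_shape = set$source_shape,
      biclusters = lapply(set$biclusters, function(b)
        list(genes = b$genes, conditions = b$conditions, size = b$size,
             correlation = b$correlation, score = b$score))
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  } else {
    df <- data.frame(
      size = vapply(set$biclusters, `[[`, 0L, "size"),
      correlation = vapply(set$biclusters, `[[`, 0, "correlation"),
      score = vapply(set$biclusters, `[[`, 0, "score"),
      genes = vapply(set$biclusters, function(b) paste(b$genes, collapse = ";"), ""),
      conditions = vapply(set$biclusters, function(b) paste(b$conditions, collapse = ";"), ""),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv"
  else stop("cannot guess format from extension; pass format=")
}

#' Read a bicluster set written by [write_biclusters()]
#'
#' @param path Input path.
#' @param format `"json"` or `"tsv"`; guessed from the extension when
#'   missing.
#' @return A `cg_bicluster_set`.
#' @export
read_biclusters <- function(path, format = c("json", "tsv")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- if (missing(format)) guess_format(path) else match.arg(format)
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
    bl <- lapply(payload$biclusters, function(b)
      bicluster(b$genes, b$conditions,
                correlation = if (is.null(b$correlation)) NA_real_ else b$correlation,
                score = if (is.null(b$score)) NA_real_ else b$score))
    bicluster_set(bl, source_shape = payload$source_shape)
  } else {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    bl <- lapply(seq_len(nrow(df)), function(i)
      bicluster(strsplit(df$genes[i], ";", fixed = TRUE)[[1]],
                strsplit(df$conditions[i], ";", fixed = TRUE)[[1]],
                correlation = df$correlation[i], score = df$score[i]))
    bicluster_set(bl)
  }
}
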