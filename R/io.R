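#' Read an expression matrix from a delimited file
#'
#' Reads a TSV/CSV file with one header row and one label column into a
#' numeric samples-by-genes matrix, transposing if the file stores genes as
#' rows. The delimiter is inferred from the extension (`.csv` = comma,
#' otherwise tab) unless `sep` is given.
#'
#' @param path File path.
#' @param orientation `"samples_by_genes"` (file rows are samples) or
#'   `"genes_by_samples"` (file rows are genes; the matrix is transposed on
#'   read).
#' @param sep Optional field delimiter overriding the extension-based
#'   default.
#' @return A numeric matrix, samples in rows (named) and genes in columns
#'   (named).
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes",
                                            "genes_by_samples"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "")
  if (length(nf) < 2L) stop("parse error: ", path, " has no data rows")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("parse error: ragged row at line ", bad, " of ", path,
         " (", nf[bad], " fields, expected ", nf[1L], ")")
  }
  dat <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
  labels <- as.character(dat[[1L]])
  if (anyDuplicated(labels))
    stop("duplicate row labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  m <- as.matrix(dat[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(labels, colnames(m))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("parse error: non-numeric value at line ", bad[1L] + 1L,
         ", column ", bad[2L] + 1L, " of ", path)
  }
  if (orientation == "genes_by_samples") num <- t(num)
  if (anyDuplicated(rownames(num)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(num)[duplicated(rownames(num))]),
               collapse = ", "))
  num
}

#' Write an expression matrix
#'
#' Writes a samples-by-genes matrix as a delimited file with a leading
#' sample-id column, at full (17 significant digit) precision so that a
#' write/read round trip is lossless.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path; `.csv` selects comma, otherwise tab.
#' @export
write_expression <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  df <- data.frame(sample = rownames(x),
                   apply(x, 2L, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample", colnames(x))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter and collapse expression probes
#'
#' Applies the standard beadchip preprocessing ahead of network analysis:
#' probes with non-detectable expression (detection p-value above
#' `detect_cutoff`) in at least `max_undetected_frac` of samples are
#' removed, and the remaining probes mapping to the same gene symbol are
#' replaced by their per-sample mean.
#'
#' @param expr Samples-by-probes numeric matrix.
#' @param detection_p Matrix of detection p-values aligned with `expr`.
#' @param detect_cutoff Detection p-value cutoff (default 0.01).
#' @param max_undetected_frac Removal threshold on the fraction of samples
#'   in which a probe is undetected (default 0.90).
#' @param probe_to_gene Optional mapping from probe id to gene symbol: a
#'   named character vector (`names` = probes) or a two-column data frame
#'   (probe, gene). Probes absent from the mapping keep their probe id.
#' @return Samples-by-genes matrix with unique gene columns, in order of
#'   first appearance.
#' @export
preprocess_probes <- function(expr, detection_p, detect_cutoff = 0.01,
                              max_undetected_frac = 0.90,
                              probe_to_gene = NULL) {
  expr <- as.matrix(expr)
  detection_p <- as.matrix(detection_p)
  if (!all(dim(expr) == dim(detection_p)))
    stop("'detection_p' must be aligned with 'expr'")
  probes <- colnames(expr)
  if (is.null(probes)) probes <- paste0("p", seq_len(ncol(expr)))
  undetected <- colMeans(detection_p > detect_cutoff)
  keep <- undetected < max_undetected_frac
  if (!any(keep))
    stop("empty result: no probes pass the detection filter")
  expr <- expr[, keep, drop = FALSE]
  probes <- probes[keep]

  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2L]]),
                           as.character(probe_to_gene[[1L]]))
  } else map <- probe_to_gene
  genes <- probes
  if (!is.null(map)) {
    hit <- probes %in% names(map)
    genes[hit] <- unname(map[probes[hit]])
  }

  ugenes <- unique(genes)
  out <- matrix(NA_real_, nrow(expr), length(ugenes),
                dimnames = list(rownames(expr), ugenes))
  for (g in ugenes) {
    cols <- which(genes == g)
    out[, g] <- if (length(cols) == 1L) expr[, cols]
                else rowMeans(expr[, cols, drop = FALSE])
  }
  out
}

#' Write a differential-network edge list
#'
#' Writes an edge table either as a delimited text file (full 17 significant
#' digit precision, losslessly re-readable with [read_network()]) or as
#' GraphML with every numeric column attached as an edge attribute (`W` is
#' the conventional weight).
#'
#' @param edges Data frame whose first two columns are the endpoint gene
#'   names, e.g. `fit$edges` from [diffnet()] or the output of
#'   [differential_network()].
#' @param path Output file path.
#' @param format `"tsv"` or `"graphml"`; default inferred from the
#'   extension.
#' @export
write_network <- function(edges, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "tsv"
  format <- match.arg(format, c("tsv", "graphml"))
  if (format == "tsv") {
    df <- edges
    for (j in seq_along(df))
      if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a differential-network edge list
#'
#' Reads an edge table written by [write_network()]; numeric columns are
#' restored.
#'
#' @param path File path (`.graphml` or delimited text).
#' @return A data frame of edges with attribute columns.
#' @export
read_network <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    names(df)[1:2] <- c("gene_i", "gene_j")
    return(df)
  }
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v)) df[[j]] <- v
  }
  df
}
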