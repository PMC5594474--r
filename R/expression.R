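#' Construct a validated expression matrix
#'
#' The central data container: a numeric matrix of log-scale expression with
#' genes in rows and samples in columns, carrying unique gene and sample
#' identifiers as dimnames. All downstream operations (whitening, multi-run
#' ICA, order scans) expect this orientation.
#'
#' @param values Numeric matrix, genes x samples.
#' @param gene_ids Character vector of unique gene identifiers (default:
#'   rownames of `values`).
#' @param sample_ids Character vector of unique sample identifiers (default:
#'   colnames of `values`).
#' @return The matrix with dimnames set and class `expression_matrix`.
#'   A warning is emitted when the maximum value exceeds 30, which usually
#'   means the data are on a linear rather than a logarithmic scale; the
#'   values are never transformed automatically.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  if (max(values) > 30) {
    warning("maximum value exceeds 30: data may not be on a log scale",
            call. = FALSE)
  }
  class(values) <- c("expression_matrix", class(matrix()))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  value range: [%.3g, %.3g]\n", min(x), max(x)))
  invisible(x)
}

as_expression_values <- function(x) {
  if (inherits(x, "expression_matrix")) return(unclass(x))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an expression_matrix or a numeric matrix", call. = FALSE)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Orientation is normalised to genes x samples internally;
#' set `genes_in_rows = FALSE` for files with samples in rows.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter (default tab).
#' @param genes_in_rows Whether rows of the file are genes (default `TRUE`).
#' @param duplicate_genes Policy for duplicated gene identifiers: `"error"`
#'   (default) or `"max_variance"` (keep the row with the largest variance).
#' @param missing_values Policy for missing cells: `"error"` (default) or
#'   `"impute_row_mean"` (replace by the gene's mean over observed samples).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t", genes_in_rows = TRUE,
                            duplicate_genes = c("error", "max_variance"),
                            missing_values = c("error", "impute_row_mean")) {
  duplicate_genes <- match.arg(duplicate_genes)
  missing_values <- match.arg(missing_values)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), delimiter, fixed = TRUE)[[1]]
  if (length(header) < 2L) stop("malformed header in ", path, call. = FALSE)
  col_ids <- header[-1]
  if (anyDuplicated(col_ids)) {
    stop("duplicate column ids in header: ",
         paste(unique(col_ids[duplicated(col_ids)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  row_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- is.na(values) & !is.na(cells) & cells != "NA" & cells != ""
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 cells[idx[1], idx[2]], row_ids[idx[1]], col_ids[idx[2]]),
         call. = FALSE)
  }
  dimnames(values) <- list(row_ids, col_ids)
  if (!genes_in_rows) values <- t(values)
  if (any(is.na(values))) {
    if (missing_values == "error") {
      idx <- which(is.na(values), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at gene '%s', sample '%s' (set missing_values = \"impute_row_mean\" to impute)",
                   rownames(values)[idx[1]], colnames(values)[idx[2]]),
           call. = FALSE)
    }
    for (i in which(rowSums(is.na(values)) > 0)) {
      mu <- mean(values[i, ], na.rm = TRUE)
      if (!is.finite(mu)) {
        stop("gene '", rownames(values)[i], "' has no observed values",
             call. = FALSE)
      }
      values[i, is.na(values[i, ])] <- mu
    }
  }
  gid <- rownames(values)
  if (anyDuplicated(gid)) {
    if (duplicate_genes == "error") {
      stop("duplicate gene ids: ",
           paste(unique(gid[duplicated(gid)])[1:3], collapse = ", "),
           call. = FALSE)
    }
    v <- apply(values, 1, stats::var)
    keep <- unlist(lapply(split(seq_along(gid), gid), function(ix) {
      ix[which.max(v[ix])]
    }), use.names = FALSE)
    values <- values[sort(keep), , drop = FALSE]
  }
  expression_matrix(values)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]: genes in rows, a `gene_id` first column
#' and sample identifiers in the header. Values are written with full double
#' precision so a read/write round trip is lossless.
#'
#' @param x An [expression_matrix()] (or plain genes x samples matrix with
#'   dimnames).
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = "\t") {
  v <- as_expression_values(x)
  write_numeric_table(v, path, delimiter, id_col = "gene_id")
  invisible(path)
}

# Write a numeric matrix with row ids as the first column, full precision.
write_numeric_table <- function(v, path, delimiter = "\t", id_col = "id") {
  header <- paste(c(id_col, colnames(v)), collapse = delimiter)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], formatC(v[i, ], format = "g", digits = 17)),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

read_numeric_table <- function(path, delimiter = "\t") {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, quote = "", comment.char = "")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a gene-set collection from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: a named list with elements
#'   `description` and `genes` per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  names(sets) <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected name, description and at least one gene", i),
           call. = FALSE)
    }
    names(sets)[i] <- fields[1]
    sets[[i]] <- list(description = fields[2], genes = unique(fields[-(1:2)]))
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names in GMT: ",
         paste(unique(names(sets)[duplicated(names(sets))])[1:3], collapse = ", "),
         call. = FALSE)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets A `gene_set_collection` (see [read_gmt()]) or a named list of
#'   character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (!inherits(sets, "gene_set_collection")) {
    sets <- structure(lapply(sets, function(g) list(description = "na", genes = g)),
                      class = "gene_set_collection")
    names(sets) <- names(sets)
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], sets[[i]]$description, sets[[i]]$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets\n", length(x)))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble::tibble(
    set = rep(names(x), vapply(x, function(s) length(s$genes), integer(1))),
    gene = unlist(lapply(x, function(s) s$genes), use.names = FALSE)
  )
}
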