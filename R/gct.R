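#' Construct an expression matrix ("gct" object)
#'
#' The central container of the package: a genes x samples numeric matrix
#' together with row (probe) and column (sample) annotation data frames and
#' an optional processing-level tag (1--5).  Levels 2--3 hold nonnegative
#' fluorescence-scale values; levels 4--5 hold unitless robust z-scores.
#'
#' @param mat numeric matrix with rownames (probe/gene ids) and colnames
#'   (sample ids).
#' @param rdesc data.frame of row annotations, one row per matrix row.  An
#'   `id` column is added from the rownames if absent.
#' @param cdesc data.frame of column annotations, one row per matrix column.
#' @param level integer processing level in 1..5, or `NULL` when untagged.
#' @return an object of class `gct`, a list with elements `mat`, `rdesc`,
#'   `cdesc`, `level`.
#' @export
gct <- function(mat, rdesc = NULL, cdesc = NULL, level = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(rownames(mat))) rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  if (is.null(rdesc)) rdesc <- data.frame(id = rownames(mat))
  if (is.null(cdesc)) cdesc <- data.frame(id = colnames(mat))
  rdesc <- as.data.frame(rdesc, stringsAsFactors = FALSE)
  cdesc <- as.data.frame(cdesc, stringsAsFactors = FALSE)
  if (!"id" %in% names(rdesc)) rdesc <- cbind(id = rownames(mat), rdesc)
  if (!"id" %in% names(cdesc)) cdesc <- cbind(id = colnames(mat), cdesc)
  if (nrow(rdesc) != nrow(mat))
    stop("row metadata has ", nrow(rdesc), " rows but matrix has ", nrow(mat))
  if (nrow(cdesc) != ncol(mat))
    stop("column metadata has ", nrow(cdesc), " rows but matrix has ",
         ncol(mat), " columns")
  if (!is.null(level)) {
    level <- as.integer(level)
    stopifnot(length(level) == 1L, level %in% 1:5)
  }
  rownames(rdesc) <- NULL
  rownames(cdesc) <- NULL
  structure(list(mat = mat, rdesc = rdesc, cdesc = cdesc, level = level),
            class = "gct")
}

#' @export
dim.gct <- function(x) dim(x$mat)

#' @export
print.gct <- function(x, ...) {
  cat(sprintf("gct object: %d genes x %d samples%s\n", nrow(x$mat),
              ncol(x$mat),
              if (is.null(x$level)) "" else sprintf(" (level %d)", x$level)))
  cat(sprintf("  row meta: %s\n", paste(names(x$rdesc), collapse = ", ")))
  cat(sprintf("  col meta: %s\n", paste(names(x$cdesc), collapse = ", ")))
  invisible(x)
}

# format one numeric cell for GCT output; missing -> "NaN"
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NaN" else sprintf("%.15g", v)
  }, character(1))
  out
}

#' Read a GCT 1.3 text file
#'
#' Parses the tab-delimited GCT version 1.3 dialect: a `#1.3` header line, a
#' dimension line `nrow ncol n_rowmeta n_colmeta`, a header row, `n_colmeta`
#' rows of column annotations, then one data row per gene.  `NaN` tokens are
#' read as missing (`NA_real_`).
#'
#' @param path path to a GCT file.
#' @param level optional processing-level tag to attach.
#' @return a [gct] object.
#' @export
read_gct <- function(path, level = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("malformed GCT: fewer than 3 lines in ", path)
  if (trimws(lines[1L]) != "#1.3")
    stop("malformed GCT header: expected '#1.3', got '", lines[1L], "'")
  dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (length(dims) != 4L || anyNA(suppressWarnings(as.integer(dims))))
    stop("malformed GCT dimension line: '", lines[2L], "'")
  dims <- as.integer(dims)
  nr <- dims[1L]; nc <- dims[2L]; nrm <- dims[3L]; ncm <- dims[4L]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (length(body) != 1L + ncm + nr)
    stop("GCT dimension mismatch: expected ", 1L + ncm + nr,
         " body lines, found ", length(body))
  width <- 1L + nrm + nc
  header <- body[[1L]]
  if (length(header) != width)
    stop("GCT dimension mismatch: header has ", length(header),
         " fields, expected ", width)
  rmeta_names <- if (nrm > 0L) header[2:(1L + nrm)] else character(0)
  sample_ids <- header[(2L + nrm):width]
  cdesc <- data.frame(id = sample_ids, stringsAsFactors = FALSE)
  for (i in seq_len(ncm)) {
    row <- body[[1L + i]]
    if (length(row) != width)
      stop("GCT dimension mismatch in column-metadata row ", i)
    vals <- row[(2L + nrm):width]
    cdesc[[row[1L]]] <- utils::type.convert(vals, as.is = TRUE,
                                            na.strings = "NaN")
  }
  rid <- character(nr)
  rmeta <- if (nrm > 0L)
    as.data.frame(matrix(NA_character_, nr, nrm), stringsAsFactors = FALSE)
  else NULL
  mat <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- body[[1L + ncm + i]]
    if (length(row) != width)
      stop("GCT dimension mismatch in data row ", i)
    rid[i] <- row[1L]
    if (nrm > 0L) rmeta[i, ] <- row[2:(1L + nrm)]
    vals <- row[(2L + nrm):width]
    vals[vals == "NaN" | vals == "NA" | vals == ""] <- NA
    mat[i, ] <- as.numeric(vals)
  }
  rownames(mat) <- rid
  colnames(mat) <- sample_ids
  rdesc <- data.frame(id = rid, stringsAsFactors = FALSE)
  if (nrm > 0L) {
    names(rmeta) <- rmeta_names
    rmeta[] <- lapply(rmeta, utils::type.convert, as.is = TRUE,
                      na.strings = "NaN")
    rdesc <- cbind(rdesc, rmeta)
  }
  gct(mat, rdesc = rdesc, cdesc = cdesc, level = level)
}

#' Write a GCT 1.3 text file
#'
#' Inverse of [read_gct]: emits the tab-delimited `#1.3` dialect with all row
#' and column annotations (the `id` column is the row/column key and is not
#' repeated as a metadata field).  Numeric cells are written at full double
#' precision; missing values as the token `NaN`.
#'
#' @param x a [gct] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "gct"))
  rmeta <- x$rdesc[setdiff(names(x$rdesc), "id")]
  cmeta <- x$cdesc[setdiff(names(x$cdesc), "id")]
  nrm <- ncol(rmeta); ncm <- ncol(cmeta)
  nr <- nrow(x$mat); nc <- ncol(x$mat)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(nr, nc, nrm, ncm, sep = "\t"), con)
  writeLines(paste(c("id", names(rmeta), colnames(x$mat)), collapse = "\t"),
             con)
  fmt_meta <- function(v) {
    out <- if (is.double(v)) .fmt_num(v) else as.character(v)
    out[is.na(out)] <- "NaN"
    out
  }
  for (j in seq_len(ncm)) {
    writeLines(paste(c(names(cmeta)[j], rep("", nrm), fmt_meta(cmeta[[j]])),
                     collapse = "\t"), con)
  }
  rm_chr <- lapply(rmeta, fmt_meta)
  for (i in seq_len(nr)) {
    meta_i <- vapply(rm_chr, `[`, character(1), i)
    writeLines(paste(c(rownames(x$mat)[i], meta_i, .fmt_num(x$mat[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}
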