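# Readers and writers for the plain-text formats the pipeline exchanges:
# count TSV (gene_id, length, one column per sample), design TSV, physio TSV,
# and GMT annotation files.

write_tsv_ <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Write a count table to TSV
#'
#' Layout: columns `gene_id`, `length`, then one column per sample.
#'
#' @param counts integer matrix, genes x samples, with rownames.
#' @param lengths numeric vector of gene lengths in bp, aligned with rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, lengths, path) {
  stopifnot(is.matrix(counts), length(lengths) == nrow(counts))
  df <- data.frame(gene_id = rownames(counts), length = as.integer(lengths),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(df, path)
}

#' Read a count table from TSV
#'
#' @param path file written by [write_counts()] (columns `gene_id`, `length`,
#'   then samples).
#' @return list with `counts` (integer matrix, genes x samples) and `lengths`
#'   (named numeric vector of bp).
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length") %in% names(df)[1:2])) {
    stop("count TSV must start with columns 'gene_id' and 'length'")
  }
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  lengths <- stats::setNames(df$length, df$gene_id)
  list(counts = counts, lengths = lengths)
}

#' Write / read a sample design table
#'
#' Design TSV columns: `sample`, `group`, `replicate`. Groups carry the
#' treatment order (e.g. M1 < M2 < M3 for Mg 0, 0.4, 0.8 mmol/L).
#'
#' @param design a design data.frame, see [make_design()].
#' @param path file path.
#' @return `path` (write) or a validated design data.frame (read).
#' @export
write_design <- function(design, path) {
  write_tsv_(design[, c("sample", "group", "replicate")], path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group", "replicate") %in% names(df)))
  df$group <- factor(df$group, levels = sort(unique(df$group)), ordered = TRUE)
  validate_design(df)
}

#' Write / read a physiochemical index table
#'
#' Physio TSV layout: column `index`, then one column per sample; an optional
#' `polarity` attribute (named character, `"benefit"`/`"cost"`) is stored as a
#' second file is avoided by keeping polarity in the index name order given by
#' [generate_physio()]; use `polarity` explicitly downstream when reading.
#'
#' @param physio numeric matrix, indexes x samples, with rownames.
#' @param path file path.
#' @return `path` (write) or the matrix (read), with a `polarity` attribute
#'   when present in the file header comment.
#' @export
write_physio <- function(physio, path) {
  pol <- attr(physio, "polarity")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(pol)) {
    writeLines(sprintf("# polarity: %s",
                       paste(sprintf("%s=%s", names(pol), pol), collapse = ",")),
               con)
  }
  utils::write.table(
    data.frame(index = rownames(physio), physio, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_physio
#' @export
read_physio <- function(path) {
  first <- readLines(path, n = 1L)
  pol <- NULL
  if (startsWith(first, "# polarity:")) {
    spec <- strsplit(sub("^# polarity:\\s*", "", first), ",")[[1]]
    kv <- strsplit(spec, "=")
    pol <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$index
  if (!is.null(pol)) attr(m, "polarity") <- pol[rownames(m)]
  m
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated fields `term`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (term -> genes), with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- stats::setNames(list(), character())
    attr(out, "description") <- stats::setNames(character(), character())
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("GMT records need >= 3 tab-separated fields (line ",
                     which(bad)[1], ")")
  terms <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(terms)) stop("duplicated term names in GMT file")
  desc <- stats::setNames(vapply(fields, `[`, "", 2L), terms)
  out <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), terms)
  attr(out, "description") <- desc
  out
}

#' Write a GMT gene-set file
#'
#' @param annotation named list of character vectors (term -> genes);
#'   an optional `description` attribute supplies the second GMT field
#'   (defaults to the term name).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path) {
  desc <- attr(annotation, "description")
  lines <- vapply(seq_along(annotation), function(i) {
    term <- names(annotation)[i]
    d <- if (!is.null(desc) && term %in% names(desc)) desc[[term]] else term
    paste(c(term, d, annotation[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression (FPKM) matrix to TSV
#'
#' @param expr numeric matrix, genes x samples, with rownames.
#' @param path output file path.
#' @return `path` (write) or the numeric matrix (read).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write_tsv_(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
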