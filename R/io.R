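# Table and set-file readers/writers with strict validation. All readers
# accept mixed line endings (CRLF is normalized); writers emit LF.

read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)
}

#' Write / read a gene-by-sample count matrix (TSV)
#'
#' Layout: header row `gene_id` + sample ids, one row per gene.
#'
#' @param counts Integer matrix with gene/sample dimnames.
#' @param path File path.
#' @return `read_counts_tsv` returns the validated integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  lines <- read_text_lines(path)
  if (!length(lines)) stop("empty counts file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(fields[[1]])
  bad <- which(vapply(fields, length, 0L) != ncol_expect)
  if (length(bad)) {
    stop("malformed counts row(s) at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " in ", path)
  }
  header <- fields[[1]]
  if (header[1] != "gene_id") stop("counts header must start with 'gene_id'")
  body <- fields[-1]
  genes <- vapply(body, `[[`, "", 1)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(ncol_expect - 1)))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol_expect - 1)
  if (anyNA(m)) {
    bad_rows <- which(rowSums(is.na(m)) > 0)
    stop("non-numeric count value(s) at line(s) ",
         paste(utils::head(bad_rows + 1, 5), collapse = ", "), " in ", path)
  }
  dimnames(m) <- list(genes, header[-1])
  validate_counts(m)
}

#' Write / read the sample design (CSV)
#'
#' Columns: `sample_id`, `fish_id`, `exposure`, `sex`, `week`, `tank`;
#' the exposure factor keeps the file's level order (first occurrence
#' first, water ahead of the dose groups when present).
#'
#' @param design Design data frame.
#' @param path File path.
#' @param group_levels Optional explicit exposure level order for reading.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, group_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "fish_id", "exposure", "sex", "week", "tank")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("design file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in design")
  if (is.null(group_levels)) group_levels <- unique(df$exposure)
  df$exposure <- factor(df$exposure, levels = group_levels)
  df$sex <- factor(df$sex)
  df$week <- factor(df$week)
  rownames(df) <- df$sample_id
  df
}

#' Write / read a GMT-style gene set file
#'
#' One set per line: `term TAB description TAB gene1 TAB gene2 ...`
#' (at least one gene per set).
#'
#' @param sets Named list term -> gene ids.
#' @param path File path.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(tm) {
    desc <- if (!is.null(descriptions) && !is.null(descriptions[[tm]]))
      descriptions[[tm]] else "na"
    paste(c(tm, desc, sets[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 3)
  if (length(bad)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(utils::head(bad, 5), collapse = ", "), " in ", path)
  }
  terms <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(terms)) stop("duplicated terms in GMT file")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- terms
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2), terms)
  sets
}

#' Write / read a generic results table (TSV)
#'
#' @param df Data frame.
#' @param path File path.
#' @param required Column names a reader must find.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("table ", path, " lacks column(s): ", paste(missing, collapse = ", "))
    }
  }
  df
}
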