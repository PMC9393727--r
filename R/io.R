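utils::globalVariables(c("rna_log2fc", "prot_log2fc", "significant",
                         "term", "adjusted"))

#' Read a feature-by-sample numeric matrix from TSV
#'
#' Expects a tab-separated file with a header row whose first column holds
#' feature IDs. Leading lines starting with `#` (provenance headers) are
#' skipped. Ragged rows, duplicated feature IDs and non-numeric cells are
#' rejected with the offending line or ID named.
#'
#' @param path File path.
#' @return Numeric matrix with feature IDs as rownames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(fields)
  if (length(unique(width)) != 1) {
    stop("ragged rows in ", path, " at line(s): ",
         paste(utils::head(which(width != width[1]), 5), collapse = ", "))
  }
  header <- fields[[1]]
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicated feature ID(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  if (length(body) == 0) {
    return(matrix(numeric(0), 0, length(header) - 1,
                  dimnames = list(NULL, header[-1])))
  }
  cells <- t(vapply(body, function(f) f[-1], character(length(header) - 1)))
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !(cells %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric cell in ", path, " at line ", bad[1, 1] + 1,
         ", column ", bad[1, 2] + 1)
  }
  dimnames(num) <- list(ids, header[-1])
  num
}

#' Write a table or matrix to TSV
#'
#' Tab-delimited, UTF-8, header row, no quoting, `NA` for missing values.
#' Matrices gain a leading ID column from their rownames. Optional
#' provenance lines are written first, each prefixed with `#` (readers in
#' this package skip them).
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param id_column Name for the rowname column when `x` is a matrix.
#' @param header_lines Optional character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, id_column = "feature",
                        header_lines = NULL) {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, stringsAsFactors = FALSE,
                     check.names = FALSE, row.names = NULL)
    names(df)[1] <- id_column
    x <- df
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires columns `sample`, `genotype`, `timepoint`, `replicate`; a
#' `group` column (`genotype_timepoint`) is added when absent.
#'
#' @param path TSV path.
#' @return Sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "genotype", "timepoint", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicated sample IDs in sample sheet")
  if (!"group" %in% names(df)) {
    df$group <- paste(df$genotype, df$timepoint, sep = "_")
  }
  df
}

#' Read a term annotation (two-column TSV or GMT)
#'
#' A `.gmt` file has one term per line (`term<TAB>description<TAB>gene...`);
#' anything else is read as a TSV with columns `term` and `gene`.
#'
#' @param path File path.
#' @return Data frame with columns `term` and `gene`.
#' @export
read_term_annotation <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(parts) < 3
    if (any(short)) {
      stop("GMT line(s) with fewer than 3 fields: ",
           paste(utils::head(which(short), 5), collapse = ", "))
    }
    return(data.frame(
      term = rep(vapply(parts, `[[`, character(1), 1),
                 lengths(parts) - 2L),
      gene = unlist(lapply(parts, function(f) f[-(1:2)])),
      stringsAsFactors = FALSE
    ))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(c("term", "gene"), names(df))
  if (length(missing) > 0) {
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  }
  df[, c("term", "gene")]
}

#' Read a standalone fold-change table for the screen
#'
#' Reads a TSV with columns `gene_id` (or `gene`), `fc1`, `fc2`, `fc3`,
#' `fc4` and optional extras (printed delta columns, gene names). Unicode
#' minus signs (U+2212), as found in typeset tables, are normalised to
#' ASCII hyphen-minus before parsing; `\\` cells (the convention for "no
#' measurement") become `NA`.
#'
#' @param path File path.
#' @return Data frame suitable for [screen_records()].
#' @export
read_fc_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- gsub("\u2212", "-", lines)
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                          na.strings = c("NA", "\\", ""))
  if ("gene_id" %in% names(df) && !"gene" %in% names(df)) {
    names(df)[names(df) == "gene_id"] <- "gene"
  }
  need <- c("gene", "fc1", "fc2", "fc3", "fc4")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("fold-change table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  for (cc in c("fc1", "fc2", "fc3", "fc4")) df[[cc]] <- as.numeric(df[[cc]])
  df
}
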