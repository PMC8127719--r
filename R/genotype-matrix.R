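#' Construct a genotype matrix
#'
#' The universal exchange object of the package: a diploid biallelic SNP
#' genotype table with individuals as rows and loci as columns. Calls are
#' coded as the number of copies of the reference allele (0, 1, 2) with
#' `NA` for missing calls.
#'
#' @param calls integer matrix of genotype codes in `{0, 1, 2, NA}`.
#' @param individual_ids character vector of unique individual identifiers;
#'   defaults to the row names of `calls`.
#' @param locus_ids character vector of unique locus names; defaults to the
#'   column names of `calls`.
#' @return an integer matrix of class `"genotype_matrix"` with individual
#'   ids as row names and locus ids as column names.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, NA, 1, 1), nrow = 2,
#'                             dimnames = list(c("a", "b"), paste0("L", 1:3))))
#' n_called(g)
#' @export
genotype_matrix <- function(calls, individual_ids = rownames(calls),
                            locus_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("ind%d", seq_len(nrow(calls)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- sprintf("locus%d", seq_len(ncol(calls)))
  }
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (length(individual_ids) != nrow(calls)) {
    stop("length of 'individual_ids' does not match number of rows")
  }
  if (length(locus_ids) != ncol(calls)) {
    stop("length of 'locus_ids' does not match number of columns")
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  }
  if (anyDuplicated(locus_ids)) {
    stop("duplicate locus ids")
  }
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  dimnames(calls) <- list(individual_ids, locus_ids)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Number of non-missing calls per individual
#'
#' @param g a [genotype_matrix()].
#' @return named integer vector, one entry per individual.
#' @export
n_called <- function(g) {
  rowSums(!is.na(unclass(g)))
}

#' Retain individuals with enough successful genotype calls
#'
#' Individuals must be genotyped at a minimum number of SNPs to be retained
#' for baseline, broodstock or fishery analysis; the rest are dropped (the
#' panel default retains individuals called at 150 or more loci). Row order
#' of the retained individuals is preserved.
#'
#' @param g a [genotype_matrix()].
#' @param threshold minimum number of non-missing calls (inclusive).
#' @param quiet suppress the message listing dropped individuals.
#' @return the filtered genotype matrix; the ids of dropped individuals are
#'   attached as attribute `"dropped"`.
#' @export
qc_min_loci <- function(g, threshold = 150, quiet = FALSE) {
  stopifnot(threshold >= 0)
  keep <- n_called(g) >= threshold
  dropped <- rownames(g)[!keep]
  if (length(dropped) && !quiet) {
    message(sprintf("qc_min_loci: dropped %d individual(s) with < %d called loci: %s",
                    length(dropped), threshold,
                    paste(utils::head(dropped, 10), collapse = ", ")))
  }
  out <- genotype_matrix(unclass(g)[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

MISSING_TOKEN <- "NA"

#' Read a genotype table from delimited text
#'
#' Expects a tab-delimited file with one header row; the first column holds
#' individual ids and the remaining columns one locus each. Genotype tokens
#' are `0`, `1`, `2`; the token `NA` (or an empty field) is a missing call.
#' Any other token is converted to missing with a warning reporting the
#' total count.
#'
#' @param path file to read.
#' @param sep field separator (tab by default).
#' @return a [genotype_matrix()].
#' @seealso [write_genotypes()] for the inverse operation.
#' @export
read_genotypes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty genotype file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  n_loci <- length(header) - 1L
  if (n_loci < 1L) stop("genotype file has no locus columns: ", path)
  rows <- fields[-1L]
  len <- lengths(rows)
  if (any(len != n_loci + 1L)) {
    bad <- which(len != n_loci + 1L)[1L]
    stop(sprintf("malformed row at line %d of %s: expected %d fields, found %d",
                 bad + 1L, path, n_loci + 1L, len[bad]))
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate individual ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tokens <- matrix(unlist(lapply(rows, `[`, -1L)), nrow = length(rows),
                   byrow = TRUE)
  calls <- suppressWarnings(matrix(as.integer(tokens), nrow = nrow(tokens)))
  known_missing <- tokens == MISSING_TOKEN | tokens == ""
  unknown <- is.na(calls) & !known_missing
  unknown <- unknown | (!is.na(calls) & !(calls %in% 0:2))
  if (any(unknown)) {
    warning(sprintf("%d unrecognized genotype token(s) converted to missing",
                    sum(unknown)))
    calls[unknown] <- NA_integer_
  }
  genotype_matrix(calls, individual_ids = ids, locus_ids = header[-1L])
}

#' Write a genotype table as delimited text
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, sep = "\t") {
  m <- unclass(g)
  tokens <- matrix(as.character(m), nrow = nrow(m))
  tokens[is.na(m)] <- MISSING_TOKEN
  lines <- c(paste(c("individual_id", colnames(m)), collapse = sep),
             paste(rownames(m), apply(tokens, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read an individual metadata table
#'
#' Sibling table to the genotype matrix, keyed by `individual_id`. Expected
#' columns: `individual_id`, `collection_year`, `fishery`, `month`,
#' `size_class` (`legal`, `sublegal` or `unknown`); optional columns
#' `known_population`, `known_broodyear`. The sampling stratum is the
#' fishery crossed with the month.
#'
#' @param path file to read.
#' @return a tibble with a `stratum` column appended.
#' @export
read_individual_meta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "collection_year", "fishery", "month", "size_class")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$individual_id)) stop("duplicate individual ids in metadata")
  bad <- !meta$size_class %in% c("legal", "sublegal", "unknown")
  if (any(bad)) stop("invalid size_class value(s): ",
                     paste(unique(meta$size_class[bad]), collapse = ", "))
  meta$stratum <- paste(meta$fishery, meta$month, sep = ":")
  tibble::as_tibble(meta)
}

#' Write a result table with deterministic formatting
#'
#' Writes a delimited report in fixed column order. Columns named in
#' `percent_cols` are interpreted as proportions, multiplied by 100 and
#' formatted to one decimal place, matching the convention of published
#' stock-composition tables. Identical inputs always produce byte-identical
#' output.
#'
#' @param df data frame of finalized results.
#' @param path output file.
#' @param percent_cols character vector of proportion columns to render as
#'   percentages.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, percent_cols = character(), sep = "\t") {
  df <- as.data.frame(df)
  for (cl in percent_cols) {
    if (!cl %in% names(df)) stop("percent column not present: ", cl)
    df[[cl]] <- sprintf("%.1f", 100 * df[[cl]])
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(paste(names(df), collapse = sep), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, as.character), sep = sep))
    writeLines(body, con)
  }
  invisible(path)
}
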