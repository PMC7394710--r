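#' Construct a character matrix
#'
#' The central data container: `N` individuals (rows) measured for `d`
#' continuous morphological characters (columns), optionally carrying a
#' taxonomist-assigned label per individual. Labels are never used to form
#' clusters; they only serve external validation.
#'
#' @param values Numeric matrix (or data frame of numeric columns),
#'   individuals in rows, characters in columns. No missing values.
#' @param individual_ids Character vector of unique row identifiers.
#'   Defaults to the rownames of `values`, or `ind_1 ... ind_N`.
#' @param character_names Character vector of unique column names. Defaults
#'   to the colnames of `values`.
#' @param ground_truth Optional vector of taxon labels, one per individual.
#'
#' @return An object of class `character_matrix`: a list with elements
#'   `values` (numeric matrix with dimnames), `individual_ids`,
#'   `character_names`, and `ground_truth` (`NULL` when absent).
#' @export
#' @examples
#' m <- character_matrix(matrix(rnorm(12), 4, 3))
#' dim(m)
character_matrix <- function(values,
                             individual_ids = NULL,
                             character_names = NULL,
                             ground_truth = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  d <- ncol(values)
  individual_ids <- as.character(individual_ids %||% rownames(values) %||%
    paste0("ind_", seq_len(n)))
  character_names <- as.character(character_names %||% colnames(values) %||%
    paste0("char_", seq_len(d)))
  if (n < 2L) stop("a character matrix needs at least 2 individuals", call. = FALSE)
  if (d < 1L) stop("a character matrix needs at least 1 character", call. = FALSE)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at individual '%s', character '%s'",
                 individual_ids[idx[1L]], character_names[idx[2L]]),
         call. = FALSE)
  }
  if (length(individual_ids) != n) stop("individual_ids length mismatch", call. = FALSE)
  if (length(character_names) != d) stop("character_names length mismatch", call. = FALSE)
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual id: ",
         individual_ids[duplicated(individual_ids)][1L], call. = FALSE)
  }
  if (anyDuplicated(character_names)) {
    stop("duplicate character name: ",
         character_names[duplicated(character_names)][1L], call. = FALSE)
  }
  if (!is.null(ground_truth)) {
    if (length(ground_truth) != n) {
      stop("ground_truth must have one label per individual", call. = FALSE)
    }
    ground_truth <- as.character(ground_truth)
  }
  dimnames(values) <- list(individual_ids, character_names)
  structure(
    list(values = values,
         individual_ids = individual_ids,
         character_names = character_names,
         ground_truth = ground_truth),
    class = "character_matrix"
  )
}

#' @export
dim.character_matrix <- function(x) dim(x$values)

#' @export
as.matrix.character_matrix <- function(x, ...) x$values

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d individuals x %d characters\n",
              nrow(x$values), ncol(x$values)))
  cat("characters:", paste(x$character_names, collapse = ", "), "\n")
  if (!is.null(x$ground_truth)) {
    cat(sprintf("ground truth: %d taxa\n", length(unique(x$ground_truth))))
  } else {
    cat("ground truth: absent\n")
  }
  invisible(x)
}

.assert_character_matrix <- function(x) {
  if (!inherits(x, "character_matrix")) {
    stop("expected a character_matrix; see ?character_matrix", call. = FALSE)
  }
  x
}

.sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
}

#' Read a morphometric character table
#'
#' Reads a delimited text table (comma or tab; sniffed from the header line
#' unless given) with a header row, one id column, optional taxon-label
#' column, and numeric character columns in file order. Missing cells,
#' duplicate ids and non-numeric character values are errors that name the
#' offending row and column.
#'
#' @param path Path to the delimited file.
#' @param id_column Name of the column holding unique individual ids.
#' @param label_column Optional name of a taxon-label column; stored as
#'   `ground_truth`.
#' @param delimiter Field delimiter; `NULL` (default) sniffs `\t` vs `,`
#'   from the header line.
#' @return A [character_matrix].
#' @seealso [write_character_table()]
#' @export
read_character_table <- function(path, id_column = "individual_id",
                                 label_column = NULL, delimiter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delimiter <- delimiter %||% .sniff_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (!id_column %in% names(raw)) {
    stop(sprintf("id column '%s' not found in %s", id_column, path), call. = FALSE)
  }
  ids <- raw[[id_column]]
  if (anyDuplicated(ids)) {
    stop("duplicate id '", ids[duplicated(ids)][1L], "' in ", path, call. = FALSE)
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(raw)) {
      stop(sprintf("label column '%s' not found in %s", label_column, path),
           call. = FALSE)
    }
    labels <- raw[[label_column]]
  }
  char_cols <- setdiff(names(raw), c(id_column, label_column))
  if (length(char_cols) == 0L) stop("no character columns in ", path, call. = FALSE)
  vals <- matrix(NA_real_, nrow(raw), length(char_cols),
                 dimnames = list(ids, char_cols))
  for (cn in char_cols) {
    cell <- trimws(raw[[cn]])
    blank <- cell == "" | toupper(cell) == "NA"
    if (any(blank)) {
      i <- which(blank)[1L]
      stop(sprintf("missing value at row '%s', column '%s'", ids[i], cn),
           call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(cell))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   cell[i], ids[i], cn), call. = FALSE)
    }
    vals[, cn] <- num
  }
  character_matrix(vals, individual_ids = ids, character_names = char_cols,
                   ground_truth = labels)
}

#' Write a character matrix as a delimited table
#'
#' Inverse of [read_character_table()]: writes the id column first, then the
#' character columns in stored order, then (if present) the ground-truth
#' label column.
#'
#' @param x A [character_matrix].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @param id_column,label_column Column names used in the header.
#' @return `path`, invisibly.
#' @export
write_character_table <- function(x, path, delimiter = "\t",
                                  id_column = "individual_id",
                                  label_column = "taxon") {
  .assert_character_matrix(x)
  df <- data.frame(x$individual_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, x$character_names)
  if (!is.null(x$ground_truth)) df[[label_column]] <- x$ground_truth
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
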