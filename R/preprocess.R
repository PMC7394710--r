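#' Convert paired length/width characters to ratios
#'
#' Morphometric tables often record the same organ as a length and a width;
#' keeping both pseudoreplicates the organ. Each named pair is replaced by a
#' single length/width ratio column, placed at the position of the length
#' column; unpaired columns are untouched. The number of characters drops by
#' exactly `length(pairs)`.
#'
#' @param x A [character_matrix].
#' @param pairs List of character vectors
#'   `c(length_column, width_column, new_name)`.
#' @return A [character_matrix] with the pairs replaced by ratios.
#' @export
#' @examples
#' m <- character_matrix(cbind(len = c(10, 8), wid = c(2, 4), other = c(1, 2)))
#' ratio_transform(m, list(c("len", "wid", "len_wid_ratio")))
ratio_transform <- function(x, pairs) {
  .assert_character_matrix(x)
  if (length(pairs) == 0L) return(x)
  pairs <- lapply(pairs, function(p) {
    if (length(p) != 3L) {
      stop("each pair must be c(length_column, width_column, new_name)",
           call. = FALSE)
    }
    as.character(p)
  })
  used <- unlist(lapply(pairs, `[`, 1:2))
  if (anyDuplicated(used)) {
    stop("character '", used[duplicated(used)][1L],
         "' appears in more than one pair", call. = FALSE)
  }
  missing_cols <- setdiff(used, x$character_names)
  if (length(missing_cols)) {
    stop("pair refers to unknown character(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- x$values
  drop_cols <- character(0)
  for (p in pairs) {
    len <- vals[, p[1L]]
    wid <- vals[, p[2L]]
    if (any(wid == 0)) {
      i <- which(wid == 0)[1L]
      stop(sprintf("width character '%s' is 0 for individual '%s'; ratio undefined",
                   p[2L], x$individual_ids[i]), call. = FALSE)
    }
    vals[, p[1L]] <- len / wid
    colnames(vals)[colnames(vals) == p[1L]] <- p[3L]
    drop_cols <- c(drop_cols, p[2L])
  }
  vals <- vals[, !colnames(vals) %in% drop_cols, drop = FALSE]
  character_matrix(vals, individual_ids = x$individual_ids,
                   ground_truth = x$ground_truth)
}

#' Flag and drop strongly correlated characters
#'
#' Pairwise Pearson correlation tests over all character pairs in column
#' order. A pair is flagged when `r^2 >= r2_threshold` and the two-sided
#' correlation p-value is below `alpha`. Unless `report_only = TRUE`, one
#' member of each flagged pair is dropped: the later column, except that
#' characters listed in `keep` survive at the expense of their partner
#' (mirroring the expert choice of retaining the biologically preferred
#' member). Both members of a pair are never dropped by the same flag.
#'
#' @param x A [character_matrix] with at least two characters.
#' @param r2_threshold Squared-correlation threshold in (0, 1]; default 0.7.
#' @param alpha Significance level for the correlation test; default 0.05.
#' @param keep Character names protected from dropping.
#' @param report_only If `TRUE`, flag pairs but drop nothing.
#' @return List with elements `matrix` (the pruned [character_matrix]) and
#'   `report`, a data frame with columns `character_a`, `character_b`,
#'   `r_squared`, `p_value`, `action` (one of `"dropped_a"`, `"dropped_b"`,
#'   `"already_dropped"`, `"none"`) and `dropped` (the dropped column name
#'   or `NA`).
#' @export
prune_correlated <- function(x, r2_threshold = 0.7, alpha = 0.05,
                             keep = character(0), report_only = FALSE) {
  .assert_character_matrix(x)
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]", call. = FALSE)
  }
  d <- ncol(x$values)
  if (d < 2L) stop("pruning needs at least 2 characters", call. = FALSE)
  nms <- x$character_names
  rows <- list()
  dropped <- character(0)
  for (i in seq_len(d - 1L)) {
    for (j in seq(i + 1L, d)) {
      ct <- stats::cor.test(x$values[, i], x$values[, j], method = "pearson")
      r2 <- unname(ct$estimate)^2
      if (r2 >= r2_threshold && ct$p.value < alpha) {
        a <- nms[i]; b <- nms[j]
        if (report_only) {
          action <- "none"; drop <- NA_character_
        } else if (a %in% dropped || b %in% dropped) {
          action <- "already_dropped"; drop <- NA_character_
        } else if (b %in% keep && !a %in% keep) {
          action <- "dropped_a"; drop <- a
        } else {
          action <- "dropped_b"; drop <- b
        }
        if (!is.na(drop)) dropped <- c(dropped, drop)
        rows[[length(rows) + 1L]] <- data.frame(
          character_a = a, character_b = b, r_squared = r2,
          p_value = ct$p.value, action = action, dropped = drop,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else data.frame(
    character_a = character(0), character_b = character(0),
    r_squared = numeric(0), p_value = numeric(0), action = character(0),
    dropped = character(0), stringsAsFactors = FALSE)
  out <- x
  if (length(dropped)) {
    vals <- x$values[, !nms %in% dropped, drop = FALSE]
    out <- character_matrix(vals, individual_ids = x$individual_ids,
                            ground_truth = x$ground_truth)
  }
  list(matrix = out, report = report)
}

#' Standardize characters to zero mean and unit spread
#'
#' Centers every character by its mean and scales by its standard deviation
#' so all characters enter the similarity kernel on the same footing.
#' Sample SD (divisor N-1) is the default, the convention for measured
#' specimens; `divisor = "n"` switches to the population form.
#'
#' @param x A [character_matrix]; every character must vary.
#' @param divisor `"n-1"` (default) or `"n"`.
#' @return A standardized [character_matrix]. Idempotent to numerical
#'   tolerance.
#' @export
#' @examples
#' m <- character_matrix(cbind(a = c(2, 4, 6), b = c(1, 0, 2)))
#' standardize(m)$values
standardize <- function(x, divisor = c("n-1", "n")) {
  .assert_character_matrix(x)
  divisor <- match.arg(divisor)
  vals <- x$values
  n <- nrow(vals)
  mu <- colMeans(vals)
  s <- apply(vals, 2L, stats::sd)
  if (divisor == "n") s <- s * sqrt((n - 1) / n)
  if (any(s == 0)) {
    stop("constant character '", x$character_names[which(s == 0)[1L]],
         "' cannot be standardized", call. = FALSE)
  }
  vals <- sweep(sweep(vals, 2L, mu, "-"), 2L, s, "/")
  character_matrix(vals, individual_ids = x$individual_ids,
                   ground_truth = x$ground_truth)
}
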