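# Catalog of standard Taguchi orthogonal arrays, stored as literal
# level-index matrices (1-based levels, 1-based columns throughout).

.oa_new <- function(id, levels_per_col, matrix) {
  storage.mode(matrix) <- "integer"
  structure(
    list(
      id = id,
      runs = nrow(matrix),
      columns = ncol(matrix),
      levels_per_col = as.integer(levels_per_col),
      matrix = matrix
    ),
    class = "tsto_oa"
  )
}

.oa_catalog <- local({
  l4 <- matrix(c(
    1, 1, 1,
    1, 2, 2,
    2, 1, 2,
    2, 2, 1
  ), ncol = 3, byrow = TRUE)

  l8 <- matrix(c(
    1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 2, 2, 2, 2,
    1, 2, 2, 1, 1, 2, 2,
    1, 2, 2, 2, 2, 1, 1,
    2, 1, 2, 1, 2, 1, 2,
    2, 1, 2, 2, 1, 2, 1,
    2, 2, 1, 1, 2, 2, 1,
    2, 2, 1, 2, 1, 1, 2
  ), ncol = 7, byrow = TRUE)

  l9 <- matrix(c(
    1, 1, 1, 1,
    1, 2, 2, 2,
    1, 3, 3, 3,
    2, 1, 2, 3,
    2, 2, 3, 1,
    2, 3, 1, 2,
    3, 1, 3, 2,
    3, 2, 1, 3,
    3, 3, 2, 1
  ), ncol = 4, byrow = TRUE)

  l12 <- matrix(c(
    1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2,
    1, 1, 2, 2, 2, 1, 1, 1, 2, 2, 2,
    1, 2, 1, 2, 2, 1, 2, 2, 1, 1, 2,
    1, 2, 2, 1, 2, 2, 1, 2, 1, 2, 1,
    1, 2, 2, 2, 1, 2, 2, 1, 2, 1, 1,
    2, 1, 2, 2, 1, 1, 2, 2, 1, 2, 1,
    2, 1, 2, 1, 2, 2, 2, 1, 1, 1, 2,
    2, 1, 1, 2, 2, 2, 1, 2, 2, 1, 1,
    2, 2, 2, 1, 1, 1, 1, 2, 2, 1, 2,
    2, 2, 1, 2, 1, 2, 1, 1, 1, 2, 2,
    2, 2, 1, 1, 2, 1, 2, 1, 2, 2, 1
  ), ncol = 11, byrow = TRUE)

  # The canonical L18 variant: columns 2-7 carry the mixed 2^1 x 3^7 plan
  # used throughout the worked example (verified by fixture tests).
  l18 <- matrix(c(
    1, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 2, 2, 2, 2, 2, 2,
    1, 1, 3, 3, 3, 3, 3, 3,
    1, 2, 1, 1, 2, 2, 3, 3,
    1, 2, 2, 2, 3, 3, 1, 1,
    1, 2, 3, 3, 1, 1, 2, 2,
    1, 3, 1, 2, 1, 3, 2, 3,
    1, 3, 2, 3, 2, 1, 3, 1,
    1, 3, 3, 1, 3, 2, 1, 2,
    2, 1, 1, 3, 3, 2, 2, 1,
    2, 1, 2, 1, 1, 3, 3, 2,
    2, 1, 3, 2, 2, 1, 1, 3,
    2, 2, 1, 2, 3, 1, 3, 2,
    2, 2, 2, 3, 1, 2, 1, 3,
    2, 2, 3, 1, 2, 3, 2, 1,
    2, 3, 1, 3, 2, 3, 1, 2,
    2, 3, 2, 1, 3, 1, 2, 3,
    2, 3, 3, 2, 1, 2, 3, 1
  ), ncol = 8, byrow = TRUE)

  list(
    "L4_2^3"      = .oa_new("L4_2^3", rep(2L, 3), l4),
    "L8_2^7"      = .oa_new("L8_2^7", rep(2L, 7), l8),
    "L9_3^4"      = .oa_new("L9_3^4", rep(3L, 4), l9),
    "L12_2^11"    = .oa_new("L12_2^11", rep(2L, 11), l12),
    "L18_2^1x3^7" = .oa_new("L18_2^1x3^7", c(2L, rep(3L, 7)), l18)
  )
})

.oa_normalize_id <- function(identifier) {
  key <- gsub("[ ()]", "", identifier)
  key <- gsub("_3_4$", "_3^4", key)  # accept L9_3_4 style
  key <- gsub("_2_3$", "_2^3", key)
  key <- gsub("_2_7$", "_2^7", key)
  key <- gsub("_2_11$", "_2^11", key)
  hits <- which(toupper(names(.oa_catalog)) == toupper(key))
  if (length(hits) == 1L) return(names(.oa_catalog)[hits])
  # bare "L9", "L18", ... prefixes are unambiguous in this catalog
  pref <- vapply(strsplit(names(.oa_catalog), "_"), `[`, "", 1L)
  hits <- which(toupper(pref) == toupper(key))
  if (length(hits) == 1L) return(names(.oa_catalog)[hits])
  NA_character_
}

#' Retrieve a standard orthogonal array from the catalog
#'
#' The catalog holds the classical Taguchi main-effect arrays L4(2^3),
#' L8(2^7), L9(3^4), L12(2^11) and the mixed-level L18(2^1 x 3^7) as
#' literal level-index matrices. Identifiers are matched loosely:
#' `"L9"`, `"L9_3^4"`, `"L9_3_4"` and `"L9(3^4)"` all name the same array.
#'
#' @param identifier Array identifier, e.g. `"L9_3^4"` or `"L18_2^1x3^7"`.
#' @return A `tsto_oa` object: list with `id`, `runs`, `columns`,
#'   `levels_per_col` (levels of each column) and `matrix` (runs x columns
#'   matrix of 1-based level indices).
#' @examples
#' l9 <- oa_get("L9_3^4")
#' l9$matrix[1, ]  # first run sits at level 1 of every column
#' @seealso [oa_verify()], [oa_list()], [make_plan()]
#' @export
oa_get <- function(identifier) {
  stopifnot(is.character(identifier), length(identifier) == 1L)
  key <- .oa_normalize_id(identifier)
  if (is.na(key)) {
    stop("Unknown orthogonal array '", identifier, "'. Available: ",
         paste(names(.oa_catalog), collapse = ", "), call. = FALSE)
  }
  .oa_catalog[[key]]
}

#' List the identifiers of all cataloged orthogonal arrays
#'
#' @return Character vector of catalog identifiers.
#' @export
oa_list <- function() names(.oa_catalog)

#' Verify single-column and pairwise balance of an orthogonal array
#'
#' An array is balanced when each level index appears equally often within
#' every column, and orthogonal when, for every pair of columns, each
#' ordered pair of level indices appears equally often. Both properties are
#' checked exhaustively; the report enumerates any violating column or
#' column pair.
#'
#' @param array A `tsto_oa` object (or any list with `matrix` and
#'   `levels_per_col` fields).
#' @return A `tsto_oa_report` list with elements `pass` (logical),
#'   `column_counts` (per-column level tallies), `pair_counts` (per-pair
#'   tally tables), `bad_columns` and `bad_pairs`.
#' @examples
#' oa_verify(oa_get("L9"))$pass
#' @export
oa_verify <- function(array) {
  m <- array$matrix
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  b <- array$levels_per_col
  nc <- ncol(m)
  col_counts <- lapply(seq_len(nc), function(j) tabulate(m[, j], nbins = b[j]))
  names(col_counts) <- paste0("col", seq_len(nc))
  bad_cols <- which(vapply(seq_len(nc), function(j) {
    cnt <- col_counts[[j]]
    any(cnt != nrow(m) / b[j])
  }, logical(1)))

  pair_counts <- list()
  bad_pairs <- list()
  if (nc >= 2L) {
    for (i in seq_len(nc - 1L)) {
      for (j in seq.int(i + 1L, nc)) {
        tab <- table(factor(m[, i], levels = seq_len(b[i])),
                     factor(m[, j], levels = seq_len(b[j])))
        key <- paste0("col", i, ":col", j)
        pair_counts[[key]] <- tab
        if (length(unique(as.vector(tab))) != 1L) {
          bad_pairs[[length(bad_pairs) + 1L]] <- c(i, j)
        }
      }
    }
  }
  structure(
    list(
      pass = length(bad_cols) == 0L && length(bad_pairs) == 0L,
      column_counts = col_counts,
      pair_counts = pair_counts,
      bad_columns = as.integer(bad_cols),
      bad_pairs = bad_pairs
    ),
    class = "tsto_oa_report"
  )
}

#' @export
print.tsto_oa <- function(x, ...) {
  cat(sprintf("Orthogonal array %s: %d runs x %d columns (levels: %s)\n",
              x$id, x$runs, x$columns,
              paste(x$levels_per_col, collapse = "/")))
  mat <- x$matrix
  dimnames(mat) <- list(paste0("run", seq_len(x$runs)),
                        paste0("c", seq_len(x$columns)))
  print(mat)
  invisible(x)
}

#' @export
print.tsto_oa_report <- function(x, ...) {
  cat("Orthogonality check:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$bad_columns)) {
    cat("  unbalanced columns:", paste(x$bad_columns, collapse = ", "), "\n")
  }
  if (length(x$bad_pairs)) {
    for (p in x$bad_pairs) {
      cat(sprintf("  unbalanced pair: col%d vs col%d\n", p[1], p[2]))
    }
  }
  invisible(x)
}
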