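#' Labelled per-cell mRNA count dataset
#'
#' A thin data.frame subclass holding one row per cell with columns
#' `cell_id`, `condition` and `count`, plus a `provenance` attribute
#' describing how the data were generated (free text, seed, parameters).
#'
#' @param cell_id Character vector of cell identifiers (unique within a
#'   condition).
#' @param condition Character vector of condition labels.
#' @param count Non-negative integer mRNA copy numbers.
#' @param provenance Optional list describing the data source; a `seed`
#'   element is conventional for simulated data.
#' @return A `count_dataset` (also a `data.frame`).
#' @export
count_dataset <- function(cell_id, condition, count, provenance = list()) {
  cell_id <- as.character(cell_id)
  condition <- as.character(condition)
  if (length(count) > 0) {
    if (any(!is.finite(count)) || any(count < 0) || any(count != floor(count)))
      stop("'count' must contain non-negative integers", call. = FALSE)
  }
  df <- data.frame(cell_id = cell_id, condition = condition,
                   count = as.integer(count), stringsAsFactors = FALSE)
  by_cond <- split(df$cell_id, df$condition)
  if (any(vapply(by_cond, anyDuplicated, 0L) > 0L))
    stop("cell_id values must be unique within each condition", call. = FALSE)
  structure(df, provenance = provenance,
            class = c("count_dataset", "data.frame"))
}

#' @export
print.count_dataset <- function(x, ...) {
  tab <- table(x$condition)
  cat("Count dataset:", nrow(x), "cells,", length(tab), "condition(s)\n")
  for (cond in names(tab)) {
    cc <- x$count[x$condition == cond]
    cat(sprintf("  %-20s n=%d  mean=%.3g  max=%d\n",
                cond, length(cc), mean(cc), max(cc)))
  }
  invisible(x)
}

#' @rdname count_dataset
#' @param x Object to test.
#' @export
is_count_dataset <- function(x) inherits(x, "count_dataset")

#' Dataset provenance
#' @param data A [count_dataset()].
#' @return The provenance list.
#' @export
provenance <- function(data) attr(data, "provenance")

# keep class/attributes through row subsetting
#' @export
`[.count_dataset` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("cell_id", "condition", "count") %in% names(out))) {
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("count_dataset", "data.frame")
  }
  out
}
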