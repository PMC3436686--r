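`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonicalize gene pairs
#'
#' Orders each pair lexicographically so that `gene_a <= gene_b`. Edge
#' identity throughout the package is the unordered canonical pair; direction
#' is carried as an annotation relative to this order.
#'
#' @param gene_a,gene_b character vectors of endpoint identifiers.
#' @return A list with components `gene_a`, `gene_b` (reordered) and
#'   `swapped`, a logical vector marking pairs whose input order was flipped.
#' @export
canonicalize_pairs <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  swapped <- gene_a > gene_b
  list(
    gene_a = ifelse(swapped, gene_b, gene_a),
    gene_b = ifelse(swapped, gene_a, gene_b),
    swapped = swapped
  )
}

pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\r")

flip_direction <- function(direction, flip) {
  out <- direction
  out[flip & direction == "forward"] <- "reverse"
  out[flip & direction == "reverse"] <- "forward"
  out
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_format(...)
}

# Even integer window schedule from `from` to `to` with at most `n` points,
# always including both ends.
decimate_windows <- function(from, to, n = NULL) {
  full <- seq.int(from, to)
  if (is.null(n) || n >= length(full)) return(full)
  unique(round(seq(from, to, length.out = max(2L, n))))
}
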