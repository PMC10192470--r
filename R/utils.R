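# round half away from zero at `digits` decimals (printed-arithmetic rule;
# base round() is banker's)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Nearest-vertex lookup
#'
#' For each query point, the index of the nearest source vertex (Euclidean),
#' ties broken by lowest source index. Chunked cross-product search.
#'
#' @param source numeric `N x 3` matrix of source points.
#' @param query numeric `M x 3` matrix of query points.
#' @param chunk rows of `query` processed per block.
#' @return integer vector of length `M` of 1-based source indices.
#' @export
nearest_vertex <- function(source, query, chunk = 4096L) {
  source <- as.matrix(source)
  query <- as.matrix(query)
  s2 <- rowSums(source^2)
  out <- integer(nrow(query))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    # squared distance = |q|^2 - 2 q.s + |s|^2; |q|^2 constant per row
    d2 <- matrix(s2, nrow(q), length(s2), byrow = TRUE) - 2 * q %*% t(source)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

# deterministic child seed below 2^31 from a base seed and small indices
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.numeric(p)) %% 2147483629
  as.integer(s)
}

# run expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Dice overlap coefficient between two vertex sets
#'
#' @param a,b logical masks or integer index vectors over the same mesh.
#' @param n total vertex count (needed when passing index vectors).
#' @return `2|A∩B| / (|A|+|B|)`, or `NA` if both sets are empty.
#' @export
dice_coefficient <- function(a, b, n = NULL) {
  if (!is.logical(a)) { stopifnot(!is.null(n)); a <- seq_len(n) %in% a }
  if (!is.logical(b)) { stopifnot(!is.null(n)); b <- seq_len(n) %in% b }
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
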