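#' Derive a reproducible child seed from a master seed and a key
#'
#' Child seeds for per-ROI simulation, per-repeat splitting, and stability
#' runs are derived by hashing the master seed together with a string key
#' (for example `patient/slide/roi` or a repeat index), so that any subset
#' of the work can be regenerated without replaying the whole stream.
#'
#' The hash is a 31-bit multiplicative string hash computed in double
#' precision (exact below 2^53), so derived seeds are identical across
#' platforms and always lie in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... further atomic components identifying the unit of work; they
#'   are pasted into the hashed key.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(7, "P001", "S1", "R2")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- 2166136261 %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample from an integer range given as c(lo, hi) (inclusive).
#' @noRd
sample_range <- function(range, n = 1) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' @noRd
assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Disease classes and phenotype names, in canonical order
#'
#' The three disease stages and the three data-driven cell phenotypes used
#' throughout the package. Order is fixed (CLL < aCLL < RT and
#' CLL-like < aCLL-like < RT-like) so that factor levels, probability
#' columns, and tie-breaks are deterministic.
#'
#' @return a character vector.
#' @export
disease_classes <- function() c("CLL", "aCLL", "RT")

#' @rdname disease_classes
#' @export
phenotype_names <- function() c("CLL-like", "aCLL-like", "RT-like")

# Nearest-neighbour distances from each row of `src` to rows of `tgt`
# (2-D points, um). If same_set, rows of src and tgt are the same point
# set in the same order and the self-distance is excluded.
#' @noRd
nn_min_dist <- function(src, tgt, same_set = FALSE) {
  if (nrow(src) == 0L) return(numeric(0))
  .nn_min_dist_cpp(src, tgt, same_set)
}

# Indices of the k nearest neighbours (excluding self) for each row of x,
# nearest first.
#' @noRd
knn_indices <- function(x, k) {
  .knn_brute(x, as.integer(k))
}

#' One-dimensional Wasserstein (earth mover's) distance
#'
#' The first Wasserstein distance between the empirical distributions of
#' two numeric samples, computed as the integral of the absolute difference
#' of the two empirical CDFs. For samples of equal size this reduces to the
#' mean absolute difference of the order statistics, and for a pure
#' translation it equals the shift.
#'
#' @param a,b numeric vectors (non-empty).
#' @return a non-negative scalar.
#' @export
#' @examples
#' wasserstein1d(c(1, 2, 3), c(1, 2, 3) + 8)  # 8
wasserstein1d <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  all_v <- sort(c(a, b))
  if (length(all_v) == 1L) return(0)
  deltas <- diff(all_v)
  pos <- all_v[-length(all_v)]
  fa <- ecdf(a)(pos)
  fb <- ecdf(b)(pos)
  sum(abs(fa - fb) * deltas)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b vectors of equal length with cluster/phenotype labels.
#' @return a scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
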