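# Core representation: a k-input Boolean function is an integer bitmask of
# length 2^k held in a double (exact up to 2^53, which covers k <= 5 and far
# beyond).  Bit i of the mask is the output on truth-table row i.
#
# Row convention (fixed across the whole package): row index i encodes the
# input assignment with x_1 as the MOST significant bit, so bit j of i
# (j = 0 least significant) carries the value of x_{k-j}.  Row 0 is the
# all-zero assignment and the text serialization lists row 0 first.

the <- new.env(parent = emptyenv())

.pow2 <- function(n) 2^(0:(n - 1))

# n x nbits 0/1 matrix of the binary expansions of v (column j = bit j-1)
.bits_matrix <- function(v, nbits) {
  out <- matrix(0, length(v), nbits)
  for (j in seq_len(nbits)) out[, j] <- (v %/% 2^(j - 1)) %% 2
  out
}

.pack_bits <- function(B) as.vector(B %*% .pow2(ncol(B)))

# 2^k x k matrix: entry [i+1, v] is the value of x_v on row i
.row_assignments <- function(k) {
  rows <- 0:(2^k - 1)
  vapply(1:k, function(v) (rows %/% 2^(k - v)) %% 2, numeric(2^k))
}

# all permutations of 1:k as a list
.perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .perms(k - 1L)) {
    for (i in 0:(k - 1L)) out[[length(out) + 1L]] <- append(p, k, after = i)
  }
  out
}

# Row remap for an input permutation: result bit i is taken from source bit
# remap[i + 1].  perm maps source variable position j to target position
# perm[j], i.e. the permuted function g satisfies
# g(y_1, ..., y_k) = f(y_{perm[1]}, ..., y_{perm[k]}).
.remap_perm <- function(perm) {
  k <- length(perm)
  rows <- 0:(2^k - 1)
  s <- numeric(2^k)
  for (j in 1:k) s <- s + ((rows %/% 2^(k - perm[j])) %% 2) * 2^(k - j)
  s
}

# Row remap for negating input i: flip bit (k - i) of the row index
.remap_negate <- function(k, i) {
  rows <- 0:(2^k - 1)
  bit <- (rows %/% 2^(k - i)) %% 2
  rows + (1 - 2 * bit) * 2^(k - i)
}

.apply_remap <- function(bits, k, remap) {
  B <- .bits_matrix(bits, 2^k)
  .pack_bits(B[, remap + 1, drop = FALSE])
}

#' Construct a vector of Boolean functions
#'
#' A `bf` object is a numeric vector of truth-table bitmasks sharing one input
#' count `k`.  Bit `i` of a mask (counting from 0 at the least significant
#' end) is the output of the function on truth-table row `i`; `x_1` is the
#' most significant bit of the row index, so row 0 is the all-zero input.
#'
#' @param bits numeric vector of bitmasks, each in `[0, 2^(2^k))`.
#' @param k number of inputs (positive integer).
#' @return A `bf` object: numeric vector with attribute `k`.
#' @examples
#' bf(6, 2)            # two-input XOR
#' bf(c(8, 14), 2)     # AND and OR
#' @export
bf <- function(bits, k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  bits <- as.numeric(bits)
  if (anyNA(bits) || any(bits < 0) || any(bits != floor(bits))) {
    stop("`bits` must be non-negative integers", call. = FALSE)
  }
  if (k <= 5 && any(bits >= 2^(2^k))) {
    bad <- which(bits >= 2^(2^k))[1]
    stop(sprintf("bitmask at position %d exceeds 2^(2^%d) - 1", bad, k),
         call. = FALSE)
  }
  structure(bits, k = k, class = "bf")
}

.new_bf <- function(bits, k) structure(as.numeric(bits), k = as.integer(k), class = "bf")

#' @export
`[.bf` <- function(x, i) .new_bf(unclass(x)[i], attr(x, "k"))

#' @export
print.bf <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("<bf> %d function(s) of %d input(s)\n", length(x), k))
  n <- min(length(x), 10L)
  if (n > 0) {
    cat(paste0("  ", format(unclass(x)[seq_len(n)], scientific = FALSE),
               "  [", bf_to_string(x[seq_len(n)]), "]"), sep = "\n")
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Number of inputs of a `bf` vector
#' @param f a `bf` object.
#' @return Integer input count `k`.
#' @export
bf_k <- function(f) {
  k <- attr(f, "k")
  if (is.null(k)) stop("not a `bf` object; construct one with bf()", call. = FALSE)
  as.integer(k)
}

.assert_bf <- function(f) {
  if (!inherits(f, "bf")) stop("expected a `bf` object", call. = FALSE)
  invisible(f)
}

#' Build Boolean functions from explicit output vectors
#'
#' The inverse of [bf_outputs()]: takes 0/1 output columns listed row 0
#' first (all-zero input assignment first) and packs them into bitmasks.
#'
#' @param outputs a vector of `2^k` binary values for a single function, or
#'   an `n x 2^k` matrix with one function per row.
#' @param k number of inputs.
#' @return A `bf` vector.
#' @examples
#' bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3)  # x1 OR (x2 AND x3)
#' @export
bf_from_outputs <- function(outputs, k) {
  k <- as.integer(k)
  if (is.matrix(outputs)) {
    if (ncol(outputs) != 2^k) {
      stop(sprintf("output matrix must have 2^%d = %d columns, got %d",
                   k, 2^k, ncol(outputs)), call. = FALSE)
    }
    m <- outputs
  } else {
    if (length(outputs) != 2^k) {
      stop(sprintf("output vector must have length 2^%d = %d, got %d",
                   k, 2^k, length(outputs)), call. = FALSE)
    }
    m <- matrix(outputs, nrow = 1)
  }
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("non-binary output entry at index %d", bad[1]), call. = FALSE)
  }
  .new_bf(.pack_bits(m), k)
}

#' Output vectors of Boolean functions
#'
#' @param f a `bf` vector.
#' @return An `n x 2^k` 0/1 matrix, one function per row, row-0 output in
#'   column 1.
#' @export
bf_outputs <- function(f) {
  .assert_bf(f)
  .bits_matrix(unclass(f), 2^bf_k(f))
}

#' Serialize Boolean functions to output bitstrings
#'
#' The text form used in catalog files: `2^k` characters `'0'`/`'1'`, row 0
#' first.
#'
#' @param f a `bf` vector.
#' @return Character vector of bitstrings.
#' @export
bf_to_string <- function(f) {
  B <- bf_outputs(f)
  apply(B, 1, paste0, collapse = "")
}

#' Parse output bitstrings into Boolean functions
#'
#' @param s character vector of `2^k`-character strings of `'0'`/`'1'`.
#' @param k number of inputs.
#' @return A `bf` vector.
#' @export
bf_from_string <- function(s, k) {
  k <- as.integer(k)
  bad <- which(nchar(s) != 2^k)
  if (length(bad)) {
    stop(sprintf("bitstring at position %d has length %d, expected 2^%d = %d",
                 bad[1], nchar(s[bad[1]]), k, 2^k), call. = FALSE)
  }
  bad <- grep("[^01]", s)
  if (length(bad)) {
    stop(sprintf("non-binary character in bitstring at position %d", bad[1]),
         call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(strsplit(s, ""), use.names = FALSE)),
              ncol = 2^k, byrow = TRUE)
  bf_from_outputs(m, k)
}

#' Bias and parity of Boolean functions
#'
#' The bias of a function is the number of ones in its output vector; the
#' parity is odd or even accordingly.
#'
#' @param f a `bf` vector.
#' @return `bf_bias`: integer vector of one-counts in `[0, 2^k]`.
#'   `bf_parity`: character vector `"odd"`/`"even"`.
#' @examples
#' bf_bias(bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3))  # 5
#' @export
bf_bias <- function(f) as.integer(rowSums(bf_outputs(f)))

#' @rdname bf_bias
#' @export
bf_parity <- function(f) ifelse(bf_bias(f) %% 2 == 1, "odd", "even")

#' Complement of Boolean functions
#'
#' Inverts every element of the output vector; an involution, and
#' `bf_bias(bf_complement(f)) == 2^k - bf_bias(f)`.
#'
#' @param f a `bf` vector.
#' @return A `bf` vector of the complemented functions.
#' @export
bf_complement <- function(f) {
  .assert_bf(f)
  k <- bf_k(f)
  .new_bf((2^(2^k) - 1) - unclass(f), k)
}

#' Permute the inputs of Boolean functions
#'
#' `perm` sends source variable position `j` to target position `perm[j]`:
#' the result `g` satisfies `g(y_1, ..., y_k) = f(y_{perm[1]}, ..., y_{perm[k]})`.
#' Applying `q` after `p` equals applying the composite `q[p]` once.
#'
#' @param f a `bf` vector.
#' @param perm integer permutation of `1:k`.
#' @return A `bf` vector.
#' @examples
#' h <- bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3)  # x1 + x2.x3
#' bf_permute(h, c(2, 1, 3))                           # x2 + x1.x3
#' @export
bf_permute <- function(f, perm) {
  .assert_bf(f)
  k <- bf_k(f)
  perm <- as.integer(perm)
  if (length(perm) != k || !setequal(perm, 1:k)) {
    stop(sprintf("`perm` must be a permutation of 1:%d", k), call. = FALSE)
  }
  .new_bf(.apply_remap(unclass(f), k, .remap_perm(perm)), k)
}

#' Negate one input of Boolean functions
#'
#' The result on any row equals `f` on the row with variable `i` flipped; an
#' involution.
#'
#' @param f a `bf` vector.
#' @param i variable index in `1:k`.
#' @return A `bf` vector.
#' @export
bf_negate_input <- function(f, i) {
  .assert_bf(f)
  k <- bf_k(f)
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > k) {
    stop(sprintf("variable index must be in 1..%d", k), call. = FALSE)
  }
  .new_bf(.apply_remap(unclass(f), k, .remap_negate(k, i)), k)
}

#' All isomorphisms of a Boolean function
#'
#' The distinct functions reachable from `f` by permuting the inputs and
#' negating any subset of them.  The set always contains `f` and its size
#' divides `2^k * k!`.
#'
#' @param f a single-function `bf` object.
#' @return A sorted `bf` vector of the distinct isomorphic functions.
#' @examples
#' length(bf_isomorphisms(bf(14, 2)))  # a OR b has 4 isomorphisms
#' @export
bf_isomorphisms <- function(f) {
  .assert_bf(f)
  if (length(f) != 1L) stop("`f` must be a single function", call. = FALSE)
  k <- bf_k(f)
  R <- 2^k
  rows <- 0:(R - 1)
  out <- numeric(0)
  for (p in .perms(k)) {
    base <- .remap_perm(p)
    for (ng in 0:(2^k - 1)) {
      nb <- (ng %/% 2^(0:(k - 1))) %% 2
      s <- base
      for (v in 1:k) {
        if (nb[v] == 1) {
          bitv <- (s %/% 2^(k - v)) %% 2
          s <- s + (1 - 2 * bitv) * 2^(k - v)
        }
      }
      out <- c(out, .apply_remap(unclass(f), k, s))
    }
  }
  .new_bf(sort(unique(out)), k)
}

# logical n x k matrix: does the function depend on variable v?
.essential_matrix <- function(bits, k) {
  B <- .bits_matrix(bits, 2^k)
  rows <- 0:(2^k - 1)
  out <- matrix(FALSE, length(bits), k)
  for (v in 1:k) {
    lo <- which(((rows %/% 2^(k - v)) %% 2) == 0)
    hi <- lo + 2^(k - v)
    out[, v] <- rowSums(abs(B[, lo, drop = FALSE] - B[, hi, drop = FALSE])) > 0
  }
  out
}

#' Essential variables of a Boolean function
#'
#' Variable `i` is essential when some pair of rows differing only in `i`
#' gives different outputs.
#'
#' @param f a single-function `bf` object.
#' @return Integer vector of essential variable indices (empty for
#'   constants).
#' @export
essential_variables <- function(f) {
  .assert_bf(f)
  if (length(f) != 1L) stop("`f` must be a single function", call. = FALSE)
  which(.essential_matrix(unclass(f), bf_k(f))[1, ])
}

#' All Boolean functions of k inputs
#'
#' The full space of `2^(2^k)` functions, materialized.  Limited to `k <= 4`
#' (65,536 functions); the 5-input space of `2^32` functions is not
#' materializable.
#'
#' @param k number of inputs, at most 4.
#' @return A `bf` vector of all functions, in bitmask order.
#' @export
all_bfs <- function(k) {
  k <- as.integer(k)
  if (k < 1L || k > 4L) {
    stop("the full function space can only be materialized for k <= 4",
         call. = FALSE)
  }
  .new_bf(0:(2^(2^k) - 1), k)
}
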