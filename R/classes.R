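# Biologically meaningful classes of Boolean update rules.
#
# Membership tests are definition-driven checkers; enumerators construct each
# class structurally (nested-canalyzing cascade, read-once formula recursion,
# monotone-function recursion plus input negations for unate, half-space
# union for canalyzing), so checkers and enumerators are independent routes
# that the test suite compares.

.class_labels <- c("UF", "CF", "NCF", "RoF")

.check_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || !label %in% .class_labels) {
    stop("`label` must be one of \"UF\", \"CF\", \"NCF\", \"RoF\"", call. = FALSE)
  }
  label
}

#' Is a Boolean function unate?
#'
#' A function is unate when it is monotone non-decreasing or monotone
#' non-increasing in every variable separately.  Constants and functions
#' with inessential inputs satisfy the condition vacuously and are counted
#' as unate.
#'
#' @param f a `bf` vector.
#' @return Logical vector.
#' @examples
#' is_unate(bf(6, 2))   # XOR: FALSE
#' is_unate(bf(8, 2))   # AND: TRUE
#' @export
is_unate <- function(f) {
  .assert_bf(f)
  k <- bf_k(f)
  B <- .bits_matrix(unclass(f), 2^k)
  rows <- 0:(2^k - 1)
  ok <- rep(TRUE, length(f))
  for (v in 1:k) {
    lo <- which(((rows %/% 2^(k - v)) %% 2) == 0)
    hi <- lo + 2^(k - v)
    d <- B[, hi, drop = FALSE] - B[, lo, drop = FALSE]
    inc <- rowSums(d < 0) == 0
    dec <- rowSums(d > 0) == 0
    ok <- ok & (inc | dec)
  }
  ok
}

#' Is a Boolean function canalyzing?
#'
#' A function is canalyzing when some input, fixed to some value, fixes the
#' output regardless of the remaining inputs.  Constants are canalyzing
#' (every input canalyzes vacuously).
#'
#' @param f a `bf` vector.
#' @return Logical vector.
#' @examples
#' is_canalyzing(bf(8, 2))  # AND: TRUE (x_i = 0 forces 0)
#' is_canalyzing(bf(6, 2))  # XOR: FALSE
#' @export
is_canalyzing <- function(f) {
  .assert_bf(f)
  k <- bf_k(f)
  B <- .bits_matrix(unclass(f), 2^k)
  rows <- 0:(2^k - 1)
  half <- 2^(k - 1)
  ok <- rep(FALSE, length(f))
  for (v in 1:k) {
    for (a in 0:1) {
      idx <- which(((rows %/% 2^(k - v)) %% 2) == a)
      s <- rowSums(B[, idx, drop = FALSE])
      ok <- ok | s == 0 | s == half
    }
  }
  ok
}

# restriction of an output vector to the half-space x_v = a; the remaining
# variables keep their order and relative significance
.restrict_out <- function(out, k, v, a) {
  rows <- 0:(2^k - 1)
  out[((rows %/% 2^(k - v)) %% 2) == a]
}

# recursive nested-canalyzing check on a raw output vector:
# f is NCF(k) iff some half-space x_i = a is constant and the complementary
# restriction is NCF(k-1); base case k = 1 is {x, not x}
.is_ncf_out <- function(out) {
  n <- length(out)
  if (n == 2) return(out[1] != out[2])
  k <- as.integer(log2(n))
  for (v in 1:k) {
    for (a in 0:1) {
      h <- .restrict_out(out, k, v, a)
      if (all(h == h[1])) {
        if (.is_ncf_out(.restrict_out(out, k, v, 1 - a))) return(TRUE)
      }
    }
  }
  FALSE
}

#' Is a Boolean function nested canalyzing?
#'
#' Nested canalyzing functions canalyze recursively: some input fixes the
#' output, and on the non-canalyzing half-space the restricted function is
#' again nested canalyzing, down to a single-variable function `x` or
#' `NOT x`.  All inputs of an NCF are essential and NCFs are never constant.
#'
#' @param f a `bf` vector.
#' @return Logical vector.
#' @examples
#' is_ncf(bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3))  # x1 + x2.x3: TRUE
#' is_ncf(bf(6, 2))                                       # XOR: FALSE
#' @export
is_ncf <- function(f) {
  .assert_bf(f)
  B <- bf_outputs(f)
  vapply(seq_len(nrow(B)), function(i) .is_ncf_out(B[i, ]), logical(1))
}

# ---- read-once machinery ----------------------------------------------------

# project an output vector (on variables `vars`, a subset of the ambient
# row space encoded densely) onto the sub-vector over a subset mask;
# out has length 2^m for m = length(vars)
.project_or <- function(out, m, keep) {
  # OR (max) over the dropped variables; `keep` = indices in 1:m to keep
  drop <- setdiff(1:m, keep)
  cur <- out
  kk <- m
  # drop variables from highest index down so positions stay valid
  for (v in sort(drop, decreasing = TRUE)) {
    cur <- pmax(.restrict_out(cur, kk, v, 0), .restrict_out(cur, kk, v, 1))
    kk <- kk - 1L
  }
  cur
}

.expand_to <- function(sub, m, keep) {
  # inverse of restriction: lift a function of the `keep` variables back to
  # the m-variable row space
  rows <- 0:(2^m - 1)
  idx <- numeric(2^m)
  for (j in seq_along(keep)) {
    idx <- idx + ((rows %/% 2^(m - keep[j])) %% 2) * 2^(length(keep) - j)
  }
  sub[idx + 1]
}

.is_rof_out <- function(out) {
  m <- as.integer(log2(length(out)))
  # every variable must be essential
  for (v in 1:m) {
    if (all(.restrict_out(out, m, v, 0) == .restrict_out(out, m, v, 1))) {
      return(FALSE)
    }
  }
  if (m == 1) return(TRUE)  # essential 1-input functions are x and NOT x
  # try f = g AND h, and dually (via De Morgan on the complement) f = g OR h,
  # over every bipartition of the variables with variable 1 fixed in A; if f
  # factorizes, the factors are exactly the OR-projections.  The read-once
  # class is closed under complement, so testing the projection factors
  # directly covers the OR case too.
  for (msk in 0:(2^(m - 1) - 2)) {
    A <- c(1L, 1L + which((msk %/% 2^(0:(m - 2))) %% 2 == 1))
    Bv <- setdiff(1:m, A)
    for (cand in list(out, 1 - out)) {
      g <- .project_or(cand, m, A)
      h <- .project_or(cand, m, Bv)
      if (all(.expand_to(g, m, A) * .expand_to(h, m, Bv) == cand) &&
          .is_rof_out(g) && .is_rof_out(h)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Is a Boolean function read-once?
#'
#' A read-once function is expressible with AND, OR and NOT such that every
#' variable appears exactly once (negations allowed, arbitrary
#' parenthesization).  All inputs of a read-once function are essential.
#' The check recursively factorizes the function across bipartitions of its
#' variables as an AND or OR of independent sub-functions.
#'
#' @param f a `bf` vector.
#' @return Logical vector.
#' @examples
#' is_rof(bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3))  # x1 + x2.x3: TRUE
#' is_rof(bf(6, 2))                                       # XOR: FALSE
#' @export
is_rof <- function(f) {
  .assert_bf(f)
  # every read-once function is unate (each literal appears once with a fixed
  # sign), so the cheap vectorized unateness test prunes the recursion
  cand <- is_unate(f)
  B <- bf_outputs(f)
  out <- logical(length(f))
  out[cand] <- vapply(which(cand), function(i) .is_rof_out(B[i, ]),
                      logical(1))
  out
}

# ---- structural enumerators -------------------------------------------------

# nested-canalyzing construction: iterate every input permutation and every
# choice of canalyzing input values a_1..a_k and canalyzed outputs b_1..b_k;
# the final branch contributes the complement of b_k
.enum_ncf <- function(k) {
  R <- 2^k
  X <- .row_assignments(k)
  p2 <- .pow2(R)
  out <- numeric(0)
  for (sg in .perms(k)) {
    Xs <- X[, sg, drop = FALSE]
    for (a in 0:(2^k - 1)) {
      ab <- (a %/% 2^(0:(k - 1))) %% 2
      E <- Xs == matrix(ab, R, k, byrow = TRUE)
      sel <- apply(E, 1, function(e) {
        w <- which(e)
        if (length(w)) w[1] else k + 1L
      })
      vals <- matrix(0, R, 2^k)
      for (b in 0:(2^k - 1)) {
        bb <- (b %/% 2^(0:(k - 1))) %% 2
        vals[, b + 1] <- c(bb, 1 - bb[k])[sel]
      }
      out <- c(out, as.vector(t(vals) %*% p2))
    }
  }
  sort(unique(out))
}

# read-once construction: recursively combine, over every set partition of
# the variables into at least two blocks, the read-once functions of the
# blocks with AND and with OR; literals carry optional negation.  Functions
# are deduplicated by truth-table bitmask, deliberately ignoring
# formula-level symmetries.
.set_partitions <- function(s) {
  if (length(s) == 1) return(list(list(s)))
  first <- s[1]
  out <- list()
  for (p in .set_partitions(s[-1])) {
    for (j in seq_along(p)) {
      q <- p
      q[[j]] <- c(first, q[[j]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

.enum_rof <- function(k) {
  R <- 2^k
  p2 <- .pow2(R)
  X <- .row_assignments(k)
  memo <- new.env(parent = emptyenv())
  rof <- function(s) {
    key <- paste(s, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (length(s) == 1) {
      res <- rbind(X[, s], 1 - X[, s])
    } else {
      acc <- NULL
      for (p in .set_partitions(s)) {
        if (length(p) < 2) next
        comb_and <- comb_or <- rof(p[[1]])
        for (j in 2:length(p)) {
          Bj <- rof(p[[j]])
          i1 <- rep(seq_len(nrow(comb_and)), times = nrow(Bj))
          i2 <- rep(seq_len(nrow(Bj)), each = nrow(comb_and))
          comb_and <- comb_and[i1, , drop = FALSE] * Bj[i2, , drop = FALSE]
          i1 <- rep(seq_len(nrow(comb_or)), times = nrow(Bj))
          comb_or <- 1 - (1 - comb_or[i1, , drop = FALSE]) *
            (1 - Bj[i2, , drop = FALSE])
        }
        acc <- rbind(acc, comb_and, comb_or)
      }
      acc <- acc[!duplicated(as.vector(acc %*% p2)), , drop = FALSE]
      res <- acc
    }
    memo[[key]] <- res
    res
  }
  sort(unique(as.vector(rof(1:k) %*% p2)))
}

# canalyzing functions as the union, over (input, canalyzing value,
# canalyzed output), of "constant b on the half-space, arbitrary elsewhere"
.enum_cf <- function(k) {
  R <- 2^k
  rows <- 0:(R - 1)
  p2 <- .pow2(R)
  nfree <- 2^(R / 2)
  out <- numeric(0)
  Fb <- .bits_matrix(0:(nfree - 1), R / 2)
  for (v in 1:k) {
    for (a in 0:1) {
      inhalf <- ((rows %/% 2^(k - v)) %% 2) == a
      free <- as.vector(Fb %*% p2[!inhalf])
      for (b in 0:1) out <- c(out, sum(p2[inhalf]) * b + free)
    }
  }
  sort(unique(out))
}

# unate functions: monotone non-decreasing functions built by the pairing
# recursion (f monotone on k variables iff f = (f0, f1) with f0, f1 monotone
# on k-1 variables and f0 <= f1 pointwise), then closed under all input
# negations
.enum_uf <- function(k) {
  mono <- c(0, 1)
  for (j in 1:k) {
    n <- 2^(2^(j - 1))
    f0 <- rep(mono, times = length(mono))
    f1 <- rep(mono, each = length(mono))
    ok <- bitwAnd(as.integer(f0), as.integer(f1)) == as.integer(f0)
    mono <- (f0 + f1 * n)[ok]
  }
  R <- 2^k
  p2 <- .pow2(R)
  B <- .bits_matrix(mono, R)
  out <- numeric(0)
  for (ng in 0:(2^k - 1)) {
    nb <- (ng %/% 2^(0:(k - 1))) %% 2
    s <- 0:(R - 1)
    for (v in 1:k) {
      if (nb[v] == 1) {
        bitv <- (s %/% 2^(k - v)) %% 2
        s <- s + (1 - 2 * bitv) * 2^(k - v)
      }
    }
    out <- c(out, as.vector(B[, s + 1, drop = FALSE] %*% p2))
  }
  sort(unique(out))
}

#' Enumerate a biologically meaningful function class
#'
#' Constructs the complete set of k-input functions of one class:
#' \describe{
#'   \item{`"NCF"`}{every input permutation combined with every choice of
#'     canalyzing input values and canalyzed output values in the nested
#'     cascade, deduplicated by truth table.}
#'   \item{`"RoF"`}{recursive read-once formula construction over all set
#'     partitions of the variables with AND/OR connectives and signed
#'     literals.}
#'   \item{`"CF"`}{union of all half-space-constant function families.}
#'   \item{`"UF"`}{monotone functions from the pairing recursion, closed
#'     under input negations.}
#' }
#' Results are cached per `(label, k)` for the session.
#'
#' @param label one of `"UF"`, `"CF"`, `"NCF"`, `"RoF"`.
#' @param k number of inputs, at most 5.
#' @return A sorted `bf` vector.
#' @examples
#' length(enumerate_class("NCF", 3))  # 64
#' length(enumerate_class("CF", 2))   # 14
#' @export
enumerate_class <- function(label, k) {
  label <- .check_label(label)
  k <- as.integer(k)
  if (k < 1L || k > 5L) {
    stop("class enumeration supports 1 <= k <= 5", call. = FALSE)
  }
  key <- sprintf("class:%s:%d", label, k)
  cached <- the[[key]]
  if (!is.null(cached)) return(cached)
  bits <- switch(label,
    NCF = .enum_ncf(k),
    RoF = .enum_rof(k),
    CF  = .enum_cf(k),
    UF  = .enum_uf(k)
  )
  res <- .new_bf(bits, k)
  the[[key]] <- res
  res
}

#' Clear the in-session enumeration caches
#'
#' Composed sets and class sets are memoized per session; this drops them,
#' mainly to bound memory in long-running processes.
#' @return Invisibly, the number of cached objects removed.
#' @export
bf_cache_clear <- function() {
  keys <- ls(the)
  keys <- keys[startsWith(keys, "class:") | startsWith(keys, "composed:")]
  rm(list = keys, envir = the)
  invisible(length(keys))
}
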