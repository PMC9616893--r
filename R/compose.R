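# Composition structures of bipartite gene-TR-gene subgraphs and exhaustive
# generation of their composed Boolean functions.
#
# A gene regulated by r transcriptional regulators, the i-th driven by t_i
# genes, carries the composition structure {t_1, ..., t_r}; the realizable
# update rules are h = g(p_1(block 1), ..., p_r(block r)) over every choice
# of the inner functions p_i and the outer function g.
#
# Enumeration strategy: a choice of (p_1, ..., p_r) induces a coloring of
# the 2^k truth-table rows by the r-tuple of regulator states (a cell index
# in 0..2^r - 1).  Since g ranges over ALL r-input functions, two colorings
# that differ only by a relabeling of cells yield the same set of composed
# functions, so colorings are canonicalized and deduplicated before the
# outer functions are applied in a single matrix product.  Everything is
# deterministic; results are memoized per (structure, mode) for the session.

#' Create a composition structure
#'
#' @param parts positive integers `t_1, ..., t_r` (any order; stored sorted
#'   non-decreasing since the bipartite subgraph is a depth-2 tree and block
#'   order is arbitrary).
#' @return An object of class `composition_structure` with fields `parts`,
#'   `k` (total inputs) and `r` (number of regulators).
#' @examples
#' composition_structure(c(2, 1))  # stored as {1,2}, k = 3
#' @export
composition_structure <- function(parts) {
  parts <- as.integer(parts)
  if (length(parts) < 1L || anyNA(parts) || any(parts < 1L)) {
    stop("`parts` must be positive integers", call. = FALSE)
  }
  parts <- sort(parts)
  structure(
    list(parts = parts, k = sum(parts), r = length(parts)),
    class = "composition_structure"
  )
}

.as_structure <- function(x) {
  if (inherits(x, "composition_structure")) return(x)
  if (is.numeric(x)) return(composition_structure(x))
  if (is.character(x) && length(x) == 1L) {
    parts <- as.integer(strsplit(gsub("[{} ]", "", x), ",")[[1]])
    return(composition_structure(parts))
  }
  stop("cannot interpret input as a composition structure", call. = FALSE)
}

#' @export
format.composition_structure <- function(x, ...) {
  sprintf("{%s}", paste(x$parts, collapse = ","))
}

#' @export
print.composition_structure <- function(x, ...) {
  cat(sprintf("composition structure %s  (k = %d, r = %d)%s\n",
              format(x), x$k, x$r,
              if (is_trivial_structure(x)) "  [trivial]" else ""))
  invisible(x)
}

#' Is a composition structure trivial?
#'
#' The structures `{k}` (one regulator fed by all genes) and `{1,...,1}`
#' (every regulator a single-gene relay) impose no restriction: every
#' k-input function is realizable.  All other structures are non-trivial.
#'
#' @param cs a `composition_structure` (or parts vector).
#' @return Logical scalar.
#' @export
is_trivial_structure <- function(cs) {
  cs <- .as_structure(cs)
  cs$r == 1L || all(cs$parts == 1L)
}

.partitions <- function(k, max_part = k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(k, max_part))) {
    for (rest in .partitions(k - p, p)) {
      out[[length(out) + 1L]] <- c(rest, p)
    }
  }
  out
}

#' Non-trivial composition structures with k inputs
#'
#' All integer partitions of `k` except `{k}` and `{1,...,1}`.  There are
#' none for `k <= 2`, exactly one (`{1,2}`) for `k = 3`, three for `k = 4`
#' and five for `k = 5`.
#'
#' @param k total number of inputs.
#' @return List of `composition_structure` objects.
#' @export
nontrivial_structures <- function(k) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be positive", call. = FALSE)
  out <- lapply(.partitions(k), composition_structure)
  Filter(function(cs) !is_trivial_structure(cs), out)
}

# ---- enumeration ------------------------------------------------------------

# colorings of the 2^k rows by regulator-state cell, one column per choice
# of the inner functions (p_1, ..., p_r)
.colorings <- function(parts) {
  k <- sum(parts)
  r <- length(parts)
  R <- 2^k
  rows <- 0:(R - 1)
  offs <- cumsum(c(0, parts[-r]))
  Ylist <- vector("list", r)
  for (j in seq_len(r)) {
    tj <- parts[j]
    sub <- (rows %/% 2^(k - offs[j] - tj)) %% 2^tj
    pv <- 0:(2^(2^tj) - 1)
    Ylist[[j]] <- outer(sub, pv, function(s, p) (p %/% 2^s) %% 2)
  }
  np <- vapply(Ylist, ncol, 0L)
  grid <- as.matrix(expand.grid(lapply(np, seq_len)))
  C <- matrix(0, R, nrow(grid))
  for (j in seq_len(r)) C <- C + Ylist[[j]][, grid[, j]] * 2^(r - j)
  C
}

.dedupe_cols <- function(C) {
  sig <- do.call(paste, c(as.data.frame(t(C)), sep = ","))
  C[, !duplicated(sig), drop = FALSE]
}

.canonicalize_cols <- function(C) {
  for (i in seq_len(ncol(C))) {
    ci <- C[, i]
    C[, i] <- match(ci, unique(ci)) - 1
  }
  .dedupe_cols(C)
}

.composed_base <- function(parts) {
  k <- sum(parts)
  r <- length(parts)
  R <- 2^k
  C <- .canonicalize_cols(.dedupe_cols(.colorings(parts)))
  ncell <- 2^r
  p2 <- .pow2(R)
  M <- matrix(0, ncell, ncol(C))
  for (cell in 0:(ncell - 1)) M[cell + 1, ] <- colSums((C == cell) * p2)
  G <- .bits_matrix(0:(2^ncell - 1), ncell)
  sort(unique(as.vector(G %*% M)))
}

.close_under_perms <- function(bits, k) {
  R <- 2^k
  p2 <- .pow2(R)
  B <- .bits_matrix(bits, R)
  acc <- lapply(.perms(k), function(p) {
    as.vector(B[, .remap_perm(p) + 1, drop = FALSE] %*% p2)
  })
  sort(unique(unlist(acc, use.names = FALSE)))
}

#' Enumerate the composed Boolean functions of a composition structure
#'
#' Without permutation closure, the set of distinct
#' `h = g(p_1(first t_1 variables), ..., p_r(last t_r variables))` over all
#' assignments of an r-input outer function `g` and t_i-input inner
#' functions `p_i`, with consecutive variable blocks wired in sorted-part
#' order.  With closure (the default), the union of that set over all `k!`
#' relabelings of the input variables; the closed set is then also closed
#' under input negation.  Both sets are closed under output complementation.
#'
#' Trivial structures realize all `2^(2^k)` functions and can only be
#' materialized for `k <= 4`; use [composed_count()] for their size at
#' `k = 5`.
#'
#' @param cs a `composition_structure`, parts vector, or string like
#'   `"1,2"`.
#' @param permutation_closed close the set under all input permutations?
#' @return A sorted `bf` vector.
#' @examples
#' length(enumerate_composed("1,2", permutation_closed = FALSE))  # 88
#' length(enumerate_composed("1,2"))                              # 152
#' @export
enumerate_composed <- function(cs, permutation_closed = TRUE) {
  cs <- .as_structure(cs)
  k <- cs$k
  if (k > 5L) stop("exhaustive enumeration supports k <= 5", call. = FALSE)
  if (is_trivial_structure(cs)) {
    if (k > 4L) {
      stop(sprintf(
        "trivial structure %s realizes all 2^(2^%d) functions; too many to materialize",
        format(cs), k), call. = FALSE)
    }
    return(all_bfs(k))
  }
  key <- sprintf("composed:%s:%d", format(cs), as.integer(permutation_closed))
  cached <- the[[key]]
  if (!is.null(cached)) return(cached)
  base <- .composed_base(cs$parts)
  bits <- if (permutation_closed) .close_under_perms(base, k) else base
  res <- .new_bf(bits, k)
  the[[key]] <- res
  res
}

#' Number of composed Boolean functions
#'
#' Like `length(enumerate_composed(cs, ...))` but answers analytically for
#' trivial structures (`2^(2^k)`) so that `k = 5` is covered without
#' materializing the full function space.
#'
#' @inheritParams enumerate_composed
#' @return Numeric count.
#' @export
composed_count <- function(cs, permutation_closed = TRUE) {
  cs <- .as_structure(cs)
  if (is_trivial_structure(cs)) return(2^(2^cs$k))
  length(enumerate_composed(cs, permutation_closed))
}

#' Fraction of all k-input functions compatible with a structure
#'
#' @inheritParams enumerate_composed
#' @return List with `count`, `total` (`2^(2^k)`) and `fraction`.
#' @examples
#' composed_fraction("2,2")$fraction  # 1208/65536 = 0.0184...
#' @export
composed_fraction <- function(cs, permutation_closed = TRUE) {
  cs <- .as_structure(cs)
  count <- composed_count(cs, permutation_closed)
  total <- 2^(2^cs$k)
  list(count = count, total = total, fraction = count / total)
}

#' Composed functions that belong to a biologically meaningful class
#'
#' Counts the members of the permutation-closed composed set of `cs` that
#' are also in the given class.
#'
#' @param cs a composition structure (see [enumerate_composed()]).
#' @param label one of `"UF"`, `"CF"`, `"NCF"`, `"RoF"`.
#' @return Integer count.
#' @examples
#' class_overlap("1,2", "NCF")  # 64: all 3-input NCFs are composed
#' @export
class_overlap <- function(cs, label) {
  cs <- .as_structure(cs)
  label <- .check_label(label)
  S <- enumerate_composed(cs, permutation_closed = TRUE)
  cls <- enumerate_class(label, cs$k)
  sum(unclass(cls) %in% unclass(S))
}

#' Exclusive intersection regions of non-trivial composition structures
#'
#' For every non-empty subset S of the non-trivial structures with `k`
#' inputs, counts the functions present in every member of S and absent
#' from every non-member (the exclusive regions of an UpSet plot).  The
#' region counts sum to the size of the union.
#'
#' @param k number of inputs, 3 to 5.
#' @return A data frame with one logical membership column per structure,
#'   plus `count`; rows are the non-empty exclusive regions (regions with
#'   zero functions are kept so that subset relations are visible).
#' @export
intersection_counts <- function(k) {
  k <- as.integer(k)
  if (k < 3L || k > 5L) {
    stop("intersection analysis is defined for k in 3..5", call. = FALSE)
  }
  structs <- nontrivial_structures(k)
  sets <- lapply(structs, function(cs) unclass(enumerate_composed(cs, TRUE)))
  univ <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (!is.matrix(memb)) memb <- matrix(memb, ncol = length(sets))
  colnames(memb) <- vapply(structs, format, character(1))
  patt <- apply(memb, 1, function(x) paste0(as.integer(x), collapse = ""))
  # all non-empty membership patterns over the structures
  full <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(sets))))
  full <- full[rowSums(full) > 0, , drop = FALSE]
  fullpatt <- apply(full, 1, function(x) paste0(as.integer(x), collapse = ""))
  counts <- as.integer(table(factor(patt, levels = fullpatt)))
  out <- as.data.frame(full)
  names(out) <- colnames(memb)
  out$count <- counts
  out
}

#' Bias spectrum of a set of Boolean functions
#'
#' @param f a `bf` vector.
#' @return Integer vector of counts indexed by bias `0..2^k` (names give
#'   the bias).  Counts sum to `length(f)`.
#' @examples
#' sp <- bias_spectrum(enumerate_composed("1,2"))
#' sum(sp)  # 152
#' @export
bias_spectrum <- function(f) {
  .assert_bf(f)
  R <- 2^bf_k(f)
  b <- bf_bias(f)
  counts <- integer(R + 1)
  tb <- table(b)
  counts[as.integer(names(tb)) + 1] <- as.integer(tb)
  names(counts) <- 0:R
  counts
}

#' Fraction of functions with odd bias
#'
#' @param f a `bf` vector.
#' @return Numeric scalar in `[0, 1]`.
#' @export
odd_bias_fraction <- function(f) {
  mean(bf_bias(f) %% 2 == 1)
}
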