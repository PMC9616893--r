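# Enrichment statistics of Boolean-function catalogs against the uniform
# random ensemble of k-input functions, with exact one-sided binomial tail
# p-values.  All statistics are stratified by input count k; the null is a
# per-k uniform draw over all 2^(2^k) functions.

#' Upper binomial tail probability
#'
#' `P(X >= m_obs)` for `X ~ Binomial(M, f0)`, the one-sided p-value for
#' observing at least `m_obs` successes.  Computed through the survival
#' function, stable for `M` up to ~10^4.  The sum starts at the observed
#' integer count; no continuity correction.
#'
#' @param M number of draws.
#' @param m_obs observed number of successes, in `0..M`.
#' @param f0 success probability under the null.
#' @return p-value in `(0, 1]`; `m_obs = 0` gives exactly 1.
#' @examples
#' binomial_tail_p(2, 2, 0.5)  # 0.25
#' @export
binomial_tail_p <- function(M, m_obs, f0) {
  if (length(M) != 1 || length(m_obs) != 1 || length(f0) != 1) {
    stop("arguments must be scalars", call. = FALSE)
  }
  if (is.na(M) || M < 0 || M != floor(M)) stop("`M` must be a non-negative integer", call. = FALSE)
  if (is.na(m_obs) || m_obs < 0 || m_obs > M || m_obs != floor(m_obs)) {
    stop("`m_obs` must be an integer in 0..M", call. = FALSE)
  }
  if (is.na(f0) || f0 < 0 || f0 > 1) stop("`f0` must be in [0, 1]", call. = FALSE)
  if (m_obs == 0) return(1)
  stats::pbinom(m_obs - 1, M, f0, lower.tail = FALSE)
}

.enrichment_row <- function(k, label, M, m_obs, f0) {
  f1 <- m_obs / M
  data.frame(
    k = as.integer(k),
    target_label = label,
    M = as.integer(M),
    m_obs = as.integer(m_obs),
    f0 = f0,
    f1 = f1,
    factor = if (f0 > 0) f1 / f0 else NA_real_,
    p_value = binomial_tail_p(M, m_obs, f0)
  )
}

.records_at_k <- function(catalog, k) {
  stopifnot(all(c("k", "bits") %in% names(catalog)))
  catalog$bits[catalog$k == k]
}

#' Enrichment factor of a function set in a catalog
#'
#' Compares the frequency `f1` of catalog records (at the target's input
#' count `k`) that fall in `target` with the frequency
#' `f0 = |target| / 2^(2^k)` expected under uniform random functions.  The
#' enrichment factor is `E = f1 / f0`; the one-sided p-value is the upper
#' binomial tail `P(X >= m_obs)` for `X ~ Binomial(M, f0)`.
#'
#' @param catalog a catalog data frame (columns `k`, `bits`).
#' @param target a `bf` vector (e.g. a composed set or class set).
#' @param label text label stored in the result.
#' @return One-row data frame: `k`, `target_label`, `M`, `m_obs`, `f0`,
#'   `f1`, `factor`, `p_value`.
#' @export
enrichment_factor <- function(catalog, target, label = "target") {
  .assert_bf(target)
  k <- bf_k(target)
  recs <- .records_at_k(catalog, k)
  if (length(recs) == 0) {
    stop(sprintf("catalog has no records with k = %d", k), call. = FALSE)
  }
  f0 <- length(target) / 2^(2^k)
  m_obs <- sum(recs %in% unclass(target))
  .enrichment_row(k, label, length(recs), m_obs, f0)
}

#' Relative enrichment of a subtype within a function set
#'
#' Within the catalog records falling in `set` (size `M_T`), compares the
#' observed fraction in `subset` with the ensemble fraction
#' `f_s0 = |subset| / |set|`.  `E_R = f_s1 / f_s0`; the p-value is the
#' upper binomial tail on `M_T` draws at probability `f_s0`.
#'
#' @param catalog a catalog data frame.
#' @param set a `bf` vector, e.g. a composed set.
#' @param subset a `bf` vector contained in `set`, e.g. its nested
#'   canalyzing members.
#' @param label text label stored in the result.
#' @return One-row data frame as in [enrichment_factor()], with `M` the
#'   number of catalog records in `set`.
#' @export
relative_enrichment <- function(catalog, set, subset, label = "subtype") {
  .assert_bf(set); .assert_bf(subset)
  k <- bf_k(set)
  if (bf_k(subset) != k) stop("`set` and `subset` must share one k", call. = FALSE)
  if (!all(unclass(subset) %in% unclass(set))) {
    stop("`subset` must be contained in `set`", call. = FALSE)
  }
  recs <- .records_at_k(catalog, k)
  in_set <- recs[recs %in% unclass(set)]
  if (length(in_set) == 0) {
    stop(sprintf("catalog has no records with k = %d inside `set`", k),
         call. = FALSE)
  }
  f_s0 <- length(subset) / length(set)
  m_obs <- sum(in_set %in% unclass(subset))
  .enrichment_row(k, label, length(in_set), m_obs, f_s0)
}

#' Enrichment of the three disjoint regions of a set pair
#'
#' Splits the union of a composed set `set_c` and a class set `set_s` into
#' the three disjoint regions `set_c` intersect `set_s`, `set_c` minus
#' `set_s` and `set_s` minus `set_c`, and computes the enrichment factor of
#' each.  When `set_s` is contained in `set_c` the third region is empty
#' and its row is flagged not applicable (`applicable = FALSE`, statistics
#' `NA`).
#'
#' @param catalog a catalog data frame.
#' @param set_c,set_s `bf` vectors at one `k`.
#' @param labels length-2 character vector naming the two sets in the
#'   region labels.
#' @return Three-row data frame with a `region` column
#'   (`"intersection"`, `"c_only"`, `"s_only"`) and an `applicable` flag.
#' @export
disjoint_enrichments <- function(catalog, set_c, set_s,
                                 labels = c("C", "S")) {
  .assert_bf(set_c); .assert_bf(set_s)
  k <- bf_k(set_c)
  if (bf_k(set_s) != k) stop("sets must share one k", call. = FALSE)
  a <- unclass(set_c); b <- unclass(set_s)
  regions <- list(
    intersection = intersect(a, b),
    c_only = setdiff(a, b),
    s_only = setdiff(b, a)
  )
  region_labels <- c(
    sprintf("%s & %s", labels[1], labels[2]),
    sprintf("%s \\ %s", labels[1], labels[2]),
    sprintf("%s \\ %s", labels[2], labels[1])
  )
  rows <- vector("list", 3)
  for (i in 1:3) {
    reg <- regions[[i]]
    if (length(reg) == 0) {
      rows[[i]] <- data.frame(
        k = k, target_label = region_labels[i], M = NA_integer_,
        m_obs = NA_integer_, f0 = NA_real_, f1 = NA_real_,
        factor = NA_real_, p_value = NA_real_
      )
    } else {
      rows[[i]] <- enrichment_factor(catalog, .new_bf(reg, k),
                                     label = region_labels[i])
    }
  }
  out <- do.call(rbind, rows)
  out$region <- names(regions)
  out$applicable <- !is.na(out$M)
  out
}
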