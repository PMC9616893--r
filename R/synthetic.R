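# Deterministic generators for synthetic inputs: mixture catalogs of Boolean
# functions (a uniform background enriched for a meaningful class or a
# composed set, emulating the statistical structure of curated model
# collections) and cis-regulatory fixtures with planted TF-enhancer
# bindings and controlled near-misses.  A single explicit seed drives all
# randomness; no global random state is touched.

.mixture_component_set <- function(name, k) {
  if (identical(name, "uniform")) return(NULL)  # sampled directly
  if (name %in% .class_labels) {
    s <- enumerate_class(name, k)
    if (length(s) == 0) stop(sprintf("class %s is empty at k = %d", name, k),
                             call. = FALSE)
    return(s)
  }
  # otherwise a composition structure spec like "1,2" or "{1,2}"
  enumerate_composed(.as_structure(name), permutation_closed = TRUE)
}

.sample_uniform_bf <- function(n, k) {
  if (k <= 4) {
    sample.int(2^(2^k), n, replace = TRUE) - 1
  } else {
    # 2^32 functions: compose two independent 16-bit halves so every mask is
    # reachable with equal probability
    lo <- sample.int(65536, n, replace = TRUE) - 1
    hi <- sample.int(65536, n, replace = TRUE) - 1
    lo + hi * 65536
  }
}

#' Simulate a Boolean-function catalog from a mixture
#'
#' Each record first samples a mixture component, then samples a function
#' uniformly from that component's set.  Components are `"uniform"` (all
#' k-input functions), a class label (`"UF"`, `"CF"`, `"NCF"`, `"RoF"`), or
#' a composition structure given as `"1,2"`-style text (its
#' permutation-closed composed set).  The true component of every record is
#' recorded so that recovery can be checked against ground truth.
#'
#' @param k input count of every record.
#' @param n number of records (>= 1).
#' @param mixture named numeric vector of non-negative weights summing
#'   to 1.
#' @param seed integer seed; fixed seed gives an identical catalog.
#' @return A catalog data frame with columns `source_id`, `node_id`, `k`,
#'   `bits` and `component`.
#' @examples
#' cat3 <- simulate_catalog(3, 100, c(uniform = 0.7, NCF = 0.3), seed = 1)
#' table(cat3$component)
#' @export
simulate_catalog <- function(k, n, mixture = c(uniform = 1), seed) {
  k <- as.integer(k); n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (is.null(names(mixture)) || any(!nzchar(names(mixture)))) {
    stop("`mixture` must be a named weight vector", call. = FALSE)
  }
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
  }
  sets <- lapply(names(mixture), .mixture_component_set, k = k)
  names(sets) <- names(mixture)
  withr::with_seed(seed, {
    comp <- sample(names(mixture), n, replace = TRUE, prob = mixture)
    bits <- numeric(n)
    for (nm in names(mixture)) {
      idx <- which(comp == nm)
      if (!length(idx)) next
      bits[idx] <- if (is.null(sets[[nm]])) {
        .sample_uniform_bf(length(idx), k)
      } else {
        unclass(sets[[nm]])[sample.int(length(sets[[nm]]), length(idx),
                                       replace = TRUE)]
      }
    }
    data.frame(
      source_id = "synthetic",
      node_id = sprintf("n%05d", seq_len(n)),
      k = k,
      bits = bits,
      component = comp
    )
  })
}

#' Simulate a co-binding fixture with planted ground truth
#'
#' Places non-overlapping enhancers on a synthetic chromosome and, for each
#' planted (TF, enhancer) binding, writes a peak whose midpoint and summit
#' both fall inside the enhancer.  For a fraction of the non-bound pairs a
#' near-miss peak is written that violates exactly one of the two
#' conditions (summit outside with midpoint inside, or vice versa), so the
#' binding rule is exercised at its boundary.  Output files are plain-text
#' narrowPeak / BED / TSV; a fixed seed gives byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param n_enhancers number of enhancers (>= 1).
#' @param tf_names character vector of TF names (one narrowPeak file each).
#' @param binding either a logical `length(tf_names) x n_enhancers` matrix
#'   of planted bindings, or a scalar per-pair binding probability.
#' @param seed integer seed.
#' @param near_miss_prob probability that a non-bound pair receives a
#'   near-miss peak.
#' @param chrom synthetic chromosome name.
#' @param enhancer_width,peak_width interval widths in bp; the enhancer
#'   must be able to contain a whole peak (`enhancer_width >= peak_width`),
#'   otherwise the geometry is infeasible and an error is raised.
#' @return A list with `peak_files` (named by TF), `enhancer_bed`,
#'   `manifest`, `truth` (data frame: `tf_name`, `enhancer_id`, `planted`
#'   in `bind` / `near_miss_summit_out` / `near_miss_midpoint_out`), and
#'   `expected_counts` (named integer vector of true per-enhancer TF
#'   counts).
#' @export
simulate_cobind_fixture <- function(dir, n_enhancers, tf_names, binding,
                                    seed, near_miss_prob = 0.15,
                                    chrom = "chrS",
                                    enhancer_width = 600, peak_width = 240) {
  if (n_enhancers < 1) stop("`n_enhancers` must be >= 1", call. = FALSE)
  if (enhancer_width < peak_width) {
    stop(sprintf(
      "infeasible geometry: enhancer width %d cannot contain a peak of width %d",
      enhancer_width, peak_width), call. = FALSE)
  }
  n_tf <- length(tf_names)
  if (is.matrix(binding)) {
    stopifnot(nrow(binding) == n_tf, ncol(binding) == n_enhancers)
    bind_mat <- binding
  } else {
    stopifnot(length(binding) == 1, binding >= 0, binding <= 1)
    bind_mat <- NULL
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gap <- 4 * enhancer_width
  enh_start <- 1000 + (seq_len(n_enhancers) - 1) * (enhancer_width + gap)
  enh <- data.frame(
    enhancer_id = sprintf("enh%05d", seq_len(n_enhancers)),
    chrom = chrom, start = enh_start, end = enh_start + enhancer_width
  )
  withr::with_seed(seed, {
    if (is.null(bind_mat)) {
      bind_mat <- matrix(stats::runif(n_tf * n_enhancers) < binding,
                         n_tf, n_enhancers)
    }
    miss_mat <- matrix(FALSE, n_tf, n_enhancers)
    miss_mat[!bind_mat] <- stats::runif(sum(!bind_mat)) < near_miss_prob
    truth <- NULL
    peak_files <- character(n_tf)
    names(peak_files) <- tf_names
    half <- peak_width %/% 2
    for (ti in seq_len(n_tf)) {
      rows <- NULL
      for (ei in seq_len(n_enhancers)) {
        es <- enh$start[ei]
        if (bind_mat[ti, ei]) {
          # whole peak inside the enhancer: midpoint and summit both inside
          slack <- enhancer_width - peak_width
          ps <- es + if (slack > 0) sample.int(slack + 1, 1) - 1 else 0
          so <- half + if (half > 2) sample.int(half - 2, 1) - 1 else 0
          rows <- rbind(rows, data.frame(start = ps, end = ps + peak_width,
                                         summit = so))
          truth <- rbind(truth, data.frame(tf_name = tf_names[ti],
                                           enhancer_id = enh$enhancer_id[ei],
                                           planted = "bind"))
        } else if (miss_mat[ti, ei]) {
          if (stats::runif(1) < 0.5) {
            # midpoint inside, summit outside (left of the enhancer)
            ps <- es - half
            so <- 2
            lab <- "near_miss_summit_out"
          } else {
            # summit inside, midpoint outside
            ps <- es - half - 10
            so <- half + 20
            lab <- "near_miss_midpoint_out"
          }
          rows <- rbind(rows, data.frame(start = ps, end = ps + peak_width,
                                         summit = so))
          truth <- rbind(truth, data.frame(tf_name = tf_names[ti],
                                           enhancer_id = enh$enhancer_id[ei],
                                           planted = lab))
        }
      }
      f <- file.path(dir, paste0(tf_names[ti], ".narrowPeak"))
      if (is.null(rows)) {
        # a far-away peak so the file is non-empty but binds nothing
        rows <- data.frame(start = 10, end = 10 + peak_width, summit = half)
      }
      np <- data.frame(
        chrom = chrom, start = rows$start, end = rows$end,
        name = sprintf("%s_peak%03d", tf_names[ti], seq_len(nrow(rows))),
        score = 0L, strand = ".", signal = 1, p = -1, q = -1,
        summit = rows$summit
      )
      utils::write.table(np, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      peak_files[ti] <- f
    }
    bed <- file.path(dir, "enhancers.bed")
    utils::write.table(enh[, c("chrom", "start", "end", "enhancer_id")], bed,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    manifest <- file.path(dir, "manifest.tsv")
    utils::write.table(
      data.frame(file = basename(peak_files), tf_name = tf_names),
      manifest, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (is.null(truth)) {
      truth <- data.frame(tf_name = character(0), enhancer_id = character(0),
                          planted = character(0))
    }
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    expected <- colSums(bind_mat)
    names(expected) <- enh$enhancer_id
    list(peak_files = peak_files, enhancer_bed = bed, manifest = manifest,
         truth = truth, expected_counts = expected)
  })
}
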