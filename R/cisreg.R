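# Enhancer-TF co-binding analysis.
#
# Binding rule: a TF binds an active enhancer if and only if BOTH the
# midpoint and the summit of one of its ChIP-seq peaks fall within the
# enhancer interval.  Coordinates are 0-based half-open throughout (BED
# convention); the midpoint of an even-length peak is the floor of the
# average (left-biased), and "within" uses a half-open right boundary.

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' @param path path to a 10-column tab-separated narrowPeak file (no
#'   header; lines starting with `#` or `track` are skipped).
#' @param tf_name transcription factor name attached to every record.
#' @param summit_fallback what to do when the summit offset (column 10) is
#'   `-1` (absent): `"error"` (default) rejects the file naming the rows;
#'   `"midpoint"` substitutes the peak midpoint with a warning.
#' @param strip_chr drop a leading `"chr"` from chromosome names, to
#'   reconcile naming schemes across inputs.
#' @return A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score`, `strand`, `signal_value`, `p_value`,
#'   `q_value`, `summit_offset`, `tf_name`.  Strand is retained but unused:
#'   peaks are unstranded for this analysis.
#' @export
read_narrowpeak <- function(path, tf_name,
                            summit_fallback = c("error", "midpoint"),
                            strip_chr = FALSE) {
  summit_fallback <- match.arg(summit_fallback)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    stop(sprintf("narrowPeak file %s has no records", path), call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10)) {
    bad <- which(nf != 10)[1]
    stop(sprintf("%s row %d: narrowPeak requires 10 columns, found %d",
                 path, bad, nf[bad]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    chrom = m[, 1],
    start = as.numeric(m[, 2]),
    end = as.numeric(m[, 3]),
    name = m[, 4],
    score = as.numeric(m[, 5]),
    strand = m[, 6],
    signal_value = as.numeric(m[, 7]),
    p_value = as.numeric(m[, 8]),
    q_value = as.numeric(m[, 9]),
    summit_offset = as.numeric(m[, 10])
  )
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$summit_offset)) {
    stop(sprintf("%s: non-numeric coordinate field", path), call. = FALSE)
  }
  if (any(df$start < 0) || any(df$start >= df$end)) {
    bad <- which(df$start < 0 | df$start >= df$end)[1]
    stop(sprintf("%s row %d: invalid interval [%s, %s)", path, bad,
                 df$start[bad], df$end[bad]), call. = FALSE)
  }
  absent <- which(df$summit_offset < 0)
  if (length(absent)) {
    if (summit_fallback == "error") {
      stop(sprintf(
        "%s: summit offset absent (-1) in row(s) %s; rerun with summit_fallback = \"midpoint\" to substitute the peak midpoint",
        path, paste(utils::head(absent, 5), collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("%s: substituted midpoint for absent summit in %d row(s)",
                    path, length(absent)), call. = FALSE)
    df$summit_offset[absent] <-
      (df$end[absent] - df$start[absent]) %/% 2
  }
  bad <- which(df$start + df$summit_offset >= df$end)
  if (length(bad)) {
    stop(sprintf("%s row %d: summit offset %d outside the peak", path,
                 bad[1], df$summit_offset[bad[1]]), call. = FALSE)
  }
  if (strip_chr) df$chrom <- sub("^chr", "", df$chrom)
  df$tf_name <- tf_name
  df
}

#' Read enhancer intervals from BED3/BED4
#'
#' @param path BED file with 3 (auto-assigned ids `enh00001`, ...) or 4+
#'   columns (column 4 taken as the enhancer id).
#' @param strip_chr drop a leading `"chr"` from chromosome names.
#' @return A data frame with columns `enhancer_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
read_enhancers <- function(path, strip_chr = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop(sprintf("%s has no records", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("%s row %d: BED requires at least 3 columns", path,
                 which(nf < 3)[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- as.numeric(vapply(fields, `[`, character(1), 2))
  end <- as.numeric(vapply(fields, `[`, character(1), 3))
  if (anyNA(start) || anyNA(end) || any(start < 0) || any(start >= end)) {
    stop(sprintf("%s: invalid interval coordinates", path), call. = FALSE)
  }
  ids <- if (all(nf >= 4)) {
    vapply(fields, `[`, character(1), 4)
  } else {
    sprintf("enh%05d", seq_along(fields))
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate enhancer id %s", path,
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  data.frame(enhancer_id = ids, chrom = chrom, start = start, end = end)
}

#' Read a peak-file manifest
#'
#' Replicate narrowPeak files are merged under one TF through a manifest:
#' a two-column TSV (`file`, `tf_name`), optionally with a header line.
#'
#' @param path manifest path; relative file paths are resolved against the
#'   manifest's directory.
#' @return A data frame with columns `file`, `tf_name`.
#' @export
read_peak_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", colClasses = "character")
  if (ncol(df) < 2) stop("manifest requires columns: file, tf_name", call. = FALSE)
  names(df)[1:2] <- c("file", "tf_name")
  if (identical(tolower(df$file[1]), "file")) df <- df[-1, , drop = FALSE]
  rel <- !grepl("^(/|~)", df$file)
  df$file[rel] <- file.path(dirname(path), df$file[rel])
  df[, c("file", "tf_name")]
}

#' Does each peak bind each enhancer?
#'
#' Applies the binding rule pairwise: chromosomes equal, AND the peak
#' midpoint `start + floor((end - start)/2)` in `[enh_start, enh_end)`,
#' AND the summit `start + summit_offset` in `[enh_start, enh_end)`.
#'
#' @param peaks a peak data frame from [read_narrowpeak()].
#' @param enhancers an enhancer data frame from [read_enhancers()].
#' @return A logical matrix, peaks in rows, enhancers in columns.
#' @export
binds <- function(peaks, enhancers) {
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2
  summit <- peaks$start + peaks$summit_offset
  out <- matrix(FALSE, nrow(peaks), nrow(enhancers),
                dimnames = list(NULL, enhancers$enhancer_id))
  for (j in seq_len(nrow(enhancers))) {
    e <- enhancers[j, ]
    out[, j] <- peaks$chrom == e$chrom &
      mid >= e$start & mid < e$end &
      summit >= e$start & summit < e$end
  }
  out
}

# (tf, enhancer) pairs with at least one binding peak, via GenomicRanges
# point-in-interval overlap on the midpoint and summit positions
.binding_pairs <- function(peaks, enhancers) {
  if (nrow(peaks) == 0) {
    return(data.frame(tf_name = character(0), enhancer_id = character(0)))
  }
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2
  summit <- peaks$start + peaks$summit_offset
  lv <- unique(c(peaks$chrom, enhancers$chrom))
  enh_gr <- GenomicRanges::GRanges(
    factor(enhancers$chrom, levels = lv),
    IRanges::IRanges(start = enhancers$start + 1, end = enhancers$end)
  )
  pt <- function(pos) {
    GenomicRanges::GRanges(factor(peaks$chrom, levels = lv),
                           IRanges::IRanges(start = pos + 1, width = 1))
  }
  ov_m <- GenomicRanges::findOverlaps(pt(mid), enh_gr)
  ov_s <- GenomicRanges::findOverlaps(pt(summit), enh_gr)
  key_m <- paste(S4Vectors::queryHits(ov_m), S4Vectors::subjectHits(ov_m))
  key_s <- paste(S4Vectors::queryHits(ov_s), S4Vectors::subjectHits(ov_s))
  both <- ov_m[key_m %in% key_s]
  pairs <- unique(data.frame(
    tf_name = peaks$tf_name[S4Vectors::queryHits(both)],
    enhancer_id = enhancers$enhancer_id[S4Vectors::subjectHits(both)]
  ))
  rownames(pairs) <- NULL
  pairs
}

#' Per-enhancer TF co-binding summary
#'
#' Counts, for every enhancer, the number of distinct TFs with at least one
#' peak binding it under the midpoint-plus-summit rule (a TF counts once
#' per enhancer however many of its peaks bind).  Reports the distribution
#' of TF counts and the fraction of enhancers bound by at least `n` TFs.
#'
#' @param peaks a single data frame of peaks (with `tf_name`), or a list of
#'   per-TF data frames which is row-bound.
#' @param enhancers an enhancer data frame from [read_enhancers()].
#' @param thresholds integer thresholds for `fraction_at_least` (0 is
#'   always included and equals 1).
#' @return An object of class `cobinding_summary`: a list with
#'   `per_enhancer` (enhancer id, coordinates, `n_tfs`, semicolon-joined
#'   `tf_list`), `distribution` (`n_tfs`, `n_enhancers`), `n_enhancers`,
#'   `n_tfs_binding_any` and `fraction_at_least` (named numeric vector).
#' @export
cobinding_summary <- function(peaks, enhancers, thresholds = c(1, 2)) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, peaks)
  }
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), summit_offset = numeric(0),
                        tf_name = character(0))
  }
  if (nrow(enhancers) == 0) stop("no enhancers supplied", call. = FALSE)
  pairs <- .binding_pairs(peaks, enhancers)
  # deterministic regardless of input order
  pairs <- pairs[order(pairs$enhancer_id, pairs$tf_name), , drop = FALSE]
  counts <- table(factor(pairs$enhancer_id, levels = sort(enhancers$enhancer_id)))
  tf_lists <- vapply(sort(enhancers$enhancer_id), function(id) {
    paste(pairs$tf_name[pairs$enhancer_id == id], collapse = ";")
  }, character(1))
  ord <- match(sort(enhancers$enhancer_id), enhancers$enhancer_id)
  per_enh <- data.frame(
    enhancer_id = sort(enhancers$enhancer_id),
    chrom = enhancers$chrom[ord],
    start = enhancers$start[ord],
    end = enhancers$end[ord],
    n_tfs = as.integer(counts),
    tf_list = unname(tf_lists)
  )
  dist <- as.data.frame(table(per_enh$n_tfs), stringsAsFactors = FALSE)
  names(dist) <- c("n_tfs", "n_enhancers")
  dist$n_tfs <- as.integer(dist$n_tfs)
  dist$n_enhancers <- as.integer(dist$n_enhancers)
  thresholds <- sort(unique(c(0, as.integer(thresholds))))
  frac <- vapply(thresholds, function(n) mean(per_enh$n_tfs >= n), numeric(1))
  names(frac) <- thresholds
  structure(list(
    per_enhancer = per_enh,
    distribution = dist,
    n_enhancers = nrow(enhancers),
    n_tfs_binding_any = length(unique(pairs$tf_name)),
    fraction_at_least = frac
  ), class = "cobinding_summary")
}

#' @export
print.cobinding_summary <- function(x, ...) {
  cat(sprintf("co-binding summary: %d enhancers, %d TF(s) binding >= 1 enhancer\n",
              x$n_enhancers, x$n_tfs_binding_any))
  for (n in names(x$fraction_at_least)) {
    cat(sprintf("  fraction of enhancers with >= %s TFs: %.4f\n",
                n, x$fraction_at_least[[n]]))
  }
  invisible(x)
}
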