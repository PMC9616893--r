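# Catalogs of observed Boolean update rules.
#
# A catalog is a plain data frame with one regulatory instance per row:
# source_id (model identifier), node_id (regulated node), k (input count)
# and bits (truth-table bitmask); duplicate functions are legitimate — they
# are distinct regulatory instances.  On disk a catalog is a TSV with a
# commented header line and columns source_id, node_id, k, output_bits
# (bitstring, row 0 first).

.catalog_columns <- c("source_id", "node_id", "k", "output_bits")

#' Read a Boolean-function catalog from TSV
#'
#' @param path path to a tab-separated file with columns `source_id`,
#'   `node_id`, `k`, `output_bits`.  Lines starting with `#` are ignored.
#' @return A data frame with columns `source_id`, `node_id`, `k` (integer)
#'   and `bits` (numeric bitmask).
#' @export
read_bf_catalog <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character", quote = "")
  missing_cols <- setdiff(.catalog_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("catalog is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("catalog file has a header but no records", call. = FALSE)
    return(data.frame(source_id = character(0), node_id = character(0),
                      k = integer(0), bits = numeric(0)))
  }
  k <- suppressWarnings(as.integer(df$k))
  bad <- which(is.na(k) | k < 1)
  if (length(bad)) {
    stop(sprintf("invalid input count in catalog row %d", bad[1]), call. = FALSE)
  }
  bad <- which(nchar(df$output_bits) != 2^k)
  if (length(bad)) {
    stop(sprintf(
      "catalog row %d: bitstring has length %d but k = %d requires 2^%d = %d",
      bad[1], nchar(df$output_bits[bad[1]]), k[bad[1]], k[bad[1]], 2^k[bad[1]]),
      call. = FALSE)
  }
  bad <- grep("[^01]", df$output_bits)
  if (length(bad)) {
    stop(sprintf("catalog row %d: non-binary character in output bitstring",
                 bad[1]), call. = FALSE)
  }
  bits <- numeric(nrow(df))
  for (kk in unique(k)) {
    idx <- which(k == kk)
    bits[idx] <- unclass(bf_from_string(df$output_bits[idx], kk))
  }
  data.frame(source_id = df$source_id, node_id = df$node_id,
             k = k, bits = bits)
}

#' Write a Boolean-function catalog to TSV
#'
#' @param catalog a catalog data frame (columns `source_id`, `node_id`,
#'   `k`, `bits`), e.g. from [read_bf_catalog()] or [simulate_catalog()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bf_catalog <- function(catalog, path) {
  stopifnot(all(c("source_id", "node_id", "k", "bits") %in% names(catalog)))
  out <- data.frame(
    source_id = catalog$source_id,
    node_id = catalog$node_id,
    k = catalog$k,
    output_bits = vapply(seq_len(nrow(catalog)), function(i) {
      bf_to_string(bf(catalog$bits[i], catalog$k[i]))
    }, character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bfcompose catalog v1", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a set of Boolean functions as a catalog data frame
#'
#' Convenience wrapper turning a `bf` vector (e.g. an enumerated class or
#' composed set) into catalog rows.
#'
#' @param f a `bf` vector.
#' @param source_id label stored in the `source_id` column.
#' @return A catalog data frame.
#' @export
bf_as_catalog <- function(f, source_id = "enumeration") {
  .assert_bf(f)
  data.frame(
    source_id = source_id,
    node_id = sprintf("f%06d", seq_along(f)),
    k = bf_k(f),
    bits = as.numeric(unclass(f))
  )
}
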