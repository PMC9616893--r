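test_that("the binding rule requires both midpoint and summit inside the enhancer", {
  enh <- enh_df("e1", "chr1", 100, 200)
  # midpoint 120, summit 130: both inside
  expect_true(binds(peak_row("chr1", 90, 150, 40), enh)[1, 1])
  # summit 95 falls outside
  expect_false(binds(peak_row("chr1", 90, 150, 5), enh)[1, 1])
  # midpoint 200 is excluded by the half-open right boundary
  expect_false(binds(peak_row("chr1", 150, 250, 50), enh)[1, 1])
  # chromosome mismatch
  expect_false(binds(peak_row("chr2", 90, 150, 40), enh)[1, 1])
  # left boundary is inclusive: midpoint and summit exactly at start
  expect_true(binds(peak_row("chr1", 50, 150, 50), enh)[1, 1])
  # even-length midpoint is the floor of the average (left-biased):
  # peak [199, 202) has midpoint 200, outside [100, 200)
  expect_false(binds(peak_row("chr1", 199, 202, 1), enh)[1, 1])
  # peak [198, 201): midpoint 199 inside, summit 199 inside
  expect_true(binds(peak_row("chr1", 198, 201, 1), enh)[1, 1])
})

test_that("narrowPeak files parse, validate, and honor the summit policy", {
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t90\t150\tp1\t0\t.\t5.2\t-1\t-1\t40",
               "chr1\t300\t380\tp2\t0\t.\t4.0\t-1\t-1\t10"), np)
  peaks <- read_narrowpeak(np, "TFA")
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$tf_name, c("TFA", "TFA"))
  expect_equal(peaks$summit_offset, c(40, 10))

  miss <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t90\t150\tp1\t0\t.\t5.2\t-1\t-1\t-1"), miss)
  expect_error(read_narrowpeak(miss, "TFA"), "row\\(s\\) 1")
  expect_warning(pk <- read_narrowpeak(miss, "TFA", summit_fallback = "midpoint"),
                 "midpoint")
  expect_equal(pk$summit_offset, 30)

  short <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t90\t150\tp1\t0\t.\t5.2\t-1\t-1", short)
  expect_error(read_narrowpeak(short, "TFA"), "10 columns")

  chr <- read_narrowpeak(np, "TFA", strip_chr = TRUE)
  expect_equal(unique(chr$chrom), "1")
})

test_that("enhancer BED files parse with automatic or explicit ids", {
  bed3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t700"), bed3)
  e <- read_enhancers(bed3)
  expect_equal(e$enhancer_id, c("enh00001", "enh00002"))
  bed4 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tEA", "chr2\t500\t700\tEB"), bed4)
  e4 <- read_enhancers(bed4)
  expect_equal(e4$enhancer_id, c("EA", "EB"))
  badbed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100", badbed)
  expect_error(read_enhancers(badbed), "3 columns")
})

test_that("a TF counts once per enhancer regardless of how many peaks bind", {
  enh <- enh_df(c("e1", "e2"), "chr1", c(100, 1000), c(400, 1400))
  peaks <- rbind(peak_row("chr1", 120, 220, 50, "TFA"),
                 peak_row("chr1", 200, 300, 50, "TFA"))
  s <- cobinding_summary(peaks, enh)
  expect_equal(s$per_enhancer$n_tfs, c(1L, 0L))
  expect_equal(s$per_enhancer$tf_list[1], "TFA")
  expect_equal(s$n_tfs_binding_any, 1L)
  expect_equal(unname(s$fraction_at_least[["2"]]), 0)
})

test_that("empty peak input yields an all-zero summary", {
  enh <- enh_df(c("e1", "e2"), "chr1", c(100, 1000), c(400, 1400))
  s <- cobinding_summary(list(), enh)
  expect_equal(s$per_enhancer$n_tfs, c(0L, 0L))
  expect_equal(unname(s$fraction_at_least[["1"]]), 0)
  expect_equal(unname(s$fraction_at_least[["0"]]), 1)
  expect_equal(s$n_tfs_binding_any, 0L)
})

test_that("summaries are invariant to input order and internally consistent", {
  fx <- simulate_cobind_fixture(withr::local_tempdir(), 8,
                                c("A", "B", "C", "D"), binding = 0.4,
                                seed = 101)
  man <- read_peak_manifest(fx$manifest)
  peaks <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    read_narrowpeak(man$file[i], man$tf_name[i])
  }))
  enh <- read_enhancers(fx$enhancer_bed)
  s1 <- cobinding_summary(peaks, enh)
  withr::with_seed(1, {
    s2 <- cobinding_summary(peaks[sample(nrow(peaks)), ],
                            enh[sample(nrow(enh)), ])
  })
  expect_identical(s1$per_enhancer, s2$per_enhancer)
  expect_identical(s1$fraction_at_least, s2$fraction_at_least)
  # distribution sums to the enhancer count; threshold identity at 2
  expect_equal(sum(s1$distribution$n_enhancers), s1$n_enhancers)
  f0 <- mean(s1$per_enhancer$n_tfs == 0)
  f1 <- mean(s1$per_enhancer$n_tfs == 1)
  expect_equal(unname(s1$fraction_at_least[["2"]]), 1 - f0 - f1)
  # agreement between the matrix rule and the overlap-based summary
  bm <- binds(peaks, enh)
  by_rule <- vapply(seq_len(nrow(enh)), function(j) {
    length(unique(peaks$tf_name[bm[, j]]))
  }, integer(1))
  ord <- match(s1$per_enhancer$enhancer_id, enh$enhancer_id)
  expect_equal(s1$per_enhancer$n_tfs, by_rule[ord])
})
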