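test_that("binomial upper tail matches direct summation and edge cases", {
  expect_equal(binomial_tail_p(2, 2, 0.5), 0.25)
  expect_equal(binomial_tail_p(10, 0, 0.3), 1)
  expect_equal(binomial_tail_p(5, 0, 0), 1)
  expect_equal(binomial_tail_p(10, 7, 0.2), oracle_binom_tail(10, 7, 0.2))
  expect_equal(signif(binomial_tail_p(10, 7, 0.2), 5), 8.6436e-4)
  withr::with_seed(2, {
    for (i in 1:50) {
      M <- sample(1:50, 1)
      m <- sample(0:M, 1)
      f0 <- runif(1)
      expect_equal(binomial_tail_p(M, m, f0), oracle_binom_tail(M, m, f0),
                   tolerance = 1e-12)
    }
  })
  # monotone non-increasing in the observed count
  p <- vapply(0:20, binomial_tail_p, numeric(1), M = 20, f0 = 0.4)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(binomial_tail_p(5, 6, 0.5), "0..M")
  expect_error(binomial_tail_p(5, 2, 1.5), "0, 1")
})

test_that("enrichment factors compare catalog frequency with the uniform ensemble", {
  s <- enumerate_composed("1,2")
  # 9 records inside the composed set, 1 outside
  inside <- bits(s)[1:9]
  outside <- setdiff(0:255, bits(s))[1]
  cat_df <- data.frame(source_id = "m", node_id = letters[1:10], k = 3,
                       bits = c(inside, outside))
  res <- enrichment_factor(cat_df, s, "{1,2}")
  expect_equal(res$M, 10L)
  expect_equal(res$m_obs, 9L)
  expect_equal(res$f0, 152 / 256)
  expect_equal(res$f1, 0.9)
  expect_equal(res$factor, 0.9 / (152 / 256), tolerance = 1e-12)
  expect_equal(res$p_value, oracle_binom_tail(10, 9, 152 / 256))
  expect_equal(round(res$p_value, 4), 0.0427)
  # the whole space as target: factor 1, p 1
  full <- enrichment_factor(data.frame(source_id = "m", node_id = "x",
                                       k = 2, bits = 5),
                            all_bfs(2), "all")
  expect_equal(full$factor, 1)
  expect_equal(full$p_value, 1)
  # disjoint target
  none <- enrichment_factor(cat_df, bf(setdiff(0:255, cat_df$bits)[1], 3), "one")
  expect_equal(none$m_obs, 0L)
  expect_equal(none$p_value, 1)
  expect_error(enrichment_factor(cat_df, all_bfs(2)), "no records")
})

test_that("relative enrichment conditions on membership in the composed set", {
  s <- enumerate_composed("1,2")
  ncf3 <- enumerate_class("NCF", 3)
  # 8 records in the set, 6 of them NCF
  in_ncf <- bits(ncf3)[1:6]
  in_set_not_ncf <- setdiff(bits(s), bits(ncf3))[1:2]
  outside <- setdiff(0:255, bits(s))[1:3]
  cat_df <- data.frame(source_id = "m", node_id = sprintf("n%d", 1:11),
                       k = 3, bits = c(in_ncf, in_set_not_ncf, outside))
  res <- relative_enrichment(cat_df, s, ncf3, "NCF in {1,2}")
  expect_equal(res$M, 8L)
  expect_equal(res$m_obs, 6L)
  expect_equal(res$f0, 64 / 152)
  expect_equal(res$f1, 0.75)
  expect_equal(res$factor, 0.75 / (64 / 152), tolerance = 1e-12)
  expect_equal(res$factor, 1.78125)
  # subtype = whole set: E_R = 1, p = 1
  triv <- relative_enrichment(cat_df, s, s)
  expect_equal(triv$factor, 1)
  expect_equal(triv$p_value, 1)
  expect_error(relative_enrichment(cat_df, ncf3, s), "contained")
})

test_that("disjoint-region enrichments partition the union and flag empty regions", {
  s22 <- enumerate_composed("2,2")
  ncf4 <- enumerate_class("NCF", 4)
  rof4 <- enumerate_class("RoF", 4)
  withr::with_seed(30, {
    cat_df <- simulate_catalog(4, 500, c(uniform = 0.5, NCF = 0.5), seed = 30)
  })
  dj <- disjoint_enrichments(cat_df, s22, ncf4, labels = c("{2,2}", "NCF"))
  expect_equal(nrow(dj), 3)
  expect_true(all(dj$applicable))
  # the three regions partition the union
  sizes <- c(length(intersect(bits(s22), bits(ncf4))),
             length(setdiff(bits(s22), bits(ncf4))),
             length(setdiff(bits(ncf4), bits(s22))))
  expect_equal(sum(sizes), length(union(bits(s22), bits(ncf4))))
  # RoF(4) is contained in {1,1,2}: third region flagged not applicable
  dj2 <- disjoint_enrichments(cat_df, enumerate_composed("1,1,2"), rof4,
                              labels = c("{1,1,2}", "RoF"))
  expect_false(dj2$applicable[3])
  expect_true(is.na(dj2$factor[3]))
})

test_that("catalogs round-trip through TSV and malformed files are rejected by row", {
  cat_df <- simulate_catalog(3, 25, c(uniform = 1), seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bf_catalog(cat_df, path)
  back <- read_bf_catalog(path)
  expect_equal(back$bits, cat_df$bits)
  expect_equal(back$k, cat_df$k)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_id\tnode_id\tk\toutput_bits",
               "m\ta\t3\t01010101",
               "m\tb\t3\t0101010"), bad)
  expect_error(read_bf_catalog(bad), "row 2")

  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_id\tnode_id\tk\toutput_bits",
               "m\ta\t2\t01x1"), bad2)
  expect_error(read_bf_catalog(bad2), "non-binary")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("source_id\tnode_id\tk\toutput_bits", empty)
  expect_warning(res <- read_bf_catalog(empty), "no records")
  expect_equal(nrow(res), 0)
})
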