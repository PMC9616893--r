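test_that("output vectors pack into bitmasks under the x1-most-significant row convention", {
  # h = x1 OR (x2 AND x3): rows 000..111 give 0,0,0,1,1,1,1,1
  expect_equal(bits(bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3)), 248)
  expect_equal(bits(bf_from_outputs(c(0, 1), 1)), 2)  # identity x1
  expect_equal(bits(bf_from_outputs(c(0, 1, 1, 0), 2)), 6)  # XOR
  expect_error(bf_from_outputs(c(0, 1, 1), 2), "length")
  expect_error(bf_from_outputs(c(0, 2, 1, 0), 2), "index 2")
  expect_error(bf(256, 2), "exceeds")
})

test_that("serialization round-trips for sampled functions at every k up to 5", {
  withr::with_seed(11, {
    for (k in 1:5) {
      bits <- if (k <= 4) sample.int(2^(2^k), 20, replace = TRUE) - 1 else
        sample.int(65536, 20, replace = TRUE) - 1 +
          (sample.int(65536, 20, replace = TRUE) - 1) * 65536
      f <- bf(bits, k)
      expect_equal(bits(bf_from_string(bf_to_string(f), k)), bits(f))
      expect_equal(bits(bf_from_outputs(bf_outputs(f), k)), bits(f))
    }
  })
})

test_that("bias counts ones and pairs with the complement", {
  h <- bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3)
  expect_equal(bf_bias(h), 5L)
  expect_equal(bf_bias(bf(0, 3)), 0L)
  # a 3-input function with three ones, as in a typical truth-table figure
  expect_equal(bf_bias(bf_from_outputs(c(0, 1, 0, 0, 1, 0, 1, 0), 3)), 3L)
  withr::with_seed(5, {
    f <- bf(sample.int(65536, 50) - 1, 4)
    expect_equal(bf_bias(f) + bf_bias(bf_complement(f)), rep(16L, 50))
    expect_equal(bits(bf_complement(bf_complement(f))), bits(f))
  })
  expect_equal(bf_parity(bf(c(1, 3), 2)), c("odd", "even"))
})

test_that("complement inverts the output vector", {
  f <- bf_from_outputs(c(0, 0, 1, 0), 2)
  expect_equal(bf_outputs(bf_complement(f))[1, ], c(1, 1, 0, 1))
  expect_equal(bits(bf_complement(bf(0, 2))), 15)  # const 0 -> const 1
})

test_that("input permutation relabels variables and respects the group action", {
  h <- bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3)  # x1 + x2.x3
  # swapping x1 and x2 gives x2 + x1.x3
  rows <- 0:7
  x1 <- rows %/% 4 %% 2; x2 <- rows %/% 2 %% 2; x3 <- rows %% 2
  expect_equal(bits(bf_permute(h, c(2, 1, 3))),
               sum(pmax(x2, x1 * x3) * 2^rows))
  # cycling to x3 + x1.x2
  expect_equal(bits(bf_permute(h, c(3, 1, 2))),
               sum(pmax(x3, x1 * x2) * 2^rows))
  expect_equal(bits(bf_permute(h, 1:3)), bits(h))
  # fully symmetric functions are fixed by any permutation
  and3 <- bf(128, 3)
  expect_equal(bits(bf_permute(and3, c(3, 1, 2))), 128)
  expect_error(bf_permute(h, c(1, 2)), "permutation")
  withr::with_seed(21, {
    for (i in 1:200) {
      k <- sample(2:5, 1)
      f <- if (k <= 4) bf(sample.int(2^(2^k), 1) - 1, k) else
        bf(sample.int(65536, 1) - 1 + (sample.int(65536, 1) - 1) * 65536, k)
      p <- sample(k); q <- sample(k)
      expect_equal(bits(bf_permute(bf_permute(f, p), q)),
                   bits(bf_permute(f, q[p])))
    }
  })
})

test_that("input negation flips one variable and is an involution", {
  a_or_b <- bf(14, 2)  # a + b
  # a + NOT b: outputs 1,0 swap on the b axis -> rows (a,b): 00->1, 01->0? no:
  # f(a,b) = a OR NOT b gives 1,0,1,1 on rows 00,01,10,11
  expect_equal(bf_outputs(bf_negate_input(a_or_b, 2))[1, ], c(1, 0, 1, 1))
  withr::with_seed(3, {
    f <- bf(sample.int(65536, 20) - 1, 4)
    for (i in 1:4) {
      expect_equal(bits(bf_negate_input(bf_negate_input(f, i), i)),
                   bits(f))
    }
  })
  expect_equal(bits(bf_negate_input(bf(0, 3), 1)), 0)
  expect_error(bf_negate_input(a_or_b, 3), "1..2")
})

test_that("isomorphism sets are complete and closed", {
  iso <- bf_isomorphisms(bf(14, 2))  # a + b
  a_or_b <- bf(14, 2)
  expected <- sort(unique(c(
    bits(a_or_b),
    bits(bf_negate_input(a_or_b, 1)),
    bits(bf_negate_input(a_or_b, 2)),
    bits(bf_negate_input(bf_negate_input(a_or_b, 1), 2))
  )))
  expect_equal(bits(iso), expected)
  expect_length(iso, 4)
  expect_equal(bits(bf_isomorphisms(bf(0, 3))), 0)   # constants are alone
  expect_equal(bits(bf_isomorphisms(bf(6, 2))), c(6, 9))  # XOR, XNOR
  # closure: any transform of any member stays inside, size divides 2^k k!
  withr::with_seed(9, {
    for (i in 1:10) {
      k <- sample(2:4, 1)
      f <- bf(sample.int(2^(2^k), 1) - 1, k)
      iso <- bf_isomorphisms(f)
      expect_true(bits(f) %in% bits(iso))
      expect_equal((2^k * factorial(k)) %% length(iso), 0)
      g <- iso[sample(length(iso), 1)]
      tr <- apply_signed_perm(g, sample(k), sample(0:1, k, replace = TRUE))
      expect_true(bits(tr) %in% bits(iso))
    }
  })
})

test_that("essential variables are detected from row pairs", {
  expect_equal(essential_variables(bf(0, 3)), integer(0))
  x2_only <- bf_from_outputs(c(0, 0, 1, 1, 0, 0, 1, 1), 3)
  expect_equal(essential_variables(x2_only), 2L)
  h <- bf_from_outputs(c(0, 0, 0, 1, 1, 1, 1, 1), 3)
  expect_equal(essential_variables(h), 1:3)
})
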