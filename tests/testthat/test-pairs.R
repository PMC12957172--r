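test_that("pair counts enumerate exact contingency tables", {
  profiles <- data.frame(patient_id = c("A", "A", "B"),
                         condition_code = c("x", "y", "x"),
                         stringsAsFactors = FALSE)
  pc <- count_pairs(profiles, c("A", "B"), c("x", "y"))
  expect_equal(pc$c_i, 2L)
  expect_equal(pc$c_j, 1L)
  expect_equal(pc$c_ij, 1L)
  expect_equal(pc$N, 2L)
  # disjoint conditions
  pc2 <- count_pairs(data.frame(patient_id = c("A", "B"),
                                condition_code = c("x", "y")),
                     c("A", "B"), c("x", "y"))
  expect_equal(pc2$c_ij, 0L)
})

test_that("pair counts match the brute-force double loop on random fixtures", {
  for (s in 1:10) {
    fx <- random_profiles(50, letters[1:6], p = 0.25, seed = 300 + s)
    fast <- count_pairs(fx$profiles, fx$patient_ids, letters[1:6])
    slow <- brute_pair_counts(fx$profiles, fx$patient_ids, letters[1:6])
    rownames(fast) <- rownames(slow) <- NULL
    expect_equal(fast$c_i, slow$c_i)
    expect_equal(fast$c_j, slow$c_j)
    expect_equal(fast$c_ij, slow$c_ij)
    expect_equal(fast$code_i, slow$code_i)
  }
})

test_that("SCI follows the cosine formula with its boundary cases", {
  expect_equal(sci(6, 6, 6), 1)
  expect_equal(sci(4, 9, 0), 0)
  expect_equal(sci(4, 9, 3), 0.5)
  expect_true(is.na(sci(0, 5, 0)))
})

test_that("phi equals the Pearson correlation of indicator vectors", {
  # independence: c_ij * N = c_i * c_j
  expect_equal(phi_coefficient(10, 10, 1, 100), 0)
  expect_equal(phi_coefficient(5, 5, 5, 10), 1)
  expect_true(is.na(phi_coefficient(0, 5, 0, 10)))
  expect_true(is.na(phi_coefficient(10, 5, 5, 10)))
  for (s in 1:20) {
    fx <- random_profiles(40, c("u", "v"), p = 0.4, seed = 500 + s)
    pc <- count_pairs(fx$profiles, fx$patient_ids, c("u", "v"))
    oracle <- brute_phi(fx$profiles, fx$patient_ids, "u", "v")
    mine <- phi_coefficient(pc$c_i, pc$c_j, pc$c_ij, pc$N)
    if (is.na(oracle)) expect_true(is.na(mine))
    else expect_equal(mine, oracle)
  }
})

test_that("t-value uses c_ij-based degrees of freedom as defined", {
  expect_equal(t_value(0, 10), 0)
  expect_equal(t_value(0.5, 11), 0.5 * 3 / sqrt(0.75))
  expect_true(is.na(t_value(0.4, 2)))      # c_ij < 3 undefined
  expect_equal(t_value(1, 10), Inf)
  expect_equal(t_value(-1, 10), -Inf)
  # sign parity
  withr::with_seed(3, {
    ph <- stats::runif(20, -0.99, 0.99)
    expect_equal(sign(t_value(ph, rep(10, 20))), sign(ph))
  })
  # conventional N-based alternative remains available
  expect_equal(t_value(0.5, 11, N = 27, df_from = "N"), 0.5 * 5 / sqrt(0.75))
})

test_that("SCI and phi are symmetric, bounded and monotone in c_ij", {
  for (s in 1:10) {
    fx <- random_profiles(30, letters[1:5], p = 0.35, seed = 700 + s)
    st <- pair_statistics(count_pairs(fx$profiles, fx$patient_ids,
                                      letters[1:5]))
    expect_true(all(st$sci >= 0 & st$sci <= 1, na.rm = TRUE))
    expect_true(all(st$phi >= -1 & st$phi <= 1, na.rm = TRUE))
    # symmetry under swapping i and j
    expect_equal(sci(st$c_j, st$c_i, st$c_ij), st$sci)
    expect_equal(phi_coefficient(st$c_j, st$c_i, st$c_ij, st$N), st$phi)
  }
  # monotone: increasing c_ij with c_i, c_j, N fixed
  cij <- 1:8
  expect_true(all(diff(sci(10, 12, cij)) > 0))
  expect_true(all(diff(phi_coefficient(10, 12, cij, 40)) > 0))
  # invariance under duplicating the whole subgroup: all counts double
  expect_equal(sci(2 * 7, 2 * 9, 2 * 4), sci(7, 9, 4))
  expect_equal(phi_coefficient(2 * 7, 2 * 9, 2 * 4, 2 * 30),
               phi_coefficient(7, 9, 4, 30))
})

test_that("cut-off derivation handles degenerate inputs", {
  empty <- pair_statistics(data.frame(
    code_i = c("a", "a"), code_j = c("b", "c"),
    c_i = c(4L, 4L), c_j = c(5L, 3L), c_ij = c(0L, 0L), N = 20L))
  co <- derive_cutoff(empty)
  expect_equal(co$q, 0L)
  expect_equal(co$e, 0L)
  expect_equal(co$sci_cutoff, Inf)
  expect_equal(nrow(significant_edges(empty, co)), 0)
})

test_that("every pair passing both criteria is kept, none below the mean", {
  # three strong pairs above the mean joint count plus one weak positive
  # pair that drags the mean down: e counts exactly the strong ones, the
  # cut-off is the e-th ranked SCI and the kept edges are the strong pairs
  st <- data.frame(
    code_i = c("a", "a", "b", "d"),
    code_j = c("b", "c", "c", "e"),
    c_i = c(12L, 12L, 12L, 6L), c_j = c(12L, 11L, 11L, 5L),
    c_ij = c(10L, 10L, 9L, 1L), N = 60L,
    stringsAsFactors = FALSE
  )
  st <- pair_statistics(st)
  expect_true(all(st$t[1:3] > 1.96))
  co <- derive_cutoff(st)
  expect_equal(co$q, 4L)
  expect_equal(co$e, 3L)
  ed <- significant_edges(st, co)
  expect_setequal(paste(ed$code_i, ed$code_j), c("a b", "a c", "b c"))
  expect_equal(co$sci_cutoff, sort(st$sci[1:3])[1])
  # strict mean rule: a lone positive pair can never exceed its own mean
  lone <- pair_statistics(data.frame(
    code_i = "a", code_j = "b", c_i = 10L, c_j = 10L, c_ij = 9L, N = 20L,
    stringsAsFactors = FALSE))
  expect_equal(derive_cutoff(lone)$e, 0L)
})

test_that("cut-off and edge set match exhaustive enumeration on fixtures", {
  for (s in 1:30) {
    fx <- random_profiles(40, letters[1:6], p = 0.3, seed = 900 + s)
    st <- pair_statistics(count_pairs(fx$profiles, fx$patient_ids,
                                      letters[1:6]))
    co <- derive_cutoff(st)
    oracle <- brute_cutoff(st)
    expect_equal(co$q, as.integer(oracle$q))
    expect_equal(co$e, as.integer(oracle$e))
    ed <- significant_edges(st, co)
    expect_equal(sort(paste(ed$code_i, ed$code_j, sep = "|")), oracle$edges)
    expect_equal(nrow(ed), co$e)
    if (co$e > 0) {
      expect_equal(min(ed$weight), co$sci_cutoff)
    }
  }
})

test_that("ties at the cut-off rank break by c_ij then pair id", {
  st <- data.frame(
    code_i = c("a", "a", "b", "a"),
    code_j = c("b", "c", "c", "d"),
    c_i = c(10L, 10L, 10L, 10L), c_j = c(10L, 10L, 10L, 10L),
    c_ij = c(5L, 8L, 5L, 5L), N = 40L,
    stringsAsFactors = FALSE
  )
  st$sci <- c(0.5, 0.5, 0.5, 0.4)
  st$phi <- rep(0.5, 4)
  st$t <- rep(3, 4)
  co <- list(q = 4L, e = 2L, sci_cutoff = 0.5, n_edges = 2L)
  ed <- significant_edges(st, co)
  # sci ties at 0.5: (a,c) wins on higher c_ij, then (a,b) beats (b,c)
  # lexicographically
  expect_equal(paste(ed$code_i, ed$code_j), c("a c", "a b"))
})
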