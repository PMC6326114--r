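test_that("code weights match the closed form and its symmetries", {
  w <- code_weights(pi_B = 0.1, eps_minus = 0.01, eps_plus = 0.01)
  expect_equal(w$w11, log(0.99 / 0.1), tolerance = 1e-12)
  expect_equal(w$w00, log(0.99 / 0.9), tolerance = 1e-12)
  expect_equal(w$w10, log(0.01 / 0.9), tolerance = 1e-12)
  expect_equal(w$w01, log(0.01 / 0.1), tolerance = 1e-12)

  # at prevalence 1/2 and equal discrepancy rates, presence and absence
  # are exchangeable
  for (e in c(0.01, 0.2)) {
    ws <- code_weights(0.5, e, e)
    expect_equal(ws$w11, log(2 * (1 - e)))
    expect_equal(ws$w00, log(2 * (1 - e)))
    expect_equal(ws$w10, log(2 * e))
    expect_equal(ws$w01, log(2 * e))
  }
  w0 <- code_weights(0.5, 0.5, 0.5)
  expect_equal(unname(unlist(w0[c("w11", "w00", "w10", "w01")])),
               rep(0, 4))

  expect_error(code_weights(c(x = 0.5, y = 0), 0.01, 0.01), "code.*y")
  expect_error(code_weights(0.5, 0, 0.01, clip = FALSE), "\\(0,1\\)")
})

test_that("weight ordering w11 > w00 holds for rare codes with equal eps", {
  set.seed(5)
  p <- runif(200, 0.001, 0.499)
  e <- runif(200, 0.001, 0.9)
  w <- code_weights(p, e, e)
  expect_true(all(w$w11 > w$w00))
})

test_that("decomposed similarity equals the naive per-pair per-code sum", {
  A <- random_records(6, 8, p = 0.3, prefix = "a", seed = 21)
  B <- random_records(5, 8, p = 0.3, prefix = "b", seed = 22)
  al <- align_codes(A, B)
  pb <- estimate_prevalence(B)[match(al$codes, colnames(B))]
  w <- code_weights(pb, 0.05, 0.02, codes = al$codes)
  s <- similarity_scores(A, B, w, al)
  expect_lt(max(abs(unclass(s) - oracle_similarity(A, B, w, al))), 1e-10)

  # single shared present code reduces to w11; all-absent pair to sum(w00)
  w1 <- code_weights(0.1, 0.01, 0.01)
  A1 <- binary_records(matrix(1, 1, 1, dimnames = list("a1", "c1")))
  B1 <- binary_records(matrix(1, 1, 1, dimnames = list("b1", "c1")))
  expect_equal(as.numeric(similarity_scores(A1, B1, w1)), log(0.99 / 0.1))
  A0 <- binary_records(matrix(0, 1, 8, dimnames = list("a1", letters[1:8])))
  B0 <- binary_records(matrix(0, 1, 8, dimnames = list("b1", letters[1:8])))
  w8 <- code_weights(runif(8, 0.05, 0.4), 0.01, 0.01)
  expect_equal(as.numeric(similarity_scores(A0, B0, w8)), sum(w8$w00))

  expect_error(similarity_scores(A, B, w1, al), "weights cover")
})

test_that("directed posteriors follow the closed form with a no-match cell", {
  s1 <- as_similarity(matrix(0, 1, 1))
  p1 <- directed_posterior(s1, 0.5, "A_to_B")
  expect_equal(as.numeric(p1), 0.5)

  s2 <- as_similarity(matrix(c(1, 2), 1, 2))
  p2 <- directed_posterior(s2, 0.1, "A_to_B")
  expect_equal(as.numeric(p2), oracle_posterior_row(c(1, 2), 0.1),
               tolerance = 1e-12)
  expect_equal(as.numeric(p2), c(0.14224, 0.38672), tolerance = 1e-4)
  expect_equal(unname(attr(p2, "no_match")), 0.47104, tolerance = 1e-4)

  expect_error(directed_posterior(as_similarity(matrix(Inf, 1, 1)), 0.1),
               "finite")
  expect_error(directed_posterior(s1, 1), "pi_0")
})

test_that("posterior rows/columns plus no-match mass are exactly normalized", {
  set.seed(31)
  for (rep in 1:20) {
    s <- as_similarity(matrix(rnorm(12 * 9, sd = 300), 12, 9))
    pa <- directed_posterior(s, runif(1, 0.01, 0.5), "A_to_B")
    expect_lt(max(abs(rowSums(unclass(pa)) + attr(pa, "no_match") - 1)), 1e-12)
    pb <- directed_posterior(s, runif(1, 0.01, 0.5), "B_to_A")
    expect_lt(max(abs(colSums(unclass(pb)) + attr(pb, "no_match") - 1)), 1e-12)
    expect_true(all(unclass(pa) >= 0 & unclass(pa) <= 1))
  }
})

test_that("posteriors are monotone in the pair's similarity", {
  s <- as_similarity(matrix(c(1, 2, 0.5, 1.5), 2, 2))
  for (dir in c("A_to_B", "B_to_A")) {
    base <- directed_posterior(s, 0.2, dir)[1, 1]
    s_up <- s; s_up[1, 1] <- s[1, 1] + 0.7
    expect_gt(directed_posterior(as_similarity(s_up), 0.2, dir)[1, 1], base)
  }
})

test_that("averaging posteriors is the elementwise mean with checks", {
  s <- as_similarity(matrix(rnorm(6), 2, 3))
  pa <- directed_posterior(s, 0.3, "A_to_B")
  pb <- directed_posterior(s, 0.3, "B_to_A")
  av <- average_posterior(pa, pb)
  expect_equal(as.numeric(av), as.numeric((unclass(pa) + unclass(pb)) / 2))
  expect_identical(dimnames(av), dimnames(pa))
  expect_identical(attr(av, "direction"), "averaged")
  expect_null(attr(av, "no_match"))
  # idempotence on identical inputs, zero on zero
  pb_same <- structure(unclass(pa), direction = "B_to_A",
                       class = class(pa), dimnames = dimnames(pa))
  expect_equal(as.numeric(average_posterior(pa, pb_same)), as.numeric(pa))
  expect_error(average_posterior(pb, pa), "A_to_B")
  s3 <- as_similarity(matrix(rnorm(4), 2, 2))
  expect_error(average_posterior(pa, directed_posterior(s3, 0.3, "B_to_A")),
               "shapes")
})

test_that("swapping the datasets transposes the averaged posterior", {
  # fully exchangeable hyper-parameters: equal eps and prevalence 1/2, so
  # that the (1,0) and (0,1) weights coincide and the per-code LLR is
  # symmetric in its two arguments
  A <- random_records(6, 10, p = 0.3, prefix = "a", seed = 41)
  B <- random_records(4, 10, p = 0.3, prefix = "b", seed = 42)
  al <- align_codes(A, B)
  w <- code_weights(rep(0.5, 10), 0.05, 0.05, codes = al$codes)
  post_ab <- average_posterior(
    directed_posterior(similarity_scores(A, B, w, al), 0.2, "A_to_B"),
    directed_posterior(similarity_scores(A, B, w, al), 0.2, "B_to_A"))
  al2 <- align_codes(B, A)
  post_ba <- average_posterior(
    directed_posterior(similarity_scores(B, A, w, al2), 0.2, "A_to_B"),
    directed_posterior(similarity_scores(B, A, w, al2), 0.2, "B_to_A"))
  expect_equal(as.numeric(unclass(post_ab)),
               as.numeric(t(unclass(post_ba))), tolerance = 1e-12)
})

test_that("thresholding declares exactly the pairs reaching alpha", {
  post <- as_averaged_posterior(matrix(c(0.95, 0.01, 0.02, 0.40), 2, 2))
  m5 <- match_pairs(post, 0.5)
  expect_identical(paste(m5$id_a, m5$id_b), "a1 b1")
  m9 <- match_pairs(post, 0.9)
  expect_identical(paste(m9$id_a, m9$id_b), "a1 b1")
  m3 <- match_pairs(post, 0.3)
  expect_setequal(paste(m3$id_a, m3$id_b), c("a1 b1", "a2 b2"))
  # ties at the threshold count as matches
  expect_identical(nrow(match_pairs(as_averaged_posterior(matrix(0.5, 1, 1)),
                                    0.5)), 1L)
  expect_error(match_pairs(directed_posterior(as_similarity(matrix(0, 1, 1)),
                                              0.5, "A_to_B"), 0.5),
               "averaged")
})
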