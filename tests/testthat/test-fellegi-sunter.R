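test_that("agreement scores match hand values and the zero-information case", {
  A1 <- binary_records(matrix(1, 1, 1, dimnames = list("a1", "k")))
  B1 <- binary_records(matrix(1, 1, 1, dimnames = list("b1", "k")))
  B0 <- binary_records(matrix(0, 1, 1, dimnames = list("b1", "k")))
  model <- dxlink:::fs_model(0.9, 0.5, 0.1, 1L, TRUE, numeric(0), "k")
  expect_equal(as.numeric(fs_scores(model, A1, B1)), log(0.9 / 0.5),
               tolerance = 1e-12)
  expect_equal(as.numeric(fs_scores(model, A1, B0)), log(0.1 / 0.5),
               tolerance = 1e-12)
  same <- suppressWarnings(dxlink:::fs_model(0.7, 0.7, 0.1, 1L, TRUE,
                                             numeric(0), "k"))
  expect_equal(as.numeric(fs_scores(same, A1, B1)), 0)
  expect_equal(as.numeric(fs_scores(same, A1, B0)), 0)
})

test_that("scores treat (0,0) and (1,1) concordances identically", {
  # the classical method's known weakness on sparse binary codes
  model <- dxlink:::fs_model(c(0.9, 0.9), c(0.4, 0.4), 0.1, 1L, TRUE,
                             numeric(0), c("k1", "k2"))
  both1 <- binary_records(matrix(c(1, 1), 1, 2, dimnames = list("a", c("k1", "k2"))))
  both0 <- binary_records(matrix(c(0, 0), 1, 2, dimnames = list("b", c("k1", "k2"))))
  s11 <- fs_scores(model, both1, both1)
  s00 <- fs_scores(model, both0, both0)
  expect_equal(as.numeric(s11), as.numeric(s00))
})

test_that("EM recovers m and u on a seeded simulation and is monotone", {
  set.seed(201)
  K <- 40; n <- 6
  Xa <- matrix(rbinom(n * K, 1, 0.5), n, K,
               dimnames = list(paste0("a", 1:n), sprintf("c%02d", 1:K)))
  flip <- matrix(rbinom(n * K, 1, 0.05), n, K)  # agreement rate 0.95
  Xb <- abs(Xa - flip)
  rownames(Xb) <- paste0("b", 1:n)
  A <- binary_records(Xa); B <- binary_records(Xb)
  fit <- fs_em(A, B, p0 = 1 / 6)
  expect_lt(abs(mean(fit$m) - 0.95), 0.1)
  expect_lt(abs(mean(fit$u) - 0.5), 0.1)
  expect_true(all(diff(fit$log_likelihood) > -1e-8))
  expect_true(fit$converged)
})

test_that("bilinear, pair-list and compressed EM paths agree with the oracle", {
  A <- random_records(7, 12, p = 0.4, prefix = "a", seed = 202)
  B <- random_records(5, 12, p = 0.4, prefix = "b", seed = 203)
  al <- align_codes(A, B)
  all_mask <- matrix(TRUE, 7, 5)
  f_bil <- suppressWarnings(fs_em(A, B, al, max_iter = 40L))
  f_raw <- suppressWarnings(fs_em(A, B, al, blocking = all_mask,
                                  compress = FALSE, max_iter = 40L))
  f_cmp <- suppressWarnings(fs_em(A, B, al, blocking = all_mask,
                                  compress = TRUE, max_iter = 40L))
  pa <- colMeans(unclass(A))[al$codes]
  pb <- colMeans(unclass(B))[al$codes]
  orc <- oracle_fs_em(A, B, al, m = rep(0.9, 12),
                      u = dxlink:::clip_unit(1 - pa - pb + 2 * pa * pb, 1e-6),
                      p = 1 / 7, max_iter = 40L)
  expect_equal(unname(f_bil$m), unname(f_raw$m), tolerance = 1e-8)
  expect_equal(unname(f_raw$m), unname(f_cmp$m), tolerance = 1e-8)
  expect_equal(unname(f_bil$u), unname(f_cmp$u), tolerance = 1e-8)
  expect_equal(f_bil$p, f_cmp$p, tolerance = 1e-8)
  expect_equal(unname(f_bil$m), unname(orc$m), tolerance = 1e-6)
  expect_equal(unname(f_bil$u), unname(orc$u), tolerance = 1e-6)
  expect_equal(f_bil$p, orc$p, tolerance = 1e-6)
})

test_that("a single fully-agreeing code is a documented degenerate case", {
  A <- binary_records(matrix(1, 3, 1, dimnames = list(paste0("a", 1:3), "k")))
  B <- binary_records(matrix(1, 2, 1, dimnames = list(paste0("b", 1:2), "k")))
  expect_warning(fit <- fs_em(A, B), "unidentifiable")
  expect_gt(min(fit$m, fit$u), 0.99)
})

test_that("one-to-one matching keeps row-and-column maxima with ties", {
  sc <- structure(matrix(c(5, 1, 1, 4), 2, 2,
                         dimnames = list(c("a1", "a2"), c("b1", "b2"))),
                  class = c("fs_scores", "matrix"))
  m <- fs_match_best(sc, 0)
  expect_setequal(paste(m$id_a, m$id_b), c("a1 b1", "a2 b2"))

  sct <- structure(matrix(c(5, 1, 5, 4), 2, 2,
                          dimnames = list(c("a1", "a2"), c("b1", "b2"))),
                   class = c("fs_scores", "matrix"))
  mt <- fs_match_best(sct, 0)
  expect_setequal(paste(mt$id_a, mt$id_b), c("a1 b1", "a1 b2"))

  expect_identical(nrow(fs_match_best(sc, 99)), 0L)

  # row-only mode can keep more pairs than row-and-column
  m_row <- fs_match_best(sct, 0, mode = "row_only")
  expect_true(all(paste(mt$id_a, mt$id_b) %in% paste(m_row$id_a, m_row$id_b)))
  expect_gte(nrow(m_row), nrow(mt))
})

test_that("plain classification thresholds scores; one-to-one is a subset", {
  sc <- structure(matrix(c(5, 1, 1, 4), 2, 2,
                         dimnames = list(c("a1", "a2"), c("b1", "b2"))),
                  class = c("fs_scores", "matrix"))
  m2 <- fs_match_all(sc, 2)
  expect_setequal(paste(m2$id_a, m2$id_b), c("a1 b1", "a2 b2"))
  expect_identical(nrow(fs_match_all(sc, -Inf)), 4L)

  set.seed(204)
  A <- random_records(8, 15, p = 0.3, prefix = "a", seed = 205)
  B <- random_records(6, 15, p = 0.3, prefix = "b", seed = 206)
  fit <- suppressWarnings(fs_em(A, B, max_iter = 50L))
  s <- fs_scores(fit, A, B)
  for (thr in c(-2, 0, 2)) {
    one <- paste(fs_match_best(s, thr)$id_a, fs_match_best(s, thr)$id_b)
    all_ <- paste(fs_match_all(s, thr)$id_a, fs_match_all(s, thr)$id_b)
    expect_true(all(one %in% all_))
  }
})

test_that("blocking masks admissibility and blocked pairs are never returned", {
  expect_identical(blocking_mask(c("x", "y"), c("x", "x")),
                   rbind(c(TRUE, TRUE), c(FALSE, FALSE)))
  expect_true(all(blocking_mask(rep("z", 3), rep("z", 2))))
  expect_warning(mask0 <- blocking_mask(c("x"), c("y")), "no pair")
  expect_false(any(mask0))
  expect_error(blocking_mask(c("x", NA), "x"), "every patient")

  A <- random_records(4, 10, p = 0.5, prefix = "a", seed = 207)
  B <- random_records(4, 10, p = 0.5, prefix = "b", seed = 208)
  mask <- blocking_mask(c(1, 1, 2, 2), c(1, 2, 2, 1))
  fit <- suppressWarnings(fs_em(A, B, blocking = mask, max_iter = 50L))
  s <- fs_scores(fit, A, B, blocking = mask)
  expect_true(all(is.na(unclass(s)[!mask])))
  got <- fs_match_all(s, -Inf)
  blocked <- !mask[cbind(match(got$id_a, rownames(s)), match(got$id_b, colnames(s)))]
  expect_false(any(blocked))
})
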