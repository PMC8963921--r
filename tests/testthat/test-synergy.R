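test_that("NNMF recovers exact low-rank structure", {
  # rank-1 outer product
  w <- c(0.2, 1, 0.5, 0.1, 0.8)
  c1 <- abs(sin(seq(0, pi, length.out = 40))) + 0.05
  M1 <- outer(w, c1)
  s1 <- extract_synergies(M1, N = 1, seed = 1, restarts = 5)
  expect_gte(s1$reconstruction_quality, 99.99)

  # exact rank-4 synthetic construction
  act <- gen_activations(synth_config())
  s4 <- extract_synergies(act$M, N = 4, seed = 1, restarts = 20)
  expect_gte(s4$reconstruction_quality, 99.5)

  M1[2, 3] <- -0.1
  expect_error(extract_synergies(M1, N = 1), class = "sts_validation_error")
  expect_error(extract_synergies(abs(M1), N = 10), class = "sts_validation_error")
})

test_that("Frobenius error is non-increasing across multiplicative updates", {
  M <- gen_activation_matrix(synth_config(seed = 5), seed = 5)
  syn <- extract_synergies(M, N = 4, seed = 2, restarts = 3)
  expect_true(all(diff(syn$error_trace) <= 1e-9))
})

test_that("reconstruction quality is the Frobenius variance accounted for", {
  set.seed(31)
  M <- matrix(runif(50, 0.1, 1), 5)
  # perfect reconstruction: 100%
  s <- extract_synergies(M, N = 5, seed = 1, restarts = 5)
  expect_equal(reconstruction_quality(M, s$W, s$C), s$reconstruction_quality)
  # zero reconstruction: 0%
  expect_equal(reconstruction_quality(M, matrix(0, 5, 2), matrix(0, 2, 10)), 0)
  # error norm at a quarter of the signal norm: 75%
  Mq <- matrix(2, 4, 4); Wq <- matrix(1, 4, 1); Cq <- matrix(1, 1, 4)
  expect_equal(reconstruction_quality(Mq, Wq, Cq), 75)
  expect_error(reconstruction_quality(matrix(0, 2, 2), matrix(0, 2, 1), matrix(0, 1, 2)),
               class = "sts_degenerate_error")
})

test_that("synergy features report peak level and first-maximum timing", {
  syn <- list(W = diag(3), C = rbind(rep(2, 11),
                                     2 * exp(-0.5 * ((0:10 - 4) / 1.5)^2),
                                     seq(0, 1, length.out = 11)),
              N = 3)
  class(syn) <- "synergy_set"
  f <- synergy_features(syn)
  expect_equal(f$peak_time_pct[1], 0)    # constant: first-index tie-break
  expect_equal(f$peak_time_pct[2], 40)   # bump centered at 40%
  expect_equal(f$peak_level[1], 2)
  syn2 <- syn; syn2$C <- 2 * syn$C
  f2 <- synergy_features(syn2)
  expect_equal(f2$peak_level, 2 * f$peak_level)
  expect_equal(f2$peak_time_pct, f$peak_time_pct)
})

test_that("column rescaling of W with compensating C leaves the product intact", {
  M <- gen_activation_matrix(synth_config(seed = 9), seed = 9)
  syn <- extract_synergies(M, N = 4, seed = 1, restarts = 5)
  expect_equal(unname(apply(syn$W, 2, max)), rep(1, 4))
  scl <- c(2, 0.5, 3, 1.5)
  W2 <- sweep(syn$W, 2, scl, `*`)
  C2 <- sweep(syn$C, 1, scl, `/`)
  expect_equal(W2 %*% C2, syn$W %*% syn$C, tolerance = 1e-12)
})

test_that("synergy matching recovers permutations by cosine similarity", {
  W <- synergy_reference_templates()
  ref <- structure(list(W = W, C = matrix(1, 4, 10), N = 4), class = "synergy_set")
  expect_equal(match_synergies(ref, ref), 1:4)

  swap <- c(3, 1, 4, 2)
  cand <- structure(list(W = W[, swap], C = matrix(1, 4, 10), N = 4),
                    class = "synergy_set")
  perm <- match_synergies(cand, ref)
  expect_equal(perm, order(swap))
  expect_equal(reorder_synergies(cand, perm)$W, W, ignore_attr = TRUE)

  # orthogonal one-hot spatial vectors: exact recovery
  hot <- diag(4)[, c(2, 4, 1, 3)]
  cand2 <- structure(list(W = hot, C = matrix(1, 4, 10), N = 4), class = "synergy_set")
  perm2 <- match_synergies(cand2, diag(4))
  expect_equal(hot[, perm2], diag(4), ignore_attr = TRUE)

  expect_error(match_synergies(cand, structure(list(W = W[, 1:3], N = 3),
                                               class = "synergy_set")),
               class = "sts_validation_error")
})

test_that("nested synergy capacity never reduces reconstruction quality", {
  M <- gen_activation_matrix(synth_config(seed = 12), seed = 12)[1:6, ]
  s_low <- extract_synergies(M, N = 3, seed = 1, restarts = 8)
  s_full <- extract_synergies(M, N = 6, seed = 1, restarts = 8)
  expect_gte(s_full$reconstruction_quality, s_low$reconstruction_quality)
})

test_that("four synergies suffice for noisy four-template data", {
  M <- gen_activation_matrix(synth_config(seed = 21, noise_sd = 0.05), seed = 21)
  syn <- extract_synergies(M, N = 4, seed = 1, restarts = 20)
  expect_gte(syn$reconstruction_quality, 90)
})

test_that("longitudinal tests dispatch by group count with calibrated p-values", {
  # identical two groups: no evidence of change
  g <- c(1:10, 1:10)
  d <- rep(c(1, 2), each = 10)
  st <- longitudinal_stats(g, d)
  expect_equal(st$test, "wilcoxon_rank_sum")
  expect_gt(st$p_value, 0.9)

  # complete separation
  st2 <- longitudinal_stats(c(1:10, 101:110), d)
  expect_lt(st2$p_value, 0.001)

  # three identical groups exercise Kruskal-Wallis; null p-values calibrated
  d3 <- rep(1:3, each = 8)
  st3 <- longitudinal_stats(c(1:8, 1:8, 1:8), d3)
  expect_equal(st3$test, "kruskal_wallis")
  set.seed(2024)
  cover <- mean(replicate(100, {
    longitudinal_stats(rnorm(24), d3)$p_value > 0.05
  }))
  expect_gte(cover, 0.88)

  expect_error(longitudinal_stats(1:5, c(1, 1, 1, 1, 2)),
               class = "sts_insufficient_data_error")
  expect_error(longitudinal_stats(1:5, rep(1, 5)),
               class = "sts_insufficient_data_error")
})

test_that("percent change is the relative first-to-last difference", {
  expect_equal(percent_change(2, 4), 100)
  expect_equal(percent_change(4, 2), -50)
  expect_equal(percent_change(1.0, 9.92), 892)
  expect_error(percent_change(0, 1), class = "sts_degenerate_error")
})
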