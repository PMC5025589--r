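single_state_model <- function(emis_row) {
  hmm_model("s1", "g", 1, matrix(1, 1, 1), matrix(emis_row, 1, 20))
}

test_that("single-state model has closed-form likelihood and a trivial path", {
  e <- rep(0.75 / 19, 20)
  e[1L] <- 0.25  # P(A) = 0.25
  m <- single_state_model(e)
  expect_equal(forward_loglik(m, "AAAA"), 4 * log(0.25), tolerance = 1e-12)
  v <- viterbi_decode(m, "AAAA")
  expect_equal(v$path, rep(1L, 4L))
  expect_equal(v$logp, 4 * log(0.25), tolerance = 1e-12)
})

test_that("forward and Viterbi agree with brute-force path enumeration", {
  for (S in 1:3) {
    for (L in c(1L, 3L, 5L, 7L)) {
      for (seed in c(101, 202)) {
        m <- random_hmm(S, seed + S + L)
        set.seed(seed * L + S)
        obs <- sample(c(0:19, -1L), L, replace = TRUE,
                      prob = c(rep(1, 20), 2))  # include ambiguous residues
        expect_equal(forward_loglik(m, obs), brute_loglik(m, obs),
                     tolerance = 1e-9)
        v <- viterbi_decode(m, obs)
        expect_equal(v$logp, brute_viterbi_logp(m, obs), tolerance = 1e-9)
        # returned path attains the reported maximum
        expect_equal(path_logp(m, v$path, obs), v$logp, tolerance = 1e-9)
      }
    }
  }
})

test_that("forward likelihood is never smaller than the Viterbi joint probability", {
  for (seed in 1:5) {
    m <- random_hmm(3, seed)
    set.seed(seed)
    obs <- sample(0:19, 30, replace = TRUE)
    expect_gte(forward_loglik(m, obs), viterbi_decode(m, obs)$logp - 1e-12)
  }
})

test_that("log-space forward matches scaled-arithmetic forward up to 5000 residues", {
  m <- build_ta_model(2L)
  set.seed(42)
  for (L in c(200L, 5000L)) {
    obs <- sample(0:19, L, replace = TRUE)
    ours <- forward_loglik(m, obs)
    expect_true(is.finite(ours))
    expect_equal(ours, scaled_forward(m, obs), tolerance = 1e-9)
  }
})

test_that("Baum-Welch log-likelihood trace is monotone and preserves structure", {
  gen <- make_generator("TA")
  set.seed(5)
  seqs <- replicate(15, sample_hmm(gen, sample(60:120, 1))$sequence)
  m0 <- build_ta_model(2L)
  fit <- baum_welch(m0, seqs, max_iter = 8L)
  expect_true(all(diff(fit$trace) >= -1e-8))
  # structural zeros preserved, all rows still normalised
  expect_true(all(fit$model$trans[m0$trans == 0] == 0))
  expect_true(all(fit$model$init[m0$init == 0] == 0))
  expect_silent(validate_hmm(fit$model))
  # training from data sampled from the model itself does not decrease it
  fit1 <- baum_welch(gen, seqs, max_iter = 2L)
  expect_gte(fit1$trace[2], fit1$trace[1] - 1e-8)
})

test_that("E-step expected counts match exact path-enumeration posteriors", {
  m <- random_hmm(2, 77)
  set.seed(78)
  for (rep in 1:5) {
    obs <- sample(0:19, sample(2:5, 1), replace = TRUE)
    ls <- tailanchor:::model_logspace(m)
    got <- tailanchor:::bw_counts_cpp(ls$log_init, ls$log_trans, ls$log_emis, obs)
    want <- brute_counts(m, obs)
    expect_equal(as.numeric(got$init), want$init, tolerance = 1e-9)
    expect_equal(unname(got$trans), unname(want$trans), tolerance = 1e-9)
    expect_equal(unname(got$emis), unname(want$emis), tolerance = 1e-9)
    expect_equal(got$loglik, brute_loglik(m, obs), tolerance = 1e-9)
  }
})

test_that("sampling is reproducible, respects degenerate emissions and the initial law", {
  e <- rep(0, 20)
  e[match("L", AA_ALPHABET)] <- 1
  m <- single_state_model(e)
  expect_equal(sample_hmm(m, 5, seed = 1)$sequence, "LLLLL")

  ta <- build_ta_model(2L)
  s1 <- sample_hmm(ta, 60, seed = 99)
  s2 <- sample_hmm(ta, 60, seed = 99)
  expect_identical(s1, s2)

  # first-state frequencies follow the initial distribution (3-sigma binomial)
  set.seed(123)
  n <- 10000L
  first <- replicate(n, sample_hmm(ta, 60)$path[1L])
  p_tail <- mean(first == 1L)
  expect_lt(abs(p_tail - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(first %in% which(ta$init > 0)))
})

test_that("degenerate and invalid inputs are reported", {
  m <- build_ta_model(2L)
  expect_error(forward_loglik(m, ""), "empty")
  expect_error(encode_residues("AC1D"), "position 3")
  # hand-made zero emission: no admissible path
  e <- rep(0, 20); e[1L] <- 1
  expect_error(viterbi_decode(single_state_model(e), "C"), "no admissible path")
  # all sequences length 1 with a multi-state model
  expect_warning(baum_welch(m, c("A", "C"), max_iter = 1L),
                 "model longer than data")
})

test_that("ambiguous residues are emitted uniformly and stay class-neutral", {
  e1 <- rdirichlet1(20); e2 <- rdirichlet1(20)
  m1 <- single_state_model(e1)
  m2 <- single_state_model(e2)
  # X contributes log(1/20) under any model
  expect_equal(forward_loglik(m1, "AXA") - 2 * log(e1[1L]), log(1 / 20),
               tolerance = 1e-12)
  expect_equal(forward_loglik(m1, "X") - forward_loglik(m2, "X"), 0,
               tolerance = 1e-12)
})
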