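seg_df <- function(...) {
  rows <- list(...)
  data.frame(region = vapply(rows, `[[`, "", 1L),
             start = as.integer(vapply(rows, function(r) r[[2L]], 0)),
             end = as.integer(vapply(rows, function(r) r[[3L]], 0)),
             stringsAsFactors = FALSE)
}

test_that("scores are zero for identical models and normalised by length", {
  e <- rdirichlet1(20)
  one <- function(orient) hmm_model("s1", "g", 1, matrix(1, 1, 1),
                                    matrix(e, 1, 20), orientation = orient)
  bundle <- structure(list(ta = list("2" = one("C-to-N")), sp = one("N-to-C"),
                           mp = one("N-to-C"), meta = list()),
                      class = "model_bundle")
  set.seed(2)
  s <- random_protein(40)
  sc <- likelihood_scores(bundle, s)
  # a one-state model gives the same likelihood forwards and reversed
  expect_equal(sc$S_sp, 0, tolerance = 1e-12)
  expect_equal(sc$S_mp, 0, tolerance = 1e-12)
  # doubling the sequence leaves the per-residue score bounded (here, zero)
  sc2 <- likelihood_scores(bundle, paste0(s, s))
  expect_equal(sc2$S_sp, 0, tolerance = 1e-12)
  expect_error(likelihood_scores(bundle, ""), "empty")
})

test_that("reversed-coordinate mapping follows end = L - rev_start, start = L - rev_end", {
  ta <- build_ta_model(2L)
  # craft a reading-direction path whose TMD run occupies reversed [5, 22)
  path <- c(rep(match("tail1", ta$ids), 5L),
            match(paste0("TMD", 1:17), ta$ids),
            rep(match("globular", ta$ids), 78L))
  seg <- tailanchor:::path_to_segments(ta, path)
  tmdish <- seg[seg$region == "TMD", ]
  expect_equal(c(tmdish$start, tmdish$end), c(78L, 95L))  # [L-22, L-5)
  tail_seg <- seg[seg$region == "tail", ]
  expect_equal(c(tail_seg$start, tail_seg$end), c(95L, 100L))
  glob <- seg[seg$region == "globular", ]
  expect_equal(c(glob$start, glob$end), c(0L, 78L))
})

test_that("decoded segments tile the original sequence for C-to-N models", {
  ta <- build_ta_model(2L)
  set.seed(14)
  for (i in 1:10) {
    s <- random_protein(sample(50:200, 1L))
    seg <- decode_regions(ta, s)
    expect_equal(seg$start[1L], 0L)
    expect_equal(seg$end[nrow(seg)], nchar(s))
    expect_true(all(seg$start[-1L] == seg$end[-nrow(seg)]))
  }
})

test_that("the decoding rule distinguishes its three failure modes", {
  ok <- seg_df(list("globular", 0, 75), list("cap", 75, 77),
               list("TMD", 77, 95), list("tail", 95, 102))  # TMD 18, tail 7
  expect_true(decoding_rule(ok)$verdict)
  expect_true(is.na(decoding_rule(ok)$reason))

  long_tail <- seg_df(list("globular", 0, 49), list("TMD", 49, 69),
                      list("tail", 69, 100))  # TMD 20, tail 31
  r <- decoding_rule(long_tail)
  expect_false(r$verdict)
  expect_equal(r$reason, "tail-too-long")

  no_tmd <- seg_df(list("globular", 0, 80), list("tail", 80, 100))
  expect_equal(decoding_rule(no_tmd)$reason, "no-TMD")

  all_tail <- seg_df(list("tail", 0, 100))
  expect_equal(decoding_rule(all_tail)$reason, "all-tail")

  # a missing tail counts as length zero: acceptable
  no_tail <- seg_df(list("globular", 0, 80), list("TMD", 80, 100))
  expect_true(decoding_rule(no_tail)$verdict)
})

test_that("threshold selection minimises BER over the candidate grid", {
  fit <- select_threshold(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(fit$threshold, 0)
  expect_equal(fit$ber_at_threshold, 0)

  same <- select_threshold(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$ber_at_threshold, 0.5)

  pos <- c(0.3, 0.1, -0.2); neg <- c(0.2, -0.1, -0.3)
  fit <- select_threshold(pos, neg)
  want <- brute_threshold(pos, neg)
  expect_equal(fit$ber_at_threshold, want$ber)
  expect_equal(fit$threshold, want$threshold)

  set.seed(90)
  for (i in 1:25) {
    pos <- round(stats::rnorm(sample(3:12, 1)), 1)
    neg <- round(stats::rnorm(sample(3:12, 1), -0.5), 1)
    fit <- select_threshold(pos, neg)
    want <- brute_threshold(pos, neg)
    expect_equal(fit$ber_at_threshold, want$ber)
    expect_equal(fit$threshold, want$threshold)
  }
  expect_error(select_threshold(numeric(0), 1), "non-empty")
})

test_that("classification modes compose as decode AND score", {
  bundle <- untrained_bundle()
  set.seed(44)
  seqs <- c(vapply(generate_dataset("TA", 6, median_length = 120,
                                    length_range = c(80, 200), sdlog = 0.3,
                                    seed = 91), `[[`, "", "sequence"),
            replicate(6, random_protein(sample(80:200, 1L))))
  got <- lapply(seqs, function(s)
    classify(bundle, s, mode = "combined", negative_context = "mp",
             threshold_mp = 0))
  got <- do.call(rbind, got)
  expect_true(all(got$combined_verdict == (got$decode_verdict & got$score_verdict)))
  # combined positives are a subset of each rule's positives
  expect_true(all(!got$combined_verdict | got$decode_verdict))
  expect_true(all(!got$combined_verdict | got$score_verdict))

  # decode mode ignores thresholds entirely
  d1 <- classify(bundle, seqs[[1L]], mode = "decode")
  d2 <- classify(bundle, seqs[[1L]], mode = "decode", threshold_mp = 1e6)
  expect_identical(d1$verdict, d2$verdict)
  expect_error(classify(bundle, seqs[[1L]], mode = "score"), "threshold")

  # verdicts do not depend on the sequence id
  a <- classify(bundle, seqs[[2L]], id = "x", mode = "decode")
  b <- classify(bundle, seqs[[2L]], id = "y", mode = "decode")
  expect_identical(a[-1L], b[-1L])
})
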