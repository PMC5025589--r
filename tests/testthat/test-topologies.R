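test_that("the three topologies have the prescribed states and initial law", {
  ta2 <- build_ta_model(2L)
  ta4 <- build_ta_model(4L)
  sp <- build_sp_model()
  mp <- build_mp_model()
  expect_length(ta2$ids, 33L)  # 2 tail + 25 TMD + 5 cap + 1 globular
  expect_length(ta4$ids, 35L)
  expect_length(sp$ids, 72L)   # 40 signal + 1 + 5 cap + 25 TMD + 1
  expect_length(mp$ids, 91L)   # 40 signal + 1 + 5 cap + 25 TMD + 20 loop

  expect_equal(unname(ta2$init[c("tail1", "TMD1")]), c(0.5, 0.5))
  expect_equal(sum(ta2$init), 1)
  expect_equal(unname(sp$init[c("sigB1", "globular1")]), c(0.5, 0.5))
  expect_equal(unname(mp$init[c("sigB1", "globular")]), c(0.5, 0.5))
  expect_equal(ta2$orientation, "C-to-N")
  expect_equal(sp$orientation, "N-to-C")
  expect_error(build_ta_model(3L), "tail_states")
})

test_that("forced chains and allowed exits match the region grammar", {
  ta <- build_ta_model(2L)
  # first 14 TMD states advance deterministically
  for (i in 1:14)
    expect_equal(unname(ta$trans[paste0("TMD", i), paste0("TMD", i + 1L)]), 1)
  # states 15-24 may advance or exit to the cap; state 25 must exit
  expect_equal(unname(ta$trans["TMD15", c("TMD16", "cap1")]), c(0.5, 0.5))
  expect_equal(unname(ta$trans["TMD25", "cap1"]), 1)
  # tail transitions: self, adjacent, TMD start, equally probable
  expect_equal(unname(ta$trans["tail1", c("tail1", "tail2", "TMD1")]),
               rep(1 / 3, 3))
  # cap states exit to the single self-looping globular state
  expect_equal(unname(ta$trans["cap5", "globular"]), 1)
  expect_equal(unname(ta$trans["globular", "globular"]), 1)

  mp <- build_mp_model()
  # each loop state: next loop state, cap start, globular, each 1/3
  for (i in c(1L, 10L, 19L))
    expect_equal(unname(mp$trans[paste0("loop", i),
                                 c(paste0("loop", i + 1L), "cap1", "globular")]),
                 rep(1 / 3, 3))

  sp <- build_sp_model()
  # signal chain forced for 14 states; exits to globular1 from state 15 on
  expect_equal(unname(sp$trans["sigB1", "sigB2"]), 1)
  expect_gt(sp$trans["sigH5", "globular1"], 0)   # signal state 15
  expect_equal(unname(sp$trans["sigH4", "globular1"]), 0)
  expect_gt(sp$trans["sigP15", "globular1"], 0)  # signal state 40
})

test_that("initial emissions favour each region's residue class", {
  cls <- residue_classes()
  tmd <- initial_emissions("TMD")
  expect_equal(sum(tmd), 1)
  expect_true(all(outer(tmd[cls$hydrophobic], tmd[setdiff(AA_ALPHABET, cls$hydrophobic)],
                        ">")))
  cap <- initial_emissions("cap")
  expect_equal(unname(cap["K"]), 0.7 / length(cls$basic))
  expect_equal(unname(cap["R"]), unname(cap["K"]))
  expect_error(initial_emissions("membrane"), "unknown region")
  # classes partition the alphabet
  expect_setequal(unlist(cls), AA_ALPHABET)
  expect_length(unlist(cls), 20L)
})

test_that("decoded region runs respect the structural length bounds", {
  set.seed(31)
  ta <- build_ta_model(2L)
  sp <- build_sp_model()
  mp <- build_mp_model()
  for (i in 1:150) {
    L <- sample(50:300, 1L)
    obs <- sample(0:19, L, replace = TRUE)
    rta <- region_runs(viterbi_decode(ta, obs)$regions)
    tmd <- rta$len[rta$region == "TMD"]
    if (length(tmd)) expect_true(all(tmd >= 15L & tmd <= 25L))
    expect_true(all(rta$len[rta$region == "cap"] <= 5L))

    rmp <- region_runs(viterbi_decode(mp, obs)$regions)
    expect_true(all(rmp$len[rmp$region == "loop"] <= 20L))

    rsp <- region_runs(viterbi_decode(sp, obs)$regions)
    sig <- grepl("^signal", rsp$region)
    if (any(sig)) {
      # contiguous signal block length (the three sub-regions together)
      sig_run <- region_runs(ifelse(grepl("^signal", viterbi_decode(sp, obs)$regions),
                                    "signal", "other"))
      lens <- sig_run$len[sig_run$region == "signal"]
      expect_true(all(lens >= 15L & lens <= 40L))
    }
    tmd_sp <- rsp$len[rsp$region == "TMD"]
    if (length(tmd_sp)) expect_true(all(tmd_sp >= 15L & tmd_sp <= 25L))
  }
})

test_that("every state reaches a self-looping state (no dead ends)", {
  for (m in list(build_ta_model(2L), build_ta_model(4L), build_sp_model(),
                 build_mp_model())) {
    S <- length(m$ids)
    adj <- m$trans > 0
    reach <- adj | diag(TRUE, S)
    for (k in seq_len(S)) reach <- reach | (reach %*% adj > 0)
    absorbing <- which(diag(m$trans) > 0)
    expect_true(all(rowSums(reach[, absorbing, drop = FALSE]) > 0))
  }
})

test_that("both tail variants build, train and decode", {
  gen <- make_generator("TA")
  set.seed(8)
  seqs <- replicate(6, sample_hmm(gen, 80)$sequence)
  for (k in c(2L, 4L)) {
    fit <- baum_welch(build_ta_model(k), seqs, max_iter = 2L)
    expect_s3_class(fit$model, "hmm_model")
    v <- viterbi_decode(fit$model, seqs[[1L]])
    expect_length(v$path, 80L)
  }
})
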