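# Independent oracles: brute-force path enumeration, scaled-arithmetic
# forward, exhaustive threshold scan, pairwise AUC. These never call the
# package's DP kernels.

rdirichlet1 <- function(k) {
  x <- stats::rgamma(k, 1)
  x / sum(x)
}

# random fully-connected HMM with S states over the 20-letter alphabet
random_hmm <- function(S, seed, orientation = "N-to-C") {
  set.seed(seed)
  ids <- paste0("s", seq_len(S))
  trans <- t(replicate(S, rdirichlet1(S)))
  if (S == 1L) trans <- matrix(1, 1, 1)
  emis <- t(replicate(S, rdirichlet1(20L)))
  if (S == 1L) emis <- matrix(rdirichlet1(20L), 1)
  hmm_model(ids, rep("g", S), rdirichlet1(S), trans, emis, orientation)
}

emit_prob <- function(model, s, o) if (o < 0L) 1 / 20 else model$emis[s, o + 1L]

all_paths <- function(S, L) {
  g <- do.call(expand.grid, rep(list(seq_len(S)), L))
  as.matrix(g)
}

path_logp <- function(model, path, obs) {
  lp <- log(model$init[path[1L]]) + log(emit_prob(model, path[1L], obs[1L]))
  if (length(obs) > 1L)
    for (t in 2:length(obs))
      lp <- lp + log(model$trans[path[t - 1L], path[t]]) +
        log(emit_prob(model, path[t], obs[t]))
  unname(lp)
}

brute_loglik <- function(model, obs) {
  paths <- all_paths(length(model$ids), length(obs))
  lps <- apply(paths, 1L, path_logp, model = model, obs = obs)
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

brute_viterbi_logp <- function(model, obs) {
  paths <- all_paths(length(model$ids), length(obs))
  max(apply(paths, 1L, path_logp, model = model, obs = obs))
}

# forward recursion in linear space with per-position scaling (the classical
# anti-underflow scheme), as an arithmetic cross-check of the log-space kernel
scaled_forward <- function(model, obs) {
  S <- length(model$ids)
  e <- function(o) vapply(seq_len(S), function(s) emit_prob(model, s, o), 0)
  a <- model$init * e(obs[1L])
  logc <- log(sum(a))
  a <- a / sum(a)
  if (length(obs) > 1L)
    for (t in 2:length(obs)) {
      a <- as.vector(a %*% model$trans) * e(obs[t])
      logc <- logc + log(sum(a))
      a <- a / sum(a)
    }
  logc
}

# exact posterior expected counts by path enumeration
brute_counts <- function(model, obs) {
  S <- length(model$ids)
  paths <- all_paths(S, length(obs))
  lps <- apply(paths, 1L, path_logp, model = model, obs = obs)
  w <- exp(lps - max(lps))
  w <- w / sum(w)
  init <- numeric(S)
  trans <- matrix(0, S, S)
  emis <- matrix(0, S, 20L)
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    init[path[1L]] <- init[path[1L]] + w[p]
    for (t in seq_along(obs)) {
      if (obs[t] >= 0L)
        emis[path[t], obs[t] + 1L] <- emis[path[t], obs[t] + 1L] + w[p]
      if (t > 1L)
        trans[path[t - 1L], path[t]] <- trans[path[t - 1L], path[t]] + w[p]
    }
  }
  list(init = init, trans = trans, emis = emis)
}

brute_threshold <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cand <- c(-Inf, if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2, Inf)
  ber <- sapply(cand, function(th)
    (mean(pos < th) + mean(neg >= th)) / 2)
  list(threshold = cand[which.min(ber)], ber = min(ber))
}

pair_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

trapezoid_auc <- function(points) {
  o <- order(points$fpr, points$tpr)
  x <- c(0, points$fpr[o]); y <- c(0, points$tpr[o])
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

random_protein <- function(L) paste(sample(AA_ALPHABET, L, TRUE), collapse = "")

region_runs <- function(regions) {
  r <- rle(regions)
  data.frame(region = r$values, len = r$lengths)
}

# untrained bundle for structural/property tests
untrained_bundle <- function() {
  structure(list(ta = list("2" = build_ta_model(2L), "4" = build_ta_model(4L)),
                 sp = build_sp_model(), mp = build_mp_model(), meta = list()),
            class = "model_bundle")
}
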