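#' @useDynLib tailanchor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, in alphabetical order. All
#' emission rows are indexed by this vector.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Ambiguous / non-canonical residue codes
#'
#' Letters accepted in input sequences but not part of the canonical alphabet:
#' ambiguity codes (B, Z, X, J) and the rare residues selenocysteine (U) and
#' pyrrolysine (O). Each is emitted with probability 1/20 in every state, so
#' ambiguous positions contribute equally to all models and never decide a
#' classification.
#'
#' @format Character vector of length 6.
#' @export
AMBIGUOUS_RESIDUES <- c("B", "Z", "X", "U", "O", "J")

stop_validation <- function(msg) {
  stop(structure(class = c("tailanchor_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Encode an amino-acid sequence as integer indices
#'
#' Canonicalises to upper case and maps each residue to its 0-based index in
#' [AA_ALPHABET]; residues in [AMBIGUOUS_RESIDUES] map to -1 (emitted uniformly
#' by every state). Any other character is an error naming the position.
#'
#' @param seq A single character string, or a character vector of one-letter
#'   residue codes.
#' @return Integer vector of 0-based letter indices, -1 for ambiguous residues.
#' @export
encode_residues <- function(seq) {
  if (length(seq) == 1L && nchar(seq[1L]) > 1L)
    seq <- strsplit(seq, "")[[1L]]
  if (length(seq) == 0L || (length(seq) == 1L && !nzchar(seq)))
    stop_validation("empty sequence")
  seq <- toupper(seq)
  idx <- match(seq, AA_ALPHABET)
  amb <- seq %in% AMBIGUOUS_RESIDUES
  bad <- is.na(idx) & !amb
  if (any(bad)) {
    pos <- which(bad)[1L]
    stop_validation(sprintf(
      "invalid residue '%s' at position %d (not an amino-acid or ambiguity code)",
      seq[pos], pos))
  }
  out <- idx - 1L
  out[amb] <- -1L
  out
}

#' Construct a hidden Markov model with region-tagged states
#'
#' Creates the parameter container used throughout the package. Probabilities
#' are stored in linear space; structurally disallowed transitions are exact
#' zeros and stay zero through training.
#'
#' @param ids Character vector of unique state identifiers.
#' @param regions Character vector of region labels, one per state (e.g.
#'   `"TMD"`, `"tail"`).
#' @param init Numeric vector of initial-state probabilities (sums to 1).
#' @param trans Square numeric matrix of transition probabilities; each row
#'   sums to 1 over its allowed (nonzero) successors. Zero entries are
#'   structural and preserved by training.
#' @param emis Numeric matrix (states x 20) of emission probabilities over
#'   [AA_ALPHABET]; each row sums to 1.
#' @param orientation `"N-to-C"` or `"C-to-N"`. A `"C-to-N"` model reads the
#'   sequence from the C-terminus; the caller reverses the sequence before
#'   decoding (see [decode_regions()]).
#' @param topology Topology-version string recorded in serialized models.
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(ids, regions, init, trans, emis,
                      orientation = c("N-to-C", "C-to-N"),
                      topology = "custom/v1") {
  orientation <- match.arg(orientation)
  S <- length(ids)
  stopifnot(length(regions) == S, length(init) == S,
            nrow(trans) == S, ncol(trans) == S,
            nrow(emis) == S, ncol(emis) == 20L)
  dimnames(trans) <- list(ids, ids)
  dimnames(emis) <- list(ids, AA_ALPHABET)
  names(init) <- ids
  m <- structure(list(ids = as.character(ids), regions = as.character(regions),
                      init = as.numeric(init), trans = trans, emis = emis,
                      orientation = orientation, topology = topology),
                 class = "hmm_model")
  names(m$init) <- ids
  validate_hmm(m)
  m
}

#' Validate an HMM parameter object
#'
#' Checks that the exponentiated initial vector sums to 1, every transition
#' row sums to 1 over its allowed successors, and every emission row sums to
#' 1, all within `tol`.
#'
#' @param model An `hmm_model`.
#' @param tol Absolute tolerance on row sums.
#' @return The model, invisibly; errors on violation.
#' @export
validate_hmm <- function(model, tol = 1e-9) {
  if (!inherits(model, "hmm_model")) stop_validation("not an hmm_model")
  if (any(model$init < 0) || abs(sum(model$init) - 1) > tol)
    stop_validation("initial probabilities do not sum to 1")
  rs <- rowSums(model$trans)
  if (any(model$trans < 0) || any(abs(rs - 1) > tol))
    stop_validation(sprintf("transition row '%s' does not sum to 1",
                            model$ids[which.max(abs(rs - 1))]))
  es <- rowSums(model$emis)
  if (any(model$emis < 0) || any(abs(es - 1) > tol))
    stop_validation(sprintf("emission row '%s' does not sum to 1",
                            model$ids[which.max(abs(es - 1))]))
  invisible(model)
}

#' @export
print.hmm_model <- function(x, ...) {
  reg <- rle(x$regions)
  cat(sprintf("<hmm_model> %d states, orientation %s, topology %s\n",
              length(x$ids), x$orientation, x$topology))
  cat("  regions:", paste(sprintf("%s(%d)", reg$values, reg$lengths),
                          collapse = " -> "), "\n")
  invisible(x)
}

# log-space view used by the C++ kernels; log(0) = -Inf marks structural zeros
model_logspace <- function(model) {
  list(log_init = log(model$init), log_trans = log(model$trans),
       log_emis = log(model$emis))
}

as_obs <- function(seq) {
  if (is.character(seq)) encode_residues(seq) else as.integer(seq)
}

#' Forward log-likelihood of a sequence
#'
#' Computes `log P(sequence)` summed over all state paths, in log space with
#' log-sum-exp (no underflow for sequences of at least 5,000 residues).
#' Because the models have no end state, the recursion terminates by summing
#' over all states at the final position.
#'
#' @param model An `hmm_model`.
#' @param seq Character string of residues, or an integer vector from
#'   [encode_residues()].
#' @return The log-likelihood (a single number, in nats).
#' @export
forward_loglik <- function(model, seq) {
  obs <- as_obs(seq)
  if (length(obs) == 0L) stop_validation("empty sequence")
  ls <- model_logspace(model)
  forward_loglik_cpp(ls$log_init, ls$log_trans, ls$log_emis, obs)
}

#' Viterbi decoding
#'
#' Returns the single most probable state path and its joint log-probability.
#' Ties are broken toward the lowest state index at each backtrack step, so
#' results are deterministic across platforms.
#'
#' @inheritParams forward_loglik
#' @return A list with `path` (integer state indices, 1-based), `states`
#'   (state ids), `regions` (region label per position), and `logp` (joint
#'   log-probability of the path, in nats).
#' @export
viterbi_decode <- function(model, seq) {
  obs <- as_obs(seq)
  if (length(obs) == 0L) stop_validation("empty sequence")
  ls <- model_logspace(model)
  v <- viterbi_cpp(ls$log_init, ls$log_trans, ls$log_emis, obs)
  if (length(v$path) == 0L || !is.finite(v$logp))
    stop("no admissible path: every state path has probability zero")
  path <- v$path + 1L
  list(path = path, states = model$ids[path], regions = model$regions[path],
       logp = v$logp)
}

#' Baum-Welch training
#'
#' Expectation-maximisation fit of an HMM to a set of sequences. Expected
#' counts are accumulated in log space (C++ kernel); the M-step renormalises
#' with a pseudocount of `pseudocount` added to every emission cell and to
#' every structurally allowed transition/initial cell, so no probability on
#' the allowed support ever becomes exactly zero while structural zeros are
#' preserved. A state whose total expected occupancy in an iteration falls
#' below one observation keeps its previous rows rather than being reset to a
#' near-uniform distribution.
#'
#' @param model Starting `hmm_model`.
#' @param seqs List (or character vector) of sequences.
#' @param tol Relative change in total log-likelihood below which iteration
#'   stops.
#' @param max_iter Maximum number of EM iterations.
#' @param pseudocount Dirichlet-style pseudocount used at every M-step.
#' @return A list with `model` (the fitted `hmm_model`), `trace` (total
#'   log-likelihood at the start of each iteration; non-decreasing), and
#'   `converged`.
#' @export
baum_welch <- function(model, seqs, tol = 1e-6, max_iter = 100L,
                       pseudocount = 1e-6) {
  if (length(seqs) < 1L) stop_validation("at least one training sequence required")
  obs_list <- lapply(seqs, as_obs)
  if (any(vapply(obs_list, length, 1L) == 0L))
    stop_validation("empty sequence in training set")
  S <- length(model$ids)
  if (max(vapply(obs_list, length, 1L)) == 1L && S > 1L)
    warning("model longer than data: all training sequences have length 1")

  allowed_trans <- model$trans > 0
  allowed_init <- model$init > 0
  trace <- numeric(0)
  ll_prev <- NA_real_
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    ls <- model_logspace(model)
    tot_ll <- 0
    init_c <- numeric(S)
    trans_c <- matrix(0, S, S)
    emis_c <- matrix(0, S, 20L)
    occ <- numeric(S)
    for (obs in obs_list) {
      cc <- bw_counts_cpp(ls$log_init, ls$log_trans, ls$log_emis, obs)
      tot_ll <- tot_ll + cc$loglik
      init_c <- init_c + cc$init
      trans_c <- trans_c + cc$trans
      emis_c <- emis_c + cc$emis
      occ <- occ + cc$occupancy
    }
    trace <- c(trace, tot_ll)
    if (!is.na(ll_prev) &&
        abs(tot_ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- tot_ll

    # M-step
    new_init <- model$init
    ic <- init_c
    ic[allowed_init] <- ic[allowed_init] + pseudocount
    ic[!allowed_init] <- 0
    new_init <- ic / sum(ic)

    new_trans <- model$trans
    new_emis <- model$emis
    out_counts <- rowSums(trans_c)
    for (s in seq_len(S)) {
      if (any(allowed_trans[s, ]) && out_counts[s] >= 1) {
        row <- trans_c[s, ]
        row[allowed_trans[s, ]] <- row[allowed_trans[s, ]] + pseudocount
        row[!allowed_trans[s, ]] <- 0
        new_trans[s, ] <- row / sum(row)
      }
      if (occ[s] >= 1) {
        erow <- emis_c[s, ] + pseudocount
        new_emis[s, ] <- erow / sum(erow)
      }
    }
    model$init <- new_init
    names(model$init) <- model$ids
    model$trans <- new_trans
    model$emis <- new_emis
    validate_hmm(model)
  }
  list(model = model, trace = trace, converged = converged,
       iterations = length(trace))
}

#' Sample a sequence and its state path from an HMM
#'
#' Draws the first state from the initial distribution, each following state
#' from the transition row, and each residue from the current state's
#' emission row. Reproducible for a fixed seed.
#'
#' @param model An `hmm_model`.
#' @param length Number of residues to generate (at least 1).
#' @param seed Optional integer seed; if `NULL`, the current RNG state is
#'   used.
#' @return A list with `sequence` (character string, in the model's reading
#'   direction), `path` (1-based state indices), and `regions`.
#' @export
sample_hmm <- function(model, length, seed = NULL) {
  if (length < 1L) stop_validation("length must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  S <- base::length(model$ids)
  path <- integer(length)
  path[1L] <- sample.int(S, 1L, prob = model$init)
  if (length > 1L)
    for (t in 2:length)
      path[t] <- sample.int(S, 1L, prob = model$trans[path[t - 1L], ])
  res <- character(length)
  for (s in unique(path)) {
    idx <- which(path == s)
    res[idx] <- sample(AA_ALPHABET, base::length(idx), replace = TRUE,
                       prob = model$emis[s, ])
  }
  list(sequence = paste0(res, collapse = ""), path = path,
       regions = model$regions[path])
}
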