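#' Per-model log-likelihoods and length-normalised scores for one sequence
#'
#' Computes `ln l_ta` (on the reversed sequence, taking the maximum over the
#' bundle's TA tail variants), `ln l_sp` and `ln l_mp`, and the prediction
#' scores `S_m = (ln l_ta - ln l_m) / L` for m in {sp, mp}. Positive scores
#' favour the TA model; dividing by the sequence length L normalises away
#' the linear growth of log-likelihood magnitudes with length. "Likelihood"
#' is the Viterbi joint log-probability by default (likelihoods are obtained
#' by decoding); set `likelihood = "forward"` to use the all-paths forward
#' probability instead.
#'
#' @param bundle A `model_bundle`.
#' @param seq Character string of residues (N-to-C).
#' @param likelihood `"viterbi"` or `"forward"`.
#' @return One-row data frame: `length`, `ln_l_ta`, `ln_l_sp`, `ln_l_mp`,
#'   `S_sp`, `S_mp`.
#' @export
likelihood_scores <- function(bundle, seq,
                              likelihood = c("viterbi", "forward")) {
  likelihood <- match.arg(likelihood)
  L <- nchar(seq)
  if (L == 0L) stop_validation("empty sequence")
  ll_fun <- if (likelihood == "viterbi")
    function(m, s) viterbi_decode(m, s)$logp else forward_loglik
  rev_s <- reverse_seq(seq)
  ln_ta <- max(vapply(bundle$ta, ll_fun, 0, s = rev_s))
  ln_sp <- ll_fun(bundle$sp, seq)
  ln_mp <- ll_fun(bundle$mp, seq)
  data.frame(length = L, ln_l_ta = ln_ta, ln_l_sp = ln_sp, ln_l_mp = ln_mp,
             S_sp = (ln_ta - ln_sp) / L, S_mp = (ln_ta - ln_mp) / L)
}

#' Viterbi region segmentation of a sequence under the TA model
#'
#' Decodes the reversed sequence with the 2-tail-state TA model and maps the
#' state path back to original N-to-C coordinates: a run occupying reversed
#' positions `[s, e)` of a length-L sequence maps to original positions
#' `[L - e, L - s)`. Consecutive states with the same region label are merged
#' into segments, which tile `[0, L)`.
#'
#' @param ta_model A TA `hmm_model` with the 2-state tail variant.
#' @param seq Character string of residues (N-to-C).
#' @return Data frame of `region`, `start`, `end` (0-based half-open, N-to-C).
#' @export
decode_regions <- function(ta_model, seq) {
  stopifnot(inherits(ta_model, "hmm_model"),
            ta_model$orientation == "C-to-N")
  v <- viterbi_decode(ta_model, reverse_seq(seq))
  path_to_segments(ta_model, v$path)
}

#' Decoding-based TA decision rule
#'
#' A sequence is accepted as tail-anchored when its decoded region structure
#' has a TMD segment of at least 15 residues and a C-terminal tail segment of
#' at most 30 residues (a missing tail counts as length 0). Failures are
#' classified as `"all-tail"` (decoded as tail over its entire length, i.e.
#' no transition to the TMD region occurred), `"no-TMD"` (no TMD segment of
#' 15 or more residues), or `"tail-too-long"`.
#'
#' @param segments Data frame from [decode_regions()].
#' @return List with `verdict` (logical) and `reason` (`NA` when accepted).
#' @export
decoding_rule <- function(segments) {
  if (all(segments$region == "tail"))
    return(list(verdict = FALSE, reason = "all-tail"))
  tmd <- seg_lengths(segments, "TMD")
  if (length(tmd) == 0L || max(tmd) < 15L)
    return(list(verdict = FALSE, reason = "no-TMD"))
  tails <- which(segments$region == "tail")
  tail_len <- if (length(tails) == 0L) 0L else {
    ct <- tails[which.max(segments$end[tails])]  # C-terminal-most tail
    segments$end[ct] - segments$start[ct]
  }
  if (tail_len > 30L)
    return(list(verdict = FALSE, reason = "tail-too-long"))
  list(verdict = TRUE, reason = NA_character_)
}

#' Select the score threshold minimising the balanced error rate
#'
#' Candidate thresholds are the midpoints between adjacent distinct values of
#' the pooled sorted scores plus -Inf/+Inf sentinels; a score greater than or
#' equal to the threshold is classified positive. Returns the candidate with
#' the smallest balanced error rate, BER = (FN/(TP+FN) + FP/(FP+TN)) / 2;
#' ties are broken toward the smallest threshold.
#'
#' @param scores_pos,scores_neg Numeric score vectors of the positive and
#'   negative fitting data.
#' @return List with `threshold` and `ber_at_threshold`.
#' @export
select_threshold <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L)
    stop_validation("both score sets must be non-empty")
  v <- sort(unique(c(scores_pos, scores_neg)))
  cand <- c(-Inf, if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2, Inf)
  ber <- vapply(cand, function(th) {
    fn <- sum(scores_pos < th)
    fp <- sum(scores_neg >= th)
    (fn / length(scores_pos) + fp / length(scores_neg)) / 2
  }, 0)
  best <- which.min(ber)  # first minimum = smallest threshold
  list(threshold = cand[best], ber_at_threshold = ber[best])
}

#' Classify a sequence as tail-anchored
#'
#' Applies the decoding rule, the score rule, or their conjunction. The score
#' rule compares `S_sp` against `threshold_sp` when the negative context is
#' `"sp"`, and `S_mp` against `threshold_mp` otherwise (the MP score and
#' threshold are also used for non-membrane and pooled negative data, which
#' have no model of their own). The combined verdict is the AND of the two
#' rules, so combined positives are always a subset of each single rule's
#' positives. The decoding rule uses no threshold at all.
#'
#' @param bundle A `model_bundle`.
#' @param seq Character string of residues (N-to-C).
#' @param mode `"score"`, `"decode"`, or `"combined"`.
#' @param negative_context `"sp"` or `"mp"`: which competitor model's score
#'   and threshold the score rule uses.
#' @param threshold_sp,threshold_mp Fitted thresholds ([select_threshold()]);
#'   required when `mode` involves scores.
#' @param id Optional sequence id carried into the output.
#' @param likelihood Passed to [likelihood_scores()].
#' @return One-row data frame: `id`, `length`, the three log-likelihoods,
#'   `S_sp`, `S_mp`, `tmd_start`, `tmd_end`, `tail_length` (0-based
#'   half-open coordinates; NA when no TMD was decoded), `decode_verdict`,
#'   `decode_reason`, `score_verdict`, `combined_verdict`, and `verdict` (the
#'   verdict of the requested mode).
#' @export
classify <- function(bundle, seq, mode = c("combined", "score", "decode"),
                     negative_context = c("mp", "sp"),
                     threshold_sp = NULL, threshold_mp = NULL, id = NA_character_,
                     likelihood = c("viterbi", "forward")) {
  mode <- match.arg(mode)
  negative_context <- match.arg(negative_context)
  sc <- likelihood_scores(bundle, seq, likelihood = likelihood)
  seg <- decode_regions(bundle$ta[["2"]], seq)
  dec <- decoding_rule(seg)
  tmd_rows <- which(seg$region == "TMD")
  tmd_start <- if (length(tmd_rows)) seg$start[tmd_rows[1L]] else NA_integer_
  tmd_end <- if (length(tmd_rows)) seg$end[tmd_rows[length(tmd_rows)]] else NA_integer_
  tails <- which(seg$region == "tail")
  tail_length <- if (length(tails) == 0L) 0L else {
    ct <- tails[which.max(seg$end[tails])]
    seg$end[ct] - seg$start[ct]
  }
  score_verdict <- NA
  if (mode %in% c("score", "combined")) {
    th <- if (negative_context == "sp") threshold_sp else threshold_mp
    if (is.null(th))
      stop_validation(sprintf("mode '%s' requires a fitted threshold_%s",
                              mode, negative_context))
    s <- if (negative_context == "sp") sc$S_sp else sc$S_mp
    score_verdict <- s >= th
  }
  combined <- if (is.na(score_verdict)) NA else dec$verdict && score_verdict
  verdict <- switch(mode, decode = dec$verdict, score = score_verdict,
                    combined = combined)
  cbind(data.frame(id = id, stringsAsFactors = FALSE), sc,
        data.frame(tmd_start = tmd_start, tmd_end = tmd_end,
                   tail_length = tail_length,
                   decode_verdict = dec$verdict, decode_reason = dec$reason,
                   score_verdict = score_verdict, combined_verdict = combined,
                   verdict = verdict, stringsAsFactors = FALSE))
}
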