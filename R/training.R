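reverse_seq <- function(s)
  vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""), "")

#' Train the TA, SP and MP models on labelled sequence sets
#'
#' Fits each model by Baum-Welch ([baum_welch()]) starting from the fixed
#' initial topology parameters. The TA model reads sequences from the
#' C-terminus, so TA training sequences are reversed before fitting (the
#' model's orientation flag records this contract); both tail variants are
#' trained by default. Non-membrane (NO) sequences are never used for
#' training: the NO class has no dedicated model.
#'
#' @param ta_set,sp_set,mp_set Character vectors of training sequences
#'   (N-to-C) for the respective classes.
#' @param tail_variants TA tail-state variants to train (subset of `c(2, 4)`).
#' @param tol,max_iter Convergence controls passed to [baum_welch()].
#' @return A `model_bundle`: `ta` (named list of fitted TA models, one per
#'   tail variant), `sp`, `mp`, and `meta` (dataset sizes, iterations, final
#'   log-likelihoods).
#' @export
train_models <- function(ta_set, sp_set, mp_set, tail_variants = c(2L, 4L),
                         tol = 1e-6, max_iter = 100L) {
  for (nm in c("ta_set", "sp_set", "mp_set"))
    if (length(get(nm)) == 0L)
      stop_validation(sprintf("training set '%s' is empty", nm))
  ta_rev <- reverse_seq(ta_set)
  ta <- lapply(tail_variants, function(k)
    baum_welch(build_ta_model(k), ta_rev, tol = tol, max_iter = max_iter))
  names(ta) <- as.character(tail_variants)
  sp <- baum_welch(build_sp_model(), sp_set, tol = tol, max_iter = max_iter)
  mp <- baum_welch(build_mp_model(), mp_set, tol = tol, max_iter = max_iter)
  meta <- list(
    n = list(ta = length(ta_set), sp = length(sp_set), mp = length(mp_set)),
    tail_variants = as.integer(tail_variants), tol = tol,
    max_iter = as.integer(max_iter),
    iterations = c(lapply(ta, `[[`, "iterations"),
                   list(sp = sp$iterations, mp = mp$iterations)),
    final_loglik = c(lapply(ta, function(f) tail(f$trace, 1L)),
                     list(sp = tail(sp$trace, 1L), mp = tail(mp$trace, 1L))))
  structure(list(ta = lapply(ta, `[[`, "model"), sp = sp$model,
                 mp = mp$model, meta = meta),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> TA tail variants: %s; SP (%d states); MP (%d states)\n",
              paste(names(x$ta), collapse = ", "),
              length(x$sp$ids), length(x$mp$ids)))
  invisible(x)
}

# reproducible fold assignment: canonical sort by id, seeded shuffle,
# round-robin -> results do not depend on input order
assign_folds <- function(ids, k, seed) {
  ord <- sort(ids)
  set.seed(seed)
  shuffled <- sample(ord)
  stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)[ids]
}

#' Cross-validated likelihood scoring of all four datasets
#'
#' Implements the evaluation protocol: for each modeled dataset X in
#' {TA, SP, MP}, the likelihood of a sequence under its own model X comes
#' from a fold model whose training set excludes that sequence (k-fold
#' cross-validation), while likelihoods under the other two models come from
#' models trained on their full datasets. NO sequences have no model of
#' their own and are scored by the full-data models only.
#'
#' @param ta_set,sp_set,mp_set,no_set Named character vectors of sequences.
#' @param k Number of folds (at least 2, at most the smallest modeled set).
#' @param seed Integer seed controlling fold assignment.
#' @param tail_variants,tol,max_iter Passed to [train_models()].
#' @param likelihood `"viterbi"` (default) or `"forward"`.
#' @return Data frame with one row per sequence: `id`, `class`, `length`,
#'   `fold` (own-model fold, NA for NO), `ln_l_ta`, `ln_l_sp`, `ln_l_mp`,
#'   `S_sp`, `S_mp`, `decode_verdict`, `decode_reason`. The fold assignment
#'   used is attached as attribute `folds`.
#' @export
crossvalidated_scores <- function(ta_set, sp_set, mp_set, no_set, k = 5L,
                                  seed = 1L, tail_variants = c(2L, 4L),
                                  tol = 1e-6, max_iter = 100L,
                                  likelihood = c("viterbi", "forward")) {
  likelihood <- match.arg(likelihood)
  if (k < 2L) stop_validation("k must be at least 2")
  sets <- list(TA = ta_set, SP = sp_set, MP = mp_set, NO = no_set)
  for (nm in c("TA", "SP", "MP")) {
    if (length(sets[[nm]]) < k)
      stop_validation(sprintf("dataset %s has fewer than k = %d members", nm, k))
  }
  for (nm in names(sets))
    if (is.null(names(sets[[nm]])))
      names(sets[[nm]]) <- sprintf("%s_%04d", nm, seq_along(sets[[nm]]))

  full <- train_models(sets$TA, sets$SP, sets$MP,
                       tail_variants = tail_variants, tol = tol,
                       max_iter = max_iter)
  folds <- lapply(sets[c("TA", "SP", "MP")], function(s)
    assign_folds(names(s), k, seed))

  # per-fold own-model fits (folds start from the same initial parameters)
  fold_models <- list()
  for (cls in c("TA", "SP", "MP")) {
    fold_models[[cls]] <- lapply(seq_len(k), function(f) {
      train_idx <- folds[[cls]] != f
      train <- sets[[cls]][train_idx]
      if (cls == "TA") {
        lapply(stats::setNames(tail_variants, tail_variants), function(kk)
          baum_welch(build_ta_model(kk), reverse_seq(train), tol = tol,
                     max_iter = max_iter)$model)
      } else if (cls == "SP") {
        baum_welch(build_sp_model(), train, tol = tol,
                   max_iter = max_iter)$model
      } else {
        baum_welch(build_mp_model(), train, tol = tol,
                   max_iter = max_iter)$model
      }
    })
  }

  ll_fun <- if (likelihood == "viterbi")
    function(m, s) viterbi_decode(m, s)$logp else forward_loglik

  rows <- list()
  for (cls in names(sets)) {
    s <- sets[[cls]]
    for (i in seq_along(s)) {
      id <- names(s)[i]
      seqc <- s[[i]]
      L <- nchar(seqc)
      fold <- if (cls %in% c("TA", "SP", "MP")) folds[[cls]][[id]] else NA_integer_
      ta_models <- if (cls == "TA") fold_models$TA[[fold]] else full$ta
      sp_model <- if (cls == "SP") fold_models$SP[[fold]] else full$sp
      mp_model <- if (cls == "MP") fold_models$MP[[fold]] else full$mp
      rev_s <- reverse_seq(seqc)
      ln_ta <- max(vapply(ta_models, ll_fun, 0, s = rev_s))
      ln_sp <- ll_fun(sp_model, seqc)
      ln_mp <- ll_fun(mp_model, seqc)
      ta2 <- ta_models[["2"]]
      dec <- if (!is.null(ta2)) decoding_rule(decode_regions(ta2, seqc))
             else list(verdict = NA, reason = NA_character_)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, class = cls, length = L, fold = fold,
        ln_l_ta = ln_ta, ln_l_sp = ln_sp, ln_l_mp = ln_mp,
        S_sp = (ln_ta - ln_sp) / L, S_mp = (ln_ta - ln_mp) / L,
        decode_verdict = dec$verdict, decode_reason = dec$reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}
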