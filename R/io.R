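#' Read protein sequences from a FASTA file
#'
#' Parses with Biostrings, canonicalises residues to upper case and validates
#' them: the 20 canonical letters and the ambiguity set
#' ([AMBIGUOUS_RESIDUES]) are accepted; anything else (digits, gaps, `*`) is
#' rejected with a message naming the record and position. Record order and
#' ids are preserved; the id is the first whitespace-delimited token of the
#' header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop_validation(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop_validation(sprintf("duplicate sequence id '%s' in %s", dup[1L], path))
  seqs <- toupper(as.character(x))
  ok <- c(AA_ALPHABET, AMBIGUOUS_RESIDUES)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1L]]
    if (length(chars) == 0L)
      stop_validation(sprintf("record '%s' is empty", ids[i]))
    bad <- which(!chars %in% ok)
    if (length(bad) > 0L)
      stop_validation(sprintf(
        "record '%s': invalid residue '%s' at position %d",
        ids[i], chars[bad[1L]], bad[1L]))
  }
  stats::setNames(seqs, ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

BUNDLE_FORMAT_VERSION <- "tailanchor-bundle/1"

hmm_to_list <- function(model) {
  ids <- model$ids
  trans <- lapply(seq_along(ids), function(i) {
    row <- model$trans[i, ]
    as.list(row[row > 0])
  })
  names(trans) <- ids
  emis <- lapply(seq_along(ids), function(i) as.list(model$emis[i, ]))
  names(emis) <- ids
  init <- model$init[model$init > 0]
  list(topology_version = model$topology,
       orientation = model$orientation,
       states = data.frame(id = ids, region = model$regions,
                           stringsAsFactors = FALSE),
       initial = as.list(init),
       transitions = trans,
       emissions = emis)
}

hmm_from_list <- function(x) {
  for (key in c("topology_version", "orientation", "states", "initial",
                "transitions", "emissions"))
    if (is.null(x[[key]]))
      stop_validation(sprintf("model entry is missing key '%s'", key))
  ids <- x$states$id
  S <- length(ids)
  init <- stats::setNames(rep(0, S), ids)
  init[names(x$initial)] <- unlist(x$initial)
  trans <- matrix(0, S, S, dimnames = list(ids, ids))
  for (i in names(x$transitions)) {
    row <- x$transitions[[i]]
    trans[i, names(row)] <- unlist(row)
  }
  emis <- matrix(0, S, 20L, dimnames = list(ids, AA_ALPHABET))
  for (i in names(x$emissions))
    emis[i, names(x$emissions[[i]])] <- unlist(x$emissions[[i]])
  hmm_model(ids, x$states$region, init, trans, emis,
            orientation = x$orientation, topology = x$topology_version)
}

#' Save a trained model bundle to JSON
#'
#' Serializes every model's states (id, region), initial/transition/emission
#' probabilities in linear space (17 significant digits, bit-exact on
#' round-trip), orientation and topology-version strings, plus training
#' metadata.
#'
#' @param bundle A `model_bundle` from [train_models()].
#' @param path Output path of the JSON file.
#' @return Invisibly, `path`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  x <- list(format_version = BUNDLE_FORMAT_VERSION,
            meta = bundle$meta,
            models = c(
              stats::setNames(lapply(bundle$ta, hmm_to_list),
                              paste0("ta", names(bundle$ta))),
              list(sp = hmm_to_list(bundle$sp), mp = hmm_to_list(bundle$mp))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Load a model bundle from JSON
#'
#' Refuses files written under a different bundle format or model topology
#' version, and files with a missing model entry.
#'
#' @param path Path to a JSON bundle written by [save_bundle()].
#' @return A `model_bundle`.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE,
                           simplifyMatrix = FALSE)
  if (is.null(x$format_version) || x$format_version != BUNDLE_FORMAT_VERSION)
    stop_validation(sprintf("unsupported bundle format '%s' (expected '%s')",
                            x$format_version, BUNDLE_FORMAT_VERSION))
  ta_keys <- grep("^ta[0-9]+$", names(x$models), value = TRUE)
  if (length(ta_keys) == 0L)
    stop_validation("bundle is missing key 'models$ta*'")
  for (key in c("sp", "mp"))
    if (is.null(x$models[[key]]))
      stop_validation(sprintf("bundle is missing key 'models$%s'", key))
  ta <- lapply(x$models[ta_keys], hmm_from_list)
  names(ta) <- sub("^ta", "", ta_keys)
  expected <- c(stats::setNames(sprintf("ta-tail%s/v1", names(ta)), ta_keys),
                sp = "sp/v1", mp = "mp/v1")
  for (key in ta_keys)
    if (ta[[sub("^ta", "", key)]]$topology != expected[[key]])
      stop_validation(sprintf("topology-version mismatch for '%s': got '%s'",
                              key, ta[[sub("^ta", "", key)]]$topology))
  sp <- hmm_from_list(x$models$sp)
  mp <- hmm_from_list(x$models$mp)
  if (sp$topology != "sp/v1" || mp$topology != "mp/v1")
    stop_validation("topology-version mismatch in sp/mp model")
  structure(list(ta = ta, sp = sp, mp = mp, meta = x$meta),
            class = "model_bundle")
}
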