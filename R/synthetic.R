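#' Ground-truth generator model for a synthetic sequence class
#'
#' Builds the generative HMM for one of the four sequence classes: `"TA"`
#' (tail-anchored: hydrophobic C-terminal TMD plus short hydrophilic tail),
#' `"SP"` (signal-peptide single-pass), `"MP"` (signal-peptide multi-pass),
#' and `"NO"` (non-membrane: a single hydrophilic self-looping state). The
#' TA/SP/MP generators reuse the corresponding model topologies with
#' sharpened emissions: at `difficulty = 1` each state places 0.9 of its
#' emission mass on its region's favoured residue class; lower difficulty
#' interpolates every emission row linearly toward the uniform distribution,
#' so `difficulty = 0` makes the classes indistinguishable.
#'
#' Difficulty measures the separation of the class emission profiles, so the
#' `difficulty = 1` endpoint makes the classes compositionally separable:
#' the soluble regions of the TA class (tail and globular domain, which face
#' the cytosol) draw their hydrophilic mass mainly from N, Q, S, T and Y,
#' while the soluble regions of the secretory-pathway classes (SP/MP
#' globular and loop regions, the polar signal block, and the whole NO
#' class) draw mainly from D, E, G and P. This exaggerates, to the point of
#' near-full separability, the mild compositional differences between
#' cytosolic and secreted compartments in real proteomes; real data
#' correspond to a much lower effective difficulty.
#'
#' Unlike the untrained predictive models (whose transitions are split
#' equally as a neutral starting point for training), the generators carry
#' realistic region dwell times: TA tails average about 8 residues (real TA
#' tails are mostly 10 residues or shorter), the single-pass ectodomain
#' between signal and TMD is long (self-transition 0.99), so a minority of
#' SP records end up with a TMD near the C-terminus and act as structurally
#' TA-like hard negatives, and multi-pass globular segments between membrane
#' passes average about 20 residues (self-transition 0.95). TMD run lengths
#' follow the empirically observed distribution (peaked near 17-18 residues
#' with a shoulder at 21) rather than the geometric law that equal exit
#' probabilities would give.
#'
#' @param class One of `"TA"`, `"SP"`, `"MP"`, `"NO"`.
#' @param difficulty Class separation in `[0, 1]`; 1 = fully separated.
#' @return An `hmm_model` usable with [sample_hmm()].
#' @export
make_generator <- function(class = c("TA", "SP", "MP", "NO"), difficulty = 1) {
  class <- match.arg(class)
  stopifnot(difficulty >= 0, difficulty <= 1)
  base <- switch(class,
    TA = set_tmd_lengths(set_dwell(build_ta_model(2L, favored_mass = 0.9),
                                   c(tail1 = 0.8, tail2 = 0.8))),
    SP = set_tmd_lengths(set_dwell(build_sp_model(favored_mass = 0.9),
                                   c(globular1 = 0.99))),
    MP = set_tmd_lengths(set_dwell(build_mp_model(favored_mass = 0.9),
                                   c(globular = 0.95))),
    NO = no_membrane_model(favored_mass = 0.9))
  soluble <- switch(class,
    TA = c("tail", "globular"),
    SP = c("globular1", "globular2", "signal_polar"),
    MP = c("globular", "loop", "signal_polar"),
    NO = "globular")
  compartment <- if (class == "TA") "cytosolic" else "secretory"
  for (s in which(base$regions %in% soluble))
    base$emis[s, ] <- soluble_profile(compartment)
  base$emis <- difficulty * base$emis + (1 - difficulty) / 20
  base$topology <- sprintf("gen-%s/v1", tolower(class))
  validate_hmm(base)
  base
}

# set a state's self-transition probability, rescaling its other allowed
# transitions proportionally
set_dwell <- function(model, self_probs) {
  for (s in names(self_probs)) {
    row <- model$trans[s, ]
    rest <- row
    rest[s] <- 0
    model$trans[s, ] <- rest / sum(rest) * (1 - self_probs[[s]])
    model$trans[s, s] <- self_probs[[s]]
  }
  validate_hmm(model)
  model
}

# Target TMD length distribution for the generators, lengths 15-25. Real
# tail-anchor TMD lengths peak around 17-18 residues with a shoulder near 21,
# rather than decaying geometrically from 15 as equal exit probabilities
# would give.
TMD_LENGTH_WEIGHTS <- c(`15` = 8, `16` = 12, `17` = 17, `18` = 19, `19` = 12,
                        `20` = 8, `21` = 10, `22` = 5, `23` = 4, `24` = 3,
                        `25` = 2)

# reshape the TMD exit probabilities so sampled TMD run lengths follow
# TMD_LENGTH_WEIGHTS (discrete hazard: exit at k with w_k / sum(w_{k..25}))
set_tmd_lengths <- function(model, weights = TMD_LENGTH_WEIGHTS) {
  w <- weights / sum(weights)
  for (k in 15:24) {
    st <- paste0("TMD", k)
    succ <- names(which(model$trans[st, ] > 0))
    exit <- setdiff(succ, paste0("TMD", k + 1L))
    h <- unname(w[as.character(k)] / sum(w[as.character(k:25)]))
    model$trans[st, ] <- 0
    model$trans[st, exit] <- h
    model$trans[st, paste0("TMD", k + 1L)] <- 1 - h
  }
  validate_hmm(model)
  model
}

# compartment-specific hydrophilic profiles used by the generators at full
# difficulty: 0.9 hydrophilic mass split 80/20 between the compartment's
# preferred sub-group and the remaining hydrophilic letters, 0.1 spread over
# the rest of the alphabet
soluble_profile <- function(compartment = c("cytosolic", "secretory")) {
  compartment <- match.arg(compartment)
  cyto <- c("N", "Q", "S", "T", "Y")
  secr <- c("D", "E", "G", "P")
  major <- if (compartment == "cytosolic") cyto else secr
  minor <- if (compartment == "cytosolic") secr else cyto
  rest <- setdiff(AA_ALPHABET, c(cyto, secr))
  e <- stats::setNames(numeric(20), AA_ALPHABET)
  e[major] <- 0.9 * 0.8 / length(major)
  e[minor] <- 0.9 * 0.2 / length(minor)
  e[rest] <- 0.1 / length(rest)
  e
}

# single hydrophilic self-looping state: the NO class has no dedicated
# predictive model, only this generator
no_membrane_model <- function(favored_mass = 0.7) {
  hmm_model(ids = "globular", regions = "globular", init = 1,
            trans = matrix(1, 1, 1),
            emis = matrix(initial_emissions("globular", favored_mass), 1, 20),
            orientation = "N-to-C", topology = "no/v1")
}

# truth segments (region, start, end; 0-based half-open, N-to-C) from a
# sampled state path; for C-to-N models the path is in reading order and is
# flipped into original coordinates
path_to_segments <- function(model, path) {
  r <- rle(model$regions[path])
  end1 <- cumsum(r$lengths)
  start1 <- end1 - r$lengths + 1L
  seg <- data.frame(region = r$values, start = start1 - 1L, end = end1,
                    stringsAsFactors = FALSE)
  if (model$orientation == "C-to-N") {
    L <- length(path)
    seg <- data.frame(region = rev(seg$region), start = L - rev(seg$end),
                      end = L - rev(seg$start), stringsAsFactors = FALSE)
  }
  seg
}

seg_lengths <- function(seg, region) {
  sel <- seg$region == region
  if (!any(sel)) integer(0) else seg$end[sel] - seg$start[sel]
}

# class-specific admissibility of a sampled record; generation resamples
# until the record shows the class's defining architecture
record_ok <- function(class, seg, L) {
  tmd <- seg_lengths(seg, "TMD")
  switch(class,
    TA = {
      tails <- which(seg$region == "tail")
      length(tmd) == 1L && tmd >= 15L && tmd <= 25L &&
        length(tails) > 0L &&
        seg$end[max(tails)] == L &&
        (L - seg$start[which(seg$region == "TMD")]) - tmd <= 30L
    },
    SP = length(tmd) == 1L && tmd >= 15L && tmd <= 25L &&
      any(startsWith(seg$region, "signal")),
    MP = length(tmd) >= 2L && all(tmd >= 15L & tmd <= 25L) &&
      any(startsWith(seg$region, "signal")),
    NO = length(tmd) == 0L)
}

#' Generate a labelled synthetic dataset
#'
#' Samples `n` sequences from the class generator ([make_generator()]) with
#' known region annotations. Lengths are drawn from a log-normal distribution
#' (median `median_length`, log-sd `sdlog`) truncated to `length_range`,
#' reflecting the 200-300 residue range in which tail-anchored proteins are
#' abundant. Records are resampled until they show the class's defining
#' architecture: TA records have exactly one TMD of 15-25 residues followed
#' by a hydrophilic tail of 1-30 residues reaching the C-terminus; SP records
#' have a signal peptide and one TMD; MP records have a signal peptide and at
#' least two complete TMDs; NO records never contain a TMD.
#'
#' @param class One of `"TA"`, `"SP"`, `"MP"`, `"NO"`.
#' @param n Number of records.
#' @param median_length Median of the length distribution, in residues.
#' @param length_range Inclusive bounds on sequence length.
#' @param sdlog Log-scale standard deviation of the length distribution.
#' @param difficulty Passed to [make_generator()].
#' @param seed Optional integer seed for reproducibility.
#' @param max_tries Resampling attempts per record before erroring.
#' @return A list of records, each a list with `id`, `class`, `sequence`
#'   (N-to-C character string), `length`, and `segments` (data frame of
#'   region, start, end; 0-based half-open N-to-C coordinates that tile the
#'   sequence). Class attribute `synth_dataset`.
#' @export
generate_dataset <- function(class = c("TA", "SP", "MP", "NO"), n,
                             median_length = 250, length_range = c(50, 1000),
                             sdlog = 0.45, difficulty = 1, seed = NULL,
                             max_tries = 1000L) {
  class <- match.arg(class)
  if (n < 1L) stop_validation("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  gen <- make_generator(class, difficulty)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      L <- draw_length(median_length, length_range, sdlog)
      s <- sample_hmm(gen, L)
      seg <- path_to_segments(gen, s$path)
      if (record_ok(class, seg, L)) break
      if (try == max_tries)
        stop(sprintf("could not sample an admissible %s record in %d tries",
                     class, max_tries))
    }
    seqc <- if (gen$orientation == "C-to-N")
      paste(rev(strsplit(s$sequence, "")[[1L]]), collapse = "") else s$sequence
    records[[i]] <- list(id = sprintf("%s_%04d", class, i), class = class,
                         sequence = seqc, length = L, segments = seg)
  }
  structure(records, class = "synth_dataset",
            generator_class = class, difficulty = difficulty)
}

draw_length <- function(median_length, length_range, sdlog) {
  for (k in 1:1000) {
    L <- round(stats::rlnorm(1, meanlog = log(median_length), sdlog = sdlog))
    if (L >= length_range[1L] && L <= length_range[2L]) return(as.integer(L))
  }
  as.integer(median_length)
}

#' Extract sequences from a synthetic dataset
#'
#' @param dataset A `synth_dataset` from [generate_dataset()].
#' @return Named character vector of N-to-C sequences.
#' @export
dataset_sequences <- function(dataset) {
  stats::setNames(vapply(dataset, `[[`, "", "sequence"),
                  vapply(dataset, `[[`, "", "id"))
}

#' Truth annotations of a synthetic dataset as a table
#'
#' @param dataset A `synth_dataset`.
#' @return Data frame with columns `id`, `class`, `region`, `start`, `end`
#'   (0-based half-open, N-to-C), one row per region segment.
#' @export
dataset_truth <- function(dataset) {
  do.call(rbind, lapply(dataset, function(r)
    cbind(data.frame(id = r$id, class = r$class, stringsAsFactors = FALSE),
          r$segments)))
}

#' Write a synthetic dataset to FASTA plus a truth side-car TSV
#'
#' @param dataset A `synth_dataset`.
#' @param fasta Path of the FASTA file to write.
#' @param truth Optional path of a tab-separated truth table
#'   ([dataset_truth()] layout).
#' @return Invisibly, the FASTA path.
#' @export
write_dataset <- function(dataset, fasta, truth = NULL) {
  write_fasta(dataset_sequences(dataset), fasta)
  if (!is.null(truth))
    utils::write.table(dataset_truth(dataset), truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fasta)
}
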