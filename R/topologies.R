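#' Residue classes used for initial emission biases
#'
#' Partition of the 20-letter alphabet into basic (K, R, H), hydrophobic
#' (Kyte-Doolittle positive: A, C, F, I, L, M, V, W) and hydrophilic (the
#' remaining nine) classes. These seed the untrained emission rows; training
#' re-estimates the exact values.
#'
#' @return Named list of character vectors `basic`, `hydrophobic`,
#'   `hydrophilic`.
#' @export
residue_classes <- function() {
  basic <- c("K", "R", "H")
  hydrophobic <- c("A", "C", "F", "I", "L", "M", "V", "W")
  hydrophilic <- setdiff(AA_ALPHABET, c(basic, hydrophobic))
  list(basic = basic, hydrophobic = hydrophobic, hydrophilic = hydrophilic)
}

# which residue class each region label favours
region_favored_class <- function(region) {
  map <- c(tail = "hydrophilic", TMD = "hydrophobic", cap = "basic",
           globular = "hydrophilic", globular1 = "hydrophilic",
           globular2 = "hydrophilic", signal_basic = "basic",
           signal_hydrophobic = "hydrophobic", signal_polar = "hydrophilic",
           loop = "hydrophilic")
  if (!region %in% names(map))
    stop_validation(sprintf("unknown region label '%s'", region))
  map[[region]]
}

#' Initial (untrained) emission distribution for a region
#'
#' Returns a normalized 20-letter distribution placing `favored_mass` of the
#' probability uniformly on the region's favoured residue class (hydrophobic
#' for TMD, basic for cap and the signal's N-block, hydrophilic elsewhere)
#' and the remainder uniformly on the other letters. The default 70/30 split
#' is strong enough to break symmetry for Baum-Welch yet weak enough to be
#' re-estimated freely.
#'
#' @param region Region label (`"tail"`, `"TMD"`, `"cap"`, `"globular"`,
#'   `"globular1"`, `"globular2"`, `"signal_basic"`, `"signal_hydrophobic"`,
#'   `"signal_polar"`, `"loop"`).
#' @param favored_mass Probability mass placed on the favoured class.
#' @return Named numeric vector over [AA_ALPHABET], summing to 1.
#' @export
initial_emissions <- function(region, favored_mass = 0.7) {
  cls <- residue_classes()[[region_favored_class(region)]]
  e <- stats::setNames(rep((1 - favored_mass) / (20 - length(cls)), 20),
                       AA_ALPHABET)
  e[cls] <- favored_mass / length(cls)
  e
}

# Assemble an hmm_model from a region plan. Each element of `plan` is
# list(region=, n=, ids=); `edges` is a list of c(from_id, to_id); transition
# probability is split equally over each state's allowed successors.
build_from_plan <- function(plan, edges, init_states, orientation, topology,
                            favored_mass = 0.7) {
  ids <- unlist(lapply(plan, `[[`, "ids"))
  regions <- unlist(lapply(plan, function(p) rep(p$region, p$n)))
  S <- length(ids)
  trans <- matrix(0, S, S, dimnames = list(ids, ids))
  for (e in edges) trans[e[1L], e[2L]] <- 1
  deg <- rowSums(trans)
  if (any(deg == 0)) stop("state without successors: ", ids[which(deg == 0)[1L]])
  trans <- trans / deg
  init <- stats::setNames(rep(0, S), ids)
  init[init_states] <- 1 / length(init_states)
  emis <- t(vapply(regions, initial_emissions, numeric(20),
                   favored_mass = favored_mass))
  hmm_model(ids, regions, init, trans, emis, orientation, topology)
}

chain_ids <- function(region, n) paste0(region, seq_len(n))

#' Build the tail-anchored (TA) protein model
#'
#' A model read from the C-terminus (orientation `"C-to-N"`), with four
#' regions in reading order: tail (2 or 4 hydrophilic states; each state may
#' loop on itself, advance, or enter the TMD), TMD (25 hydrophobic states,
#' the first 14 forced to advance so every membrane-spanning run is 15-25
#' residues), cap (up to 5 basic states, each may exit to the globular
#' state), and a single self-looping hydrophilic globular state. The initial
#' distribution puts 0.5 on the tail start and 0.5 on the TMD start, so a
#' protein may have no tail at all.
#'
#' @param tail_states Number of tail states, 2 or 4. Region decoding uses the
#'   2-state variant; likelihood scoring may combine both.
#' @param favored_mass Initial emission bias passed to [initial_emissions()].
#' @return An `hmm_model` with 31 + `tail_states` states.
#' @export
build_ta_model <- function(tail_states = 2L, favored_mass = 0.7) {
  if (!tail_states %in% c(2L, 4L))
    stop_validation("tail_states must be 2 or 4")
  tail <- chain_ids("tail", tail_states)
  tmd <- chain_ids("TMD", 25L)
  cap <- chain_ids("cap", 5L)
  glob <- "globular"
  plan <- list(list(region = "tail", n = tail_states, ids = tail),
               list(region = "TMD", n = 25L, ids = tmd),
               list(region = "cap", n = 5L, ids = cap),
               list(region = "globular", n = 1L, ids = glob))
  edges <- list()
  for (i in seq_len(tail_states)) {
    edges <- c(edges, list(c(tail[i], tail[i])))            # self
    if (i < tail_states) edges <- c(edges, list(c(tail[i], tail[i + 1L])))
    edges <- c(edges, list(c(tail[i], tmd[1L])))
  }
  for (i in 1:24) edges <- c(edges, list(c(tmd[i], tmd[i + 1L])))
  for (i in 15:25) edges <- c(edges, list(c(tmd[i], cap[1L])))
  for (i in 1:4) edges <- c(edges, list(c(cap[i], cap[i + 1L])))
  for (i in 1:5) edges <- c(edges, list(c(cap[i], glob)))
  edges <- c(edges, list(c(glob, glob)))
  build_from_plan(plan, edges, c(tail[1L], tmd[1L]), "C-to-N",
                  sprintf("ta-tail%d/v1", tail_states), favored_mass)
}

# shared signal-peptide block: 10 basic + 15 hydrophobic + 15 polar states in
# a chain; exits to `exit_to` allowed from state 15 through 40 (signal
# lengths 15-40)
signal_plan_edges <- function(exit_to) {
  sb <- chain_ids("sigB", 10L)
  sh <- chain_ids("sigH", 15L)
  sp <- chain_ids("sigP", 15L)
  all <- c(sb, sh, sp)
  plan <- list(list(region = "signal_basic", n = 10L, ids = sb),
               list(region = "signal_hydrophobic", n = 15L, ids = sh),
               list(region = "signal_polar", n = 15L, ids = sp))
  edges <- list()
  for (i in 1:39) edges <- c(edges, list(c(all[i], all[i + 1L])))
  for (i in 15:40) edges <- c(edges, list(c(all[i], exit_to)))
  list(plan = plan, edges = edges, start = all[1L])
}

#' Build the signal-peptide single-pass (SP) model
#'
#' An N-to-C model for membrane proteins with a cleavable signal peptide and
#' one transmembrane domain. Regions in order: signal peptide (10
#' basic-biased, 15 hydrophobic-biased, 15 polar-biased chained states;
#' exits allowed after 15 residues, so signal lengths span 15-40), globular
#' region 1 (single self-looping state), cap (up to 5 basic states), TMD (25
#' states, first 14 forced, runs 15-25 residues), and a terminal self-looping
#' globular region 2. Initial probability is split 0.5/0.5 between the
#' signal start and globular 1.
#'
#' @inheritParams build_ta_model
#' @return An `hmm_model` with 72 states.
#' @export
build_sp_model <- function(favored_mass = 0.7) {
  g1 <- "globular1"
  cap <- chain_ids("cap", 5L)
  tmd <- chain_ids("TMD", 25L)
  g2 <- "globular2"
  sig <- signal_plan_edges(g1)
  plan <- c(sig$plan,
            list(list(region = "globular1", n = 1L, ids = g1),
                 list(region = "cap", n = 5L, ids = cap),
                 list(region = "TMD", n = 25L, ids = tmd),
                 list(region = "globular2", n = 1L, ids = g2)))
  edges <- sig$edges
  edges <- c(edges, list(c(g1, g1), c(g1, cap[1L])))
  for (i in 1:4) edges <- c(edges, list(c(cap[i], cap[i + 1L])))
  for (i in 1:5) edges <- c(edges, list(c(cap[i], tmd[1L])))
  for (i in 1:24) edges <- c(edges, list(c(tmd[i], tmd[i + 1L])))
  for (i in 15:25) edges <- c(edges, list(c(tmd[i], g2)))
  edges <- c(edges, list(c(g2, g2)))
  build_from_plan(plan, edges, c(sig$start, g1), "N-to-C", "sp/v1",
                  favored_mass)
}

#' Build the signal-peptide multi-pass (MP) model
#'
#' An N-to-C model for membrane proteins with a signal peptide and multiple
#' transmembrane domains. The signal, globular, cap and TMD regions are
#' structured as in the SP model, but the TMD exits into a hydrophilic loop
#' region (20 chained states, runs of 1-20 residues) instead of a terminal
#' globular region. Each loop state may advance within the loop, re-enter
#' the cap (leading to the next TMD), or exit to the globular state with
#' equal probability; the globular state loops on itself or re-enters the
#' cap, so long inter-TMD segments can return to the membrane.
#'
#' @inheritParams build_ta_model
#' @return An `hmm_model` with 91 states.
#' @export
build_mp_model <- function(favored_mass = 0.7) {
  g <- "globular"
  cap <- chain_ids("cap", 5L)
  tmd <- chain_ids("TMD", 25L)
  loop <- chain_ids("loop", 20L)
  sig <- signal_plan_edges(g)
  plan <- c(sig$plan,
            list(list(region = "globular", n = 1L, ids = g),
                 list(region = "cap", n = 5L, ids = cap),
                 list(region = "TMD", n = 25L, ids = tmd),
                 list(region = "loop", n = 20L, ids = loop)))
  edges <- sig$edges
  edges <- c(edges, list(c(g, g), c(g, cap[1L])))
  for (i in 1:4) edges <- c(edges, list(c(cap[i], cap[i + 1L])))
  for (i in 1:5) edges <- c(edges, list(c(cap[i], tmd[1L])))
  for (i in 1:24) edges <- c(edges, list(c(tmd[i], tmd[i + 1L])))
  for (i in 15:25) edges <- c(edges, list(c(tmd[i], loop[1L])))
  for (i in 1:19)
    edges <- c(edges, list(c(loop[i], loop[i + 1L]), c(loop[i], cap[1L]),
                           c(loop[i], g)))
  edges <- c(edges, list(c(loop[20L], cap[1L]), c(loop[20L], g)))
  build_from_plan(plan, edges, c(sig$start, g), "N-to-C", "mp/v1",
                  favored_mass)
}
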