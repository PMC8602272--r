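#' Configuration for the synthetic fossil dataset generator
#'
#' Bundles every tunable of the generator. Defaults emulate a Late
#' Triassic--Middle Jurassic sample of fossil taxa scored on a large
#' cladistic matrix: 67 tips on a birth-death tree rooted at 235 Ma and run
#' to 163.5 Ma, 419 mostly binary characters evolved under Mk with
#' lognormal among-character rates, heavy taxon-wise missing data
#' (beta-distributed in [0.3, 0.95]), Brownian-motion log body mass (log kg)
#' and a locomotion class that switches to quadrupedal above a body-mass
#' threshold.
#'
#' @param n_tips number of terminal taxa (>= 4).
#' @param birth_rate,death_rate per-lineage rates per Myr (> 0, >= 0).
#' @param root_age root age in Ma; the simulation stops at `min_age`.
#' @param min_age youngest age considered (Ma); surviving lineages get FADs
#'   just above it.
#' @param min_per_bin target minimum number of sampled taxa per time bin
#'   (stratified taxon sampling; see [simulate_timetree()]).
#' @param n_characters number of discrete characters.
#' @param n_states_max maximum number of states per character (>= 2);
#'   state counts are drawn with probability proportional to `0.3^(k-2)`.
#' @param prop_ordered proportion of characters with ordered (linear) states.
#' @param rate_meanlog,rate_sdlog lognormal parameters of the per-character
#'   Mk rate (events per Myr).
#' @param polymorphism_prob per-cell probability of widening a scored cell
#'   to a two-state polymorphism.
#' @param missing_beta_a,missing_beta_b beta parameters of the per-taxon
#'   missingness rate, rescaled to `missing_range`.
#' @param missing_range range the beta draw is scaled into (default
#'   `c(0.3, 0.95)`).
#' @param bm_root,bm_sigma2 Brownian-motion root value and rate (per Myr)
#'   for log body mass.
#' @param locomotion_threshold log body mass above which a taxon is
#'   quadrupedal.
#' @param locomotion_flip_prob probability a taxon's locomotion class is
#'   flipped (decouples the trait from mass).
#' @param locomotion_unknown_prob probability a taxon's locomotion is
#'   recorded as unknown (to be imputed downstream).
#' @param continent_rate Mk rate of the slow 4-state continent trait.
#' @param seed integer seed; every generator output is a pure function of
#'   the config including the seed.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_tips = 67,
                              birth_rate = 0.35, death_rate = 0.33,
                              root_age = 245, min_age = 163.5,
                              min_per_bin = 7,
                              n_characters = 419, n_states_max = 4,
                              prop_ordered = 0.2,
                              rate_meanlog = log(0.002), rate_sdlog = 0.7,
                              polymorphism_prob = 0.005,
                              missing_beta_a = 4, missing_beta_b = 2,
                              missing_range = c(0.3, 0.95),
                              bm_root = log(300), bm_sigma2 = 0.05,
                              locomotion_threshold = log(500),
                              locomotion_flip_prob = 0.05,
                              locomotion_unknown_prob = 0.15,
                              continent_rate = 0.01,
                              seed = 1234) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tips >= 4, cfg$birth_rate > 0, cfg$death_rate >= 0,
            cfg$root_age > cfg$min_age, cfg$n_characters >= 1,
            cfg$n_states_max >= 2,
            cfg$prop_ordered >= 0, cfg$prop_ordered <= 1,
            cfg$bm_sigma2 >= 0,
            all(cfg$missing_range >= 0), all(cfg$missing_range <= 1),
            diff(cfg$missing_range) >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a birth-death time tree with fossil tips
#'
#' Grows a birth-death tree from `root_age` down to `min_age` and keeps a
#' subset of `n_tips` tips (extinct and surviving mixed), retrying a bounded
#' number of times when extinction leaves too few lineages. Tip extinction
#' ages become first appearance dates (FADs), clamped into the bin-table
#' window (lineages surviving past `min_age`, or originating before the
#' oldest bin, get FADs nudged just inside it). When a bin table is given,
#' the taxon subsample is stratified so that every bin receives at least
#' `min(config$min_per_bin, n_tips %/% n_bins)` taxa -- the sampling
#' structure of a stage-binned fossil dataset -- regrowing the tree when a
#' bin has no standing diversity; if no attempt achieves the target the
#' subsample falls back to unstratified with a warning. The tree is not
#' ultrametric.
#'
#' @param config a [simulation_config()].
#' @param bins a [bin_table()] used for FAD clamping and stratification
#'   (`NULL` disables both; default [default_bin_table()]).
#' @param max_attempts retries before giving up on a runaway extinction.
#' @return list with `tree` (a `phylo`, durations in Myr, `$root.time` set)
#'   and `tip_ages` (named FADs in Ma).
#' @export
simulate_timetree <- function(config, bins = default_bin_table(),
                              max_attempts = 100) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  span <- config$root_age - config$min_age
  fad_of <- function(tr) {
    depth <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    age <- pmax(config$root_age - depth, config$min_age + 0.1)
    if (!is.null(bins)) age <- pmin(age, max(bins$older))
    stats::setNames(age, tr$tip.label)
  }
  target <- if (is.null(bins)) 0L
            else min(config$min_per_bin, config$n_tips %/% nrow(bins))
  best <- NULL
  pick <- NULL
  for (a in seq_len(max_attempts)) {
    tr <- tryCatch(ape::rlineage(config$birth_rate, config$death_rate,
                                 Tmax = span),
                   error = function(e) NULL)
    if (is.null(tr) || length(tr$tip.label) < config$n_tips) next
    if (is.null(best)) best <- tr
    if (is.null(bins)) { best <- tr; pick <- sample(tr$tip.label, config$n_tips); break }
    fads <- fad_of(tr)
    lab <- vapply(fads, function(x) bins_for_range(bins, x)[1], "")
    avail <- split(names(fads), factor(lab, levels = bins$label))
    if (any(lengths(avail) < target)) next
    chosen <- unlist(lapply(avail, function(v)
      sample(v, min(target, length(v)))), use.names = FALSE)
    rest <- setdiff(names(fads), chosen)
    extra <- config$n_tips - length(chosen)
    if (extra > 0) chosen <- c(chosen, sample(rest, extra))
    best <- tr; pick <- chosen
    break
  }
  if (is.null(best)) {
    stop("could not reach ", config$n_tips, " tips in ", max_attempts,
         " attempts (extinction too strong)")
  }
  if (is.null(pick)) {
    warning("could not fill every time bin with ", target,
            " taxa; sampling unstratified")
    pick <- sample(best$tip.label, config$n_tips)
  }
  raw_full <- config$root_age -
    ape::node.depth.edgelength(best)[seq_along(best$tip.label)]
  names(raw_full) <- best$tip.label
  tree <- if (length(best$tip.label) > config$n_tips) {
    ape::keep.tip(best, pick)
  } else best
  # keep.tip reroots at the MRCA of the kept tips: recover its age from any
  # tip's age in the full tree plus its depth in the reduced tree
  raw <- raw_full[tree$tip.label]
  red_depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  tree$root.time <- unname(raw[1] + red_depth[1])
  tree$tip.label <- sprintf("taxon_%02d", seq_along(tree$tip.label))
  ages <- pmax(unname(raw), config$min_age + 0.1)
  if (!is.null(bins)) ages <- pmin(ages, max(bins$older))
  list(tree = tree, tip_ages = stats::setNames(ages, tree$tip.label))
}

# exact continuous-time simulation of one character along one branch.
# unordered: leave at `rate`, move to a uniform other state;
# ordered: adjacent moves only, each at rate/2 (halved at the boundaries).
evolve_state <- function(state, t, rate, k, ordered) {
  if (rate <= 0) return(state)
  repeat {
    if (ordered) {
      up <- state < k - 1L; dn <- state > 0L
      tot <- (up + dn) * rate / 2
    } else tot <- rate
    if (tot <= 0) return(state)
    t <- t - stats::rexp(1, tot)
    if (t < 0) return(state)
    if (ordered) {
      moves <- c(if (state > 0L) state - 1L, if (state < k - 1L) state + 1L)
      state <- if (length(moves) == 1L) moves else sample(moves, 1)
    } else {
      others <- setdiff(0:(k - 1L), state)
      state <- if (length(others) == 1L) others else sample(others, 1)
    }
  }
}

# simulate one discrete character on the whole tree; returns tip states
simulate_mk_character <- function(tree, rate, k, ordered,
                                  root_state = sample.int(k, 1) - 1L) {
  n_tip <- length(tree$tip.label)
  state <- integer(n_tip + tree$Nnode)
  state[n_tip + 1L] <- root_state
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  len <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edge))) {
    state[edge[e, 2]] <- evolve_state(state[edge[e, 1]], len[e], rate, k,
                                      ordered)
  }
  state[seq_len(n_tip)]
}

#' Simulate a cladistic character matrix under the Mk model
#'
#' Each character draws a state count, an ordering flag and a lognormal
#' rate, then evolves along the tree under a continuous-time Mk process
#' (ordered characters move only between adjacent states). A small fraction
#' of scored cells is widened to polymorphisms, and taxon-wise missingness
#' (beta-distributed per taxon) masks cells to missing. Invariant characters
#' are kept.
#'
#' @param tree a `phylo` with branch durations (from [simulate_timetree()]).
#' @param config a [simulation_config()].
#' @return a [clado_matrix()].
#' @export
simulate_character_matrix <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_tip <- length(tree$tip.label)
  m <- config$n_characters
  kk <- 2:config$n_states_max
  k_per <- sample(kk, m, replace = TRUE, prob = 0.3^(kk - 2))
  ordered <- stats::runif(m) < config$prop_ordered
  rates <- stats::rlnorm(m, config$rate_meanlog, config$rate_sdlog)
  codes <- matrix(CM_MISSING, n_tip, m)
  for (ch in seq_len(m)) {
    st <- simulate_mk_character(tree, rates[ch], k_per[ch], ordered[ch])
    codes[, ch] <- bitwShiftL(1L, st)
    poly <- which(stats::runif(n_tip) < config$polymorphism_prob)
    for (i in poly) {
      extra <- if (ordered[ch]) {
        cand <- c(st[i] - 1L, st[i] + 1L)
        cand <- cand[cand >= 0L & cand < k_per[ch]]
        if (length(cand)) sample(cand, 1) else st[i]
      } else sample(setdiff(0:(k_per[ch] - 1L), st[i]), 1)
      codes[i, ch] <- bitwOr(codes[i, ch], bitwShiftL(1L, extra))
    }
  }
  p_miss <- config$missing_range[1] + diff(config$missing_range) *
    stats::rbeta(n_tip, config$missing_beta_a, config$missing_beta_b)
  for (i in seq_len(n_tip)) {
    mask <- stats::runif(m) < p_miss[i]
    codes[i, mask] <- CM_MISSING
  }
  new_clado_matrix(codes, tree$tip.label,
                   ifelse(ordered, "ordered", "unordered"), 1)
}

#' Simulate taxon traits and time-bin assignments
#'
#' Log body mass evolves by Brownian motion (rate `bm_sigma2` per Myr) from
#' `bm_root`; locomotion is quadrupedal when log mass exceeds the threshold,
#' with a small flip probability; the continent is a slow 4-state Mk trait
#' (phylogenetically clumped); femoral length and limb-shaft circumferences
#' are generated allometrically from mass (circumference ratio higher in
#' quadrupeds). Time bins come from the FADs via the bin table.
#'
#' @param tree a `phylo` with branch durations.
#' @param tip_ages named FADs in Ma (from [simulate_timetree()]).
#' @param config a [simulation_config()].
#' @param bins a [bin_table()]; default [default_bin_table()].
#' @return a metadata `data.frame` as produced by [read_taxon_metadata()]
#'   (list-column `bins`, attribute `"bin_table"`).
#' @export
simulate_traits_and_bins <- function(tree, tip_ages, config,
                                     bins = default_bin_table()) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_tip <- length(tree$tip.label)
  # BM for log mass along the branches
  val <- numeric(n_tip + tree$Nnode)
  val[n_tip + 1L] <- config$bm_root
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] +
      stats::rnorm(1, 0, sqrt(config$bm_sigma2 * tr$edge.length[e]))
  }
  logmass <- val[seq_len(n_tip)]
  loco <- ifelse(logmass > config$locomotion_threshold, "quadruped", "biped")
  flip <- stats::runif(n_tip) < config$locomotion_flip_prob
  loco[flip] <- ifelse(loco[flip] == "biped", "quadruped", "biped")
  loco[stats::runif(n_tip) < config$locomotion_unknown_prob] <- "unknown"
  continent <- paste0("continent_",
    simulate_mk_character(tr, config$continent_rate, 4L, FALSE) + 1L)
  fl <- exp(0.36 * logmass + 3.3 + stats::rnorm(n_tip, 0, 0.05))
  fc <- exp(0.38 * logmass + 2.0 + stats::rnorm(n_tip, 0, 0.05))
  ratio <- ifelse(loco == "quadruped", 0.95, 0.75) +
    stats::rnorm(n_tip, 0, 0.03)
  hc <- fc * ratio
  fad <- tip_ages[tree$tip.label]
  df <- data.frame(taxon = tree$tip.label,
                   fad_ma = as.numeric(fad), lad_ma = as.numeric(fad),
                   locomotion = loco, continent = continent,
                   log_body_mass = logmass,
                   femoral_length = fl, humeral_circ = hc,
                   femoral_circ = fc,
                   stringsAsFactors = FALSE)
  df$bins <- lapply(df$fad_ma, function(a) bins_for_range(bins, a))
  attr(df, "bin_table") <- bins
  df
}

#' Generate a complete synthetic dataset bundle
#'
#' Runs [simulate_timetree()], [simulate_character_matrix()] and
#' [simulate_traits_and_bins()] under one config and optionally writes the
#' bundle to disk (NEXUS matrix, Newick tree, CSV metadata). The bundle is a
#' deterministic function of the config (including its seed).
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory.
#' @param bins a [bin_table()].
#' @return list with `tree`, `tip_ages`, `matrix`, `metadata`, `config`,
#'   and `files` (paths, when written).
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL,
                             bins = default_bin_table()) {
  tt <- simulate_timetree(config, bins)
  mat <- simulate_character_matrix(tt$tree, config)
  meta <- simulate_traits_and_bins(tt$tree, tt$tip_ages, config, bins)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(matrix = file.path(dir, "matrix.nex"),
               tree = file.path(dir, "tree.nwk"),
               metadata = file.path(dir, "metadata.csv"))
    write_character_matrix(mat, files["matrix"])
    ape::write.tree(tt$tree, files["tree"])
    out <- meta
    out$bins <- vapply(out$bins, paste, "", collapse = ";")
    utils::write.csv(out, files["metadata"], row.names = FALSE, quote = FALSE)
  }
  list(tree = tt$tree, tip_ages = tt$tip_ages, matrix = mat,
       metadata = meta, config = config, files = files)
}
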