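# Shared fixtures: reference parameter sets and small utilities.

# RY-lumpable null used for calibration experiments.
null_model <- function() {
  substitutionModel(c(0.1, 0.2, 0.3, 0.4), c(0.2, 0.25, 0.2, 0.2, 0.15, 0.2))
}

# Non-lumpable alternative (s_AC raised to 0.5; eta ~ 0.058 for RY).
alt_model <- function() {
  substitutionModel(c(0.1, 0.2, 0.3, 0.4), c(0.5, 0.25, 0.2, 0.2, 0.15, 0.2))
}

# RY-lumpable / KM-non-lumpable model used for the recoding-bias experiments.
bias_model <- function() {
  substitutionModel(c(0.2, 0.3, 0.2, 0.3), c(0.2, 0.1, 0.3, 0.3, 1.0, 0.2))
}

jc_model <- function() substitutionModel(rep(0.25, 4), rep(1, 6))

# Random valid model, frequencies kept away from the boundary.
rand_model <- function() {
  p <- rgamma(4, 5)
  substitutionModel(p / sum(p), rgamma(6, 2, rate = 4))
}

# Brute-force enumeration of all set partitions of {A,C,G,T} into 2 or 3
# blocks, each partition canonicalized as a sorted "block/block" key.
brute_force_partitions <- function() {
  states <- c("A", "C", "G", "T")
  keys <- character()
  # assign each state a block label 1..3; keep assignments using 2 or 3
  # non-empty blocks; canonicalize to kill label permutations
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3) {
    lab <- c(a, b, cc, d)
    nb <- length(unique(lab))
    if (nb < 2L || nb > 3L) next
    blocks <- split(states, lab)
    key <- paste(sort(vapply(blocks, function(x) paste(sort(x), collapse = ""),
                             "")), collapse = "/")
    keys <- c(keys, key)
  }
  sort(unique(keys))
}

scheme_key <- function(scheme) {
  paste(sort(vapply(schemeBlocks(scheme),
                    function(b) paste(sort(b), collapse = ""), "")),
        collapse = "/")
}

# The synthetic 7-leaf simulation tree shipped with the package.
fixture_tree <- function() {
  ape::read.tree(system.file("extdata", "sim_tree_synthetic.nwk",
                             package = "lumpability"))
}
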