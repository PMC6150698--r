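# Shared fixtures, all generated in code.

# smooth band-limited test image for registration tests
smooth_image <- function(n = 48) {
  outer(seq(0, 4 * pi, length.out = n), seq(0, 4 * pi, length.out = n),
        function(a, b) sin(a) + cos(b) + 0.5 * sin(2 * a + b) + 0.3 * cos(3 * b - a))
}

# circular integer shift of a matrix (content moves by +dy, +dx)
circ_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  img[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# brute-force integer registration oracle: the shift to apply to img that
# maximizes circular correlation with ref
brute_force_shift <- function(ref, img) {
  nr <- nrow(ref); nc <- ncol(ref)
  best <- c(0, 0); best_cc <- -Inf
  for (dy in seq(-floor(nr / 2), floor(nr / 2) - 1))
    for (dx in seq(-floor(nc / 2), floor(nc / 2) - 1)) {
      cc <- sum(ref * circ_shift(img, dy, dx))
      if (cc > best_cc) { best_cc <- cc; best <- c(dy, dx) }
    }
  best
}

# connectome of `npair` anatomically non-overlapping pairs (kind "none"):
# bouton regions and spine regions are drawn from disjoint alphabets
null_connectome <- function(npair = 60) {
  bout <- c("SMP", "WED", "IB", "AMP", "Cre", "GA")
  spin <- c("LAL", "BU", "SPS", "NO3A", "FBl7", "NO1")
  types <- paste0(bout[rep(1:6, 2)], ".b-", spin[c(1:6, 6:1)], ".s")
  idx <- utils::combn(12, 2)
  pairs <- data.frame(pre = types[idx[1, ]], post = types[idx[2, ]],
                      kind = "none")[seq_len(npair), ]
  connectome(types, pairs)
}

# simulate an all-null screen at a single stimulation strength
null_screen <- function(npair = 60, n_flies = 6, seed = 1) {
  simulate_experiment(null_connectome(npair), n_flies = n_flies,
                      protocols = default_protocols(30), seed = seed)
}
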