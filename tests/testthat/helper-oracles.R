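# Independent oracles, kept deliberately naive and separate from the
# implementation code paths they check.

# Patristic distances by explicit path summation: for every tip pair, walk
# the node path and add the length of each traversed edge.
patristic_oracle <- function(tree) {
  n <- length(tree$tip.label)
  edge_len <- function(a, b) {
    hit <- (tree$edge[, 1] == a & tree$edge[, 2] == b) |
      (tree$edge[, 1] == b & tree$edge[, 2] == a)
    tree$edge.length[which(hit)]
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- ape::nodepath(tree, i, j)
      d[i, j] <- d[j, i] <- sum(mapply(edge_len, p[-length(p)], p[-1]))
    }
  }
  d
}

# MNTD by a double loop over the sample.
mntd_oracle <- function(sample, d) {
  mean(vapply(sample, function(i) min(d[i, setdiff(sample, i)]), 0))
}

# Approximate Monte-Carlo standard error of a standardized effect size
# estimated from n_reps null draws (delta method, near-normal null).
ses_mc_se <- function(ses, n_reps) sqrt((1 + ses^2 / 2) / n_reps)

# Weighted-mean-age oracle for MDT.
mdt_oracle <- function(ages, counts) sum(ages * counts) / sum(counts)
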