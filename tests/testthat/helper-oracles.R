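# Independent brute-force oracles used to cross-check the implementation.

# Textbook Benjamini-Hochberg step-up written from the definition:
# sort p ascending, q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# MCC from the phi-coefficient identity on the 2x2 table:
# phi = (n * n11 - r1 * c1) / sqrt(r1 * r2 * c1 * c2)
oracle_mcc_phi <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  r1 <- tp + fn; r2 <- fp + tn    # actual pos / neg
  c1 <- tp + fp; c2 <- fn + tn    # called pos / neg
  den <- sqrt(r1) * sqrt(r2) * sqrt(c1) * sqrt(c2)
  if (den == 0) return(0)
  (n * tp - r1 * c1) / den
}

# Exhaustive pairwise average-linkage agglomeration on a distance matrix.
# Returns the merge heights and the flat grouping at k clusters.
oracle_average_linkage <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  avg_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- avg_dist(clusters[[i]], clusters[[j]])
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    if (length(clusters) == k) flat_at_k <- clusters
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  if (k == 1L) flat_at_k <- clusters
  membership <- integer(n)
  for (ci in seq_along(flat_at_k)) membership[flat_at_k[[ci]]] <- ci
  list(heights = heights, membership = membership)
}

# Cluster assignments compared up to relabelling.
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1))]))
}

# Random peptide over the 20 standard residues.
random_peptide <- function(n) {
  paste(sample(strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# A tiny three-member family with known shared and unique peptides.
toy_family <- function() {
  data.frame(
    id = c("A", "B", "C"),
    accession = c("ACC_A", "ACC_B", "ACC_C"),
    sequence = c("MSHAREDKVVVQNDTLLQKAAPK",   # SHAREDK also in B
                 "MSHAREDKWWWTTTPPPKGGGK",
                 "MFFFYYYKDDDEEEKAAPK"),      # AAPK also in A
    stringsAsFactors = FALSE)
}
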