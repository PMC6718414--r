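# Independent brute-force oracles used across the suite. These are written
# from the definitions, not from the package internals.

# Cleavage positions (cut after residue i), recomputed from the rules.
oracle_cut_sites <- function(letters, enzymes, acetyl_sites = integer(),
                             not_before_p = TRUE, gluc_d = FALSE) {
  n <- length(letters)
  sites <- integer()
  for (i in seq_len(max(n - 1L, 0L))) {
    tryp <- "trypsin" %in% enzymes && letters[i] %in% c("K", "R") &&
      !(not_before_p && letters[i + 1L] == "P") &&
      !(letters[i] == "K" && i %in% acetyl_sites)
    gluc <- "gluc" %in% enzymes &&
      (letters[i] == "E" || (gluc_d && letters[i] == "D"))
    if (tryp || gluc) sites <- c(sites, i)
  }
  sites
}

# Every substring whose ends are cleavage boundaries and whose interior
# skips at most max_missed cut sites.
oracle_digest <- function(sequence, enzymes = c("trypsin", "gluc"),
                          max_missed = 0L, acetyl_sites = integer(),
                          not_before_p = TRUE, gluc_d = FALSE) {
  letters <- strsplit(sequence, "")[[1]]
  n <- length(letters)
  sites <- oracle_cut_sites(letters, enzymes, acetyl_sites, not_before_p, gluc_d)
  boundaries <- c(0L, sites, n)
  out <- list()
  for (a in seq_len(n)) for (b in a:n) {
    if (!((a - 1L) %in% boundaries) || !(b %in% boundaries)) next
    internal <- sum(sites > (a - 1L) & sites < b)
    if (internal <= max_missed)
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b, sequence = substr(sequence, a, b),
        missed_cleavages = internal)
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# Hypergeometric upper tail from binomial coefficients, no phyper.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up applied literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# KS D statistic by exhaustive ECDF-difference maximisation.
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# O(n^3) complete-linkage agglomeration; returns sorted merge heights.
oracle_complete_linkage_heights <- function(m) {
  clusters <- as.list(seq_len(nrow(m)))
  d <- as.matrix(dist(m))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Rank-based AUC of score against binary truth.
oracle_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
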