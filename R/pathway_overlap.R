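# Over-representation analysis, localization binning, cross-model overlap
# and concordance, KS comparison, and hierarchical clustering for heatmap
# row ordering.

#' Over-representation analysis against a gene-set collection
#'
#' For each set, the hypergeometric upper tail P(X >= k) of drawing k set
#' members in a hit list of size n from a universe of size N containing K
#' set members. Sets are restricted to the universe and filtered by size;
#' p-values are Benjamini-Hochberg adjusted across the tested sets.
#'
#' @param hits Character vector of hit identifiers. Hits outside the
#'   universe are dropped with a warning.
#' @param sets Named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @param universe Character vector of all assayable identifiers.
#' @param min_size,max_size Set-size window after universe restriction.
#' @param fdr FDR threshold for the `enriched` flag.
#' @param universe_size Optional explicit N overriding
#'   `length(unique(universe))` (e.g. the full protein-coding gene count);
#'   set membership is still computed on `universe`.
#' @return `data.frame`: `pathway_id`, `overlap_k`, `hits_n`, `set_K`,
#'   `universe_N`, `fold_enrichment`, `p_value`, `fdr`, `enriched`.
#' @export
ora <- function(hits, sets, universe, min_size = 5L, max_size = 500L,
                fdr = 0.05, universe_size = NULL) {
  universe <- unique(universe)
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    warning(length(outside), " hit(s) outside the universe dropped")
    hits <- setdiff(hits, outside)
  }
  if (!length(hits)) {
    warning("empty hit list; returning no enrichment results")
    return(data.frame(pathway_id = character(), overlap_k = integer(),
                      hits_n = integer(), set_K = integer(),
                      universe_N = integer(), fold_enrichment = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      enriched = logical()))
  }
  restricted <- lapply(sets, intersect, universe)
  sizes <- lengths(restricted)
  keep <- sizes >= min_size & sizes <= max_size
  restricted <- restricted[keep]
  n <- length(hits)
  N <- if (is.null(universe_size)) length(universe) else as.integer(universe_size)
  res <- do.call(rbind, lapply(names(restricted), function(id) {
    members <- restricted[[id]]
    K <- length(members)
    k <- length(intersect(hits, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, overlap_k = k, hits_n = n, set_K = K,
               universe_N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    warning("no gene set within the size window")
    return(data.frame(pathway_id = character(), overlap_k = integer(),
                      hits_n = integer(), set_K = integer(),
                      universe_N = integer(), fold_enrichment = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      enriched = logical()))
  }
  res$fdr <- bh_adjust(res$p_value)
  res$enriched <- res$fdr < fdr
  res[order(res$p_value), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Default subcellular-localization binning scheme
#'
#' Term-to-bin dictionary mapping primary annotation terms to four bins:
#' secretory (endoplasmic reticulum, Golgi apparatus, proteasome,
#' lysosome, extracellular, secreted), mitochondria, nucleus (nucleus and
#' chromosome), and cytoplasm (cytoskeleton, cytosol, ribosome, and all
#' other organelles as catch-all). Shipped as a TSV under
#' `extdata/localization_bins.tsv` so users can extend it.
#'
#' @return Named character vector: lower-case term -> bin.
#' @export
localization_scheme <- function() {
  path <- system.file("extdata", "localization_bins.tsv", package = "acetylflux",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$bin, tolower(tab$term))
}

#' Assign annotation terms to localization bins
#'
#' Lookup is case-insensitive and exact on the scheme's terms; unmatched
#' terms fall to `"cytoplasm"` (the all-other-organelles catch-all) with
#' a warning.
#'
#' @param term Character vector of annotation terms.
#' @param scheme Named vector term -> bin ([localization_scheme()]).
#' @return Character vector of bins.
#' @export
#' @examples
#' \dontrun{assign_localization(c("Golgi apparatus", "chromosome"))}
assign_localization <- function(term, scheme = localization_scheme()) {
  if (any(!nzchar(term))) stop("empty annotation term")
  bin <- unname(scheme[tolower(term)])
  unmatched <- is.na(bin)
  if (any(unmatched)) {
    warning(sum(unmatched), " unmatched term(s) assigned to cytoplasm: ",
            paste(unique(term[unmatched]), collapse = ", "))
    bin[unmatched] <- "cytoplasm"
  }
  bin
}

#' Overlap and sign concordance of two signed change maps
#'
#' Counts identifiers unique to each map and shared between them, and for
#' shared identifiers whether the signed changes agree (concordant) or
#' oppose (discordant). Zero changes are excluded with a warning.
#'
#' @param a,b Named numeric vectors of signed changes (e.g. per-site
#'   stoichiometry percent change per genotype model).
#' @return List: `n_only_a`, `n_only_b`, `n_both`, `concordant`,
#'   `discordant`.
#' @export
#' @examples
#' overlap_concordance(c(s1 = 5, s2 = -3), c(s1 = -2, s2 = -1))
overlap_concordance <- function(a, b) {
  drop_zero <- function(x, label) {
    if (any(x == 0)) {
      warning(sum(x == 0), " zero change(s) excluded from ", label)
      x <- x[x != 0]
    }
    x
  }
  a <- drop_zero(a, "a"); b <- drop_zero(b, "b")
  shared <- intersect(names(a), names(b))
  same <- sign(a[shared]) == sign(b[shared])
  list(n_only_a = length(setdiff(names(a), names(b))),
       n_only_b = length(setdiff(names(b), names(a))),
       n_both = length(shared),
       concordant = sum(same),
       discordant = sum(!same))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D = sup |ECDF_x - ECDF_y| with the asymptotic two-sided p-value by
#' default (exact small-sample p available via `exact = TRUE`).
#'
#' @param x,y Numeric samples (each >= 2 values).
#' @param exact Use the exact p-value computation.
#' @return List with `D` and `p_value`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Hierarchical clustering for heat-map row ordering
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' between rows of a fold-change matrix; missing values are imputed as 0
#' with a warning. Ties are broken deterministically by input row order.
#'
#' @param m Numeric matrix (rows = features, e.g. log2 fold changes).
#' @return List: `hclust` (the tree; `NULL` for a single row), `order`
#'   (leaf ordering of row indices), `labels`.
#' @export
hierarchical_cluster <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " missing value(s) imputed as 0")
    m[is.na(m)] <- 0
  }
  labels <- rownames(m)
  if (nrow(m) < 2)
    return(list(hclust = NULL, order = seq_len(nrow(m)), labels = labels))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  list(hclust = hc, order = hc$order, labels = labels)
}

#' Export a clustering dendrogram as Newick
#'
#' @param cluster Result of [hierarchical_cluster()] (needs >= 2 rows).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(cluster, path) {
  if (is.null(cluster$hclust)) stop("no tree: fewer than 2 rows were clustered")
  phy <- ape::as.phylo(cluster$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
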