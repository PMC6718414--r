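# Two-batch 4-plex isobaric reporter-ion differential proteome statistics.

#' Retain only PSMs with all reporter channels present
#'
#' A peptide-spectrum match contributes to quantification only when every
#' reporter channel was observed with positive intensity.
#'
#' @param psms `data.frame` with intensity columns `channels`.
#' @param channels Names of the reporter intensity columns.
#' @return The filtered `data.frame`; warns when nothing survives.
#' @export
filter_complete_psms <- function(psms, channels = paste0("ch", 1:4)) {
  missing_cols <- setdiff(channels, names(psms))
  if (length(missing_cols))
    stop("missing channel column(s): ", paste(missing_cols, collapse = ", "))
  intens <- as.matrix(psms[, channels, drop = FALSE])
  keep <- rowSums(is.na(intens) | intens <= 0) == 0
  if (!any(keep)) warning("no PSM has all reporter channels present")
  psms[keep, , drop = FALSE]
}

#' Per-protein channel abundances and log2 fold change for one batch
#'
#' Sums unique-PSM intensities per protein and channel, then computes
#' log2(mean of mutant channels / mean of control channels). Proteins need
#' at least one unique quantified peptide; proteins whose control mean is
#' zero are excluded with a warning.
#'
#' @param psms Complete-channel PSM table with columns `protein_group`,
#'   `unique` (0/1) and the channel intensities.
#' @param channel_groups Character vector (same length as `channels`)
#'   assigning each channel to `"MUT"` or `"WT"`.
#' @param channels Reporter intensity column names.
#' @return `data.frame`: `protein_group`, per-channel summed values,
#'   `log2_fc`, `n_unique_peptides`.
#' @export
protein_batch_ratio <- function(psms, channel_groups = c("MUT", "MUT", "WT", "WT"),
                                channels = paste0("ch", 1:4)) {
  if (length(channel_groups) != length(channels))
    stop("channel_groups must match channels in length")
  if (!all(channel_groups %in% c("MUT", "WT")) ||
      !all(c("MUT", "WT") %in% channel_groups))
    stop("channel_groups must contain both MUT and WT labels")
  u <- psms[psms$unique > 0, , drop = FALSE]
  if (!nrow(u)) stop("no unique PSMs in batch")
  sums <- rowsum(as.matrix(u[, channels, drop = FALSE]), u$protein_group)
  n_pep <- as.integer(table(u$protein_group)[rownames(sums)])
  mut_mean <- rowMeans(sums[, channel_groups == "MUT", drop = FALSE])
  wt_mean <- rowMeans(sums[, channel_groups == "WT", drop = FALSE])
  ok <- wt_mean > 0
  if (any(!ok))
    warning(sum(!ok), " protein(s) excluded: zero control-channel mean")
  data.frame(protein_group = rownames(sums), sums,
             log2_fc = ifelse(ok, log2(mut_mean / wt_mean), NA_real_),
             n_unique_peptides = n_pep,
             row.names = NULL, stringsAsFactors = FALSE)[ok, , drop = FALSE]
}

#' Variance-gated two-sample t-test
#'
#' An F-test of variance equality decides the t-test flavour: when the
#' F-test does not reject at `gate_alpha`, a pooled-variance Student test
#' is used; otherwise the Welch unequal-variance test.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param gate_alpha F-test significance level for the gate.
#' @param alternative Passed to [stats::t.test()] (default two-sided).
#' @return List: `p_value`, `equal_variance` (gate outcome), `statistic`.
#' @export
variance_gated_t <- function(a, b, gate_alpha = 0.05, alternative = "two.sided") {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: no within-group spread at all
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(p_value = p, equal_variance = TRUE, statistic = NA_real_))
  }
  equal_var <- stats::var.test(a, b)$p.value >= gate_alpha
  tt <- stats::t.test(a, b, var.equal = equal_var, alternative = alternative)
  list(p_value = tt$p.value, equal_variance = equal_var,
       statistic = unname(tt$statistic))
}

#' Combine p-values by Fisher's method
#'
#' X = -2 * sum(log p) is referred to a chi-square distribution with 2k
#' degrees of freedom. Zero p-values are clamped to the smallest positive
#' representable double with a warning.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05))
fisher_combine <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  if (any(p > 1) || any(p < 0)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning(sum(p == 0), " zero p-value(s) clamped")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Two-batch differential proteome analysis
#'
#' Runs the per-batch pipeline (complete-channel PSM filter, unique-PSM
#' protein ratios, variance-gated t-test on per-channel protein values)
#' on both batches, averages the batch log2 fold changes, and combines
#' the batch p-values with Fisher's method. Only proteins quantified in
#' both batches enter the combined table.
#'
#' @param batch1,batch2 PSM tables (`psm_id`, `protein_group`, `unique`,
#'   channel intensity columns).
#' @param channel_groups Channel-to-group assignment shared by both
#'   batches (default MUT, MUT, WT, WT).
#' @param channels Reporter intensity column names.
#' @param alpha Significance level on the combined p-value.
#' @param gate_alpha F-test gate level.
#' @param alternative t-test tail.
#' @return Object of class `dileu_fit`: list with `proteins` (combined
#'   table: `protein_group`, `fc_batch1`, `p_batch1`, `fc_batch2`,
#'   `p_batch2`, `fc_mean`, `fisher_p`, `significant`), `batches`
#'   (per-batch ratio tables), and parameters.
#' @export
dileu_analysis <- function(batch1, batch2,
                           channel_groups = c("MUT", "MUT", "WT", "WT"),
                           channels = paste0("ch", 1:4), alpha = 0.05,
                           gate_alpha = 0.05, alternative = "two.sided") {
  one_batch <- function(psms) {
    ratios <- protein_batch_ratio(filter_complete_psms(psms, channels),
                                  channel_groups, channels)
    mut_cols <- channels[channel_groups == "MUT"]
    wt_cols <- channels[channel_groups == "WT"]
    ratios$p_value <- vapply(seq_len(nrow(ratios)), function(i) {
      variance_gated_t(as.numeric(ratios[i, mut_cols]),
                       as.numeric(ratios[i, wt_cols]),
                       gate_alpha = gate_alpha,
                       alternative = alternative)$p_value
    }, numeric(1))
    ratios
  }
  b1 <- one_batch(batch1)
  b2 <- one_batch(batch2)
  shared <- intersect(b1$protein_group, b2$protein_group)
  i1 <- match(shared, b1$protein_group)
  i2 <- match(shared, b2$protein_group)
  fisher_p <- mapply(function(p, q) fisher_combine(c(p, q)),
                     b1$p_value[i1], b2$p_value[i2])
  proteins <- data.frame(
    protein_group = shared,
    fc_batch1 = b1$log2_fc[i1], p_batch1 = b1$p_value[i1],
    fc_batch2 = b2$log2_fc[i2], p_batch2 = b2$p_value[i2],
    fc_mean = (b1$log2_fc[i1] + b2$log2_fc[i2]) / 2,
    fisher_p = fisher_p,
    significant = fisher_p < alpha,
    stringsAsFactors = FALSE)
  structure(list(proteins = proteins, batches = list(b1, b2), alpha = alpha,
                 channel_groups = channel_groups),
            class = "dileu_fit")
}

#' Summarise a differential proteome result
#'
#' @param proteins Combined protein table (as in `dileu_fit$proteins`) or
#'   a `dileu_fit`.
#' @return List: `n_quantified`, `n_significant`, `mean_log2_fc` (over all
#'   quantified proteins).
#' @export
summarize_proteome <- function(proteins) {
  if (inherits(proteins, "dileu_fit")) proteins <- proteins$proteins
  if (!nrow(proteins))
    return(list(n_quantified = 0L, n_significant = 0L, mean_log2_fc = NA_real_))
  list(n_quantified = nrow(proteins),
       n_significant = sum(proteins$significant),
       mean_log2_fc = mean(proteins$fc_mean))
}

#' Compare two fold-change distributions
#'
#' Kolmogorov-Smirnov comparison of the combined log2 fold-change
#' distributions of two differential analyses (e.g. the two genotype
#' models).
#'
#' @param fit_a,fit_b `dileu_fit` objects or protein tables.
#' @param ... Passed to [ks_two_sample()].
#' @return List with `D` and `p_value`.
#' @export
compare_fc_distributions <- function(fit_a, fit_b, ...) {
  if (inherits(fit_a, "dileu_fit")) fit_a <- fit_a$proteins
  if (inherits(fit_b, "dileu_fit")) fit_b <- fit_b$proteins
  ks_two_sample(fit_a$fc_mean, fit_b$fc_mean, ...)
}

#' @export
print.dileu_fit <- function(x, ...) {
  s <- summarize_proteome(x)
  cat("Two-batch isobaric differential proteome analysis\n")
  cat(sprintf("  proteins quantified in both batches: %d\n", s$n_quantified))
  cat(sprintf("  significant (Fisher p < %.2g): %d\n", x$alpha, s$n_significant))
  cat(sprintf("  mean log2 fold change: %.3f\n", s$mean_log2_fc))
  invisible(x)
}

#' @export
summary.dileu_fit <- function(object, ...) {
  s <- summarize_proteome(object)
  s$fc_quartiles <- stats::quantile(object$proteins$fc_mean, c(0.25, 0.5, 0.75))
  class(s) <- "summary.dileu_fit"
  s
}

#' @export
print.summary.dileu_fit <- function(x, ...) {
  cat(sprintf("Quantified: %d; significant: %d; mean log2 FC: %.3f\n",
              x$n_quantified, x$n_significant, x$mean_log2_fc))
  cat("log2 FC quartiles:\n")
  print(round(x$fc_quartiles, 3))
  invisible(x)
}
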