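# Synthetic cohort generator: determinism, ground-truth structure, and
# noiseless round trips through every consuming stage.

test_that("generation is bit-identical for identical config and seed", {
  cfg <- cohort_config(n_proteins = 25, n_sites = 30, seed = 99)
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_fragment_areas(t1, "MUT_up"),
                   simulate_fragment_areas(t2, "MUT_up"))
  expect_identical(simulate_dileu_batches(t1, "MUT_down"),
                   simulate_dileu_batches(t2, "MUT_down"))
  expect_identical(simulate_tracer_and_ocr(t1), simulate_tracer_and_ocr(t2))
  t3 <- simulate_cohort(cohort_config(n_proteins = 25, n_sites = 30,
                                      seed = 100))
  expect_false(identical(t1$proteins$fc_MUT_up, t3$proteins$fc_MUT_up))
})

test_that("ground truth respects the configured effect structure", {
  cfg0 <- cohort_config(n_proteins = 50, n_sites = 40,
                        frac_signif_proteome = 0, seed = 2)
  t0 <- simulate_cohort(cfg0)
  expect_true(all(t0$proteins$fc_MUT_up == 0))
  expect_true(all(t0$proteins$fc_MUT_down == 0))

  cfg <- cohort_config(n_sites = 400, frac_affected_both = 0.5,
                       discordance_prob = 1, seed = 3)
  t1 <- simulate_cohort(cfg)
  both <- t1$sites[t1$sites$category == "both", ]
  expect_gt(nrow(both), 100)
  concordant <- sum(sign(both$shift_MUT_up) == sign(both$shift_MUT_down))
  expect_equal(concordant, 0L)
  expect_true(all(t1$sites$base_stoich > 0.005 & t1$sites$base_stoich < 0.995))
  expect_true(all(t1$sites$stoich_MUT_up > 0 & t1$sites$stoich_MUT_up < 1))
  expect_error(simulate_cohort(list()), "cohort_config")
})

test_that("noiseless fragment areas return the truth exactly", {
  cfg <- cohort_config(n_proteins = 15, n_sites = 20, noise_cv = 0,
                       envelope_leakage = FALSE, seed = 4)
  truth <- simulate_cohort(cfg)
  fr <- simulate_fragment_areas(truth, "MUT_up")
  s <- fragment_stoichiometry(fr$light_area, fr$heavy_area)
  wt <- fr$group == "WT"
  expect_equal(s[wt], truth$sites$base_stoich[match(fr$site_id[wt],
                                                    truth$sites$site_id)],
               tolerance = 1e-12)
  expect_equal(s[!wt], truth$sites$stoich_MUT_up[match(fr$site_id[!wt],
                                                       truth$sites$site_id)],
               tolerance = 1e-12)
})

test_that("uncorrected stoichiometry is biased low when leakage is on", {
  cfg <- cohort_config(n_proteins = 30, n_sites = 60, seed = 6)
  truth <- simulate_cohort(cfg)
  fr <- simulate_fragment_areas(truth, "MUT_up")
  naive <- stoich_analysis(fr, correct_envelope = FALSE)
  corrected <- stoich_analysis(fr, correct_envelope = TRUE)
  truth_wt <- truth$sites$base_stoich[match(naive$records$site_id[
    naive$records$group == "WT"], truth$sites$site_id)]
  bias_naive <- naive$records$stoichiometry[naive$records$group == "WT"] - truth_wt
  bias_corr <- corrected$records$stoichiometry[corrected$records$group == "WT"] -
    truth_wt
  # sign test: the naive estimate underestimates on the clear majority
  expect_gt(mean(bias_naive < 0), 0.75)
  expect_lt(abs(median(bias_corr)), abs(median(bias_naive)))
  expect_lt(abs(median(bias_corr)), 0.005)
})

test_that("zeroed channels are injected and removed by the filter", {
  cfg <- cohort_config(n_proteins = 334, n_sites = 10, psms_per_protein = 3,
                       zero_channel_frac = 0.3, seed = 10)
  truth <- simulate_cohort(cfg)
  b <- simulate_dileu_batches(truth, "MUT_up")
  n_total <- nrow(b$batch1)
  expect_gte(n_total, 1000)
  kept <- filter_complete_psms(b$batch1)
  n_zeroed <- sum(apply(b$batch1[, paste0("ch", 1:4)] == 0, 1, any))
  expect_equal(nrow(kept), n_total - n_zeroed)
  expect_equal(abs(n_zeroed / n_total - 0.3) < 0.05, TRUE)
})

test_that("noiseless tracer tables invert exactly and OCR encodes capacity", {
  cfg <- cohort_config(n_proteins = 10, n_sites = 10, tracer_cv = 0, seed = 12)
  truth <- simulate_cohort(cfg)
  tr <- simulate_tracer_and_ocr(truth)
  res <- tracer_analysis(tr$isotopologues, tr$metabolite_spec)
  one <- res[res$metabolite == "fumarate" & res$group == "MUT_up", ]
  frac_true <- truth$metabolites$frac_MUT_up[
    truth$metabolites$metabolite == "fumarate"]
  expect_equal(unique(round(one$fraction, 9)), round(frac_true, 9))

  s <- summarize_ocr(tr$ocr)
  caps <- fao_capacity(s$baseline, s$post_ukbptes, s$post_all)
  grp <- sub("_hep.*", "", s$sample_id)
  expect_equal(unname(caps), unname(truth$fao[grp]), tolerance = 1e-9)
})

test_that("every generated table passes the consuming module's validation", {
  cfg <- cohort_config(n_proteins = 20, n_sites = 25, seed = 14)
  truth <- simulate_cohort(cfg)
  fr <- simulate_fragment_areas(truth, "MUT_down")
  expect_s3_class(stoich_analysis(fr), "stoich_fit")
  b <- simulate_dileu_batches(truth, "MUT_down")
  expect_s3_class(dileu_analysis(b$batch1, b$batch2), "dileu_fit")
  tr <- simulate_tracer_and_ocr(truth)
  expect_true(all(tracer_analysis(tr$isotopologues,
                                  tr$metabolite_spec)$corrected >= 0))
  expect_true(all(summarize_ocr(tr$ocr)$baseline > 0))
  sets <- simulate_gene_sets(truth)
  expect_true(all(lengths(sets) > 0))
  expect_true(all(unlist(sets) %in% truth$proteins$accession))
})

test_that("simulate_all writes a complete plain-text data set", {
  outdir <- file.path(tempdir(), "simall")
  cfg <- cohort_config(n_proteins = 20, n_sites = 25, seed = 15)
  truth <- simulate_all(cfg, outdir)
  files <- c("fragment_areas_MUT_up.tsv", "fragment_areas_MUT_down.tsv",
             "dileu_MUT_up_batch1.tsv", "dileu_MUT_down_batch2.tsv",
             "isotopologues.tsv", "metabolite_spec.tsv", "ocr.tsv",
             "proteins.fasta", "pathways.gmt", "annotation.tsv",
             "ground_truth_proteins.tsv", "ground_truth_sites.tsv")
  expect_true(all(file.exists(file.path(outdir, files))))
  fasta <- read_protein_fasta(file.path(outdir, "proteins.fasta"))
  expect_equal(fasta$sequence, truth$proteins$sequence)
  gmt <- read_gmt(file.path(outdir, "pathways.gmt"))
  expect_true(any(grepl("^PLANTED", names(gmt))))
  fr <- read_tsv(file.path(outdir, "fragment_areas_MUT_up.tsv"))
  expect_s3_class(stoich_analysis(fr), "stoich_fit")
  ann <- read_tsv(file.path(outdir, "annotation.tsv"))
  expect_true(all(assign_localization(ann$localization) %in%
                    c("secretory", "mitochondria", "nucleus", "cytoplasm")))
})
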