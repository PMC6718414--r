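# Seeded synthetic cohort generator. Emulates a two-genotype mouse liver
# study: one genotype shifting lysine-acetylation stoichiometry down
# (MUT_down, transporter overexpression draining cytosolic acetyl-CoA) and
# one shifting it up (MUT_up, haploinsufficient transporter), each against
# n = 4 littermate controls, with two 4-plex isobaric batches per genotype,
# lognormal multiplicative peak-area noise, natural-isotope leakage of the
# light acetyl species into the +3 Da heavy channel, and 13C-glutamine
# labeling of TCA intermediates.

#' Synthetic cohort configuration
#'
#' Defaults encode the emulated study design: 4 animals per group, two
#' genotypes with predominantly opposite-direction stoichiometry shifts
#' (discordance probability 0.95), per-site baseline stoichiometries
#' spanning 1-99%, 10% coefficient-of-variation multiplicative peak-area
#' noise, and two 4-plex reporter batches per genotype with two mutant and
#' two control channels each.
#'
#' @param n_per_group Animals per genotype group.
#' @param n_proteins,n_sites Number of synthetic proteins / acetyl sites.
#' @param fragments_per_site Fragment ions quantified per site.
#' @param frac_signif_proteome Fraction of proteins with a true abundance
#'   effect per genotype.
#' @param frac_affected_both Fraction of sites with a true stoichiometry
#'   shift in both genotypes.
#' @param frac_affected_single Fraction of sites shifted in exactly one
#'   genotype (each).
#' @param discordance_prob Probability that a site shifted in both
#'   genotypes has opposite-sign shifts.
#' @param fc_mean,fc_sd Mean/sd of the true |log2 FC| of affected proteins.
#' @param stoich_shift_mean,stoich_shift_sd Mean/sd of the true
#'   stoichiometry shift magnitude (fraction points).
#' @param noise_cv Multiplicative lognormal CV of fragment peak areas.
#' @param envelope_leakage Add natural-isotope leakage of the light
#'   species into the heavy channel.
#' @param psms_per_protein Unique PSMs per protein and batch.
#' @param dileu_cv Multiplicative CV of reporter intensities.
#' @param zero_channel_frac Fraction of PSMs with one zeroed channel
#'   (exercises the completeness filter).
#' @param tracer_cv Multiplicative CV of isotopologue intensities.
#' @param fao_capacity_by_group Named vector of true FAO capacities.
#' @param seed Integer seed; all stages derive independent substreams
#'   from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 4L, n_proteins = 300L, n_sites = 600L,
                          fragments_per_site = 6L,
                          frac_signif_proteome = 0.1,
                          frac_affected_both = 0.10,
                          frac_affected_single = 0.20,
                          discordance_prob = 0.95,
                          fc_mean = 1, fc_sd = 0.25,
                          stoich_shift_mean = 0.15, stoich_shift_sd = 0.05,
                          noise_cv = 0.10, envelope_leakage = TRUE,
                          psms_per_protein = 3L, dileu_cv = 0.10,
                          zero_channel_frac = 0.05, tracer_cv = 0.01,
                          fao_capacity_by_group = c(WT = 0.30, MUT_up = 0.45,
                                                    MUT_down = 0.60),
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_per_group >= 2,
            frac_signif_proteome >= 0, frac_signif_proteome <= 1,
            frac_affected_both >= 0,
            frac_affected_both + 2 * frac_affected_single <= 1,
            discordance_prob >= 0, discordance_prob <= 1,
            noise_cv >= 0, dileu_cv >= 0, tracer_cv >= 0,
            zero_channel_frac >= 0, zero_channel_frac <= 1)
  class(cfg) <- "cohort_config"
  cfg
}

# Independent substream seeds derived from the global seed, one per stage.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 1L, frag_MUT_up = 2L, frag_MUT_down = 3L,
               dileu_MUT_up = 4L, dileu_MUT_down = 5L, tracer = 6L,
               pathways = 7L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

# lognormal multiplicative noise with mean 1 and given CV
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

random_peptide_with_k <- function(len) {
  aas <- setdiff(AA_LETTERS, c("K", "R", "E", "D", "P"))  # one clean K site
  pep <- sample(aas, len, replace = TRUE)
  kpos <- sample(seq_len(len - 1L), 1L) # keep K internal-ish
  pep[kpos] <- "K"
  list(sequence = paste(pep, collapse = ""), k_pos = kpos)
}

#' Simulate the ground truth of a two-genotype cohort
#'
#' Draws per-protein true log2 fold changes per genotype (null proteins at
#' 0; effects with random sign), per-site baseline stoichiometries
#' Uniform(0.01, 0.99), and signed stoichiometry shifts whose
#' cross-genotype sign pattern follows `discordance_prob` (MUT_up shifts
#' are predominantly positive, MUT_down predominantly negative). Fully
#' determined by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List of class `ground_truth`: `config`, `proteins`, `sites`,
#'   `metabolites`, `fao`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  set.seed(stage_seed(config$seed, "cohort"))
  np <- config$n_proteins; ns <- config$n_sites

  draw_fc <- function() {
    affected <- stats::runif(np) < config$frac_signif_proteome
    mag <- abs(stats::rnorm(np, config$fc_mean, config$fc_sd))
    sign <- sample(c(-1, 1), np, replace = TRUE)
    ifelse(affected, sign * mag, 0)
  }
  sequences <- vapply(seq_len(np), function(i)
    paste(sample(AA_LETTERS, sample(100:250, 1L), replace = TRUE),
          collapse = ""), "")
  proteins <- data.frame(
    accession = sprintf("PROT%04d", seq_len(np)),
    sequence = sequences,
    fc_MUT_up = draw_fc(), fc_MUT_down = draw_fc(),
    stringsAsFactors = FALSE)

  # site categories: shifted in both genotypes / one / neither
  cat_probs <- c(both = config$frac_affected_both,
                 up_only = config$frac_affected_single,
                 down_only = config$frac_affected_single)
  cat_probs <- c(cat_probs, null = 1 - sum(cat_probs))
  category <- sample(names(cat_probs), ns, replace = TRUE, prob = cat_probs)

  peps <- lapply(sample(8:18, ns, replace = TRUE), random_peptide_with_k)
  prot_idx <- sample(np, ns, replace = TRUE)
  position <- sample(5:200, ns, replace = TRUE)
  base <- stats::runif(ns, 0.01, 0.99)
  mag_up <- pmax(abs(stats::rnorm(ns, config$stoich_shift_mean,
                                  config$stoich_shift_sd)), 0.02)
  mag_down <- pmax(abs(stats::rnorm(ns, config$stoich_shift_mean,
                                    config$stoich_shift_sd)), 0.02)

  sign_up <- sign_down <- numeric(ns)
  dominant <- function(n, dominant_sign)  # genotype's prevailing direction
    ifelse(stats::runif(n) < 0.9, dominant_sign, -dominant_sign)
  for (i in seq_len(ns)) {
    if (category[i] == "both") {
      if (stats::runif(1) < config$discordance_prob) {
        sign_up[i] <- 1; sign_down[i] <- -1
      } else {
        s <- sample(c(-1, 1), 1L); sign_up[i] <- s; sign_down[i] <- s
      }
    } else if (category[i] == "up_only") {
      sign_up[i] <- dominant(1L, 1)
    } else if (category[i] == "down_only") {
      sign_down[i] <- dominant(1L, -1)
    }
  }
  clamp <- function(x) pmin(pmax(x, 0.005), 0.995)
  sites <- data.frame(
    site_id = sprintf("%sK%d", proteins$accession[prot_idx], position),
    accession = proteins$accession[prot_idx],
    position = position,
    peptide_sequence = vapply(peps, `[[`, "", "sequence"),
    k_pos = vapply(peps, `[[`, 0L, "k_pos"),
    category = category,
    base_stoich = base,
    shift_MUT_up = sign_up * mag_up,
    shift_MUT_down = sign_down * mag_down,
    stringsAsFactors = FALSE)
  sites <- sites[!duplicated(sites$site_id), , drop = FALSE]
  sites$stoich_MUT_up <- clamp(sites$base_stoich + sites$shift_MUT_up)
  sites$stoich_MUT_down <- clamp(sites$base_stoich + sites$shift_MUT_down)

  metabolites <- data.frame(
    metabolite = c("citrate", "alpha-ketoglutarate", "succinate",
                   "fumarate", "malate", "aspartate"),
    n_carbons = c(6L, 5L, 4L, 4L, 4L, 4L),
    frac_WT = c(0.20, 0.25, 0.18, 0.18, 0.18, 0.12),
    frac_MUT_up = c(0.24, 0.35, 0.22, 0.26, 0.24, 0.15),
    frac_MUT_down = c(0.20, 0.26, 0.18, 0.19, 0.18, 0.12),
    stringsAsFactors = FALSE)

  structure(list(config = config, proteins = proteins, sites = sites,
                 metabolites = metabolites,
                 fao = config$fao_capacity_by_group),
            class = "ground_truth")
}

#' Simulate paired light/heavy fragment peak areas
#'
#' Forward model of the stoichiometry assay for one genotype contrast:
#' per site, animal, and fragment, total area is lognormal; the light
#' (endogenous acetyl) area is total x stoichiometry x noise, the true
#' heavy (chemical d3-acetyl) area is total x (1 - stoichiometry) x noise,
#' and the observed heavy area additionally receives the light species'
#' natural M+3 isotopologue, `light x a3/a0` from the peptide's theoretical
#' envelope.
#'
#' @param truth A [simulate_cohort()] result.
#' @param genotype `"MUT_up"` or `"MUT_down"`.
#' @param noise_cv Override of the config's fragment-area CV.
#' @param envelope_leakage Override of the config's leakage switch.
#' @return `data.frame` with columns `site_id`, `fragment_id`,
#'   `sample_id`, `group`, `light_area`, `heavy_area`,
#'   `peptide_sequence`, `mods`.
#' @export
simulate_fragment_areas <- function(truth, genotype = c("MUT_up", "MUT_down"),
                                    noise_cv = NULL, envelope_leakage = NULL) {
  genotype <- match.arg(genotype)
  cfg <- truth$config
  if (is.null(noise_cv)) noise_cv <- cfg$noise_cv
  if (is.null(envelope_leakage)) envelope_leakage <- cfg$envelope_leakage
  set.seed(stage_seed(cfg$seed, paste0("frag_", genotype)))
  sites <- truth$sites
  nsite <- nrow(sites)
  npg <- cfg$n_per_group
  nfrag <- cfg$fragments_per_site

  samples <- c(sprintf("WT_%d", seq_len(npg)),
               sprintf("%s_%d", genotype, seq_len(npg)))
  groups <- rep(c("WT", "MUT"), each = npg)
  mut_stoich <- sites[[paste0("stoich_", genotype)]]

  mods <- sprintf("%d:light_acetyl", sites$k_pos)
  ratio <- if (envelope_leakage) {
    vapply(seq_len(nsite), function(i) {
      env <- isotope_envelope(
        elemental_composition(sites$peptide_sequence[i],
                              stats::setNames("light_acetyl", sites$k_pos[i])),
        n_peaks = 4L)
      env[4L] / env[1L]
    }, numeric(1))
  } else rep(0, nsite)

  n <- nsite * length(samples) * nfrag
  site_i <- rep(rep(seq_len(nsite), each = length(samples)), each = nfrag)
  samp_i <- rep(rep(seq_along(samples), times = nsite), each = nfrag)
  stoich <- ifelse(groups[samp_i] == "WT", sites$base_stoich[site_i],
                   mut_stoich[site_i])
  total <- stats::rlnorm(n, meanlog = log(1e5), sdlog = 0.5)
  light <- total * stoich * ln_noise(n, noise_cv)
  heavy_true <- total * (1 - stoich) * ln_noise(n, noise_cv)
  heavy_obs <- heavy_true + light * ratio[site_i]

  data.frame(site_id = sites$site_id[site_i],
             fragment_id = sprintf("frag%d", rep(seq_len(nfrag),
                                                 times = n / nfrag)),
             sample_id = samples[samp_i],
             group = groups[samp_i],
             light_area = light, heavy_area = heavy_obs,
             peptide_sequence = sites$peptide_sequence[site_i],
             mods = mods[site_i], stringsAsFactors = FALSE)
}

#' Simulate two 4-plex reporter-ion batches for one genotype
#'
#' Each batch carries two mutant and two control channels; per-channel PSM
#' intensity is protein base intensity x PSM share x 2^(true log2 FC for
#' mutant channels) x lognormal noise. A configurable fraction of PSMs get
#' one zeroed channel to exercise the completeness filter.
#'
#' @param truth A [simulate_cohort()] result.
#' @param genotype `"MUT_up"` or `"MUT_down"`.
#' @param noise_cv,zero_channel_frac Optional overrides.
#' @return List with elements `batch1` and `batch2` (PSM tables:
#'   `psm_id`, `protein_group`, `unique`, `ch1..ch4`) and `channel_groups`.
#' @export
simulate_dileu_batches <- function(truth, genotype = c("MUT_up", "MUT_down"),
                                   noise_cv = NULL, zero_channel_frac = NULL) {
  genotype <- match.arg(genotype)
  cfg <- truth$config
  if (is.null(noise_cv)) noise_cv <- cfg$dileu_cv
  if (is.null(zero_channel_frac)) zero_channel_frac <- cfg$zero_channel_frac
  set.seed(stage_seed(cfg$seed, paste0("dileu_", genotype)))
  channel_groups <- c("MUT", "MUT", "WT", "WT")
  fc <- truth$proteins[[paste0("fc_", genotype)]]
  np <- nrow(truth$proteins)
  base <- stats::rlnorm(np, meanlog = log(1e6), sdlog = 0.7)

  one_batch <- function(batch_id) {
    npsm <- np * cfg$psms_per_protein
    prot_i <- rep(seq_len(np), each = cfg$psms_per_protein)
    share <- stats::rlnorm(npsm, meanlog = 0, sdlog = 0.4)
    intens <- sapply(seq_along(channel_groups), function(ch) {
      eff <- if (channel_groups[ch] == "MUT") 2^fc[prot_i] else 1
      base[prot_i] * share * eff * ln_noise(npsm, noise_cv)
    })
    colnames(intens) <- paste0("ch", seq_along(channel_groups))
    zeroed <- stats::runif(npsm) < zero_channel_frac
    if (any(zeroed)) {
      ch <- sample(length(channel_groups), sum(zeroed), replace = TRUE)
      intens[cbind(which(zeroed), ch)] <- 0
    }
    data.frame(psm_id = sprintf("b%d_psm%05d", batch_id, seq_len(npsm)),
               protein_group = truth$proteins$accession[prot_i],
               unique = 1L, intens, stringsAsFactors = FALSE)
  }
  list(batch1 = one_batch(1L), batch2 = one_batch(2L),
       channel_groups = channel_groups)
}

#' Simulate isotopologue and oxygen-consumption tables
#'
#' Isotopologue intensities are the natural-abundance forward product of
#' the true labeled-carbon distribution (binomial over skeleton carbons at
#' the group's true labeled fraction), scaled by a lognormal pool size and
#' multiplicative noise. OCR traces follow the fuel-flex design: three
#' baseline cycles, then UK5099+BPTES, then all inhibitors, with phase
#' plateaus implied by each group's true FAO capacity.
#'
#' @param truth A [simulate_cohort()] result.
#' @param noise_cv Optional override of the tracer CV (also used,
#'   halved, for OCR cycles).
#' @return List: `isotopologues` (long table: `metabolite`, `sample_id`,
#'   `group`, `isotopologue`, `intensity`), `metabolite_spec`, `ocr`
#'   (`sample_id`, `group`, `phase`, `cycle`, `ocr`).
#' @export
simulate_tracer_and_ocr <- function(truth, noise_cv = NULL) {
  cfg <- truth$config
  if (is.null(noise_cv)) noise_cv <- cfg$tracer_cv
  set.seed(stage_seed(cfg$seed, "tracer"))
  groups <- c("WT", "MUT_up", "MUT_down")
  npg <- cfg$n_per_group
  met <- truth$metabolites

  iso <- list(); k <- 0L
  for (g in groups) for (s in seq_len(npg)) {
    sample_id <- sprintf("%s_hep%d", g, s)
    for (m in seq_len(nrow(met))) {
      n <- met$n_carbons[m]
      frac <- met[[paste0("frac_", g)]][m]
      x_true <- stats::dbinom(0:n, n, frac)
      mat <- correction_matrix(n)
      pool <- stats::rlnorm(1, meanlog = log(1e6), sdlog = 0.3)
      obs <- as.numeric(mat %*% (x_true * pool)) * ln_noise(n + 1L, noise_cv)
      k <- k + 1L
      iso[[k]] <- data.frame(metabolite = met$metabolite[m],
                             sample_id = sample_id, group = g,
                             isotopologue = 0:n, intensity = obs,
                             stringsAsFactors = FALSE)
    }
  }
  isotopologues <- do.call(rbind, iso)

  ocr <- list(); k <- 0L
  ocr_cv <- noise_cv / 2
  for (g in groups) for (s in seq_len(npg)) {
    sample_id <- sprintf("%s_hep%d", g, s)
    capacity <- truth$fao[[g]]
    baseline <- 100 * ln_noise(1, ocr_cv)
    post_all <- 30 * ln_noise(1, ocr_cv)
    post_uk <- baseline - (1 - capacity) * (baseline - post_all)
    for (phase in c("baseline", "ukbptes", "all_inhibitors")) {
      level <- switch(phase, baseline = baseline, ukbptes = post_uk,
                      all_inhibitors = post_all)
      ncyc <- if (phase == "ukbptes") 6L else 3L
      k <- k + 1L
      ocr[[k]] <- data.frame(sample_id = sample_id, group = g, phase = phase,
                             cycle = seq_len(ncyc),
                             ocr = level * ln_noise(ncyc, ocr_cv),
                             stringsAsFactors = FALSE)
    }
  }
  list(isotopologues = isotopologues,
       metabolite_spec = met[, c("metabolite", "n_carbons")],
       ocr = do.call(rbind, ocr))
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Background pathways sample members uniformly from the protein universe;
#' planted pathways sample predominantly from proteins carrying a true
#' abundance effect in the given genotype, so over-representation analysis
#' has signal to find.
#'
#' @param truth A [simulate_cohort()] result.
#' @param genotype Genotype whose affected proteins seed the planted sets.
#' @param n_pathways Total number of sets.
#' @param n_planted Number of enrichment-planted sets.
#' @param set_size Range of set sizes.
#' @return Named list of character vectors; planted sets are named
#'   `PLANTED_*`.
#' @export
simulate_gene_sets <- function(truth, genotype = "MUT_up", n_pathways = 20L,
                               n_planted = 3L, set_size = c(10L, 40L)) {
  cfg <- truth$config
  set.seed(stage_seed(cfg$seed, "pathways"))
  universe <- truth$proteins$accession
  affected <- universe[truth$proteins[[paste0("fc_", genotype)]] != 0]
  sets <- list()
  for (i in seq_len(n_pathways)) {
    size <- min(sample(seq(set_size[1], set_size[2]), 1L), length(universe))
    planted <- i <= n_planted && length(affected) >= 2
    members <- if (planted) {
      n_aff <- min(length(affected), max(2L, round(0.6 * size)))
      aff <- sample(affected, n_aff)
      rest <- setdiff(universe, aff)
      c(aff, sample(rest, min(size - n_aff, length(rest))))
    } else {
      sample(universe, size)
    }
    nm <- if (planted) sprintf("PLANTED_%02d", i) else sprintf("PATH_%02d", i)
    sets[[nm]] <- members
  }
  sets
}

#' Write a complete synthetic data set to disk
#'
#' Generates every input table the pipeline consumes -- fragment-area
#' tables for both genotypes, two reporter batches per genotype, a FASTA
#' of the synthetic proteins, a GMT of synthetic pathways with planted
#' enrichment, a localization annotation table, isotopologue and OCR
#' tables -- plus the ground truth, all as plain-text TSV/FASTA/GMT.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if needed).
#' @return The `ground_truth` object, invisibly.
#' @export
simulate_all <- function(config = cohort_config(), outdir) {
  truth <- simulate_cohort(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  for (g in c("MUT_up", "MUT_down")) {
    wtsv(simulate_fragment_areas(truth, g),
         sprintf("fragment_areas_%s.tsv", g))
    batches <- simulate_dileu_batches(truth, g)
    wtsv(batches$batch1, sprintf("dileu_%s_batch1.tsv", g))
    wtsv(batches$batch2, sprintf("dileu_%s_batch2.tsv", g))
  }
  tracer <- simulate_tracer_and_ocr(truth)
  wtsv(tracer$isotopologues, "isotopologues.tsv")
  wtsv(tracer$metabolite_spec, "metabolite_spec.tsv")
  wtsv(tracer$ocr, "ocr.tsv")

  write_protein_fasta(truth$proteins$accession, truth$proteins$sequence,
                      file.path(outdir, "proteins.fasta"))
  write_gmt(simulate_gene_sets(truth), file.path(outdir, "pathways.gmt"))

  set.seed(stage_seed(config$seed, "pathways") + 1L)
  terms <- utils::read.delim(system.file("extdata", "localization_bins.tsv",
                                         package = "acetylflux"))$term
  wtsv(data.frame(accession = truth$proteins$accession,
                  localization = sample(terms, nrow(truth$proteins),
                                        replace = TRUE)),
       "annotation.tsv")

  wtsv(truth$proteins[, c("accession", "fc_MUT_up", "fc_MUT_down")],
       "ground_truth_proteins.tsv")
  wtsv(truth$sites[, c("site_id", "category", "base_stoich",
                       "stoich_MUT_up", "stoich_MUT_down")],
       "ground_truth_sites.tsv")
  invisible(truth)
}
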