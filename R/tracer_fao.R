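# 13C natural-abundance isotopologue correction, fractional labeling, and
# the fuel-flex fatty-acid-oxidation capacity statistic.

#' Natural-abundance 13C correction matrix
#'
#' Entry \[i, j\] (0-based isotopologue indices) is the probability that a
#' molecule with j tracer-labeled carbons is observed at mass M+i due to
#' natural 13C on its n - j unlabeled carbons:
#' `choose(n-j, i-j) p^(i-j) (1-p)^(n-j-(i-j))` for i >= j, else 0.
#' Columns sum to 1.
#'
#' @param n_carbons Number of carbons in the metabolite skeleton (>= 1).
#' @param p13 Natural 13C abundance (default 0.0107).
#' @return `(n_carbons+1) x (n_carbons+1)` lower-triangular matrix.
#' @export
#' @examples
#' correction_matrix(2)
correction_matrix <- function(n_carbons, p13 = 0.0107) {
  if (n_carbons < 1) stop("n_carbons must be >= 1")
  if (p13 < 0 || p13 >= 1) stop("p13 must lie in [0, 1)")
  n <- n_carbons
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n)
    m[(j:n) + 1L, j + 1L] <- stats::dbinom(0:(n - j), size = n - j, prob = p13)
  m
}

#' Full-formula (derivatization-aware) correction matrix
#'
#' Like [correction_matrix()] but accounts for all natural-abundance
#' isotopes of the complete (e.g. derivatized) molecular formula, not just
#' the carbon skeleton: column j is the theoretical envelope of the
#' molecule with j skeleton carbons fixed as 13C, shifted by j and
#' truncated to the observed window. Columns sum to slightly below 1 due
#' to truncation.
#'
#' @param comp Named element-count vector of the full molecule
#'   (as from [elemental_composition()], or `c(C = ..., H = ..., ...)`).
#' @param n_carbons Number of tracer-labelable skeleton carbons.
#' @param abundances Isotope abundance table.
#' @return `(n_carbons+1) x (n_carbons+1)` matrix.
#' @export
correction_matrix_formula <- function(comp, n_carbons,
                                      abundances = isotope_abundances()) {
  if (n_carbons < 1) stop("n_carbons must be >= 1")
  if (comp[["C"]] < n_carbons)
    stop("formula has fewer carbons than n_carbons")
  n <- n_carbons
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    cj <- comp
    cj[["C"]] <- cj[["C"]] - j  # j carbons are pure 13C, no natural spread
    env <- isotope_envelope(cj, n_peaks = n - j + 1L, abundances = abundances)
    m[(j:n) + 1L, j + 1L] <- env
  }
  m
}

#' Correct observed isotopologue intensities for natural 13C
#'
#' Solves `obs = M x` for the true labeled-carbon distribution x under a
#' non-negativity constraint (least squares, `x >= 0`), then rescales x to
#' the observed total intensity.
#'
#' @param obs Numeric vector of observed M+0..M+n intensities.
#' @param m Correction matrix from [correction_matrix()] (or the
#'   full-formula variant).
#' @return Corrected intensity vector, same length and total as `obs`.
#' @export
correct_isotopologues <- function(obs, m) {
  if (length(obs) != nrow(m)) stop("matrix dimension does not match vector")
  if (any(obs < 0)) stop("intensities must be >= 0")
  x <- pracma::lsqnonneg(m, obs)$x
  total <- sum(obs)
  if (sum(x) > 0) x <- x * total / sum(x)
  x
}

#' Mean labeled-carbon fraction of a corrected isotopologue vector
#'
#' @param x Corrected M+0..M+n intensities (total > 0).
#' @return List: `fraction` = sum(i * x_i) / (n * sum(x)), the mean
#'   fraction of labeled carbons; `labeled_pool` = sum of M+1..M+n.
#' @export
#' @examples
#' fractional_labeling(c(0.5, 0.25, 0.25))
fractional_labeling <- function(x) {
  total <- sum(x)
  if (total <= 0) stop("zero total intensity: labeling undefined")
  n <- length(x) - 1L
  list(fraction = sum((0:n) * x) / (n * total),
       labeled_pool = sum(x[-1L]))
}

#' Fatty-acid-oxidation capacity from a fuel-flex assay
#'
#' `1 - ((baseline - post_ukbptes) / (baseline - post_all))`: the share of
#' inhibitor-sensitive respiration that persists when glucose and
#' glutamine oxidation are blocked (UK5099 + BPTES) and is only abolished
#' once fatty-acid oxidation is also inhibited (etomoxir).
#'
#' @param baseline Baseline oxygen consumption rate (pmol/min).
#' @param post_ukbptes OCR after UK5099 + BPTES injection.
#' @param post_all OCR after all three inhibitors.
#' @param warn_out_of_range Warn (rather than clip) when the value falls
#'   outside \[0, 1\], i.e. when post_all <= post_ukbptes <= baseline is
#'   violated.
#' @return FAO capacity (vectorised).
#' @export
#' @examples
#' fao_capacity(100, 80, 40)
fao_capacity <- function(baseline, post_ukbptes, post_all,
                         warn_out_of_range = TRUE) {
  if (any(baseline == post_all))
    stop("baseline equals all-inhibitor OCR: capacity undefined")
  cap <- 1 - (baseline - post_ukbptes) / (baseline - post_all)
  if (warn_out_of_range && any(cap < 0 | cap > 1))
    warning(sum(cap < 0 | cap > 1),
            " capacity value(s) outside [0, 1]; check phase ordering")
  cap
}

#' Summarise an OCR trace into per-sample assay phases
#'
#' Averages measurement cycles within each phase of the fuel-flex assay.
#'
#' @param ocr `data.frame` with columns `sample_id`, `phase` (one of
#'   `baseline`, `ukbptes`, `all_inhibitors`), `cycle`, `ocr`.
#' @return `data.frame`: `sample_id`, `baseline`, `post_ukbptes`,
#'   `post_all` (mean OCR per phase).
#' @export
summarize_ocr <- function(ocr) {
  required <- c("sample_id", "phase", "ocr")
  if (!all(required %in% names(ocr)))
    stop("OCR table needs columns: ", paste(required, collapse = ", "))
  bad <- setdiff(unique(ocr$phase), c("baseline", "ukbptes", "all_inhibitors"))
  if (length(bad)) stop("unknown phase(s): ", paste(bad, collapse = ", "))
  agg <- stats::aggregate(ocr ~ sample_id + phase, data = ocr, FUN = mean)
  wide <- stats::reshape(agg, idvar = "sample_id", timevar = "phase",
                         direction = "wide")
  need <- c("ocr.baseline", "ocr.ukbptes", "ocr.all_inhibitors")
  if (!all(need %in% names(wide)) || anyNA(wide[need]))
    stop("each sample needs all three assay phases")
  data.frame(sample_id = wide$sample_id,
             baseline = wide$ocr.baseline,
             post_ukbptes = wide$ocr.ukbptes,
             post_all = wide$ocr.all_inhibitors,
             stringsAsFactors = FALSE)
}

#' Tracer correction and labeling analysis of an isotopologue table
#'
#' Applies the natural-abundance correction per metabolite and sample and
#' reports corrected intensities and labeling summaries.
#'
#' @param isotopologues Long `data.frame`: `metabolite`, `sample_id`,
#'   `group`, `isotopologue` (0-based index), `intensity`.
#' @param metabolite_spec `data.frame`: `metabolite`, `n_carbons`.
#' @param p13 Natural 13C abundance.
#' @return `data.frame` per metabolite x sample: corrected intensities in
#'   long form plus `fraction` and `labeled_pool` columns repeated per row.
#' @export
tracer_analysis <- function(isotopologues, metabolite_spec, p13 = 0.0107) {
  mats <- lapply(stats::setNames(metabolite_spec$n_carbons,
                                 metabolite_spec$metabolite),
                 correction_matrix, p13 = p13)
  pieces <- split(isotopologues,
                  interaction(isotopologues$metabolite,
                              isotopologues$sample_id, drop = TRUE))
  out <- lapply(pieces, function(d) {
    d <- d[order(d$isotopologue), , drop = FALSE]
    m <- mats[[as.character(d$metabolite[1])]]
    if (is.null(m)) stop("no carbon spec for metabolite ", d$metabolite[1])
    if (nrow(d) != nrow(m))
      stop("isotopologue count does not match n_carbons for ", d$metabolite[1])
    x <- correct_isotopologues(d$intensity, m)
    fl <- fractional_labeling(x)
    d$corrected <- x
    d$fraction <- fl$fraction
    d$labeled_pool <- fl$labeled_pool
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
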