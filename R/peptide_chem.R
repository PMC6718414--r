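# Protein digestion, elemental composition, and theoretical isotope envelopes.
# Coordinates are 1-based inclusive throughout (K123-style site naming).

AA_LETTERS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

# Residue (in-chain) elemental compositions; free peptide = residues + H2O.
RESIDUE_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

# Monoisotopic atomic masses; D is the heavy-label deuterium slot.
MONOISOTOPIC_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                       O = 15.9949146196, S = 31.97207100, D = 2.0141017778)

# Mass added per d3-acetyl relative to light acetyl: 3 x (2H - 1H).
DELTA_D3_ACETYL <- 3 * (MONOISOTOPIC_MASS[["D"]] - MONOISOTOPIC_MASS[["H"]])

#' Natural isotope abundance table
#'
#' Per-element natural abundances of the M+1 (and M+2, where relevant)
#' isotopes used for theoretical envelope computation. Heavy-label
#' deuterium (`D`) is modelled as isotopically pure. Override entries to
#' use a different abundance set.
#'
#' @return Named list; each element is a numeric vector of relative
#'   abundances for mass shifts +0, +1 (and +2), summing to 1.
#' @export
#' @examples
#' isotope_abundances()$C
isotope_abundances <- function() {
  list(
    C = c(1 - 0.0107, 0.0107),
    H = c(1 - 0.000115, 0.000115),
    N = c(1 - 0.00364, 0.00364),
    O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    S = c(1 - 0.0075 - 0.0421, 0.0075, 0.0421),
    D = 1
  )
}

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("protein/peptide sequence must be a non-empty character scalar")
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters), AA_LETTERS)
  if (length(bad))
    stop("non-canonical residue letter(s): ", paste(bad, collapse = ", "))
  letters
}

#' In-silico protease digestion
#'
#' Digests a protein sequence with trypsin (cleaves C-terminal of K/R,
#' optionally suppressed before P) and/or GluC (cleaves C-terminal of E;
#' D cleavage optional), allowing up to `max_missed` missed cleavages.
#' Lysines carrying an acetyl mark (endogenous light or chemical heavy)
#' are not trypsin substrates when `acetyl_blocks_trypsin` is on, matching
#' the behaviour of chemically per-acetylated samples.
#'
#' @param sequence Amino-acid string (20 canonical residues).
#' @param enzymes Character subset of `c("trypsin", "gluc")`.
#' @param max_missed Maximum number of internal (skipped) cleavage sites.
#' @param acetyl_sites Integer vector of 1-based K positions carrying any
#'   acetyl mark.
#' @param acetyl_blocks_trypsin Whether acetylated K blocks trypsin.
#' @param trypsin_not_before_p Suppress trypsin cleavage when the next
#'   residue is proline (standard convention).
#' @param gluc_cleaves_d Whether GluC also cleaves after aspartate.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive),
#'   `sequence`, `missed_cleavages`.
#' @export
#' @examples
#' digest("AKEMR", max_missed = 0)
digest <- function(sequence, enzymes = c("trypsin", "gluc"), max_missed = 5L,
                   acetyl_sites = integer(), acetyl_blocks_trypsin = TRUE,
                   trypsin_not_before_p = TRUE, gluc_cleaves_d = FALSE) {
  letters <- validate_sequence(sequence)
  enzymes <- match.arg(enzymes, c("trypsin", "gluc"), several.ok = TRUE)
  if (max_missed < 0) stop("max_missed must be >= 0")
  n <- length(letters)
  cut_after <- logical(n)
  if ("trypsin" %in% enzymes) {
    tr <- letters %in% c("K", "R")
    if (trypsin_not_before_p) {
      idx <- which(tr)
      idx <- idx[idx < n & letters[idx + 1L] == "P"]
      tr[idx] <- FALSE
    }
    if (acetyl_blocks_trypsin && length(acetyl_sites))
      tr[intersect(acetyl_sites, which(letters == "K"))] <- FALSE
    cut_after <- cut_after | tr
  }
  if ("gluc" %in% enzymes) {
    gc_res <- if (gluc_cleaves_d) c("E", "D") else "E"
    cut_after <- cut_after | letters %in% gc_res
  }
  cut_after[n] <- FALSE  # the C-terminus is a boundary, not a missed site
  boundaries <- c(0L, which(cut_after), n)
  nb <- length(boundaries)
  out <- vector("list", nb - 1L)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    j <- (i + 1L):jmax
    out[[i]] <- data.frame(start = boundaries[i] + 1L, end = boundaries[j],
                           missed_cleavages = j - i - 1L)
  }
  res <- do.call(rbind, out)
  res$sequence <- substring(sequence, res$start, res$end)
  res[order(res$start, res$end), c("start", "end", "sequence", "missed_cleavages")]
}

#' Elemental composition of a peptide
#'
#' Sums the in-chain residue formulas plus one water. A `light_acetyl`
#' modification adds C2H2O (acetyl replacing one amine hydrogen); a
#' `heavy_acetyl` adds the d3-acetyl group: 2 C, 1 O, 3 deuteriums, net
#' -1 light hydrogen (a +45.0294 Da addition).
#'
#' @param sequence Peptide amino-acid string.
#' @param mods Optional named character vector or list mapping 1-based
#'   residue positions (as names) to `"light_acetyl"` or `"heavy_acetyl"`;
#'   positions must be K residues.
#' @return Named integer vector with counts for C, H, N, O, S, D.
#' @export
#' @examples
#' elemental_composition("G")                      # free glycine, C2H5NO2
#' elemental_composition("GK", mods = c("2" = "light_acetyl"))
elemental_composition <- function(sequence, mods = NULL) {
  letters <- validate_sequence(sequence)
  comp <- c(C = 0, H = 2, N = 0, O = 1, S = 0, D = 0)  # one water
  for (r in letters) comp[1:5] <- comp[1:5] + RESIDUE_COMPOSITION[[r]]
  if (length(mods)) {
    pos <- as.integer(names(mods))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(letters)))
      stop("modification positions out of range")
    if (any(letters[pos] != "K"))
      stop("acetyl modifications are only allowed on K residues")
    for (m in unlist(mods)) {
      if (m == "light_acetyl") {
        comp <- comp + c(C = 2, H = 2, N = 0, O = 1, S = 0, D = 0)
      } else if (m == "heavy_acetyl") {
        comp <- comp + c(C = 2, H = -1, N = 0, O = 1, S = 0, D = 3)
      } else if (m != "none") {
        stop("unknown modification: ", m)
      }
    }
  }
  storage.mode(comp) <- "integer"
  comp
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Named integer vector as returned by
#'   [elemental_composition()].
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  sum(MONOISOTOPIC_MASS[names(comp)] * comp)
}

#' Mass shift between heavy and light acetyl variants
#'
#' @param n_heavy_sites Number of sites converted from light to d3-acetyl.
#' @return Mass delta in Da (`n_heavy_sites` x 3.01883).
#' @export
#' @examples
#' heavy_pair_mass_shift(1)
heavy_pair_mass_shift <- function(n_heavy_sites) {
  if (any(n_heavy_sites < 0)) stop("n_heavy_sites must be >= 0")
  n_heavy_sites * DELTA_D3_ACETYL
}

# Truncated linear convolution of two abundance vectors.
conv_trunc <- function(a, b, n_peaks) {
  out <- numeric(n_peaks)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n_peaks - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# n-fold convolution power of a per-atom distribution, truncated.
conv_power <- function(dist, n, n_peaks) {
  result <- 1
  base <- dist
  while (n > 0) {
    if (n %% 2 == 1) result <- conv_trunc(result, base, n_peaks)
    base <- conv_trunc(base, base, n_peaks)
    n <- n %/% 2
  }
  result <- c(result, numeric(n_peaks))[seq_len(n_peaks)]
  result
}

#' Theoretical isotope envelope of an elemental composition
#'
#' Computes relative abundances of the M+0 .. M+(n_peaks-1) isotopologues
#' by multinomial convolution of the per-element natural-abundance
#' distributions. Two-isotope elements (C, H, N) use the binomial directly;
#' O and S carry +1 and +2 isotopes. Heavy-label deuteriums are treated as
#' isotopically pure and contribute no spread. Abundances are reported
#' unnormalised, so truncation leaves the sum slightly below 1.
#'
#' @param comp Named integer vector (C, H, N, O, S, D counts).
#' @param n_peaks Number of isotopologue peaks to return (>= 1).
#' @param abundances Abundance table, by default [isotope_abundances()].
#' @return Numeric vector of length `n_peaks`, M+0 first.
#' @export
#' @examples
#' isotope_envelope(c(C = 1L), n_peaks = 2)
isotope_envelope <- function(comp, n_peaks, abundances = isotope_abundances()) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  if (any(comp < 0)) stop("element counts must be >= 0")
  env <- c(1, numeric(n_peaks - 1L))
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n == 0) next
    dist <- abundances[[el]]
    if (is.null(dist)) stop("no abundance entry for element ", el)
    if (length(dist) == 1) next  # isotopically pure
    part <- if (length(dist) == 2) {
      stats::dbinom(0:(n_peaks - 1L), size = n, prob = dist[2])
    } else {
      conv_power(dist, n, n_peaks)
    }
    env <- conv_trunc(env, part, n_peaks)
  }
  env
}
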