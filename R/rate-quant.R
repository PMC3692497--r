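#' Relative-rate decomposition to a hypothetical ancestor
#'
#' Given the three pairwise distances among two ingroup species A, B and an
#' outgroup C, decomposes the A-B distance into the two ancestor-to-tip
#' path lengths via
#' K_OA = (K_AB + K_AC - K_BC) / 2 and K_OB = (K_AB + K_BC - K_AC) / 2,
#' where O is the last common ancestor of A and B. The identity
#' K_OA + K_OB = K_AB holds exactly. Violations of the triangle condition
#' (negative path lengths) are reported as-is with a warning so that
#' rate-test violations stay visible.
#'
#' @param kAB,kAC,kBC pairwise distances in substitutions/site (>= 0).
#' @return named numeric vector \code{c(K_oa, K_ob)}.
#' @examples
#' ancestorDistances(0.027, 0.052, 0.063)  # 0.008, 0.019
#' @export
ancestorDistances <- function(kAB, kAC, kBC) {
  stopifnot(kAB >= 0, kAC >= 0, kBC >= 0)
  if (kAB > kAC + kBC)
    warning("triangle condition violated: K_AB > K_AC + K_BC")
  kOA <- (kAB + kAC - kBC) / 2
  kOB <- (kAB + kBC - kAC) / 2
  if (kOA < 0 || kOB < 0)
    warning("negative ancestor-to-tip distance (relative-rate violation)")
  c(K_oa = kOA, K_ob = kOB)
}

#' Absolute substitution rate from distance and divergence time
#'
#' Divides an ancestor-to-tip distance by the divergence time to give a
#' rate in units of 1e-8 substitutions/site/year. Full precision is kept;
#' rounding to 3 decimals happens only at the reporting layer.
#'
#' @param kO ancestor-to-tip distance (substitutions/site).
#' @param timeMa divergence time in Ma (> 0).
#' @return rate in 1e-8 substitutions/site/year.
#' @examples
#' round(absoluteRate(0.008, 203), 3)  # 0.004
#' @export
absoluteRate <- function(kO, timeMa) {
  if (any(timeMa <= 0)) stop("divergence time must be positive")
  kO / (timeMa * 1e6) * 1e8
}

#' Fold difference between two reported rates
#'
#' Ratio of two rates as reported (each rounded to 3 decimals in 1e-8
#' units), itself reported to 1 decimal, matching the reporting convention
#' of the rate table.
#'
#' @param rateHigh,rateLow rates in 1e-8 substitutions/site/year;
#'   \code{rateLow} must be positive after rounding.
#' @return fold difference to 1 decimal.
#' @examples
#' rateRatio(0.028, 0.004)  # 7.0
#' @export
rateRatio <- function(rateHigh, rateLow) {
  h <- round(rateHigh, 3)
  l <- round(rateLow, 3)
  if (l <= 0) stop("rateLow must be positive at reporting precision")
  round(h / l, 1)
}

#' Build a relative-rate table
#'
#' For each (species pair, outgroup, divergence time) combination, takes
#' the three pairwise distances — either supplied directly or computed as
#' pairwise ML distances from an alignment after complete deletion —
#' decomposes them into ancestor-to-tip distances, and converts those to
#' absolute rates. One row per pair, mirroring the layout of a
#' per-pair rate report (site count, time, the five distances, two rates).
#'
#' @param pairs data.frame with columns \code{species_a}, \code{species_b},
#'   \code{outgroup}, \code{time_Ma}.
#' @param distances optional data.frame (same row order) with columns
#'   \code{n_sites}, \code{K_ac}, \code{K_bc}, \code{K_ab}.
#' @param alignments optional list of [GeneAlignment-class] (one per pair,
#'   containing the three taxa) used when \code{distances} is missing.
#' @param model [SubstitutionModel-class] for ML distances.
#' @return list with \code{table} (one row per pair: inputs, K_oa, K_ob,
#'   rate_a, rate_b at full precision), \code{reported} (distances and
#'   rates rounded to 3 decimals) and \code{rateOrder} (species sorted
#'   from lower to higher reported rate, by each species' minimum).
#' @export
buildRateTable <- function(pairs, distances = NULL, alignments = NULL,
                           model = NULL) {
  need <- c("species_a", "species_b", "outgroup", "time_Ma")
  if (!all(need %in% names(pairs)))
    stop("pairs needs columns: ", paste(need, collapse = ", "))
  n <- nrow(pairs)
  if (is.null(distances)) {
    if (is.null(alignments) || is.null(model))
      stop("supply either distances or alignments + model")
    if (length(alignments) != n) stop("one alignment per pair required")
    distances <- do.call(rbind, lapply(seq_len(n), function(i) {
      aln <- alignments[[i]]
      trio <- c(pairs$species_a[i], pairs$species_b[i], pairs$outgroup[i])
      miss <- setdiff(trio, taxonNames(aln))
      if (length(miss))
        stop("missing distance inputs for pair ", pairs$species_a[i], "-",
             pairs$species_b[i], ": taxa ", paste(miss, collapse = ", "))
      sub <- GeneAlignment(seqMatrix(aln)[trio, , drop = FALSE],
                           alphabet = seqAlphabet(aln))
      sub <- completeDeletion(sub)
      s <- apply(seqMatrix(sub), 1, paste, collapse = "")
      data.frame(n_sites = nSites(sub),
                 K_ac = pairwiseMLDistance(s[trio[1]], s[trio[3]], model),
                 K_bc = pairwiseMLDistance(s[trio[2]], s[trio[3]], model),
                 K_ab = pairwiseMLDistance(s[trio[1]], s[trio[2]], model))
    }))
  }
  if (anyNA(distances[, c("K_ac", "K_bc", "K_ab")]))
    stop("missing distance for pair ",
         pairs$species_a[which(is.na(distances$K_ab))[1]])
  tab <- cbind(pairs, distances)
  dec <- t(mapply(ancestorDistances, tab$K_ab, tab$K_ac, tab$K_bc))
  tab$K_oa <- dec[, 1]; tab$K_ob <- dec[, 2]
  tab$rate_a <- absoluteRate(tab$K_oa, tab$time_Ma)
  tab$rate_b <- absoluteRate(tab$K_ob, tab$time_Ma)
  reported <- tab
  for (cn in c("K_ac", "K_bc", "K_ab", "K_oa", "K_ob", "rate_a", "rate_b"))
    reported[[cn]] <- round(reported[[cn]], 3)
  sp <- c(tab$species_a, tab$species_b)
  rt <- round(c(tab$rate_a, tab$rate_b), 3)
  minRate <- tapply(rt, sp, min)
  rateOrder <- names(sort(minRate))
  list(table = tab, reported = reported, rateOrder = rateOrder)
}
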