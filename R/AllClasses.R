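#' @import methods
NULL

.AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.DNA_STATES <- c("A", "C", "G", "T")

.alphabetChars <- function(alphabet) {
  switch(alphabet,
         AA = c(.AA_STATES, "-", "X"),
         DNA = c(.DNA_STATES, "-", "N"),
         stop("unknown alphabet: ", alphabet))
}

.missingChars <- function(alphabet) {
  switch(alphabet, AA = c("-", "X"), DNA = c("-", "N"))
}

#' Multiple sequence alignment with gene partitions
#'
#' An aligned set of amino-acid or nucleotide sequences, stored as a
#' character matrix (one row per taxon, one column per site), together with
#' an optional partition table mapping gene names to column intervals.
#' Column intervals are 0-based and half-open, and partitions must tile a
#' prefix of the columns without overlap.
#'
#' @slot seqs character matrix of single residues; rownames are taxon labels.
#' @slot alphabet either \code{"AA"} (20 amino acids, gap \code{-},
#'   unknown \code{X}) or \code{"DNA"} (ACGT, gap \code{-}, unknown \code{N}).
#' @slot partitions data.frame with columns \code{gene}, \code{start},
#'   \code{end} (0-based half-open column intervals).
#'
#' @seealso [GeneAlignment()] for construction from FASTA input,
#'   [concatenateAlignments()], [completeDeletion()].
#' @export
setClass("GeneAlignment",
         representation(seqs = "matrix",
                        alphabet = "character",
                        partitions = "data.frame"))

setValidity("GeneAlignment", function(object) {
  msgs <- character()
  if (!is.character(object@seqs))
    msgs <- c(msgs, "seqs must be a character matrix")
  if (is.null(rownames(object@seqs)) ||
      anyDuplicated(rownames(object@seqs)))
    msgs <- c(msgs, "seqs must have unique rownames (taxon labels)")
  if (!(object@alphabet %in% c("AA", "DNA")))
    msgs <- c(msgs, "alphabet must be 'AA' or 'DNA'")
  else {
    bad <- !(object@seqs %in% .alphabetChars(object@alphabet))
    if (any(bad)) {
      idx <- which(bad)[1L]
      msgs <- c(msgs, sprintf(
        "illegal character '%s' for alphabet %s (taxon %s, column %d)",
        object@seqs[idx], object@alphabet,
        rownames(object@seqs)[(idx - 1L) %% nrow(object@seqs) + 1L],
        (idx - 1L) %/% nrow(object@seqs) + 1L))
    }
  }
  p <- object@partitions
  if (nrow(p) > 0) {
    if (!all(c("gene", "start", "end") %in% names(p)))
      msgs <- c(msgs, "partitions needs columns gene, start, end")
    else {
      if (any(p$end <= p$start))
        msgs <- c(msgs, "partition intervals must be non-empty")
      if (p$start[1] != 0 ||
          (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)])))
        msgs <- c(msgs, "partitions must tile a prefix of columns")
      if (max(p$end) > ncol(object@seqs))
        msgs <- c(msgs, "partitions exceed alignment length")
      if (anyDuplicated(p$gene))
        msgs <- c(msgs, "duplicate gene names in partitions")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Amino-acid substitution model with rate heterogeneity
#'
#' A time-reversible amino-acid model assembled from symmetric
#' exchangeabilities and equilibrium frequencies, with discrete-gamma
#' among-site rate variation and an optional proportion of invariant sites.
#' The generator is normalized to one expected substitution per site per
#' unit branch length at equilibrium (including the rate-class mixture), and
#' its eigendecomposition is cached for fast transition probabilities.
#'
#' @slot rates symmetric 20x20 exchangeability matrix (zero diagonal).
#' @slot freqs equilibrium frequencies (length 20, sum 1).
#' @slot alpha gamma shape parameter (> 0).
#' @slot nCategories number of discrete gamma categories.
#' @slot pInv proportion of invariant sites in [0, 1).
#' @slot Q normalized generator matrix.
#' @slot eig cached eigendecomposition of the frequency-symmetrized generator.
#' @slot catRates relative rates of the gamma categories (mean 1 across the
#'   variable classes).
#' @slot catWeights category weights (each (1 - pInv)/k; the invariant class
#'   carries pInv).
#'
#' @seealso [buildJTT()], [discretizeGamma()], [transitionProb()].
#' @export
setClass("SubstitutionModel",
         representation(rates = "matrix",
                        freqs = "numeric",
                        alpha = "numeric",
                        nCategories = "integer",
                        pInv = "numeric",
                        Q = "matrix",
                        eig = "list",
                        catRates = "numeric",
                        catWeights = "numeric"))

setValidity("SubstitutionModel", function(object) {
  msgs <- character()
  if (!isTRUE(all.equal(sum(object@freqs), 1, tolerance = 1e-8)))
    msgs <- c(msgs, "frequencies must sum to 1")
  if (object@alpha <= 0) msgs <- c(msgs, "alpha must be > 0")
  if (object@pInv < 0 || object@pInv >= 1)
    msgs <- c(msgs, "pInv must be in [0, 1)")
  if (max(abs(rowSums(object@Q))) > 1e-8)
    msgs <- c(msgs, "generator rows must sum to 0")
  if (length(msgs)) msgs else TRUE
})

#' MCMC trace from relaxed-clock dating
#'
#' Posterior samples from [runClockMCMC()]: node ages (in 100-My time
#' units internally), per-branch substitution rates, the mean rate mu and
#' the log-rate drift variance sigma2, plus the sampler configuration needed
#' to interpret them.
#'
#' @slot samples numeric matrix, one row per retained sample; columns are
#'   named \code{t_<node>}, \code{r_<edge>}, \code{mu}, \code{sigma2}.
#' @slot tree the fixed rooted topology (ape \code{phylo}).
#' @slot nodeLabels labels identifying the internal nodes whose ages are
#'   sampled (ordered as the \code{t_} columns).
#' @slot settings list of chain settings (burn-in, thinning, seed, mode).
#' @slot acceptance named acceptance fractions per move type.
#'
#' @seealso [summarizeTrace()], [convergenceCheck()].
#' @export
setClass("ClockTrace",
         representation(samples = "matrix",
                        tree = "ANY",
                        nodeLabels = "character",
                        settings = "list",
                        acceptance = "numeric"))

setMethod("show", "GeneAlignment", function(object) {
  cat(sprintf("GeneAlignment: %d taxa x %d sites (%s)\n",
              nrow(object@seqs), ncol(object@seqs), object@alphabet))
  if (nrow(object@partitions))
    cat(sprintf("  %d gene partition(s): %s\n", nrow(object@partitions),
                paste(utils::head(object@partitions$gene, 5),
                      collapse = ", ")))
  cat("  taxa:", paste(utils::head(rownames(object@seqs), 8),
                       collapse = ", "),
      if (nrow(object@seqs) > 8) "..." else "", "\n")
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf(
    "SubstitutionModel: JTT-type, alpha = %.4g, %d gamma categories, pInv = %.3g\n",
    object@alpha, object@nCategories, object@pInv))
  cat("  category rates:",
      paste(sprintf("%.4f", object@catRates), collapse = " "), "\n")
})

setMethod("show", "ClockTrace", function(object) {
  cat(sprintf("ClockTrace: %d samples of %d parameters (%s likelihood)\n",
              nrow(object@samples), ncol(object@samples),
              object@settings$mode))
  cat(sprintf("  burn-in %d, thin %d, seed %s\n",
              object@settings$burnIn, object@settings$thin,
              as.character(object@settings$seed)))
})
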