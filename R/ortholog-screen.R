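#' Local-alignment bit score between two peptides
#'
#' Optimal Smith-Waterman local alignment score under an affine gap model
#' (a gap of length L costs \code{gapOpen + L * gapExtend}), converted to
#' bits with the Karlin-Altschul rescaling S' = (lambda * S - ln kappa) /
#' ln 2. Defaults correspond to BLOSUM62 with gap open 11 / extend 1 and
#' the conventional gapped constants for that scheme.
#'
#' @param query,subject amino-acid sequences (single strings).
#' @param scoring substitution matrix name (passed to Biostrings).
#' @param gapOpen,gapExtend positive gap penalties.
#' @param lambda,kappa Karlin-Altschul parameters for the scoring scheme.
#' @param raw if \code{TRUE} return the raw score instead of bits.
#' @return numeric bit score (or raw score). The empty local alignment has
#'   raw score 0, so scores never go negative.
#' @examples
#' localAlignBitscore("WWWW", "WWWW", raw = TRUE)  # 44
#' @export
localAlignBitscore <- function(query, subject, scoring = "BLOSUM62",
                               gapOpen = 11, gapExtend = 1,
                               lambda = 0.267, kappa = 0.041,
                               raw = FALSE) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  if (gapOpen <= 0 || gapExtend <= 0) stop("gap penalties must be positive")
  mat <- .substitutionMatrix(scoring)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query)),
    Biostrings::AAString(toupper(subject)),
    type = "local", substitutionMatrix = mat,
    gapOpening = gapOpen, gapExtension = gapExtend, scoreOnly = TRUE)
  s <- max(0, s)
  if (raw) return(s)
  (lambda * s - log(kappa)) / log(2)
}

.substitutionMatrix <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, cache)) {
      e <- new.env()
      utils::data(list = name, package = "Biostrings", envir = e)
      assign(name, get(name, e), cache)
    }
    get(name, cache)
  }
})

#' Best database hit for a query peptide
#'
#' Scores the query against every subject and returns the best bit score,
#' the best subject's identifier, and the number of subjects at or above a
#' reporting threshold (used by the copy-number filter).
#'
#' @param query amino-acid sequence (single string).
#' @param database named character vector of subject sequences.
#' @param reportThreshold bit-score threshold for counting a subject as a
#'   hit (default 50 bits).
#' @param ... passed to [localAlignBitscore()].
#' @return list with \code{bits}, \code{subject}, \code{hitCount}.
#' @export
bestHitScore <- function(query, database, reportThreshold = 50, ...) {
  if (length(database) == 0) stop("empty database")
  if (is.null(names(database)))
    names(database) <- paste0("subject", seq_along(database))
  bits <- vapply(database, function(s)
    localAlignBitscore(query, s, ...), numeric(1))
  best <- which.max(bits)
  list(bits = unname(bits[best]), subject = names(database)[best],
       hitCount = sum(bits >= reportThreshold))
}

#' Preliminary orthology rule on a bit-score triple
#'
#' A candidate chimaera gene passes when its best-hit bit score towards the
#' outgroup database (S_co) is strictly smaller than its best-hit scores
#' towards both the shark (S_cs) and ray/skate (S_cr) databases; ties fail.
#'
#' @param sCo,sCs,sCr non-negative bit scores (query vs outgroup, sharks,
#'   rays/skates).
#' @param gene optional gene identifier carried into the result.
#' @return data.frame row with columns \code{gene}, \code{passed},
#'   \code{reason} (one of \code{passed},
#'   \code{outgroup-score-not-smaller}).
#' @examples
#' preliminaryOrthologyRule(50, 80, 70)$passed  # TRUE
#' preliminaryOrthologyRule(80, 80, 90)$passed  # FALSE (tie)
#' @export
preliminaryOrthologyRule <- function(sCo, sCs, sCr, gene = NA_character_) {
  if (anyNA(c(sCo, sCs, sCr)))
    stop("missing score: gene cannot be evaluated")
  passed <- (sCo < sCs) && (sCo < sCr)
  data.frame(gene = gene, passed = passed,
             reason = if (passed) "passed" else "outgroup-score-not-smaller",
             stringsAsFactors = FALSE)
}

#' Copy-number exclusion filter
#'
#' Excludes candidates whose database hit count exceeds the threshold
#' (spuriously expanded families; strictly greater than, so a count equal
#' to the threshold passes).
#'
#' @param hitCount non-negative integer hit count.
#' @param threshold exclusion threshold (default 500 copies).
#' @param gene optional gene identifier.
#' @return data.frame row with \code{gene}, \code{passed}, \code{reason}.
#' @export
copyNumberFilter <- function(hitCount, threshold = 500,
                             gene = NA_character_) {
  stopifnot(hitCount >= 0)
  passed <- hitCount <= threshold
  data.frame(gene = gene, passed = passed,
             reason = if (passed) "passed" else "copy-number-exceeded",
             stringsAsFactors = FALSE)
}

#' Trim gappy alignment ends against reference taxa
#'
#' Truncates the 5' and 3' ends of an alignment that contain large
#' stretches of missing data in the reference taxa (typically the
#' chondrichthyan sequences). Leading columns are removed up to the first
#' window of \code{window} consecutive columns in which each column has at
#' least \code{minOccupancy} non-missing fraction among the reference taxa;
#' the 3' end is treated symmetrically. Interior columns are never removed.
#'
#' @param alignment a [GeneAlignment-class].
#' @param referenceTaxa tip labels whose occupancy drives the trimming
#'   (defaults to all taxa).
#' @param window number of consecutive dense columns required (default 20).
#' @param minOccupancy minimum non-missing fraction per column (default 0.9).
#' @return the trimmed [GeneAlignment-class].
#' @export
trimAlignmentEnds <- function(alignment, referenceTaxa = NULL,
                              window = 20, minOccupancy = 0.9) {
  m <- seqMatrix(alignment)
  if (is.null(referenceTaxa)) referenceTaxa <- rownames(m)
  if (!all(referenceTaxa %in% rownames(m)))
    stop("referenceTaxa not in alignment: ",
         paste(setdiff(referenceTaxa, rownames(m)), collapse = ", "))
  ref <- m[referenceTaxa, , drop = FALSE]
  miss <- .missingChars(seqAlphabet(alignment))
  occ <- 1 - colSums(matrix(ref %in% miss, nrow(ref))) / nrow(ref)
  dense <- occ >= minOccupancy
  n <- length(dense)
  if (n < window) stop("alignment empty after trimming")
  runFrom <- function(d) {
    # first index starting a run of `window` consecutive dense columns
    r <- rle(d)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= window)
    if (!length(hit)) return(NA_integer_)
    ends[hit[1]] - r$lengths[hit[1]] + 1L
  }
  from <- runFrom(dense)
  toRev <- runFrom(rev(dense))
  if (is.na(from) || is.na(toRev)) stop("alignment empty after trimming")
  to <- n - toRev + 1L
  GeneAlignment(m[, from:to, drop = FALSE],
                alphabet = seqAlphabet(alignment))
}

#' Screen candidate genes for preliminary orthology
#'
#' Applies the full preliminary screen to a set of query peptides: best-hit
#' bit scores against the outgroup, shark and ray/skate databases, the
#' strict S_co < S_cs and S_co < S_cr rule, and the copy-number filter.
#' Precomputed score triples (e.g. from an external search) can be supplied
#' instead of databases.
#'
#' @param queries named character vector of query peptides, or \code{NULL}
#'   when \code{scores} is given.
#' @param outgroupDb,sharkDb,rayDb named character vectors of database
#'   peptides.
#' @param scores optional data.frame with columns \code{gene}, \code{s_co},
#'   \code{s_cs}, \code{s_cr} (and optionally \code{hit_count}) that
#'   bypasses internal alignment scoring.
#' @param copyThreshold copy-number exclusion threshold (default 500).
#' @param ... passed to [bestHitScore()].
#' @return data.frame with one row per gene: the three scores, hit count,
#'   \code{passed} and \code{reason}.
#' @export
screenGenes <- function(queries = NULL, outgroupDb = NULL, sharkDb = NULL,
                        rayDb = NULL, scores = NULL, copyThreshold = 500,
                        ...) {
  if (is.null(scores)) {
    stopifnot(!is.null(queries), !is.null(outgroupDb), !is.null(sharkDb),
              !is.null(rayDb))
    scores <- do.call(rbind, lapply(names(queries), function(g) {
      co <- bestHitScore(queries[[g]], outgroupDb, ...)
      cs <- bestHitScore(queries[[g]], sharkDb, ...)
      cr <- bestHitScore(queries[[g]], rayDb, ...)
      data.frame(gene = g, s_co = co$bits, s_cs = cs$bits, s_cr = cr$bits,
                 hit_count = co$hitCount + cs$hitCount + cr$hitCount,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(scores$hit_count)) scores$hit_count <- 0L
  out <- do.call(rbind, lapply(seq_len(nrow(scores)), function(i) {
    cn <- copyNumberFilter(scores$hit_count[i], copyThreshold,
                           gene = scores$gene[i])
    if (!cn$passed) return(cn)
    preliminaryOrthologyRule(scores$s_co[i], scores$s_cs[i],
                             scores$s_cr[i], gene = scores$gene[i])
  }))
  cbind(scores[match(out$gene, scores$gene),
               c("s_co", "s_cs", "s_cr", "hit_count")],
        out)[, c("gene", "s_co", "s_cs", "s_cr", "hit_count", "passed",
                 "reason")]
}

#' Read a precomputed score-triple table
#'
#' @param path TSV with header columns \code{gene}, \code{s_co},
#'   \code{s_cs}, \code{s_cr} and optionally \code{hit_count}.
#' @return data.frame suitable for \code{screenGenes(scores = ...)}.
#' @export
readScoreTriples <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "s_co", "s_cs", "s_cr")
  if (!all(need %in% names(tab)))
    stop("score table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$s_co < 0 | tab$s_cs < 0 | tab$s_cr < 0, na.rm = TRUE))
    stop("bit scores must be non-negative")
  tab
}
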