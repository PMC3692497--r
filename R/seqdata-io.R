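#' Read sequences from a FASTA file
#'
#' Parses a FASTA file into a named character vector of uppercased residue
#' strings. Identifiers are taken as the first whitespace-delimited token of
#' each header. The alphabet can be declared or auto-detected (sequences
#' consisting only of A/C/G/T/N/- are taken as nucleotide).
#'
#' @param path path to a FASTA file.
#' @param alphabet \code{"auto"} (default), \code{"AA"} or \code{"DNA"}.
#' @return named character vector of sequences, with attribute
#'   \code{alphabet}.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MKV", ">b", "M-V"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, alphabet = c("auto", "AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate identifiers in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) stop("empty sequence for record: ",
                               ids[!nzchar(seqs)][1])
  if (alphabet == "auto") {
    nuc <- all(!grepl("[^ACGTN-]", seqs))
    alphabet <- if (nuc) "DNA" else "AA"
  }
  legal <- .alphabetChars(alphabet)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    bad <- which(!(ch %in% legal))
    if (length(bad))
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
                   ch[bad[1]], bad[1], ids[i]))
  }
  structure(seqs, alphabet = alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param x a [GeneAlignment-class] or named character vector of sequences.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(x, path) {
  if (is(x, "GeneAlignment"))
    x <- apply(seqMatrix(x), 1, paste, collapse = "")
  if (is.null(names(x))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x))
    writeLines(c(paste0(">", names(x)[i]), x[i]), con)
  invisible(path)
}

#' Construct a GeneAlignment
#'
#' Builds an alignment object from equal-length sequences: a named character
#' vector (as returned by [readFasta()]), a character matrix of single
#' residues, or a Biostrings XStringSet.
#'
#' @param seqs sequences (all the same length).
#' @param alphabet \code{"auto"}, \code{"AA"} or \code{"DNA"}.
#' @param partitions optional data.frame with columns \code{gene},
#'   \code{start}, \code{end} (0-based half-open column intervals).
#' @return a [GeneAlignment-class].
#' @examples
#' aln <- GeneAlignment(c(a = "MKV", b = "M-V"))
#' nSites(aln)
#' @export
GeneAlignment <- function(seqs, alphabet = c("auto", "AA", "DNA"),
                          partitions = NULL) {
  alphabet <- match.arg(alphabet)
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.character(seqs) && !is.matrix(seqs)) {
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("sequences are not aligned (lengths ",
           paste(unique(lens), collapse = ", "), ")")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
    seqs <- m
  }
  if (alphabet == "auto") {
    attr_a <- attr(seqs, "alphabet")
    if (!is.null(attr_a)) alphabet <- attr_a
    else alphabet <- if (all(seqs %in% c(.DNA_STATES, "-", "N")))
      "DNA" else "AA"
  }
  if (is.null(partitions))
    partitions <- data.frame(gene = character(), start = integer(),
                             end = integer())
  new("GeneAlignment", seqs = seqs, alphabet = alphabet,
      partitions = partitions)
}

#' Read an aligned FASTA file as a GeneAlignment
#'
#' @inheritParams readFasta
#' @return a [GeneAlignment-class].
#' @export
readAlignment <- function(path, alphabet = c("auto", "AA", "DNA")) {
  seqs <- readFasta(path, alphabet)
  GeneAlignment(seqs, alphabet = attr(seqs, "alphabet"))
}

#' Concatenate gene alignments into a supermatrix
#'
#' Joins per-gene alignments column-wise into one alignment, recording each
#' gene's column interval in the partition table. All alignments must share
#' an identical taxon set; with \code{padMissing = TRUE}, taxa absent from a
#' gene are filled with gaps instead (for the few genes lacking a core
#' taxon).
#'
#' @param alignments list of [GeneAlignment-class] objects with a common
#'   alphabet.
#' @param geneNames character vector naming each alignment (defaults to
#'   list names or \code{gene1, gene2, ...}).
#' @param padMissing if \code{TRUE}, pad missing taxa with gap rows; if
#'   \code{FALSE} (default), a taxon-set mismatch is an error.
#' @return a [GeneAlignment-class] whose column count is the sum of the
#'   inputs' and whose partitions record each gene's 0-based half-open
#'   interval.
#' @examples
#' a <- GeneAlignment(c(x = "MK", y = "MR"))
#' b <- GeneAlignment(c(x = "V", y = "I"))
#' genePartitions(concatenateAlignments(list(a, b), c("g1", "g2")))
#' @export
concatenateAlignments <- function(alignments, geneNames = NULL,
                                  padMissing = FALSE) {
  stopifnot(length(alignments) >= 1)
  if (is.null(geneNames))
    geneNames <- if (!is.null(names(alignments))) names(alignments)
                 else paste0("gene", seq_along(alignments))
  if (length(geneNames) != length(alignments))
    stop("geneNames length must match alignments")
  alph <- unique(vapply(alignments, seqAlphabet, character(1)))
  if (length(alph) != 1) stop("alignments mix alphabets")
  allTaxa <- sort(unique(unlist(lapply(alignments, taxonNames))))
  gapChar <- "-"
  mats <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    m <- seqMatrix(alignments[[i]])
    missing <- setdiff(allTaxa, rownames(m))
    extra <- setdiff(rownames(m), allTaxa)
    if (length(missing) && !padMissing)
      stop("taxon sets differ across alignments (gene '", geneNames[i],
           "'): missing {", paste(missing, collapse = ", "),
           "}; use padMissing = TRUE to gap-fill")
    if (length(extra))
      stop("unexpected taxa in gene '", geneNames[i], "': ",
           paste(extra, collapse = ", "))
    if (length(missing)) {
      pad <- matrix(gapChar, length(missing), ncol(m),
                    dimnames = list(missing, NULL))
      m <- rbind(m, pad)
    }
    mats[[i]] <- m[allTaxa, , drop = FALSE]
  }
  out <- do.call(cbind, mats)
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  partitions <- data.frame(gene = geneNames,
                           start = c(0L, ends[-length(ends)]),
                           end = ends)
  new("GeneAlignment", seqs = out, alphabet = alph,
      partitions = partitions)
}

#' Split a concatenated alignment back into its gene blocks
#'
#' @param alignment a [GeneAlignment-class] with a partition table.
#' @return named list of [GeneAlignment-class] objects, one per gene.
#' @export
splitByPartition <- function(alignment) {
  p <- genePartitions(alignment)
  if (!nrow(p)) stop("alignment has no partitions")
  m <- seqMatrix(alignment)
  out <- lapply(seq_len(nrow(p)), function(i) {
    cols <- (p$start[i] + 1L):p$end[i]
    GeneAlignment(m[, cols, drop = FALSE], alphabet = seqAlphabet(alignment))
  })
  names(out) <- p$gene
  out
}

#' Remove all columns containing gaps or missing data
#'
#' Complete-deletion filtering: keeps exactly the columns where every taxon
#' has a determined residue (no gap, no X/N), preserving column order.
#' Partition intervals are remapped to the surviving columns.
#'
#' @param alignment a [GeneAlignment-class].
#' @return a [GeneAlignment-class]; may have zero columns.
#' @examples
#' aln <- GeneAlignment(c(a = "MKV", b = "M-V"))
#' nSites(completeDeletion(aln))  # 2
#' @export
completeDeletion <- function(alignment) {
  m <- seqMatrix(alignment)
  if (nrow(m) == 0) stop("empty alignment")
  miss <- .missingChars(seqAlphabet(alignment))
  keep <- colSums(matrix(m %in% miss, nrow(m))) == 0
  p <- genePartitions(alignment)
  newp <- NULL
  if (nrow(p)) {
    kept_cum <- cumsum(keep)
    starts <- ifelse(p$start == 0, 0L, kept_cum[p$start])
    ends <- kept_cum[p$end]
    ok <- ends > starts
    newp <- data.frame(gene = p$gene[ok], start = as.integer(starts[ok]),
                       end = as.integer(ends[ok]))
  }
  GeneAlignment(m[, keep, drop = FALSE], alphabet = seqAlphabet(alignment),
                partitions = newp)
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick parser that add the validation this
#' pipeline relies on: non-empty text, unique tip labels, and a parse error
#' on malformed input. \code{writeNewick} emits branch lengths to 10
#' significant digits so that write-then-read round-trips preserve them.
#'
#' @param text a Newick string (or a file path for \code{readNewickFile}).
#' @param tree an ape \code{phylo} object.
#' @return \code{readNewick}: an ape \code{phylo}; \code{writeNewick}: a
#'   Newick string.
#' @examples
#' tr <- readNewick("(a:1,b:2);")
#' writeNewick(tr)
#' @export
readNewick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("Newick parse error: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  tr
}

#' @rdname readNewick
#' @export
writeNewick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

#' Read a fossil-calibration table
#'
#' Reads a TSV with columns \code{clade_tips} (comma-separated tip labels
#' identifying the calibrated node as their most recent common ancestor),
#' \code{lower_Ma}, \code{upper_Ma} (empty/NA when absent) and \code{style}
#' (\code{soft} or \code{hard-lower}).
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{clade_tips} (list column of
#'   character vectors), \code{lower_Ma}, \code{upper_Ma}, \code{style}.
#' @export
readCalibrations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clade_tips", "lower_Ma", "upper_Ma", "style")
  if (!all(need %in% names(tab)))
    stop("calibration table needs columns: ", paste(need, collapse = ", "))
  tab$clade_tips <- lapply(strsplit(tab$clade_tips, ","), trimws)
  tab$lower_Ma <- as.numeric(tab$lower_Ma)
  tab$upper_Ma <- as.numeric(tab$upper_Ma)
  .validateCalibrations(tab)
  tab
}

.validateCalibrations <- function(tab) {
  for (i in seq_len(nrow(tab))) {
    st <- tab$style[i]
    if (!(st %in% c("soft", "hard-lower")))
      stop("unknown calibration style: ", st)
    lo <- tab$lower_Ma[i]; up <- tab$upper_Ma[i]
    if (st == "hard-lower" && !is.na(up))
      stop("hard-lower calibration cannot have an upper bound (row ", i, ")")
    if (!is.na(lo) && !is.na(up) && lo >= up)
      stop("calibration lower >= upper (row ", i, ")")
  }
  invisible(tab)
}
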