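# Nucleotide primitives, FASTA I/O, k-mer index, and the LCS oracle.
# Coordinates are 0-based, half-open throughout the package.

DNA_ALPHABET <- c("A", "C", "G", "T")

.assertDna <- function(x, what = "sequence", allowAmbiguous = FALSE) {
  pat <- if (allowAmbiguous) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T}",
         if (allowAmbiguous) "/N" else "",
         ": ", paste(head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' Watson-Crick reverse complement over the strict \{A,C,G,T\} alphabet.
#' An involution: \code{revComp(revComp(x)) == x}.
#'
#' @param x Character vector of DNA strings (upper case A/C/G/T only;
#'   ambiguity codes are rejected).
#' @return Character vector of the same length and element widths.
#' @examples
#' revComp("ACGT")  # palindromic: "ACGT"
#' revComp("AAAA")  # "TTTT"
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  .assertDna(x, "revComp input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Render a DNA string as RNA
#'
#' All internal sequence handling is DNA; this converts T to U for
#' RNA-facing output (e.g. printing guide strands as siRNA).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector with T replaced by U.
#' @export
asRna <- function(x) chartr("T", "U", x)

#' Read a DNA FASTA file
#'
#' Multi-record FASTA (wrapped or unwrapped). Record identifiers are the
#' first whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with cleaned names.
#' @export
readFastaDNA <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a DNA FASTA file
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFastaDNA <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Longest common substring length of two DNA strings
#'
#' Dynamic-programming length of the longest contiguous substring shared
#' by `a` and `b`. This is the package's operational definition of
#' "k nt complementarity": a guide whose target window shares a length-k
#' substring with a transcript has k nt of contiguous Watson-Crick
#' complementarity to it. Symmetric in its arguments.
#'
#' @param a,b Non-empty DNA strings.
#' @return Integer length of the longest shared substring (0 if none).
#' @examples
#' longestCommonSubstring("AAAA", "TTTT")             # 0
#' longestCommonSubstring("ACGTACGT", "ACGTACGT")     # 8
#' @export
longestCommonSubstring <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L,
            nzchar(a), nzchar(b))
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  nb <- length(bv)
  prev <- integer(nb)
  best <- 0L
  for (ca in av) {
    hit <- bv == ca
    cur <- integer(nb)
    cur[hit] <- c(0L, prev[-nb])[hit] + 1L
    m <- max(cur)
    if (m > best) best <- m
    prev <- cur
  }
  best
}

# All k-mers of a set of sequences (character vector), as one character
# vector. Sequences shorter than k contribute nothing.
.allKmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  })
  unlist(out, use.names = FALSE)
}

#' K-mer membership index over a background transcriptome
#'
#' Answers "does any non-target transcript contain this length-k
#' substring?" in support of the off-target rule: with `k = 16`, a
#' 22-nt target window that shares any 16-mer with a non-target
#' transcript has more than 15 nt of contiguous complementarity to it.
#' Queries are defined only for strings of length exactly `k` and agree
#' with brute-force substring search on the same transcripts.
#'
#' @slot k Integer k-mer length.
#' @slot kmers Sorted unique character vector of all k-mers occurring in
#'   the indexed (non-target) transcripts.
#' @slot nTranscripts Number of transcripts indexed (after excluding
#'   targets).
#' @export
setClass("KmerIndex",
  representation(k = "integer", kmers = "character",
                 nTranscripts = "integer"),
  validity = function(object) {
    if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
      return("k must be a single integer >= 2")
    if (is.unsorted(object@kmers, strictly = TRUE) &&
        length(object@kmers) > 1L)
      return("kmers must be sorted and unique")
    TRUE
  })

#' Build a k-mer index from a transcriptome
#'
#' @param transcripts A [Biostrings::DNAStringSet] or named character
#'   vector of transcript sequences.
#' @param targetIds Identifiers of the target gene's isoforms; these are
#'   excluded from the index so the target itself never counts as an
#'   off-target. Must be a subset of the transcript names.
#' @param k Seed length in nt (default 16 = off-target threshold + 1).
#' @return A [KmerIndex-class] object.
#' @export
buildKmerIndex <- function(transcripts, targetIds = character(0), k = 16L) {
  k <- as.integer(k)
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  if (length(transcripts) && is.null(names(transcripts)))
    stop("transcripts must be named")
  unknown <- setdiff(targetIds, names(transcripts))
  if (length(unknown))
    stop("targetIds not present in transcriptome: ",
         paste(unknown, collapse = ", "))
  keep <- transcripts[!(names(transcripts) %in% targetIds)]
  km <- if (length(keep)) sort(unique(.allKmers(keep, k))) else character(0)
  methods::new("KmerIndex", k = k, kmers = km,
               nTranscripts = length(keep))
}

#' Query a k-mer index
#'
#' @param index A [KmerIndex-class].
#' @param s Character vector of query strings, each of length `index@k`.
#' @return Logical vector: does each query occur in any indexed
#'   transcript?
#' @export
hasKmer <- function(index, s) {
  stopifnot(methods::is(index, "KmerIndex"))
  if (length(s) == 0L) return(logical(0))
  if (any(nchar(s) != index@k))
    stop("queries must have length exactly k = ", index@k)
  !is.na(match(s, index@kmers))
}

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex: k =", object@k, "|",
      length(object@kmers), "distinct k-mers from",
      object@nTranscripts, "transcripts\n")
})
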