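#' Reference assembly container
#'
#' Loads a genome assembly from FASTA into an `ig_assembly` object:
#' uppercased sequences, contig lengths, and an index of N-runs (maximal
#' runs of the ambiguity base N, typically scaffolding gaps). Soft-masked
#' (lowercase) bases are uppercased before any comparison, since masking
#' is not sequence difference.
#'
#' @param path path to a FASTA file.
#' @param nonstandard what to do with IUPAC ambiguity codes other than N:
#'   `"error"` (default) rejects the assembly, `"mask"` converts them to N.
#' @return an `ig_assembly`: list with `seqs` (`DNAStringSet`), `lengths`
#'   (named integer, bp) and `n_runs` (named list of data.frames with
#'   0-based half-open `start`/`end` columns, sorted, non-overlapping,
#'   maximal).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTACGT", ">c2", "ACGTNNNNAC"), fa)
#' asm <- load_assembly(fa)
#' asm$n_runs$c2  # one run, positions [4, 8)
#' @export
load_assembly <- function(path, nonstandard = c("error", "mask")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("assembly FASTA not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  as_assembly(setNames(toupper(as.character(seqs)), names(seqs)),
              nonstandard = nonstandard)
}

#' Build an `ig_assembly` from in-memory sequences
#'
#' @param x named character vector of contig sequences (A/C/G/T/N after
#'   uppercasing).
#' @inheritParams load_assembly
#' @return an `ig_assembly`; see [load_assembly()].
#' @export
as_assembly <- function(x, nonstandard = c("error", "mask")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(is.character(x), !is.null(names(x)), all(nzchar(names(x))))
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    if (nonstandard == "error")
      stop("non-ACGTN characters in contig(s): ",
           paste(names(x)[bad], collapse = ", "),
           " (use nonstandard = \"mask\" to convert to N)")
    x <- gsub("[^ACGTN]", "N", x)
  }
  seqs <- Biostrings::DNAStringSet(x)
  n_runs <- lapply(seq_along(seqs), function(i) {
    hits <- Biostrings::matchPattern("N", seqs[[i]], fixed = TRUE)
    .ir_df(IRanges::reduce(methods::as(hits, "IRanges")))
  })
  names(n_runs) <- names(seqs)
  structure(
    list(seqs = seqs,
         lengths = setNames(Biostrings::width(seqs), names(seqs)),
         n_runs = n_runs),
    class = "ig_assembly"
  )
}

#' @export
print.ig_assembly <- function(x, ...) {
  cat("ig_assembly:", length(x$seqs), "contig(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  n_gap <- sum(vapply(x$n_runs, nrow, 0L))
  cat("  N-runs:", n_gap, "\n")
  invisible(x)
}

## character substring of a contig, 0-based half-open coords
assembly_subseq <- function(assembly, contig, start0, end0) {
  as.character(Biostrings::subseq(assembly$seqs[[contig]], start0 + 1L, end0))
}

## do any N-runs of `contig` overlap [start0, end0)?
overlaps_n_run <- function(assembly, contig, start0, end0) {
  nr <- assembly$n_runs[[contig]]
  if (is.null(nr) || nrow(nr) == 0L) return(FALSE)
  any(nr$start < end0 & nr$end > start0)
}
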