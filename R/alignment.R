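#' Aligned COI haplotype matrix
#'
#' Container for a fixed-length nucleotide alignment. Sequences are stored
#' upper-case as a character matrix (one row per sample, one column per site);
#' `U` is mapped to `T` on construction. IUPAC ambiguity codes, `N` and `-`
#' are retained but treated as missing data by all downstream statistics
#' (pairwise deletion). Sites are indexed 1-based in every user-facing report.
#'
#' @param ids character vector of unique sample identifiers.
#' @param seqs character vector of equal-length sequences (one string each).
#' @return An object of class `coi_alignment`: a list with elements `ids`,
#'   `mat` (character site matrix), `code` (integer matrix, 1..4 for A/C/G/T,
#'   `NA` for anything else) and `L` (alignment length in bp).
#' @examples
#' aln <- alignment(c("a", "b"), c("ACGT", "ACGA"))
#' aln$L
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length", call. = FALSE)
  if (length(ids) == 0L)
    stop("empty alignment: no sequences", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sample ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), " bp)", call. = FALSE)
  L <- lens[1L]
  if (L < 1L) stop("alignment length must be positive", call. = FALSE)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(ids), ncol = L, byrow = TRUE,
                dimnames = list(ids, NULL))
  structure(list(ids = ids, mat = mat, code = .acgt_code(mat), L = L),
            class = "coi_alignment")
}

# integer coding: A=1 C=2 G=3 T=4, everything else (gap, N, IUPAC) missing
.acgt_code <- function(mat) {
  code <- match(mat, c("A", "C", "G", "T"))
  dim(code) <- dim(mat)
  dimnames(code) <- dimnames(mat)
  code
}

#' @export
print.coi_alignment <- function(x, ...) {
  cat(sprintf("COI alignment: %d sequences x %d sites (%.1f%% missing/ambiguous)\n",
              length(x$ids), x$L, 100 * mean(is.na(x$code))))
  invisible(x)
}

#' @export
`[.coi_alignment` <- function(x, i, ...) {
  idx <- seq_along(x$ids)
  names(idx) <- x$ids
  i <- idx[i]
  if (anyNA(i)) stop("unknown sample index or id", call. = FALSE)
  structure(list(ids = x$ids[i],
                 mat = x$mat[i, , drop = FALSE],
                 code = x$code[i, , drop = FALSE],
                 L = x$L),
            class = "coi_alignment")
}

#' Read an aligned FASTA file
#'
#' Thin wrapper around [ape::read.FASTA()]: sequences are upper-cased, `U`
#' (RNA notation, which the DNA bit-level coding cannot hold) is mapped to
#' `T` before parsing, and the result is validated as a proper alignment
#' (equal lengths, unique ids, non-empty).
#'
#' @param path path to a FASTA file of pre-aligned, pre-trimmed sequences.
#' @return A [alignment()] object.
#' @seealso [write_alignment()], [slice_window()]
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop("empty FASTA file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr)) stop("not a FASTA file (no '>' headers): ", path, call. = FALSE)
  lines[!is_hdr] <- gsub("[Uu]", "T", lines[!is_hdr])
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  dna <- ape::read.FASTA(tmp)
  ids <- sub("\\s.*$", "", names(dna))
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  alignment(ids, seqs)
}

#' Write an alignment to FASTA
#'
#' @param x a [alignment()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "coi_alignment"))
  seqs <- apply(x$mat, 1L, paste, collapse = "")
  dna <- ape::as.DNAbin(strsplit(tolower(seqs), "", fixed = TRUE))
  names(dna) <- x$ids
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Slice an alignment window
#'
#' Convenience sub-alignment over a 1-based inclusive site range. The package
#' assumes pre-trimmed input (the COI fragment analysed is trimmed upstream);
#' this is only an inspection helper, no automatic trimming is ever applied.
#'
#' @param x a [alignment()] object.
#' @param start,end 1-based inclusive site bounds.
#' @export
slice_window <- function(x, start, end) {
  stopifnot(inherits(x, "coi_alignment"))
  if (start < 1L || end > x$L || start > end)
    stop("window out of range [1, ", x$L, "]", call. = FALSE)
  sel <- start:end
  structure(list(ids = x$ids,
                 mat = x$mat[, sel, drop = FALSE],
                 code = x$code[, sel, drop = FALSE],
                 L = length(sel)),
            class = "coi_alignment")
}
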