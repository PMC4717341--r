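#' Read the per-sample metadata table
#'
#' The metadata table maps every sequence to its mite species, host bird
#' individual and sampling locality, mirroring the sampling-design table of a
#' multi-host survey. Required columns: `sample_id`, `species`, `bird_id`,
#' `locality`. An optional `source` column (`multi_per_bird` /
#' `one_per_bird`) records the sampling scheme; extra columns are kept but
#' ignored by the analysis.
#'
#' @param path path to a TSV/CSV file with a header row. The delimiter is
#'   inferred from the extension (`.csv` = comma, otherwise tab).
#' @return A `data.frame` with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param md a data.frame to validate in place of a file.
#' @export
validate_metadata <- function(md) {
  required <- c("sample_id", "species", "bird_id", "locality")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in required) md[[col]] <- as.character(md[[col]])
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(md$bird_id)))
    stop("empty bird_id in metadata", call. = FALSE)
  md
}

#' Read the per-species median infrapopulation size table
#'
#' Median infrapopulation size (mites per infected host individual) is the
#' census-size surrogate of the analysis; it comes from host-survey counts,
#' not from the sequence data.
#'
#' @param path TSV/CSV with header columns `species` and `median_load`.
#' @return A named numeric vector of loads, names = species.
#' @export
read_loads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("species", "median_load") %in% names(tab)))
    stop("loads table needs columns 'species' and 'median_load'", call. = FALSE)
  loads <- as.numeric(tab$median_load)
  names(loads) <- as.character(tab$species)
  if (any(!is.finite(loads) | loads <= 0))
    stop("median loads must be positive and finite", call. = FALSE)
  if (anyDuplicated(names(loads)))
    stop("duplicate species in loads table", call. = FALSE)
  loads
}

#' Assemble one dataset per symbiont species
#'
#' Joins the alignment to the metadata and the load table and splits the
#' samples by mite species. Samples present in only one of alignment /
#' metadata are dropped and reported; species with fewer than 2 sequences are
#' excluded with a warning (no within-species statistic is defined for them).
#'
#' @param aln a [alignment()] object covering all species.
#' @param metadata data.frame as returned by [read_metadata()].
#' @param loads named numeric vector as returned by [read_loads()].
#' @return A named list of `species_dataset` objects, each a list with
#'   `species`, `alignment`, `metadata` (rows for that species, in alignment
#'   order) and `median_load`. The join report is attached as attribute
#'   `join_report` (ids unmatched on either side).
#' @export
build_species_datasets <- function(aln, metadata, loads) {
  stopifnot(inherits(aln, "coi_alignment"))
  metadata <- validate_metadata(metadata)
  only_aln <- setdiff(aln$ids, metadata$sample_id)
  only_md <- setdiff(metadata$sample_id, aln$ids)
  matched <- intersect(aln$ids, metadata$sample_id)
  if (length(only_aln) || length(only_md))
    warning(sprintf("join report: %d sequence(s) without metadata, %d metadata row(s) without sequence",
                    length(only_aln), length(only_md)), call. = FALSE)
  md <- metadata[match(matched, metadata$sample_id), , drop = FALSE]
  species <- unique(md$species)
  miss <- setdiff(species, names(loads))
  if (length(miss))
    stop("no median load for species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (sp in species) {
    ids <- md$sample_id[md$species == sp]
    if (length(ids) < 2L) {
      warning("species '", sp, "' has < 2 sequences; excluded", call. = FALSE)
      next
    }
    out[[sp]] <- species_dataset(sp, aln[ids],
                                 md[md$species == sp, , drop = FALSE],
                                 loads[[sp]])
  }
  attr(out, "join_report") <- list(unmatched_sequences = only_aln,
                                   unmatched_metadata = only_md)
  out
}

#' @rdname build_species_datasets
#' @param sp species label.
#' @param alignment a [alignment()] for this species only.
#' @param md metadata rows for this species.
#' @param median_load positive median infrapopulation size.
#' @export
species_dataset <- function(sp, alignment, md, median_load) {
  stopifnot(inherits(alignment, "coi_alignment"))
  if (!all(alignment$ids %in% md$sample_id))
    stop("every alignment id needs a metadata row", call. = FALSE)
  if (!is.numeric(median_load) || length(median_load) != 1L ||
      !is.finite(median_load) || median_load <= 0)
    stop("median_load must be a positive number", call. = FALSE)
  if (length(alignment$ids) < 2L)
    stop("a species dataset needs at least 2 sequences", call. = FALSE)
  md <- md[match(alignment$ids, md$sample_id), , drop = FALSE]
  structure(list(species = sp, alignment = alignment, metadata = md,
                 median_load = as.numeric(median_load)),
            class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(sprintf("<%s> %d mites, %d birds, median load %.1f\n", x$species,
              length(x$alignment$ids), length(unique(x$metadata$bird_id)),
              x$median_load))
  invisible(x)
}
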