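#' Read assembled contigs from FASTA
#'
#' Sequences are uppercased on load. Optionally drops contigs shorter than
#' a minimum length, mirroring the usual assembly post-filter.
#'
#' @param path FASTA file path.
#' @param library Library tag to attach to every contig (default: file
#'   name without extension).
#' @param min_nt If not `NULL`, contigs shorter than this many nucleotides
#'   are removed (the conventional assembly filter is 200 nt).
#' @return data.frame with columns `id`, `seq`, `library`, `read_count`
#'   (NA until counts are attached).
#' @export
read_fasta <- function(path, library = NULL, min_nt = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", path)
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in records: ", paste(ids[bad], collapse = ", "))
  if (is.null(library)) library <- tools::file_path_sans_ext(basename(path))
  df <- data.frame(id = ids, seq = unname(seqs), library = library,
                   read_count = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(min_nt)) df <- df[nchar(df$seq) >= min_nt, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write contigs (or proteins) to FASTA
#'
#' @param x data.frame with `id` and `seq`, or a named character vector.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Attach per-contig read counts from a TSV
#'
#' @param contigs Contig data.frame from [read_fasta()].
#' @param path Tab-delimited file with header columns `contig_id` and
#'   `read_count`.
#' @return The contig data.frame with `read_count` filled where known.
#' @export
attach_counts <- function(contigs, path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "read_count") %in% names(counts)))
    stop("counts TSV must have columns contig_id and read_count")
  idx <- match(contigs$id, counts$contig_id)
  contigs$read_count <- counts$read_count[idx]
  contigs
}

# Deterministic TSV writer used for every report: tab-separated, header
# row, no quoting, "." decimal mark.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
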