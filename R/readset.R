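# Read container and FASTQ I/O (phred+33), backed by Biostrings.

#' Construct a read set
#'
#' A `read_set` is a data.frame with one row per read and columns `id`,
#' `sequence`, `quality` (phred+33 string of the same length), `role`
#' (`"concatemer"` or `"monomer-segment"`), `parent` (id of the originating
#' concatemer for segments) and `strand` (`"+"`, `"-"`, or `NA` when unknown).
#'
#' @param id character vector of read identifiers.
#' @param sequence DNA strings.
#' @param quality phred+33-encoded quality strings; lengths must match
#'   `sequence` record by record.
#' @param role read role.
#' @param parent parent read id (for monomer segments).
#' @param strand read strand where known.
#' @return a `read_set` data.frame.
#' @export
read_set <- function(id, sequence, quality,
                     role = "concatemer", parent = NA_character_,
                     strand = NA_character_) {
  sequence <- as.character(sequence)
  quality <- as.character(quality)
  bad <- which(nchar(quality) != nchar(sequence))
  if (length(bad))
    stop("sequence/quality length mismatch for read(s): ",
         paste(head(id[bad], 5), collapse = ", "))
  n <- length(id)
  structure(data.frame(id = as.character(id), sequence = sequence,
                       quality = quality, role = rep_len(role, n),
                       parent = rep_len(as.character(parent), n),
                       strand = rep_len(as.character(strand), n),
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' @rdname read_set
#' @param role read role for the empty set.
#' @export
empty_read_set <- function(role = "monomer-segment") {
  read_set(character(), character(), character(), role = character())
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file (4-line records, phred+33). Truncated or malformed
#'   records raise an error.
#' @param role role to assign to the reads.
#' @return a [read_set()].
#' @export
read_fastq <- function(path, role = "concatemer") {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  # the metadata-column note from the internal XStringSet constructor is noise
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  read_set(id = sub("\\s.*$", "", names(x)),
           sequence = as.character(x),
           quality = as.character(Biostrings::quality(x)),
           role = role)
}

#' Write a read set to FASTQ
#'
#' `write_fastq` followed by [read_fastq()] is the identity on sequences and
#' qualities.
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  q <- Biostrings::PhredQuality(reads$quality)
  # metadata-column warning from the internal XStringSet constructor is noise
  y <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(x, q))
  Biostrings::writeQualityScaledXStringSet(y, path)
  invisible(path)
}

# constant-quality string for a given per-base error rate
qual_string <- function(n, error_rate) {
  q <- max(0L, min(93L, as.integer(round(error_to_phred(error_rate)))))
  strrep(intToUtf8(33L + q), n)
}

# mean phred score across all bases of a read set
mean_phred <- function(reads) {
  if (!nrow(reads)) return(NA_real_)
  qs <- unlist(lapply(reads$quality, function(s) utf8ToInt(s) - 33L))
  mean(qs)
}
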