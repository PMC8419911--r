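# Deconcatenation: approximate junction-adapter matching and read splitting.

#' Find approximate junction-adapter occurrences in a read
#'
#' Searches both orientations of the adapter with a bit-parallel edit-distance
#' scan; all occurrences with edit distance `<= max_edit_fraction * adapter
#' length` are reported. Overlapping candidates are resolved greedily by
#' lowest edit distance, ties by leftmost start.
#'
#' @param read a single read sequence (character) or a 1-row [read_set()].
#' @param junction_adapter adapter sequence, 10-64 nt.
#' @param max_edit_fraction maximum edit distance as a fraction of the adapter
#'   length, in `[0, 0.5)`. Default 0.25: at a 7-10% read error rate a 20-mer
#'   adapter carries 1.4-2 expected errors, so a quarter-length budget retains
#'   sensitivity without spurious hits.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `edits`, `strand` (`"+"`/`"-"`), sorted by `start`; zero rows if the
#'   adapter is absent.
#' @export
find_junctions <- function(read, junction_adapter, max_edit_fraction = 0.25) {
  seq <- if (is.data.frame(read)) read$sequence[[1]] else read
  m <- cpp_find_junctions(seq, junction_adapter, max_edit_fraction)
  data.frame(start = m[, "start"], end = m[, "end"], edits = m[, "edits"],
             strand = ifelse(m[, "strand"] == 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Split a read at junction hits
#'
#' Segments are the maximal intervals between the read start, the junction
#' hits, and the read end. Segments shorter than `min_segment_length` are
#' dropped and their bases counted, so that
#' `segment bases + junction bases + dropped bases == read length`.
#' Qualities are sliced in register with the sequence.
#'
#' @param read a 1-row [read_set()] (or list with `id`, `sequence`,
#'   `quality`).
#' @param hits junction hits from [find_junctions()] (non-overlapping,
#'   sorted by start).
#' @param min_segment_length minimum retained segment length.
#' @return list with `segments` (a [read_set()] of monomer segments with
#'   parent linkage), `n_segments`, `n_hits`, `dropped_bases`,
#'   `junction_bases`.
#' @export
split_read <- function(read, hits, min_segment_length = 30) {
  seq <- read$sequence[[1]]
  qual <- read$quality[[1]]
  id <- read$id[[1]]
  len <- nchar(seq)
  bounds_lo <- c(0L, hits$end)
  bounds_hi <- c(hits$start, len)
  w <- bounds_hi - bounds_lo
  keep <- w >= min_segment_length
  dropped <- sum(w[!keep])
  lo <- bounds_lo[keep]; hi <- bounds_hi[keep]
  segs <- if (length(lo)) {
    read_set(id = sprintf("%s/%d", id, seq_along(lo)),
             sequence = substring(seq, lo + 1L, hi),
             quality = substring(qual, lo + 1L, hi),
             role = "monomer-segment", parent = id)
  } else empty_read_set()
  list(segments = segs, n_segments = nrow(segs), n_hits = nrow(hits),
       dropped_bases = dropped, junction_bases = sum(hits$end - hits$start))
}

#' Deconcatenate a read set
#'
#' Applies [find_junctions()] and [split_read()] to every read. Reads without
#' adapter hits pass through as a single segment (monomer-only input is
#' returned unchanged apart from role/parent bookkeeping).
#'
#' @param reads a [read_set()] of concatemer reads.
#' @param junction_adapter adapter sequence.
#' @param max_edit_fraction see [find_junctions()].
#' @param min_segment_length minimum retained segment length; a practical
#'   default is half the shortest panel amplicon (shorter fragments are
#'   uninformative and inflate mis-mapping). [run_pipeline()] sets this
#'   automatically from the panel.
#' @return list with `segments` (a [read_set()]), `per_read` (data.frame:
#'   `read_id`, `n_hits`, `n_segments`, `dropped_bases`) and `summary` (list:
#'   `n_reads`, `n_segments`, `mean_segments_per_read`, `reads_without_segments`,
#'   `total_input_bases`, `segment_bases`, `junction_bases`, `dropped_bases`).
#' @export
deconcatenate <- function(reads, junction_adapter, max_edit_fraction = 0.25,
                          min_segment_length = 30) {
  n <- nrow(reads)
  if (!n) {
    return(list(segments = empty_read_set(),
                per_read = data.frame(read_id = character(), n_hits = integer(),
                                      n_segments = integer(),
                                      dropped_bases = integer()),
                summary = list(n_reads = 0L, n_segments = 0L,
                               mean_segments_per_read = NaN,
                               reads_without_segments = 0L,
                               total_input_bases = 0L, segment_bases = 0L,
                               junction_bases = 0L, dropped_bases = 0L)))
  }
  # per-read junction scan, then one vectorized substring pass for all
  # segments (same semantics as find_junctions() + split_read() per read)
  lo_list <- vector("list", n); hi_list <- vector("list", n)
  n_hits <- integer(n); n_segs <- integer(n); dropped <- integer(n)
  junction_bases <- 0L
  seqs <- reads$sequence
  lens <- nchar(seqs)
  for (i in seq_len(n)) {
    hits <- cpp_find_junctions(seqs[i], junction_adapter, max_edit_fraction)
    lo <- c(0L, hits[, "end"])
    hi <- c(hits[, "start"], lens[i])
    keep <- (hi - lo) >= min_segment_length
    lo_list[[i]] <- lo[keep]; hi_list[[i]] <- hi[keep]
    n_hits[i] <- nrow(hits)
    n_segs[i] <- sum(keep)
    dropped[i] <- sum((hi - lo)[!keep])
    junction_bases <- junction_bases + sum(hits[, "end"] - hits[, "start"])
  }
  lo <- unlist(lo_list, use.names = FALSE)
  hi <- unlist(hi_list, use.names = FALSE)
  parent_idx <- rep.int(seq_len(n), n_segs)
  slot <- unlist(lapply(n_segs, seq_len), use.names = FALSE)
  segments <- read_set(
    id = sprintf("%s/%d", reads$id[parent_idx], slot),
    sequence = substring(seqs[parent_idx], lo + 1L, hi),
    quality = substring(reads$quality[parent_idx], lo + 1L, hi),
    role = "monomer-segment", parent = reads$id[parent_idx])
  list(segments = segments,
       per_read = data.frame(read_id = reads$id, n_hits = n_hits,
                             n_segments = n_segs, dropped_bases = dropped,
                             stringsAsFactors = FALSE),
       summary = list(n_reads = n, n_segments = nrow(segments),
                      mean_segments_per_read = mean(n_segs),
                      reads_without_segments = sum(n_segs == 0L),
                      total_input_bases = sum(nchar(reads$sequence)),
                      segment_bases = sum(nchar(segments$sequence)),
                      junction_bases = junction_bases,
                      dropped_bases = sum(dropped)))
}
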