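# Alignment of monomer segments to panel amplicons and per-position pileup.

#' Default alignment scoring (nanopore-typical)
#'
#' Match +2, mismatch -4, gap open -4 plus gap extend -2 per gap base.
#' @return named list of scoring parameters.
#' @export
alignment_scoring <- function() {
  list(match = 2L, mismatch = 4L, gap_open = 4L, gap_extend = 2L,
       min_identity = 0.7)
}

#' Align monomer segments to a panel
#'
#' Candidate (amplicon, strand) pairs are pre-screened by shared 11-mers and
#' the best candidates are aligned with an affine-gap aligner that is
#' end-free: the segment may be truncated at junctions, so unaligned reference
#' flanks carry no penalty. Minus-strand segments are aligned as their reverse
#' complement, so all coordinates are in forward amplicon space. Segments
#' whose best and second-best scores tie across two different amplicons are
#' discarded as ambiguous (conservative: prevents pseudogene-style
#' cross-mapping), and segments with alignment identity below `min_identity`
#' are reported unaligned.
#'
#' @param segments a [read_set()] of segments (or character vector).
#' @param panel an [amplicon_panel()].
#' @param scoring scoring list, see [alignment_scoring()].
#' @param return_events keep per-segment pileup events (needed by
#'   [build_pileup()]).
#' @return data.frame with one row per segment: `id`, `amplicon` (NA if
#'   unaligned), `strand`, `score`, `identity`, `ref_start`, `ref_end`
#'   (0-based half-open), `status` (`aligned`, `ambiguous`, `low_identity`,
#'   `no_kmer_match`, `unaligned`). With `return_events`, the events are
#'   attached as attributes `obs` and `ins`.
#' @export
align_segments <- function(segments, panel, scoring = alignment_scoring(),
                           return_events = FALSE) {
  seqs <- if (is.data.frame(segments)) segments$sequence else segments
  ids <- if (is.data.frame(segments)) segments$id else
    sprintf("segment_%06d", seq_along(seqs))
  res <- cpp_align_batch(seqs, panel$amplicons$sequence,
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, scoring$min_identity,
                         return_events)
  out <- data.frame(id = ids,
                    amplicon = panel$amplicons$name[res$amplicon],
                    strand = c("+", "-")[res$strand + 1L],
                    score = res$score, identity = res$identity,
                    ref_start = res$ref_start, ref_end = res$ref_end,
                    status = res$status, stringsAsFactors = FALSE)
  if (return_events) {
    attr(out, "obs") <- res$obs
    attr(out, "ins") <- res$ins
  }
  out
}

#' Align a single segment
#'
#' @param segment sequence (character) or 1-row [read_set()].
#' @inheritParams align_segments
#' @return a 1-row data.frame, see [align_segments()].
#' @export
align_segment <- function(segment, panel, scoring = alignment_scoring()) {
  seq <- if (is.data.frame(segment)) segment$sequence[[1]] else segment
  align_segments(seq, panel, scoring)
}

#' Downsample segments to a per-amplicon coverage cap
#'
#' If more than `max_depth - 1` segments are assigned to an amplicon, a
#' uniform random subset of `max_depth - 1` is retained, so the resulting
#' coverage is strictly below `max_depth` (the variant-caller regime the
#' gates were tuned for). Below the cap, segments pass through unchanged.
#' Uses the current RNG state; seed upstream for determinism.
#'
#' @param amplicon character vector: assigned amplicon per segment (NA =
#'   unassigned, always dropped).
#' @param max_depth coverage cap (default 150).
#' @return integer indices of retained segments, in their original order.
#' @export
downsample_segments <- function(amplicon, max_depth = 150) {
  stopifnot(max_depth > 0)
  keep <- integer(0)
  for (a in unique(amplicon[!is.na(amplicon)])) {
    idx <- which(!is.na(amplicon) & amplicon == a)
    if (length(idx) >= max_depth)
      idx <- sort(sample(idx, max_depth - 1L))
    keep <- c(keep, idx)
  }
  sort(keep)
}

#' Build a per-amplicon pileup from aligned segments
#'
#' Counts, at every reference position of every amplicon, the A/C/G/T
#' observations, deletions, and insertion-after events. Substitutions and
#' matches increment the base counts; a deletion increments the deletion count
#' at each deleted reference position; an insertion increments the
#' insertion-after count once per event at its anchor position (multi-base
#' insertions count once). Depth at a position is `A + C + G + T + del`.
#'
#' @param segments a [read_set()] of segments (or character vector).
#' @param panel an [amplicon_panel()].
#' @param alignments optional precomputed [align_segments()] result with
#'   events attached; computed if missing.
#' @param scoring see [alignment_scoring()].
#' @return a `pileup_matrix`: list with `counts` (per amplicon, a 6 x L
#'   integer matrix with rows A, C, G, T, del, ins), `n_segments` (aligned
#'   segments per amplicon) and `panel`.
#' @export
build_pileup <- function(segments, panel, alignments = NULL,
                         scoring = alignment_scoring()) {
  if (is.null(alignments) || is.null(attr(alignments, "obs")))
    alignments <- align_segments(segments, panel, scoring, return_events = TRUE)
  obs <- attr(alignments, "obs")
  ins <- attr(alignments, "ins")
  amps <- panel$amplicons
  counts <- lapply(seq_len(nrow(amps)), function(i) {
    m <- matrix(0L, nrow = 6, ncol = nchar(amps$sequence[i]),
                dimnames = list(c("A", "C", "G", "T", "del", "ins"), NULL))
    m
  })
  names(counts) <- amps$name
  n_seg <- setNames(integer(nrow(amps)), amps$name)
  aligned <- which(alignments$status == "aligned")
  for (si in aligned) {
    a <- alignments$amplicon[si]
    n_seg[[a]] <- n_seg[[a]] + 1L
    o <- obs[[si]]
    if (length(o)) {
      pos <- alignments$ref_start[si] + seq_along(o)  # 1-based columns
      valid <- o >= 0 & o <= 4
      idx <- cbind(o[valid] + 1L, pos[valid])
      # accumulate with tabulation to tolerate repeated columns
      flat <- (idx[, 2] - 1L) * 6L + idx[, 1]
      tab <- tabulate(flat, nbins = 6L * ncol(counts[[a]]))
      counts[[a]] <- counts[[a]] + matrix(tab, nrow = 6)
    }
    anchors <- ins[[si]]
    anchors <- anchors[anchors >= 0]
    if (length(anchors)) {
      tab <- tabulate(anchors + 1L, nbins = ncol(counts[[a]]))
      counts[[a]]["ins", ] <- counts[[a]]["ins", ] + tab
    }
  }
  structure(list(counts = counts, n_segments = n_seg, panel = panel),
            class = "pileup_matrix")
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat("pileup_matrix over", length(x$counts), "amplicon(s)\n")
  for (a in names(x$counts)) {
    d <- pileup_depth(x, a)
    cat(sprintf("  %-14s %5d segment(s), depth %d-%d\n", a, x$n_segments[[a]],
                if (length(d)) min(d) else 0L, if (length(d)) max(d) else 0L))
  }
  invisible(x)
}

#' Per-position depth of one amplicon's pileup
#'
#' Depth is `A + C + G + T + del` (insertion events do not add depth).
#' @param pileup a `pileup_matrix`.
#' @param amplicon amplicon name.
#' @return integer vector of depths.
#' @export
pileup_depth <- function(pileup, amplicon) {
  m <- pileup$counts[[amplicon]]
  as.integer(colSums(m[c("A", "C", "G", "T", "del"), , drop = FALSE]))
}

#' Flatten a pileup to a data.frame
#'
#' @param x a `pileup_matrix`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `amplicon`, `position` (0-based), `ref`,
#'   `A`, `C`, `G`, `T`, `ins`, `del`, `depth`.
#' @export
as.data.frame.pileup_matrix <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- lapply(names(x$counts), function(a) {
    m <- x$counts[[a]]
    seq <- x$panel$amplicons$sequence[x$panel$amplicons$name == a]
    data.frame(amplicon = a, position = seq_len(ncol(m)) - 1L,
               ref = strsplit(seq, "")[[1]],
               A = m["A", ], C = m["C", ], G = m["G", ], T = m["T", ],
               ins = m["ins", ], del = m["del", ],
               depth = pileup_depth(x, a), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a pileup TSV
#'
#' @param pileup a `pileup_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  write.table(as.data.frame(pileup), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
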