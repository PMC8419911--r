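# Amplicon panel definition, validation and I/O.
#
# All coordinates are 0-based half-open in amplicon space; 1-based coordinates
# appear only in VCF-like output.

#' Construct a single amplicon record
#'
#' @param name unique amplicon identifier.
#' @param sequence uppercase DNA string (A/C/G/T only).
#' @param fwd_primer,rev_primer integer length-2 vectors, 0-based half-open
#'   intervals of the forward and reverse primer binding sites on the amplicon.
#' @param enrichment_region integer length-2 vector, 0-based half-open interval
#'   of the positions covered by the blocker (the only positions where
#'   enrichment, and therefore calling, can occur). Must not overlap either
#'   primer span.
#' @param chrom,genome_start optional genome anchor (chromosome name and
#'   1-based genomic start) used for reporting only.
#' @return a one-row data.frame used as a building block of [amplicon_panel()].
#' @export
amplicon <- function(name, sequence, fwd_primer, rev_primer, enrichment_region,
                     chrom = NA_character_, genome_start = NA_integer_) {
  sequence <- toupper(sequence)
  df <- data.frame(
    name = as.character(name), sequence = sequence,
    fwd_start = as.integer(fwd_primer[1]), fwd_end = as.integer(fwd_primer[2]),
    rev_start = as.integer(rev_primer[1]), rev_end = as.integer(rev_primer[2]),
    enrich_start = as.integer(enrichment_region[1]),
    enrich_end = as.integer(enrichment_region[2]),
    chrom = as.character(chrom), genome_start = as.integer(genome_start),
    stringsAsFactors = FALSE)
  validate_amplicon(df)
  df
}

validate_amplicon <- function(a) {
  len <- nchar(a$sequence)
  if (grepl("[^ACGT]", a$sequence))
    stop("amplicon '", a$name, "': sequence contains non-ACGT characters")
  chk <- function(lo, hi, what) {
    if (is.na(lo) || is.na(hi) || lo < 0 || hi > len || lo >= hi)
      stop("amplicon '", a$name, "': invalid ", what, " interval [", lo, ", ",
           hi, ") on sequence of length ", len)
  }
  chk(a$fwd_start, a$fwd_end, "forward primer")
  chk(a$rev_start, a$rev_end, "reverse primer")
  chk(a$enrich_start, a$enrich_end, "enrichment region")
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  if (overlaps(a$enrich_start, a$enrich_end, a$fwd_start, a$fwd_end) ||
      overlaps(a$enrich_start, a$enrich_end, a$rev_start, a$rev_end))
    stop("amplicon '", a$name,
         "': enrichment region overlaps a primer span")
  invisible(a)
}

#' Construct an amplicon panel
#'
#' @param amplicons a data.frame of amplicon records (rbind of [amplicon()]
#'   rows).
#' @param enrichment_fold named numeric vector of calibrated enrichment folds.
#'   Names are either an amplicon name (panel-wide default for that amplicon)
#'   or a locus key `"amplicon:position:variant"` (per-locus override, e.g.
#'   `"KRAS-12:57:G>T"`). All folds must be positive. Amplicons without a fold
#'   are permitted but flagged: VAF estimation for them refuses to guess.
#' @param blacklist data.frame with columns `amplicon`, `position` (0-based)
#'   and `variant` (`"ref>alt"`, `"ins"`, `"del"`, or `"*"` for any variant);
#'   matching loci are excluded from calling (e.g. pseudogene cross-mapping).
#' @param junction_adapter DNA string ligated between monomers in concatemers
#'   (10-64 nt).
#' @return an object of class `amplicon_panel`.
#' @export
amplicon_panel <- function(amplicons, enrichment_fold = numeric(),
                           blacklist = NULL, junction_adapter) {
  if (anyDuplicated(amplicons$name))
    stop("amplicon names must be unique")
  for (i in seq_len(nrow(amplicons))) validate_amplicon(amplicons[i, ])
  if (length(enrichment_fold)) {
    if (is.null(names(enrichment_fold)) || any(!nzchar(names(enrichment_fold))))
      stop("enrichment_fold must be a named vector")
    if (any(!is.finite(enrichment_fold)) || any(enrichment_fold <= 0))
      stop("all enrichment folds must be positive and finite")
    amp_of <- sub(":.*$", "", names(enrichment_fold))
    bad <- setdiff(amp_of, amplicons$name)
    if (length(bad))
      stop("enrichment_fold refers to unknown amplicon(s): ",
           paste(unique(bad), collapse = ", "))
  }
  if (is.null(blacklist)) {
    blacklist <- data.frame(amplicon = character(), position = integer(),
                            variant = character(), stringsAsFactors = FALSE)
  } else {
    blacklist <- data.frame(amplicon = as.character(blacklist$amplicon),
                            position = as.integer(blacklist$position),
                            variant = as.character(blacklist$variant),
                            stringsAsFactors = FALSE)
    idx <- match(blacklist$amplicon, amplicons$name)
    if (anyNA(idx))
      stop("blacklist refers to unknown amplicon(s): ",
           paste(unique(blacklist$amplicon[is.na(idx)]), collapse = ", "))
    len <- nchar(amplicons$sequence)[idx]
    if (any(blacklist$position < 0 | blacklist$position >= len))
      stop("blacklist position outside amplicon bounds")
  }
  junction_adapter <- toupper(junction_adapter)
  if (nchar(junction_adapter) < 10)
    stop("junction adapter must be at least 10 nt")
  if (grepl("[^ACGT]", junction_adapter))
    stop("junction adapter contains non-ACGT characters")
  structure(list(amplicons = amplicons,
                 enrichment_fold = enrichment_fold,
                 blacklist = blacklist,
                 junction_adapter = junction_adapter),
            class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("amplicon_panel:", nrow(x$amplicons), "amplicon(s),",
      length(x$enrichment_fold), "enrichment fold(s),",
      nrow(x$blacklist), "blacklisted locus/loci\n")
  cat("junction adapter:", x$junction_adapter, "\n")
  df <- x$amplicons
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-14s %4d nt  enrichment [%d,%d)\n", df$name[i],
                nchar(df$sequence[i]), df$enrich_start[i], df$enrich_end[i]))
  invisible(x)
}

# look up the enrichment fold for a locus: per-locus override first,
# then the per-amplicon default; NA when uncalibrated.
panel_fold <- function(panel, amplicon, position, variant) {
  key <- paste(amplicon, position, variant, sep = ":")
  ef <- panel$enrichment_fold
  out <- unname(ef[key])
  miss <- is.na(out)
  out[miss] <- unname(ef[amplicon[miss]])
  out
}

is_blacklisted <- function(panel, amplicon, position, variant) {
  bl <- panel$blacklist
  if (!nrow(bl)) return(rep(FALSE, length(amplicon)))
  key <- paste(amplicon, position, variant, sep = ":")
  keyany <- paste(amplicon, position, "*", sep = ":")
  blkey <- paste(bl$amplicon, bl$position, bl$variant, sep = ":")
  key %in% blkey | keyany %in% blkey
}

region_of <- function(panel_row, position) {
  out <- rep("other", length(position))
  out[position >= panel_row$fwd_start & position < panel_row$fwd_end] <- "primer"
  out[position >= panel_row$rev_start & position < panel_row$rev_end] <- "primer"
  out[position >= panel_row$enrich_start & position < panel_row$enrich_end] <- "enrichment"
  out
}

#' Read an amplicon panel from a config file
#'
#' The panel config is a single tab-separated text file with a leading
#' `record` column naming the record type:
#' \describe{
#'   \item{adapter}{`adapter <tab> SEQUENCE`}
#'   \item{amplicon}{`amplicon <tab> name <tab> sequence <tab> fwd_start <tab>
#'     fwd_end <tab> rev_start <tab> rev_end <tab> enrich_start <tab>
#'     enrich_end [<tab> chrom <tab> genome_start]`}
#'   \item{fold}{`fold <tab> key <tab> E` where key is an amplicon name or an
#'     `amplicon:position:variant` locus key}
#'   \item{blacklist}{`blacklist <tab> amplicon <tab> position <tab> variant`}
#' }
#' Lines starting with `#` are comments. Amplicons with no calibrated fold are
#' reported in a warning (estimation later refuses rather than guessing).
#'
#' @param path path to the panel config file.
#' @return an [amplicon_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  amps <- list(); folds <- numeric(); bl <- list(); adapter <- NULL
  for (f in fields) {
    rec <- f[[1]]
    if (rec == "adapter") {
      adapter <- f[[2]]
    } else if (rec == "amplicon") {
      if (length(f) < 9) stop("malformed amplicon record: ", paste(f, collapse = "\t"))
      amps[[length(amps) + 1]] <- amplicon(
        name = f[[2]], sequence = f[[3]],
        fwd_primer = as.integer(f[4:5]), rev_primer = as.integer(f[6:7]),
        enrichment_region = as.integer(f[8:9]),
        chrom = if (length(f) >= 10) f[[10]] else NA_character_,
        genome_start = if (length(f) >= 11) as.integer(f[[11]]) else NA_integer_)
    } else if (rec == "fold") {
      folds[f[[2]]] <- as.numeric(f[[3]])
    } else if (rec == "blacklist") {
      bl[[length(bl) + 1]] <- data.frame(
        amplicon = f[[2]], position = as.integer(f[[3]]), variant = f[[4]],
        stringsAsFactors = FALSE)
    } else stop("unknown panel record type: ", rec)
  }
  if (!length(amps)) stop("panel config contains no amplicon records")
  if (is.null(adapter)) stop("panel config contains no adapter record")
  amplicons <- do.call(rbind, amps)
  panel <- amplicon_panel(
    amplicons, enrichment_fold = folds,
    blacklist = if (length(bl)) do.call(rbind, bl) else NULL,
    junction_adapter = adapter)
  no_fold <- setdiff(amplicons$name, sub(":.*$", "", names(folds)))
  if (length(no_fold))
    warning("no calibrated enrichment fold for amplicon(s): ",
            paste(no_fold, collapse = ", "),
            " (VAF estimation will refuse for these loci)")
  panel
}

#' Write an amplicon panel to a config file
#'
#' Inverse of [read_panel()]; round-trips all amplicons, folds, blacklist
#' entries and the junction adapter.
#'
#' @param panel an [amplicon_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("adapter", panel$junction_adapter, sep = "\t"), con)
  a <- panel$amplicons
  for (i in seq_len(nrow(a))) {
    f <- c("amplicon", a$name[i], a$sequence[i], a$fwd_start[i], a$fwd_end[i],
           a$rev_start[i], a$rev_end[i], a$enrich_start[i], a$enrich_end[i])
    if (!is.na(a$chrom[i])) f <- c(f, a$chrom[i], a$genome_start[i])
    writeLines(paste(f, collapse = "\t"), con)
  }
  for (key in names(panel$enrichment_fold))
    writeLines(paste("fold", key, format(panel$enrichment_fold[[key]], digits = 15),
                     sep = "\t"), con)
  bl <- panel$blacklist
  for (i in seq_len(nrow(bl)))
    writeLines(paste("blacklist", bl$amplicon[i], bl$position[i], bl$variant[i],
                     sep = "\t"), con)
  invisible(path)
}

#' Generate a synthetic amplicon panel
#'
#' Random panels for simulation and testing. Amplicon sequences are rejected
#' and regenerated if they contain an approximate match to the junction
#' adapter (either orientation, edit distance <= floor(0.25 * adapter length)
#' + 2): the wet-lab analogue is that amplicons carrying an internal
#' restriction/adapter site would be destroyed during concatemer assembly, and
#' computationally it keeps deconcatenation exact on error-free reads.
#'
#' @param n_amplicons number of amplicons.
#' @param amplicon_length length of every amplicon in nt.
#' @param primer_length primer span length at each end.
#' @param enrichment_width width(s) of the central enrichment region; recycled
#'   across amplicons.
#' @param enrichment_fold per-amplicon enrichment fold(s); recycled.
#' @param junction_adapter junction adapter sequence.
#' @param names optional amplicon names (default `AMP01`...).
#' @return an [amplicon_panel()].
#' @export
synthetic_panel <- function(n_amplicons = 3, amplicon_length = 160,
                            primer_length = 20, enrichment_width = 26,
                            enrichment_fold = 1000,
                            junction_adapter = "ATGGTCTCACGGATCGTTGAGACC",
                            names = NULL) {
  if (is.null(names))
    names <- sprintf("AMP%02d", seq_len(n_amplicons))
  stopifnot(length(names) == n_amplicons)
  enrichment_width <- rep_len(enrichment_width, n_amplicons)
  enrichment_fold <- rep_len(enrichment_fold, n_amplicons)
  max_dist <- floor(0.25 * nchar(junction_adapter)) + 2
  amps <- vector("list", n_amplicons)
  for (i in seq_len(n_amplicons)) {
    for (try in 1:200) {
      seq <- paste(sample(c("A", "C", "G", "T"), amplicon_length, replace = TRUE),
                   collapse = "")
      hits <- cpp_find_junctions(seq, junction_adapter,
                                 min(0.49, max_dist / nchar(junction_adapter)))
      if (nrow(hits) == 0) break
      if (try == 200) stop("could not generate adapter-free amplicon sequence")
    }
    ew <- enrichment_width[i]
    es <- primer_length + floor((amplicon_length - 2 * primer_length - ew) / 2)
    amps[[i]] <- amplicon(
      name = names[i], sequence = seq,
      fwd_primer = c(0L, primer_length),
      rev_primer = c(amplicon_length - primer_length, amplicon_length),
      enrichment_region = c(es, es + ew))
  }
  amplicon_panel(do.call(rbind, amps),
                 enrichment_fold = setNames(enrichment_fold, names),
                 junction_adapter = junction_adapter)
}

#' A melanoma-like 15-amplicon demonstration panel
#'
#' Fifteen synthetic amplicons named after recurrently mutated melanoma
#' gene/codon combinations. Enrichment-region widths are chosen so the panel
#' assesses 384 loci in total (nine regions of 26 nt and six of 25 nt), the
#' assessed-locus count of a 15-plex melanoma panel.
#'
#' @param enrichment_fold per-amplicon enrichment fold (default 1000).
#' @param seed integer seed controlling the random amplicon sequences.
#' @return an [amplicon_panel()] with 384 enrichment-region positions.
#' @export
melanoma_like_panel <- function(enrichment_fold = 1000, seed = 104) {
  nm <- c("AKT1-17", "AKT3-17", "BRAF-600", "KRAS-12", "KRAS-61",
          "MAP2K1-57", "MAP2K1-124", "MAP2K2-207", "NRAS-12", "NRAS-61",
          "PIK3CA-542", "PIK3CA-545", "PIK3CA-1047", "CDKN2A-80", "TERT-124")
  widths <- c(rep(26L, 9), rep(25L, 6))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  synthetic_panel(n_amplicons = 15, amplicon_length = 160, primer_length = 20,
                  enrichment_width = widths, enrichment_fold = enrichment_fold,
                  names = nm)
}

# save/restore the RNG state so fixed-seed constructors do not disturb the
# caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
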