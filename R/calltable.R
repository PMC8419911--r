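# Call table container and writers (TSV and minimal VCF-like output).

#' Construct a call table
#'
#' One row per assessed locus per sample. Positions are 0-based in amplicon
#' space; [write_calls()] emits 1-based positions in VCF-like output.
#'
#' @param df data.frame with columns `sample`, `amplicon`, `position`,
#'   `ref_base`, `variant` (`"ref>alt"`, `"ins"` or `"del"`), `vrf`,
#'   `coverage`, `score`, `called`, and optionally gate flags
#'   (`gate_vrf`, `gate_score`, `gate_coverage`, `gate_region`,
#'   `gate_blacklist`), `indel_caveat`, `estimated_vaf`, `saturated`,
#'   `classification`.
#' @return a `call_table` data.frame.
#' @export
call_table <- function(df) {
  required <- c("sample", "amplicon", "position", "ref_base", "variant",
                "vrf", "coverage", "score", "called")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("call table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    ok <- is.na(df$vrf) | (df$vrf >= 0 & df$vrf <= 1)
    if (!all(ok)) stop("VRF outside [0, 1]")
    if (any(df$coverage < 0, na.rm = TRUE)) stop("negative coverage")
  }
  fill <- list(estimated_vaf = NA_real_, saturated = NA,
               classification = NA_character_)
  for (col in names(fill))
    if (is.null(df[[col]])) df[[col]] <- rep(fill[[col]], nrow(df))
  class(df) <- c("call_table", "data.frame")
  df
}

#' @rdname call_table
#' @export
empty_call_table <- function() {
  call_table(data.frame(sample = character(), amplicon = character(),
                        position = integer(), ref_base = character(),
                        variant = character(), vrf = numeric(),
                        coverage = integer(), score = numeric(),
                        called = logical(), stringsAsFactors = FALSE))
}

#' Write a call table
#'
#' TSV output keeps all columns with documented names and 0-based positions.
#' VCF-like output is 1-based with explicit ref/alt alleles: substitutions are
#' written as `REF=ref, ALT=alt`; deletions anchor on the previous reference
#' base (`REF` spans anchor + deleted base, `ALT` is the anchor); insertions
#' anchor on the variant position with the (unknown, event-level) inserted
#' sequence written as `N` appended to the anchor base.
#'
#' @param calls a [call_table()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param panel the [amplicon_panel()] (required for `"vcf"` to recover anchor
#'   bases).
#' @param called_only for `"vcf"`, write only rows with `called == TRUE`
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("tsv", "vcf"), panel = NULL,
                        called_only = TRUE) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(panel)) stop("VCF-like output requires the panel")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=concatseq",
               paste0("##INFO=<ID=VRF,Number=1,Type=Float,Description=",
                      "\"Variant read fraction\">"),
               paste0("##INFO=<ID=DP,Number=1,Type=Integer,Description=",
                      "\"Coverage after downsampling\">"),
               paste0("##INFO=<ID=EVAF,Number=1,Type=Float,Description=",
                      "\"Estimated original sample VAF\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  rows <- if (called_only && nrow(calls)) calls[which(calls$called), , drop = FALSE]
          else calls
  if (nrow(rows)) {
    seqs <- setNames(panel$amplicons$sequence, panel$amplicons$name)
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      seq <- seqs[[r$amplicon]]
      pos0 <- r$position
      if (grepl(">", r$variant)) {
        pos1 <- pos0 + 1L
        ref <- sub(">.*$", "", r$variant)
        alt <- sub("^.*>", "", r$variant)
      } else if (r$variant == "del") {
        # anchor on the previous base; ref spans the deleted base
        anchor0 <- max(0L, pos0 - 1L)
        pos1 <- anchor0 + 1L
        ref <- substr(seq, anchor0 + 1L, pos0 + 1L)
        alt <- substr(seq, anchor0 + 1L, anchor0 + 1L)
      } else {  # insertion after pos0; inserted bases unknown at event level
        pos1 <- pos0 + 1L
        ref <- substr(seq, pos0 + 1L, pos0 + 1L)
        alt <- paste0(ref, "N")
      }
      info <- sprintf("VRF=%.6g;DP=%d", r$vrf, as.integer(r$coverage))
      if (!is.na(r$estimated_vaf))
        info <- paste0(info, sprintf(";EVAF=%.6g", r$estimated_vaf))
      writeLines(paste(r$amplicon, pos1, ".", ref, alt,
                       ifelse(is.na(r$score), ".", format(round(r$score, 2))),
                       ifelse(isTRUE(r$called), "PASS", "gate_fail"),
                       info, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a call table written by [write_calls()] (TSV format)
#'
#' @param path TSV path.
#' @return a [call_table()].
#' @export
read_calls <- function(path) {
  call_table(read.delim(path, stringsAsFactors = FALSE))
}
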