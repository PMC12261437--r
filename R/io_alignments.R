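# Reading name-collated transcriptome alignments (SAM/BAM) and writing
# quantification tables.

# SAM flag bits used below
.FLAG_UNMAPPED <- 4L
.FLAG_REVERSE <- 16L

#' Ensure a BAM representation of an alignment file
#'
#' Text SAM input is converted to a temporary BAM (record order preserved) so
#' that all downstream access goes through Rsamtools.
#' @noRd
.as_bam <- function(path) {
  stopifnot(length(path) == 1L, is.character(path))
  if (!file.exists(path)) {
    rlang::abort(paste0("alignment file not found: ", path))
  }
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(path)
  }
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

#' Read the transcript catalog from an alignment file header
#'
#' Transcript names and lengths are taken from the `@SQ` records of the SAM/BAM
#' header. The row order of the returned tibble fixes the transcript index used
#' throughout an analysis.
#'
#' @param path Path to a SAM or BAM file aligned to a transcriptome.
#' @return A tibble with columns `tname` (character) and `length` (integer,
#'   nucleotides), one row per reference sequence in header order.
#' @examples
#' sim <- simulate_reads(out_dir = tempfile(), n_transcripts = 3,
#'                       n_reads = 50, seed = 1)
#' read_transcript_catalog(sim$sam)
#' @export
read_transcript_catalog <- function(path) {
  # htslib silently drops duplicate @SQ entries on SAM->BAM conversion, so
  # duplicates must be caught on the text header itself
  if (!grepl("\\.bam$", path, ignore.case = TRUE) && file.exists(path)) {
    con <- file(path, "r")
    on.exit(close(con))
    sq <- character()
    repeat {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L || !startsWith(line, "@")) break
      if (startsWith(line, "@SQ")) sq <- c(sq, line)
    }
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    if (anyDuplicated(sn)) {
      rlang::abort("duplicated reference sequence names in alignment header")
    }
  }
  bam <- .as_bam(path)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(targets) || length(targets) == 0L) {
    rlang::abort("alignment header declares no reference sequences")
  }
  nms <- names(targets)
  if (anyDuplicated(nms)) {
    rlang::abort("duplicated reference sequence names in alignment header")
  }
  if (any(targets < 1L)) {
    rlang::abort("reference sequence lengths must be >= 1")
  }
  tibble::tibble(tname = nms, length = as.integer(unname(targets)))
}

#' Read name-collated alignment records into a read-grouped tibble
#'
#' Reads all mapped alignment records, drops unmapped records and (by default)
#' reverse-strand alignments, collapses duplicate (read, transcript) pairs to
#' the best-scoring record, and returns one row per retained alignment with
#' reads contiguous in file order. Every mapped record must carry an `AS` tag;
#' the file must be name-collated (all records of a read adjacent).
#'
#' @param path Path to a name-collated SAM or BAM file.
#' @param catalog Optional transcript catalog (as from
#'   [read_transcript_catalog()]); when supplied it must match the file header.
#' @param keep_reverse Keep reverse-strand alignments? Default `FALSE`:
#'   transcriptome references are sense-stranded, so reverse hits are
#'   artifacts under most protocols.
#' @param min_score_fraction Optional per-read score filter: alignments with
#'   `score < min_score_fraction * max(score)` are dropped (applied only when
#'   the read's best score is positive). Default `NULL` (off).
#' @return A tibble with columns `read_id`, `tname`, `tx` (1-based transcript
#'   index), `score` (AS tag), `start`, `end` (0-based half-open transcript
#'   coordinates), `is_reverse`. Attributes: `catalog` and `dropped`, a named
#'   list of counts of discarded records/reads.
#' @export
read_alignments <- function(path, catalog = NULL, keep_reverse = FALSE,
                            min_score_fraction = NULL) {
  bam <- .as_bam(path)
  if (is.null(catalog)) {
    catalog <- read_transcript_catalog(bam)
  } else {
    hdr <- read_transcript_catalog(bam)
    if (!identical(hdr$tname, catalog$tname) ||
        !identical(hdr$length, catalog$length)) {
      rlang::abort("supplied catalog does not match the alignment header")
    }
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "AS"
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  qname <- rec$qname
  if (length(qname) == 0L) {
    rlang::abort("alignment file contains no records")
  }

  # name collation: a read's records must be contiguous in the file
  runs <- rle(qname)
  if (anyDuplicated(runs$values)) {
    bad <- runs$values[duplicated(runs$values)][1]
    rlang::abort(paste0(
      "alignment file is not name-collated: read '", bad,
      "' reappears after records of another read"
    ))
  }

  flag <- rec$flag
  unmapped <- bitwAnd(flag, .FLAG_UNMAPPED) > 0L
  as_tag <- rec$tag$AS
  if (is.null(as_tag)) as_tag <- rep(NA_integer_, length(qname))
  if (any(is.na(as_tag[!unmapped]))) {
    rlang::abort("mapped record without an AS tag; AS is required")
  }
  reverse <- bitwAnd(flag, .FLAG_REVERSE) > 0L
  keep <- !unmapped & (keep_reverse | !reverse)

  n_unmapped <- sum(unmapped)
  n_reverse <- sum(!unmapped & reverse & !keep_reverse)

  aln <- tibble::tibble(
    row = seq_along(qname)[keep],
    read_id = qname[keep],
    tname = as.character(rec$rname[keep]),
    score = as.integer(as_tag[keep]),
    start = rec$pos[keep] - 1L,
    is_reverse = reverse[keep]
  )
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  aln$end <- aln$start + width
  aln$tx <- match(aln$tname, catalog$tname)
  if (anyNA(aln$tx)) {
    rlang::abort("alignment references a sequence absent from the catalog")
  }
  len <- catalog$length[aln$tx]
  if (any(aln$start < 0L | aln$start >= aln$end | aln$end > len)) {
    rlang::abort("alignment span outside [0, transcript length)")
  }

  # duplicate (read, transcript) hits: keep the best score (first on ties)
  n_before <- nrow(aln)
  aln <- aln |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE,
                     by = c("read_id", "tx")) |>
    dplyr::arrange(.data$row)
  n_dup <- n_before - nrow(aln)

  n_score_filtered <- 0L
  if (!is.null(min_score_fraction)) {
    stopifnot(is.numeric(min_score_fraction), min_score_fraction >= 0)
    n_before <- nrow(aln)
    aln <- aln |>
      dplyr::filter(
        max(.data$score) <= 0 |
          .data$score >= min_score_fraction * max(.data$score),
        .by = "read_id"
      )
    n_score_filtered <- n_before - nrow(aln)
  }

  aln <- dplyr::select(aln, "read_id", "tname", "tx", "score",
                       "start", "end", "is_reverse")
  dropped <- list(
    unmapped = n_unmapped,
    reverse_strand = n_reverse,
    duplicate_target = n_dup,
    score_filtered = n_score_filtered
  )
  if (sum(unlist(dropped)) > 0) {
    rlang::inform(paste0(
      "read_alignments: dropped ", n_unmapped, " unmapped, ", n_reverse,
      " reverse-strand, ", n_dup, " duplicate-target, ", n_score_filtered,
      " score-filtered record(s)"
    ))
  }
  attr(aln, "catalog") <- catalog
  attr(aln, "dropped") <- dropped
  aln
}

#' Write a quantification table
#'
#' Writes the per-transcript estimates as a TSV with columns
#' `tname`, `len`, `num_reads`, `frac`, in catalog order. `num_reads` is the
#' expected read count `frac * n_assigned`; `frac` is the relative abundance
#' itself (no length normalisation is applied anywhere in the model).
#'
#' @param fit An `em_fit` object from [em_quantify()] or [quantify()].
#' @param catalog The transcript catalog the fit was computed against.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_quantification <- function(fit, catalog, path) {
  stopifnot(inherits(fit, "em_fit"))
  if (length(fit$theta) != nrow(catalog)) {
    rlang::abort("estimate does not cover the catalog (transcript count mismatch)")
  }
  out <- tibble::tibble(
    tname = catalog$tname,
    len = catalog$length,
    num_reads = fit$theta * fit$n_assigned,
    frac = fit$theta
  )
  readr::write_tsv(out, path)
  invisible(path)
}
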