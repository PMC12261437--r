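# One-call quantification pipeline: alignments -> profiles -> conditionals ->
# EM -> output files.

#' Quantify transcript abundances from a long-read alignment file
#'
#' Runs the full pipeline: read the catalog and name-collated alignments,
#' build coverage profiles (for `model = "cov"`), compute conditional
#' assignment probabilities, and maximise the likelihood by EM. Optionally
#' writes the quantification TSV and a JSON run report.
#'
#' @param alignments Path to a name-collated SAM/BAM file of reads aligned to
#'   a transcriptome (AS tags required).
#' @param output Optional output TSV path; when given, the abundance table is
#'   written there and a run report to `<output>.report.json`.
#' @param model `"cov"` (default) to include the coverage start-end model,
#'   `"nocov"` for the alignment-score model alone.
#' @param bin_width Coverage segment width in nucleotides (default 100).
#' @param growth_rate Logistic growth rate of the coverage model (default 2).
#' @param score_scale Exponential decay scale of the score model (default 10).
#' @param keep_reverse Keep reverse-strand alignments (default FALSE).
#' @param min_score_fraction Optional per-read score-fraction filter
#'   (default off).
#' @param max_iters,tol EM iteration cap and convergence threshold on expected
#'   counts.
#' @return The `em_fit` object, invisibly when `output` is given.
#' @export
quantify <- function(alignments, output = NULL, model = c("cov", "nocov"),
                     bin_width = 100, growth_rate = 2, score_scale = 10,
                     keep_reverse = FALSE, min_score_fraction = NULL,
                     max_iters = 1000, tol = 1e-3) {
  model <- rlang::arg_match(model)
  t0 <- Sys.time()
  bam <- .as_bam(alignments)
  catalog <- read_transcript_catalog(bam)
  aln <- read_alignments(bam, catalog, keep_reverse = keep_reverse,
                         min_score_fraction = min_score_fraction)
  if (nrow(aln) == 0L) {
    rlang::abort("no alignments retained; nothing to quantify")
  }
  prof <- NULL
  if (model == "cov") {
    prof <- coverage_profiles(aln, catalog, bin_width = bin_width,
                              growth_rate = growth_rate)
  }
  cond <- alignment_conditionals(aln, prof, model = model,
                                 score_scale = score_scale)
  fit <- em_quantify(cond, catalog, max_iters = max_iters, tol = tol)
  if (!is.null(output)) {
    write_quantification(fit, catalog, output)
    dropped <- attr(aln, "dropped")
    report <- list(
      model = model,
      n_records_dropped = dropped,
      n_reads_retained = fit$n_assigned,
      n_transcripts = nrow(catalog),
      n_iters = fit$n_iters,
      converged = fit$converged,
      final_loglik = utils::tail(fit$loglik_trace, 1),
      wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(report, paste0(output, ".report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }
  fit
}
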