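## Per-read editing-outcome classification for the short genotyping amplicon.
##
## Category logic (applied to retained, window-covering reads):
## the informative signal is the set of *silent* template SNVs (blocking +
## bridging) — the correction base alone cannot distinguish a corrected
## target allele from the unedited non-target allele, which carries the same
## base at the variant position; that is precisely why the silent SNVs make
## perfect HDR countable. Per planned SNV the aligned read base is called
## template_base / ref_base / other (a third base) / deleted / uncovered;
## `other`, `deleted` and `uncovered` are uninformative. Window indels
## shorter than `min_indel_len` are attributed to sequencing error.
##
##  1. window indel present and no silent SNV at the template base -> indel
##  2. >=1 informative silent SNV, every informative planned SNV (incl. the
##     correction) at the template base, no window indel -> perfect_hdr
##  3. >=1 silent SNV at the template base otherwise -> imperfect_hdr
##  4. no silent template SNV, window indel -> indel; otherwise -> unedited
##
## Reads are discarded (with a reason) when rejected by the full-length
## filter, when the window is not covered, or when the correction position
## is outside the aligned span.

SNV_STATUS_LEVELS <- c("template_base", "ref_base", "other", "deleted",
                       "uncovered")

#' Quantification window spanning both nick sites
#'
#' @param pair A [guide_pair()].
#' @param flank Flank (bp) added beyond each nick (default 10).
#' @return `(start, end)` locus interval.
#' @export
quant_window <- function(pair, flank = 10L) {
  stopifnot(inherits(pair, "guide_pair"))
  c(pair$left$nick_position - flank, pair$right$nick_position + flank)
}

## indels overlapping the window (boundary-overlapping events count; an
## insertion anchored at window_start - 1 abuts the window and counts)
window_indels <- function(aln, window, min_indel_len = 3L) {
  ops <- aln$ops
  if (is.null(ops)) return(ops)
  sel <- ops$op %in% c("insertion", "deletion") & ops$len >= min_indel_len
  if (!any(sel)) return(ops[0L, ])
  ops <- ops[sel, , drop = FALSE]
  lo <- ops$ref_start
  hi <- ifelse(ops$op == "deletion", ops$ref_start + ops$len - 1L,
               ops$ref_start + 1L)
  ops[hi >= window[1L] & lo <= window[2L], , drop = FALSE]
}

#' Classify one aligned read
#'
#' @param aln A `read_alignment` (from [align_reads()] or
#'   [align_reads_minimap2()]).
#' @param template A `repair_template`.
#' @param window Quantification window from [quant_window()].
#' @param locus The [reference_locus()] the read was aligned to (supplies
#'   the reference and template haplotypes for the SNV vote).
#' @param min_indel_len Minimum indel length (bp) treated as a real editing
#'   event rather than sequencing error.
#' @param tpl_seq Precomputed template-applied locus sequence (internal
#'   fast path; computed from `template` when `NULL`).
#' @return A one-row data.frame (class `read_call`): read_id, category,
#'   reason, identity, n_window_indels, plus attribute `"snv_status"` (named
#'   character vector over the template SNVs).
#' @export
classify_read <- function(aln, template, window, locus,
                          min_indel_len = 3L, tpl_seq = NULL) {
  snvs <- template$snvs
  if (is.null(tpl_seq)) tpl_seq <- apply_snvs(locus$sequence, snvs)
  status <- rep("uncovered", nrow(snvs))
  n_ind <- 0L
  if (!aln$retained) {
    category <- "discarded"
    reason <- aln$reason
  } else if (is.na(aln$ref_span[1L]) || aln$ref_span[1L] > window[1L] ||
             aln$ref_span[2L] < window[2L]) {
    category <- "discarded"
    reason <- "window_uncovered"
  } else {
    status <- call_snv_status(aln, snvs, locus$sequence, tpl_seq)
    is_corr <- snvs$role == "correction"
    if (any(status[is_corr] == "uncovered")) {
      category <- "discarded"
      reason <- "correction_uncovered"
    } else {
      reason <- NA_character_
      wi <- window_indels(aln, window, min_indel_len)
      n_ind <- nrow(wi)
      has_indel <- n_ind > 0L
      silent <- !is_corr
      n_tpl_silent <- sum(status[silent] == "template_base")
      informative <- status %in% c("template_base", "ref_base")
      all_tpl <- sum(informative) > 0L &&
        all(status[informative] == "template_base")
      category <- if (has_indel && n_tpl_silent == 0L) "indel"
      else if (n_tpl_silent >= 1L && all_tpl &&
               sum(informative & silent) >= 1L && !has_indel) "perfect_hdr"
      else if (n_tpl_silent >= 1L) "imperfect_hdr"
      else if (has_indel) "indel"
      else "unedited"
    }
  }
  out <- data.frame(read_id = aln$read_id, category = category,
                    reason = reason, identity = aln$identity,
                    n_window_indels = n_ind, stringsAsFactors = FALSE)
  attr(out, "snv_status") <- setNames(status, as.character(snvs$position))
  class(out) <- c("read_call", class(out))
  out
}

#' Classify a set of aligned reads
#'
#' @param alns List of `read_alignment` objects.
#' @inheritParams classify_read
#' @return data.frame of per-read calls with attribute `"snv_status"` (a
#'   reads x SNVs character matrix) and `"template"`.
#' @export
classify_reads <- function(alns, template, window, locus,
                           min_indel_len = 3L) {
  tpl_seq <- apply_snvs(locus$sequence, template$snvs)
  calls <- lapply(alns, classify_read, template = template, window = window,
                  locus = locus, min_indel_len = min_indel_len,
                  tpl_seq = tpl_seq)
  out <- do.call(rbind, lapply(calls, function(x) {
    class(x) <- "data.frame"
    x
  }))
  rownames(out) <- NULL
  status <- do.call(rbind, lapply(calls, attr, "snv_status"))
  rownames(status) <- out$read_id
  attr(out, "snv_status") <- status
  attr(out, "template") <- template
  out
}

#' Aggregate read calls into outcome frequencies
#'
#' Fractions are computed over retained (non-discarded) reads; a
#' low-coverage flag is raised when fewer than `min_reads` (default 10,000,
#' the conventional minimum analysed-read depth) are retained. Wilson 95%
#' CIs accompany every fraction. `total_editing` is the combined
#' perfect + imperfect + indel fraction.
#'
#' @param calls Output of [classify_reads()].
#' @param min_reads Minimum retained reads before the summary is considered
#'   adequately powered.
#' @return Object of class `outcome_summary`.
#' @export
summarize_outcomes <- function(calls, min_reads = 10000L) {
  if (is.null(calls) || nrow(calls) == 0L) {
    stop("empty call list", call. = FALSE)
  }
  cats <- c("perfect_hdr", "imperfect_hdr", "indel", "unedited")
  retained <- calls[calls$category != "discarded", , drop = FALSE]
  n_ret <- nrow(retained)
  counts <- setNames(vapply(cats, function(ct) sum(retained$category == ct),
                            integer(1)), cats)
  fr <- if (n_ret > 0) counts / n_ret else setNames(rep(NA_real_, 4L), cats)
  cis <- t(vapply(counts, wilson_ci, numeric(2), n = n_ret))
  snv_inc <- snv_incorporation(calls)
  structure(
    list(n_total = nrow(calls), n_retained = n_ret,
         counts = counts, fractions = fr,
         total_editing = unname(fr[["perfect_hdr"]] + fr[["imperfect_hdr"]] +
                                  fr[["indel"]]),
         ci = cis,
         snv_incorporation = snv_inc,
         low_coverage = n_ret < min_reads,
         min_reads = as.integer(min_reads)),
    class = "outcome_summary"
  )
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Editing outcomes over %d retained / %d total reads%s\n",
              x$n_retained, x$n_total,
              if (x$low_coverage) sprintf(" [LOW COVERAGE < %d]", x$min_reads)
              else ""))
  for (ct in names(x$fractions)) {
    cat(sprintf("  %-14s %6.2f%%  (95%% CI %.2f-%.2f%%)\n", ct,
                100 * x$fractions[[ct]], 100 * x$ci[ct, 1L],
                100 * x$ci[ct, 2L]))
  }
  cat(sprintf("  %-14s %6.2f%%\n", "total_editing", 100 * x$total_editing))
  invisible(x)
}

#' Per-SNV incorporation fractions
#'
#' For each planned template SNV: the fraction of informative covering
#' retained reads carrying the template base. Reads whose status at the SNV
#' is `other`, `deleted` or `uncovered` are excluded from the denominator;
#' an SNV covered by zero informative reads reports `NA`, not 0.
#'
#' @param calls Output of [classify_reads()].
#' @return data.frame: position, role, n_informative, incorporation,
#'   ci_lower, ci_upper.
#' @export
snv_incorporation <- function(calls) {
  status <- attr(calls, "snv_status")
  template <- attr(calls, "template")
  keep <- calls$category != "discarded"
  status <- status[keep, , drop = FALSE]
  res <- lapply(seq_len(ncol(status)), function(j) {
    s <- status[, j]
    m <- sum(s %in% c("template_base", "ref_base"))
    k <- sum(s == "template_base")
    ci <- wilson_ci(k, m)
    data.frame(n_informative = m,
               incorporation = if (m > 0) k / m else NA_real_,
               ci_lower = ci[1L], ci_upper = ci[2L])
  })
  cbind(template$snvs[, c("position", "role", "guide_id")],
        do.call(rbind, res))
}

#' One-call pipeline: align, classify and summarise short-amplicon reads
#'
#' @param reads Named character vector of reads (or a FASTQ path).
#' @param locus A [reference_locus()] with guides attached.
#' @param template A `repair_template`.
#' @param window Quantification window (default [quant_window()] of the
#'   locus guide pair).
#' @param min_identity,min_span Full-length-filter thresholds.
#' @param min_indel_len Error-tolerance threshold for window indels.
#' @param min_reads Low-coverage threshold for the summary.
#' @return List with `alignments`, `calls` and `summary`.
#' @export
classify_amplicon <- function(reads, locus, template,
                              window = quant_window(locus$guides),
                              min_identity = 0.8, min_span = 0.9,
                              min_indel_len = 3L, min_reads = 10000L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  alns <- align_reads(reads, locus, amplicon = locus$short_amplicon,
                      min_identity = min_identity, min_span = min_span)
  calls <- classify_reads(alns, template, window, locus,
                          min_indel_len = min_indel_len)
  list(alignments = alns, calls = calls,
       summary = summarize_outcomes(calls, min_reads = min_reads))
}
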