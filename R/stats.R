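## Comparative statistics: per-site off-target control-vs-edited comparison
## (Fisher exact, Bonferroni across sites) and the independent two-sample
## t-test used for group contrasts. Base R supplies the tests themselves
## (fisher.test, t.test, p.adjust); this module owns the off-target event
## definition and the reporting contract.

#' Count reads with an edit call at an (off-target) site
#'
#' An "edited call" is any insertion or deletion of at least `min_indel_len`
#' overlapping a window of `flank` bp around the predicted nick/cut
#' position. Template SNVs do not apply off-target, so substitutions are
#' never counted.
#'
#' @param alns List of `read_alignment` objects for the site amplicon.
#' @param cut_position Predicted nick/cut locus coordinate.
#' @param flank Half-window in bp (default 10).
#' @param min_indel_len Minimum indel length counted (default 3, matching
#'   the on-target classifier's error tolerance).
#' @return List with `n_retained` and `n_edited`.
#' @export
count_window_edits <- function(alns, cut_position, flank = 10L,
                               min_indel_len = 3L) {
  window <- c(cut_position - flank, cut_position + flank)
  retained <- Filter(function(a) a$retained, alns)
  n_edited <- sum(vapply(retained, function(a) {
    nrow(window_indels(a, window, min_indel_len)) > 0L
  }, logical(1)))
  list(n_retained = length(retained), n_edited = n_edited)
}

#' Compare off-target sites between control and edited samples
#'
#' Per site, a two-sided Fisher exact test on the 2x2 table
#' (edited-call vs clean) x (control vs edited condition), Bonferroni
#' corrected over the number of sites. A site is called `editing_detected`
#' only when the corrected p-value falls below `alpha` AND the edited
#' condition's event rate exceeds the control's.
#'
#' @param sites data.frame with columns `site_id`, `n_control`,
#'   `edited_control` (edit-call reads in the control), `n_edited`,
#'   `edited_edited` (edit-call reads in the edited sample). One row per
#'   site; each site must be present in both conditions (non-missing
#'   counts).
#' @param alpha Significance level (default 0.05).
#' @param min_reads Minimum retained reads required per condition
#'   (default 10,000); shallower sites are flagged, not dropped.
#' @return data.frame of class `site_comparison`: the input columns plus
#'   `raw_p`, `corrected_p`, `verdict` and `low_coverage`.
#' @export
compare_off_targets <- function(sites, alpha = 0.05, min_reads = 10000L) {
  need <- c("site_id", "n_control", "edited_control", "n_edited",
            "edited_edited")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    stop("sites is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id", call. = FALSE)
  }
  counts <- sites[, c("n_control", "edited_control", "n_edited",
                      "edited_edited")]
  if (any(is.na(as.matrix(counts)))) {
    stop("every site needs counts for both conditions", call. = FALSE)
  }
  if (any(sites$edited_control > sites$n_control) ||
      any(sites$edited_edited > sites$n_edited)) {
    stop("edit-call counts cannot exceed read counts", call. = FALSE)
  }
  raw_p <- vapply(seq_len(nrow(sites)), function(i) {
    tab <- matrix(c(sites$edited_control[i],
                    sites$n_control[i] - sites$edited_control[i],
                    sites$edited_edited[i],
                    sites$n_edited[i] - sites$edited_edited[i]),
                  nrow = 2L)
    fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  corrected_p <- p.adjust(raw_p, method = "bonferroni")
  rate_c <- sites$edited_control / sites$n_control
  rate_e <- sites$edited_edited / sites$n_edited
  out <- cbind(
    sites,
    data.frame(raw_p = raw_p, corrected_p = corrected_p,
               verdict = ifelse(corrected_p < alpha & rate_e > rate_c,
                                "editing_detected", "no_editing_detected"),
               low_coverage = sites$n_control < min_reads |
                 sites$n_edited < min_reads,
               stringsAsFactors = FALSE))
  class(out) <- c("site_comparison", "data.frame")
  out
}

#' Independent two-sample t-test
#'
#' Standard two-sided independent-samples t statistic (pooled variance, or
#' Welch when `equal_var = FALSE`). The degenerate case of zero variance in
#' both groups with equal means returns `t = 0, p = 1` by convention.
#'
#' @param x,y Numeric vectors of replicate values (each length >= 2).
#' @param equal_var Assume equal variances (pooled df)? Default TRUE.
#' @return List with `t`, `df` and `p`.
#' @export
two_sample_t <- function(x, y, equal_var = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    df <- if (equal_var) length(x) + length(y) - 2L else NA_real_
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    return(list(t = if (mean(x) > mean(y)) Inf else -Inf, df = df, p = 0))
  }
  fit <- t.test(x, y, var.equal = equal_var, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}
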