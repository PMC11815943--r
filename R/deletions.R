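## Large on-target deletion profiling from long-amplicon alignments:
## unique deletion alleles (clustered breakpoints), size-class proportions
## and the fraction of reads whose deletion removes a short-amplicon primer
## site and therefore evades standard genotyping.

## per-read deletions >= min size; a read's *assigned* deletion (for
## read-exclusive binning) is its largest
read_deletions <- function(alns, min_deletion_size) {
  rows <- lapply(alns, function(a) {
    if (!a$retained || is.null(a$ops)) return(NULL)
    d <- a$ops[a$ops$op == "deletion" & a$ops$len >= min_deletion_size, ,
               drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(read_id = a$read_id, del_start = d$ref_start,
               del_end = d$ref_start + d$len - 1L, size = d$len,
               assigned = seq_len(nrow(d)) == which.max(d$len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = character(), del_start = integer(),
                      del_end = integer(), size = integer(),
                      assigned = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Extract unique deletion alleles from long-amplicon alignments
#'
#' Per-read deletions of at least `min_deletion_size` are clustered: events
#' whose start and end each lie within `breakpoint_tol` of a cluster's
#' current breakpoints join it; cluster breakpoints are support-weighted
#' medians, recomputed after assignment (the procedure is idempotent for
#' well-separated alleles). Clusters below `min_support` reads are dropped.
#'
#' @param alns List of `read_alignment` objects from the long amplicon
#'   (full-length filtered; rejected reads are ignored).
#' @param min_deletion_size Smallest deletion (bp) treated as a large
#'   deletion rather than a nick-site indel (default 50).
#' @param breakpoint_tol Breakpoint clustering tolerance in bp (default 20).
#' @param min_support Minimum supporting reads per allele (default 3).
#' @return data.frame of class `deletion_alleles`: del_start, del_end, size,
#'   support, frequency (support / retained reads), sorted by frequency
#'   descending. Attribute `"n_retained"` carries the retained read count;
#'   attribute `"events"` the per-read event table with cluster assignment.
#' @export
extract_deletion_alleles <- function(alns, min_deletion_size = 50L,
                                     breakpoint_tol = 20L, min_support = 3L) {
  n_retained <- sum(vapply(alns, `[[`, logical(1), "retained"))
  ev <- read_deletions(alns, min_deletion_size)
  ev$cluster <- rep(NA_integer_, nrow(ev))
  clusters <- list()
  if (nrow(ev)) {
    ord <- order(ev$del_start, ev$del_end)
    for (i in ord) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (abs(ev$del_start[i] - cl$start) <= breakpoint_tol &&
            abs(ev$del_end[i] - cl$end) <= breakpoint_tol) {
          clusters[[ci]]$members <- c(cl$members, i)
          ev$cluster[i] <- ci
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        clusters[[length(clusters) + 1L]] <-
          list(start = ev$del_start[i], end = ev$del_end[i], members = i)
        ev$cluster[i] <- length(clusters)
      }
    }
    ## recompute breakpoints as support-weighted medians
    for (ci in seq_along(clusters)) {
      m <- clusters[[ci]]$members
      clusters[[ci]]$start <- weighted_median(ev$del_start[m], rep(1, length(m)))
      clusters[[ci]]$end <- weighted_median(ev$del_end[m], rep(1, length(m)))
    }
  }
  alleles <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(del_start = cl$start, del_end = cl$end,
               size = cl$end - cl$start + 1L,
               support = length(unique(ev$read_id[cl$members])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(alleles)) {
    alleles <- data.frame(del_start = integer(), del_end = integer(),
                          size = integer(), support = integer())
  }
  alleles$frequency <- if (n_retained > 0) alleles$support / n_retained
  else numeric(nrow(alleles))
  keep <- alleles$support >= min_support
  drop_clusters <- which(!keep)
  ev$cluster[ev$cluster %in% drop_clusters] <- NA_integer_
  alleles <- alleles[keep, , drop = FALSE]
  ord <- order(-alleles$frequency, alleles$del_start)
  alleles <- alleles[ord, , drop = FALSE]
  rownames(alleles) <- NULL
  structure(alleles, n_retained = n_retained, events = ev,
            class = c("deletion_alleles", "data.frame"))
}

#' Read-weighted deletion-size distribution
#'
#' Each deletion-carrying read contributes once, through its largest
#' deletion, so bin proportions sum to 1. The final bin is open-ended.
#'
#' @param alleles Output of [extract_deletion_alleles()].
#' @param bin_edges Strictly increasing bp edges; the default
#'   `c(50, 500, 1000, 2000, 5000)` yields the 1-2 kb and >5 kb classes.
#' @return data.frame: lo, hi (`Inf` for the last bin), n_reads, proportion
#'   (of deletion-carrying reads; all-NA proportions when there are none).
#' @export
bin_deletions <- function(alleles, bin_edges = c(50L, 500L, 1000L, 2000L, 5000L)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  ev <- attr(alleles, "events")
  ev <- ev[ev$assigned & !is.na(ev$cluster), , drop = FALSE]
  lo <- bin_edges
  hi <- c(bin_edges[-1L] - 1L, Inf)
  n <- vapply(seq_along(lo), function(i) {
    sum(ev$size >= lo[i] & ev$size <= hi[i])
  }, integer(1))
  total <- sum(n)
  data.frame(lo = lo, hi = hi, n_reads = n,
             proportion = if (total > 0) n / total else rep(NA_real_, length(n)))
}

#' Fraction of reads evading short-amplicon genotyping
#'
#' A deletion evades standard genotyping when it removes (intersects) the
#' short amplicon's forward or reverse primer footprint — the allele then
#' yields no short-amplicon product. Reported as a fraction of all retained
#' long-amplicon reads, with a Wilson CI.
#'
#' @param alleles Output of [extract_deletion_alleles()].
#' @param short_amplicon The short [amplicon_def()].
#' @return List with `fraction`, `ci`, `n_evading`, `n_retained` and the
#'   per-allele `evades` flag.
#' @export
evasion_fraction <- function(alleles, short_amplicon) {
  n_retained <- attr(alleles, "n_retained")
  evades <- logical(nrow(alleles))
  for (i in seq_len(nrow(alleles))) {
    d <- c(alleles$del_start[i], alleles$del_end[i])
    evades[i] <- iv_overlaps(d, short_amplicon$fwd_primer) ||
      iv_overlaps(d, short_amplicon$rev_primer)
  }
  ## count reads (not alleles): use the event table, one count per read
  ## whose assigned deletion belongs to an evading cluster
  ev <- attr(alleles, "events")
  ev <- ev[ev$assigned & !is.na(ev$cluster), , drop = FALSE]
  n_evading <- 0L
  if (nrow(ev)) {
    read_evades <- (ev$del_start <= short_amplicon$fwd_primer[2L] &
                      ev$del_end >= short_amplicon$fwd_primer[1L]) |
      (ev$del_start <= short_amplicon$rev_primer[2L] &
         ev$del_end >= short_amplicon$rev_primer[1L])
    n_evading <- sum(read_evades)
  }
  frac <- if (n_retained > 0) n_evading / n_retained else NA_real_
  list(fraction = frac, ci = wilson_ci(n_evading, n_retained),
       n_evading = n_evading, n_retained = n_retained, evades = evades)
}

#' Full deletion-spectrum profile of long-amplicon reads
#'
#' Aligns long reads with minimap2, applies the full-length filter, extracts
#' clustered deletion alleles, bins sizes and computes the evasion fraction.
#'
#' @param reads Named character vector of long-amplicon reads (or FASTQ path).
#' @param locus A [reference_locus()].
#' @param min_deletion_size,breakpoint_tol,min_support See
#'   [extract_deletion_alleles()].
#' @param bin_edges See [bin_deletions()].
#' @param min_identity,min_span Full-length-filter thresholds.
#' @return Object of class `deletion_spectrum`: list with `alleles`,
#'   `size_bins`, `evasion` and `n_retained`.
#' @export
deletion_spectrum <- function(reads, locus, min_deletion_size = 50L,
                              breakpoint_tol = 20L, min_support = 3L,
                              bin_edges = c(50L, 500L, 1000L, 2000L, 5000L),
                              min_identity = 0.8, min_span = 0.9) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  alns <- align_reads_minimap2(reads, locus,
                               amplicon = locus$long_amplicon,
                               min_identity = min_identity,
                               min_span = min_span)
  alleles <- extract_deletion_alleles(alns, min_deletion_size,
                                      breakpoint_tol, min_support)
  structure(
    list(alleles = alleles,
         size_bins = bin_deletions(alleles, bin_edges),
         evasion = evasion_fraction(alleles, locus$short_amplicon),
         n_retained = attr(alleles, "n_retained")),
    class = "deletion_spectrum"
  )
}

#' @export
print.deletion_spectrum <- function(x, ...) {
  cat(sprintf("Deletion spectrum over %d retained long reads: %d allele(s)\n",
              x$n_retained, nrow(x$alleles)))
  if (nrow(x$alleles)) print(as.data.frame(x$alleles))
  cat(sprintf("Evading short-amplicon genotyping: %.2f%% of reads\n",
              100 * x$evasion$fraction))
  invisible(x)
}
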