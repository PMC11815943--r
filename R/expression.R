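## Transcript-level analysis: target-exon inclusion from cDNA reads,
## template-SNV incorporation restricted to exon-containing transcripts,
## ddPCR-style relative expression with geometric-mean housekeeper
## normalisation, and the monoallelic protein-expectation conversion.

#' Build the two-isoform transcript model
#'
#' The full isoform concatenates every annotated exon; the skipped isoform
#' omits exactly the target exon (the alternatively spliced exon-14
#' analogue).
#'
#' @param locus A [reference_locus()].
#' @param target_exon Index of the target exon in `locus$exons`.
#' @return Object of class `isoform_model` with fields `full`, `skipped`,
#'   `target_exon`, `exon_widths` and `locus`.
#' @export
isoform_model <- function(locus, target_exon = exon_index_of(locus, locus$pathogenic_variant$position)) {
  stopifnot(inherits(locus, "reference_locus"))
  k <- length(locus$exons)
  if (is.na(target_exon) || target_exon < 1L || target_exon > k) {
    stop("target_exon must index an annotated exon", call. = FALSE)
  }
  exon_seq <- function(idx) {
    paste(vapply(locus$exons[idx],
                 function(e) substr(locus$sequence, e[1L], e[2L]),
                 character(1)), collapse = "")
  }
  structure(
    list(full = exon_seq(seq_len(k)),
         skipped = exon_seq(setdiff(seq_len(k), target_exon)),
         target_exon = as.integer(target_exon),
         exon_widths = vapply(locus$exons, iv_width, integer(1)),
         locus = locus),
    class = "isoform_model"
  )
}

#' @export
print.isoform_model <- function(x, ...) {
  cat(sprintf("<isoform_model: %d exons, target exon %d; full %d nt, skipped %d nt>\n",
              length(x$exon_widths), x$target_exon, nchar(x$full),
              nchar(x$skipped)))
  invisible(x)
}

## map template SNVs to coordinates on the full (exon-including) transcript;
## tx_position is NA for SNVs outside annotated exons
transcript_snv_positions <- function(isoforms, template) {
  snvs <- template$snvs
  snvs$tx_position <- vapply(snvs$position, function(p) {
    si <- spliced_index(isoforms$locus, p)
    if (is.na(si)) NA_integer_ else si
  }, integer(1))
  snvs
}

#' Quantify target-exon inclusion from cDNA reads
#'
#' Each read is scored (semi-global DP, both strands) against the full and
#' exon-skipped isoform sequences and assigned to the higher-scoring isoform
#' when the score margin reaches `margin`; otherwise it is discarded as
#' ambiguous. Inclusion = included / (included + skipped), with a Wilson CI.
#'
#' @param reads Named character vector of cDNA reads.
#' @param isoforms An [isoform_model()].
#' @param margin Minimum score margin for an unambiguous assignment.
#' @param chunk_size Reads per vectorised scoring call.
#' @return List with `inclusion`, `ci` (Wilson 95%), `n_included`,
#'   `n_skipped`, `n_ambiguous` and per-read `assignment` data.frame.
#'   `inclusion` is `NA` when no read is assignable.
#' @export
exon_inclusion <- function(reads, isoforms, margin = 10, chunk_size = 1000L) {
  stopifnot(inherits(isoforms, "isoform_model"))
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  mat <- substitution_matrix()
  full <- Biostrings::DNAString(isoforms$full)
  skip <- Biostrings::DNAString(isoforms$skipped)

  fwd <- Biostrings::DNAStringSet(toupper(reads))
  rev <- Biostrings::reverseComplement(fwd)
  score_vs <- function(set, subj) {
    Biostrings::pairwiseAlignment(
      set, subj, type = "global-local", substitutionMatrix = mat,
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT, scoreOnly = TRUE)
  }

  n <- length(reads)
  assign <- character(n)
  strand <- character(n)
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  for (idx in idx_chunks) {
    sf_f <- score_vs(fwd[idx], full)
    sf_r <- score_vs(rev[idx], full)
    use_rev <- sf_r > sf_f
    canon <- fwd[idx]
    canon[use_rev] <- rev[idx][use_rev]
    s_full <- pmax(sf_f, sf_r)
    s_skip <- score_vs(canon, skip)
    d <- s_full - s_skip
    assign[idx] <- ifelse(d >= margin, "included",
                   ifelse(d <= -margin, "skipped", "ambiguous"))
    strand[idx] <- ifelse(use_rev, "-", "+")
  }

  n_inc <- sum(assign == "included")
  n_skp <- sum(assign == "skipped")
  denom <- n_inc + n_skp
  list(
    inclusion = if (denom > 0) n_inc / denom else NA_real_,
    ci = wilson_ci(n_inc, denom),
    n_included = n_inc, n_skipped = n_skp,
    n_ambiguous = sum(assign == "ambiguous"),
    assignment = data.frame(read_id = names(reads), isoform = assign,
                            strand = strand, stringsAsFactors = FALSE)
  )
}

#' Template-SNV incorporation at the transcript level
#'
#' Restricted to exon-including reads (the planned SNVs live in the target
#' exon): each such read is aligned to the full isoform and the base at every
#' template-SNV transcript position is called. Reports the per-SNV
#' template-base fraction among informative covering reads, plus the mean
#' across SNVs (the "average incorporation rate").
#'
#' @param reads Named character vector of cDNA reads.
#' @param template A `repair_template`.
#' @param isoforms An [isoform_model()].
#' @param margin Isoform-assignment margin, as in [exon_inclusion()].
#' @param min_identity,min_span Retention thresholds for the transcript
#'   alignment (span measured over the full isoform).
#' @param inclusion Optional precomputed [exon_inclusion()] result for these
#'   reads (avoids re-scoring).
#' @return List with `per_snv` data.frame (position, tx_position, n_covering,
#'   incorporation, ci_lower, ci_upper) and `mean_incorporation`.
#' @export
transcript_snv_incorporation <- function(reads, template, isoforms,
                                         margin = 10, min_identity = 0.8,
                                         min_span = 0.9, inclusion = NULL) {
  inc <- inclusion %||% exon_inclusion(reads, isoforms, margin = margin)
  stopifnot(identical(inc$assignment$read_id, names(reads)))
  keep <- inc$assignment$isoform == "included"
  if (!any(keep)) stop("no exon-including reads to analyse", call. = FALSE)
  sub <- reads[keep]

  ## align against the full transcript as a standalone reference
  tx_locus <- structure(list(sequence = isoforms$full), class = "reference_locus")
  tx_len <- nchar(isoforms$full)
  tx_amp <- amplicon_def(c(1L, 1L), c(tx_len, tx_len))
  alns <- align_reads(sub, tx_locus, amplicon = tx_amp,
                      min_identity = min_identity, min_span = min_span,
                      margin = 0L)

  snvs <- transcript_snv_positions(isoforms, template)
  tx_snvs <- snvs[!is.na(snvs$tx_position), , drop = FALSE]
  tx_snvs$position <- tx_snvs$tx_position
  tx_ref <- isoforms$full
  tx_tpl <- apply_snvs(tx_ref, tx_snvs)
  retained <- Filter(function(a) a$retained, alns)
  status <- do.call(rbind, lapply(retained, call_snv_status, snvs = tx_snvs,
                                  ref_seq = tx_ref, tpl_seq = tx_tpl))
  res <- lapply(seq_len(nrow(snvs)), function(i) {
    j <- match(snvs$tx_position[i], tx_snvs$tx_position)
    if (is.na(j)) {
      return(data.frame(n_covering = 0L, incorporation = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_))
    }
    s <- status[, j]
    m <- sum(s %in% c("template_base", "ref_base"))
    k <- sum(s == "template_base")
    ci <- wilson_ci(k, m)
    data.frame(n_covering = m,
               incorporation = if (m > 0) k / m else NA_real_,
               ci_lower = ci[1L], ci_upper = ci[2L])
  })
  per_snv <- cbind(snvs[, c("position", "tx_position", "role")],
                   do.call(rbind, res))
  list(per_snv = per_snv,
       mean_incorporation = mean(per_snv$incorporation, na.rm = TRUE))
}

#' ddPCR-style relative expression with two housekeepers
#'
#' Normalises a target concentration by the geometric mean of exactly two
#' housekeeping-gene concentrations: `target / sqrt(hk1 * hk2)`.
#'
#' @param target Target concentration (copies/µl), positive.
#' @param housekeepers Numeric vector of exactly two positive housekeeper
#'   concentrations.
#' @return Normalised expression (numeric scalar).
#' @export
relative_expression <- function(target, housekeepers) {
  if (length(housekeepers) != 2L) {
    stop("exactly two housekeeper concentrations are required", call. = FALSE)
  }
  if (any(c(target, housekeepers) <= 0) || any(is.na(c(target, housekeepers)))) {
    stop("concentrations must be positive", call. = FALSE)
  }
  target / sqrt(housekeepers[1L] * housekeepers[2L])
}

#' Expected allele-level protein re-expression after monoallelic correction
#'
#' A variant present on `n_target_alleles` of `total_alleles` corrected in a
#' fraction `genomic_correction_fraction` of reads is expected to restore
#' expression from `genomic_correction_fraction * n_target_alleles /
#' total_alleles` of all alleles (e.g. 54% correction of a heterozygous
#' variant -> 27% of total alleles).
#'
#' @param genomic_correction_fraction Perfect-correction fraction in \[0, 1\].
#' @param n_target_alleles Number of alleles carrying the variant.
#' @param total_alleles Total allele count (> 0).
#' @return Expected expressing-allele fraction.
#' @export
expected_allelic_expression <- function(genomic_correction_fraction,
                                        n_target_alleles = 1L,
                                        total_alleles = 2L) {
  if (total_alleles <= 0) stop("total_alleles must be positive", call. = FALSE)
  if (n_target_alleles > total_alleles) {
    stop("n_target_alleles cannot exceed total_alleles", call. = FALSE)
  }
  if (genomic_correction_fraction < 0 || genomic_correction_fraction > 1) {
    stop("genomic_correction_fraction must lie in [0, 1]", call. = FALSE)
  }
  genomic_correction_fraction * n_target_alleles / total_alleles
}
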