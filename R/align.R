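## Pairwise semi-global alignment of amplicon reads against the locus.
##
## Two engines produce the same per-read structure:
##  * "dp": exact affine-gap dynamic programming (Biostrings::pairwiseAlignment,
##    type "global-local": the read is aligned end-to-end, end gaps on the
##    reference are free). Used for short (~700 bp) amplicon and cDNA reads.
##  * "minimap2": the minimap2 CLI (map-ont preset) parsed via Rsamtools.
##    Used for long (~10.5 kb) amplicon reads, where quadratic DP is
##    impractical and where minimap2 retains multi-kilobase deletions as
##    single in-alignment D operations.
##
## Scoring (dp engine): match +2, mismatch -4, gap open 4, gap extend 2
## (a gap of length L costs 4 + 2L). N mismatches every base and is never
## counted as SNV evidence. Identity is gap-compressed:
## matches / (matches + mismatches + gap events), the standard long-read
## divergence measure, so a single large deletion does not crater identity.

ALN_MATCH <- 2
ALN_MISMATCH <- -4
ALN_GAP_OPEN <- 4
ALN_GAP_EXT <- 2

substitution_matrix <- function() {
  b <- c(DNA_BASES, "N")
  m <- matrix(ALN_MISMATCH, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- ALN_MATCH
  m
}

## ops data.frame from gapped pattern/subject strings (equal nchar)
ops_from_gapped <- function(p, s, ref_offset = 0L, read_offset = 0L) {
  pv <- strsplit(p, "")[[1L]]
  sv <- strsplit(s, "")[[1L]]
  code <- ifelse(sv == "-", "insertion",
          ifelse(pv == "-", "deletion",
          ifelse(pv == sv & pv != "N", "match", "mismatch")))
  r <- rle(code)
  n <- length(r$lengths)
  ref_consumed <- r$values != "insertion"
  read_consumed <- r$values != "deletion"
  ends_ref <- cumsum(r$lengths * ref_consumed)
  ends_read <- cumsum(r$lengths * read_consumed)
  starts_ref <- ref_offset + c(0L, ends_ref[-n]) +
    ifelse(ref_consumed, 1L, 0L)
  starts_read <- read_offset + c(0L, ends_read[-n]) +
    ifelse(read_consumed, 1L, 0L)
  data.frame(op = r$values, len = r$lengths,
             ref_start = as.integer(starts_ref),
             read_start = as.integer(starts_read),
             stringsAsFactors = FALSE)
}

ops_identity <- function(ops) {
  m <- sum(ops$len[ops$op == "match"])
  x <- sum(ops$len[ops$op == "mismatch"])
  g <- sum(ops$op %in% c("insertion", "deletion"))
  if (m + x + g == 0) return(0)
  m / (m + x + g)
}

ops_ref_span <- function(ops) {
  refc <- ops$op %in% c("match", "mismatch", "deletion")
  if (!any(refc)) return(c(NA_integer_, NA_integer_))
  c(min(ops$ref_start[refc]),
    max(ops$ref_start[refc] + ops$len[refc] - 1L))
}

new_alignment <- function(read_id, read, strand, score, ops, rejected = FALSE,
                          reason = NA_character_) {
  span <- if (is.null(ops)) c(NA_integer_, NA_integer_) else ops_ref_span(ops)
  structure(
    list(read_id = read_id, read = read, strand = strand, score = score,
         ops = ops,
         identity = if (is.null(ops)) NA_real_ else ops_identity(ops),
         ref_span = span,
         retained = !rejected, reason = reason),
    class = "read_alignment"
  )
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("<alignment %s: strand %s, ref %d-%d, identity %.3f%s>\n",
              x$read_id, x$strand, x$ref_span[1L], x$ref_span[2L], x$identity,
              if (x$retained) "" else paste0(", rejected: ", x$reason)))
  invisible(x)
}

## full-length filter: retain iff aligned ref span covers >= min_span of the
## amplicon interval AND gap-compressed identity >= min_identity
apply_fulllength_filter <- function(aln, amplicon, min_identity, min_span) {
  if (!aln$retained) return(aln)
  cov <- 0
  if (!any(is.na(aln$ref_span))) {
    lo <- max(aln$ref_span[1L], amplicon$interval[1L])
    hi <- min(aln$ref_span[2L], amplicon$interval[2L])
    if (hi >= lo) cov <- (hi - lo + 1) / iv_width(amplicon$interval)
  }
  if (cov < min_span) {
    aln$retained <- FALSE
    aln$reason <- sprintf("span %.3f < %.2f of amplicon", cov, min_span)
  } else if (aln$identity < min_identity) {
    aln$retained <- FALSE
    aln$reason <- sprintf("identity %.3f < %.2f", aln$identity, min_identity)
  }
  aln
}

#' Align reads to the locus with exact semi-global DP
#'
#' Each read (and its reverse complement) is aligned end-to-end against the
#' target region with free end gaps on the reference; the better-scoring
#' strand is kept and all coordinates are reported locus-forward. Reads
#' failing the full-length filter are flagged rejected, never dropped.
#'
#' @param reads Named character vector of reads (A/C/G/T/N only).
#' @param locus A [reference_locus()].
#' @param amplicon [amplicon_def()] used for the full-length span filter and,
#'   by default, to restrict the alignment target region. Defaults to the
#'   locus short amplicon.
#' @param min_identity Minimum gap-compressed identity to retain a read.
#' @param min_span Minimum fraction of the amplicon interval the aligned
#'   reference span must cover.
#' @param margin Extra reference flank (bp) added around the amplicon when
#'   restricting the target region.
#' @param chunk_size Reads per vectorised alignment call.
#' @return List of `read_alignment` objects (one per input read, same order).
#' @export
align_reads <- function(reads, locus, amplicon = locus$short_amplicon,
                        min_identity = 0.8, min_span = 0.9, margin = 30L,
                        chunk_size = 500L) {
  stopifnot(inherits(locus, "reference_locus"))
  if (min_identity <= 0 || min_identity > 1 || min_span <= 0 || min_span > 1) {
    stop("min_identity and min_span must lie in (0, 1]", call. = FALSE)
  }
  if (length(reads) == 0L) return(list())
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)
  bad <- !is_dna(reads)
  if (any(bad)) {
    stop("read(s) contain non-ACGTN symbols: ",
         paste(head(names(reads)[bad], 5), collapse = ", "), call. = FALSE)
  }

  region <- c(max(1L, amplicon$interval[1L] - margin),
              min(nchar(locus$sequence), amplicon$interval[2L] + margin))
  subject <- Biostrings::DNAString(substr(locus$sequence, region[1L], region[2L]))
  ref_offset <- region[1L] - 1L
  mat <- substitution_matrix()

  fwd <- Biostrings::DNAStringSet(reads)
  rev <- Biostrings::reverseComplement(fwd)
  out <- vector("list", length(reads))

  idx_chunks <- split(seq_along(reads),
                      ceiling(seq_along(reads) / chunk_size))
  for (idx in idx_chunks) {
    sc_f <- Biostrings::pairwiseAlignment(
      fwd[idx], subject, type = "global-local", substitutionMatrix = mat,
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT, scoreOnly = TRUE)
    sc_r <- Biostrings::pairwiseAlignment(
      rev[idx], subject, type = "global-local", substitutionMatrix = mat,
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT, scoreOnly = TRUE)
    use_rev <- sc_r > sc_f
    canon <- fwd[idx]
    canon[use_rev] <- rev[idx][use_rev]
    pa <- Biostrings::pairwiseAlignment(
      canon, subject, type = "global-local", substitutionMatrix = mat,
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
    pg <- as.character(Biostrings::pattern(pa))
    sg <- as.character(Biostrings::subject(pa))
    sstart <- Biostrings::start(Biostrings::subject(pa))
    for (k in seq_along(idx)) {
      i <- idx[k]
      ops <- ops_from_gapped(pg[k], sg[k], ref_offset = ref_offset + sstart[k] - 1L)
      out[[i]] <- new_alignment(
        read_id = names(reads)[i],
        read = as.character(canon[[k]]),
        strand = if (use_rev[k]) "-" else "+",
        score = Biostrings::score(pa)[k], ops = ops)
      out[[i]] <- apply_fulllength_filter(out[[i]], amplicon,
                                          min_identity, min_span)
    }
  }
  names(out) <- names(reads)
  out
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one read.
#'
#' @inheritParams align_reads
#' @param read A single read sequence.
#' @return A `read_alignment`.
#' @export
align_read <- function(read, locus, amplicon = locus$short_amplicon,
                       min_identity = 0.8, min_span = 0.9, margin = 30L) {
  align_reads(c(read1 = unname(read)), locus, amplicon = amplicon,
              min_identity = min_identity, min_span = min_span,
              margin = margin)[[1L]]
}

#' Align long-amplicon reads with minimap2
#'
#' Writes the locus and reads to temporary files, runs `minimap2 -a`
#' (map-ont preset, `--eqx`, secondary alignments suppressed), converts the
#' SAM via [Rsamtools::asBam()] and parses primary records into the same
#' per-read structure as [align_reads()]. Unmapped reads and reads absent
#' from the output are flagged rejected.
#'
#' @inheritParams align_reads
#' @param amplicon Amplicon used by the full-length filter; defaults to the
#'   locus long amplicon.
#' @param preset minimap2 preset (`-x`).
#' @return List of `read_alignment` objects, in input read order.
#' @export
align_reads_minimap2 <- function(reads, locus,
                                 amplicon = locus$long_amplicon,
                                 min_identity = 0.8, min_span = 0.9,
                                 preset = "map-ont") {
  stopifnot(inherits(locus, "reference_locus"))
  if (Sys.which("minimap2") == "") {
    stop("minimap2 executable not found on PATH", call. = FALSE)
  }
  if (length(reads) == 0L) return(list())
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)

  td <- tempfile("mm2")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  ref_fa <- file.path(td, "ref.fa")
  rd_fq <- file.path(td, "reads.fq")
  write_fasta(setNames(locus$sequence, locus$name), ref_fa)
  write_fastq(reads, rd_fq)

  sam <- file.path(td, "aln.sam")
  status <- system2("minimap2",
                    c("-a", "-x", preset, "--eqx", "--secondary=no",
                      "-t", "1", shQuote(ref_fa), shQuote(rd_fq)),
                    stdout = sam, stderr = FALSE)
  if (status != 0L) stop("minimap2 failed with status ", status, call. = FALSE)
  bam <- Rsamtools::asBam(sam, file.path(td, "aln"), overwrite = TRUE,
                          indexDestination = FALSE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "seq")))[[1L]]

  out <- setNames(vector("list", length(reads)), names(reads))
  seqs <- as.character(b$seq)
  for (j in seq_along(b$qname)) {
    flag <- b$flag[j]
    if (bitwAnd(flag, 0x900L) != 0L) next       # secondary/supplementary
    id <- b$qname[j]
    if (bitwAnd(flag, 0x4L) != 0L) {
      out[[id]] <- new_alignment(id, reads[[id]], "+", NA_real_, NULL,
                                 rejected = TRUE, reason = "unmapped")
      next
    }
    ops <- ops_from_cigar(b$cigar[j], ref_start = b$pos[j])
    out[[id]] <- new_alignment(
      id, seqs[j],
      strand = if (bitwAnd(flag, 0x10L)) "-" else "+",
      score = NA_real_, ops = ops)
    out[[id]] <- apply_fulllength_filter(out[[id]], amplicon,
                                         min_identity, min_span)
  }
  for (id in names(out)) {
    if (is.null(out[[id]])) {
      out[[id]] <- new_alignment(id, reads[[id]], "+", NA_real_, NULL,
                                 rejected = TRUE, reason = "no alignment")
    }
  }
  out
}

## expand an --eqx CIGAR into the four op types; soft clips advance the read
## cursor but are not emitted as ops
ops_from_cigar <- function(cigar, ref_start) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  typs <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  ref_adv <- typs %in% c("M", "=", "X", "D", "N")
  read_adv <- typs %in% c("M", "=", "X", "I", "S")
  ref_before <- ref_start + cumsum(c(0L, lens * ref_adv))[seq_along(lens)]
  read_before <- 1L + cumsum(c(0L, lens * read_adv))[seq_along(lens)]
  op <- c("=" = "match", X = "mismatch", M = "match", I = "insertion",
          D = "deletion", N = "deletion")[typs]
  keep <- !is.na(op)
  data.frame(
    op = unname(op[keep]), len = lens[keep],
    ref_start = as.integer(ifelse(op[keep] == "insertion",
                                  ref_before[keep] - 1L, ref_before[keep])),
    read_start = as.integer(read_before[keep]),
    stringsAsFactors = FALSE)
}

#' CIGAR-style string for an alignment's op list
#'
#' @param aln A `read_alignment`.
#' @return Character CIGAR string using `=`/`X`/`I`/`D`.
#' @export
cigar_string <- function(aln) {
  if (is.null(aln$ops)) return("")
  code <- c(match = "=", mismatch = "X", insertion = "I", deletion = "D")
  paste0(aln$ops$len, code[aln$ops$op], collapse = "")
}

#' Read base aligned at given reference positions
#'
#' For each locus position, reports the read base aligned there, `"-"` when
#' the position falls inside a deletion in the read, or `NA` when the
#' position is outside the aligned reference span.
#'
#' @param aln A `read_alignment`.
#' @param positions Integer vector of locus coordinates.
#' @return Character vector, one element per position.
#' @export
read_base_at <- function(aln, positions) {
  res <- rep(NA_character_, length(positions))
  if (is.null(aln$ops) || !nrow(aln$ops)) return(res)
  ops <- aln$ops
  for (j in seq_along(positions)) {
    pos <- positions[j]
    hit <- which(ops$op %in% c("match", "mismatch", "deletion") &
                   ops$ref_start <= pos & pos <= ops$ref_start + ops$len - 1L)
    if (!length(hit)) next
    o <- ops[hit[1L], ]
    res[j] <- if (o$op == "deletion") "-" else {
      substr(aln$read, o$read_start + pos - o$ref_start,
             o$read_start + pos - o$ref_start)
    }
  }
  res
}

#' Read segment aligned to a reference interval
#'
#' Returns the read substring whose bases align inside `[lo, hi]` on the
#' reference, including any inserted bases between them; `NA` when no read
#' base aligns in the interval.
#'
#' @param aln A `read_alignment`.
#' @param lo,hi Reference interval (locus coordinates).
#' @return Character scalar or `NA`.
#' @export
read_segment <- function(aln, lo, hi) {
  if (is.null(aln$ops)) return(NA_character_)
  ops <- aln$ops[aln$ops$op %in% c("match", "mismatch"), , drop = FALSE]
  if (!nrow(ops)) return(NA_character_)
  idx <- integer(0)
  for (r in seq_len(nrow(ops))) {
    a <- max(lo, ops$ref_start[r])
    b <- min(hi, ops$ref_start[r] + ops$len[r] - 1L)
    if (a <= b) {
      idx <- c(idx, ops$read_start[r] + a - ops$ref_start[r],
               ops$read_start[r] + b - ops$ref_start[r])
    }
  }
  if (!length(idx)) return(NA_character_)
  substr(aln$read, min(idx), max(idx))
}

#' Call planned-SNV status on one aligned read
#'
#' Per SNV the aligned read base is inspected first: an uncovered position
#' reports `uncovered`, a position inside a read deletion reports `deleted`.
#' Otherwise the call is a *local haplotype vote*: the read segment aligned
#' to `position +/- flank` is compared by edit distance against the two
#' window haplotypes that differ only in the focal base (template base vs
#' reference base, both on the all-template background). The closer
#' haplotype wins; ties report `other` (uninformative). The vote makes the
#' call robust to sequencing errors and to ambiguous gap placement next to
#' the SNV column, which single-column calls are not.
#'
#' @param aln A `read_alignment`.
#' @param snvs data.frame with `position`, `ref_base`, `alt_base` (positions
#'   in the alignment's reference coordinates).
#' @param ref_seq The reference sequence the alignment was computed against.
#' @param tpl_seq `ref_seq` with all template SNVs applied (same length).
#' @param flank Half-window for the vote (default 5).
#' @return Character vector of statuses: `template_base`, `ref_base`,
#'   `other`, `deleted` or `uncovered`.
#' @export
call_snv_status <- function(aln, snvs, ref_seq, tpl_seq, flank = 5L) {
  base <- read_base_at(aln, snvs$position)
  n <- nchar(ref_seq)
  out <- character(nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    if (is.na(base[i])) { out[i] <- "uncovered"; next }
    if (base[i] == "-") { out[i] <- "deleted"; next }
    pos <- snvs$position[i]
    lo <- max(1L, pos - flank)
    hi <- min(n, pos + flank)
    seg <- read_segment(aln, lo, hi)
    if (is.na(seg)) { out[i] <- "uncovered"; next }
    tplwin <- substr(tpl_seq, lo, hi)
    refwin <- tplwin
    substr(refwin, pos - lo + 1L, pos - lo + 1L) <- snvs$ref_base[i]
    d <- utils::adist(c(refwin, tplwin), seg)
    out[i] <- if (d[2L] < d[1L]) "template_base"
    else if (d[1L] < d[2L]) "ref_base"
    else "other"
  }
  out
}

#' Tabulate a list of alignments
#'
#' @param alns List of `read_alignment` objects.
#' @return data.frame with read_id, strand, retained, reason, identity,
#'   ref_start, ref_end and cigar columns.
#' @export
alignment_table <- function(alns) {
  data.frame(
    read_id = vapply(alns, `[[`, character(1), "read_id"),
    strand = vapply(alns, `[[`, character(1), "strand"),
    retained = vapply(alns, `[[`, logical(1), "retained"),
    reason = vapply(alns, `[[`, character(1), "reason"),
    identity = vapply(alns, `[[`, numeric(1), "identity"),
    ref_start = vapply(alns, function(a) a$ref_span[1L], integer(1)),
    ref_end = vapply(alns, function(a) a$ref_span[2L], integer(1)),
    cigar = vapply(alns, cigar_string, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
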