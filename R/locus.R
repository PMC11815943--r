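## Domain types for the target locus: amplicons, guides, guide pairs and the
## reference locus itself. The locus sequence is the *target allele as it
## exists in the cell before editing* (i.e. it carries the pathogenic base);
## `pathogenic_variant$alt_base` is the corrective base the repair template
## restores. All intervals are 1-based closed, locus-forward.

#' Define a PCR amplicon by its primer footprints
#'
#' @param fwd_primer Integer pair `(start, end)`: forward primer footprint.
#' @param rev_primer Integer pair `(start, end)`: reverse primer footprint.
#' @return An object of class `amplicon_def` with fields `fwd_primer`,
#'   `rev_primer`, `interval` (`fwd_primer[1]..rev_primer[2]`) and
#'   `expected_length`.
#' @export
amplicon_def <- function(fwd_primer, rev_primer) {
  fwd_primer <- check_interval(fwd_primer, "fwd_primer")
  rev_primer <- check_interval(rev_primer, "rev_primer")
  if (fwd_primer[2L] >= rev_primer[1L]) {
    stop("fwd_primer must end before rev_primer starts", call. = FALSE)
  }
  structure(
    list(
      fwd_primer = fwd_primer,
      rev_primer = rev_primer,
      interval = c(fwd_primer[1L], rev_primer[2L]),
      expected_length = rev_primer[2L] - fwd_primer[1L] + 1L
    ),
    class = "amplicon_def"
  )
}

#' @export
print.amplicon_def <- function(x, ...) {
  cat(sprintf("<amplicon %d-%d (%d bp)>\n", x$interval[1L], x$interval[2L],
              x$expected_length))
  invisible(x)
}

#' Describe a single sgRNA for a D10A Cas9 nickase
#'
#' The nick position is the locus coordinate of the base immediately 5'
#' (locus-forward) of the cut, which SpCas9 D10A places between protospacer
#' positions 17 and 18, i.e. 3 nt 5' of the PAM on the protospacer strand.
#'
#' @param protospacer 20-nt protospacer sequence (as read on the guide, 5'-3').
#' @param start Locus coordinate where the protospacer footprint begins.
#' @param strand `"+"` or `"-"`: strand carrying the protospacer/PAM.
#' @param locus Optional [reference_locus()]; when given, the protospacer and
#'   NGG PAM are checked against the locus sequence.
#' @param id Optional guide identifier.
#' @return Object of class `guide` with fields `id`, `protospacer`, `strand`,
#'   `footprint` (protospacer interval), `pam_interval` and `nick_position`.
#' @export
guide <- function(protospacer, start, strand = c("+", "-"), locus = NULL,
                  id = NULL) {
  protospacer <- check_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L) {
    stop("protospacer must be exactly 20 nt", call. = FALSE)
  }
  strand <- match.arg(strand)
  start <- as.integer(start)
  footprint <- c(start, start + 19L)
  if (strand == "+") {
    pam_interval <- c(start + 20L, start + 22L)
    nick_position <- start + 16L
  } else {
    pam_interval <- c(start - 3L, start - 1L)
    nick_position <- start + 2L
  }
  g <- structure(
    list(id = if (is.null(id)) sprintf("g%s%d", strand, start) else id,
         protospacer = protospacer, strand = strand, footprint = footprint,
         pam_interval = pam_interval, nick_position = nick_position),
    class = "guide"
  )
  if (!is.null(locus)) validate_guide(g, locus)
  g
}

validate_guide <- function(g, locus) {
  seq <- locus$sequence
  n <- nchar(seq)
  if (g$footprint[1L] < 1L || g$footprint[2L] > n ||
      g$pam_interval[1L] < 1L || g$pam_interval[2L] > n) {
    stop("guide footprint/PAM falls outside the locus", call. = FALSE)
  }
  fp <- substr(seq, g$footprint[1L], g$footprint[2L])
  obs <- if (g$strand == "+") fp else revcomp(fp)
  if (obs != g$protospacer) {
    stop(sprintf("guide %s: protospacer does not match locus sequence", g$id),
         call. = FALSE)
  }
  pam <- substr(seq, g$pam_interval[1L], g$pam_interval[2L])
  pam <- if (g$strand == "+") pam else revcomp(pam)
  if (substr(pam, 2L, 3L) != "GG") {
    stop(sprintf("guide %s: PAM is not NGG (found %s)", g$id, pam),
         call. = FALSE)
  }
  invisible(g)
}

#' Pair two nickase guides
#'
#' Orientation is derived from the strands: a PAM-out pair has the left
#' guide on "-" (PAM pointing 5', away from the inter-nick segment) and the
#' right guide on "+".
#'
#' @param left,right [guide()] objects; `left` must nick 5' of `right`.
#' @return Object of class `guide_pair` with `offset` (nick-to-nick distance
#'   in bp) and `orientation` (`PAM-out`, `PAM-in` or `tandem`).
#' @export
guide_pair <- function(left, right) {
  stopifnot(inherits(left, "guide"), inherits(right, "guide"))
  if (left$nick_position >= right$nick_position) {
    stop("left guide must nick 5' of right guide", call. = FALSE)
  }
  orientation <- if (left$strand == "-" && right$strand == "+") "PAM-out"
  else if (left$strand == "+" && right$strand == "-") "PAM-in"
  else "tandem"
  structure(
    list(left = left, right = right,
         offset = right$nick_position - left$nick_position,
         orientation = orientation),
    class = "guide_pair"
  )
}

#' @export
print.guide_pair <- function(x, ...) {
  cat(sprintf("<guide pair %s: nicks %d/%d, offset %d bp (%s)>\n",
              x$orientation, x$left$nick_position, x$right$nick_position,
              x$offset, paste(x$left$id, x$right$id, sep = "+")))
  invisible(x)
}

#' Construct a reference locus model
#'
#' @param name Locus identifier.
#' @param sequence Uppercase DNA sequence of the target allele (carries the
#'   pathogenic base at the variant position).
#' @param coordinate_origin Genomic coordinate of locus position 1 (used only
#'   at I/O boundaries).
#' @param exons List (or 2-column matrix) of `(start, end)` closed intervals,
#'   sorted, non-overlapping, within the locus.
#' @param cds_frame Number of leading exonic bases (0, 1 or 2) that complete
#'   an upstream codon; translation starts after them.
#' @param pathogenic_variant List with `position`, `ref_base` (the base present
#'   in `sequence`) and `alt_base` (the corrective base).
#' @param short_amplicon,long_amplicon [amplicon_def()] objects; the short
#'   amplicon must nest inside the long one.
#' @param guides Optional [guide_pair()] validated against the locus.
#' @return Object of class `reference_locus`.
#' @export
reference_locus <- function(name, sequence, coordinate_origin = 0L,
                            exons, cds_frame = 0L, pathogenic_variant,
                            short_amplicon, long_amplicon, guides = NULL) {
  sequence <- check_dna(sequence, "locus sequence")
  n <- nchar(sequence)
  if (is.matrix(exons)) exons <- lapply(seq_len(nrow(exons)), function(i) exons[i, ])
  exons <- lapply(exons, check_interval, what = "exon")
  starts <- vapply(exons, `[`, integer(1), 1L)
  ends <- vapply(exons, `[`, integer(1), 2L)
  if (is.unsorted(starts, strictly = TRUE) || any(ends > n) ||
      any(starts[-1L] <= ends[-length(ends)])) {
    stop("exons must be sorted, non-overlapping and within the locus",
         call. = FALSE)
  }
  if (!cds_frame %in% 0:2) stop("cds_frame must be 0, 1 or 2", call. = FALSE)

  pv <- pathogenic_variant
  if (!all(c("position", "ref_base", "alt_base") %in% names(pv))) {
    stop("pathogenic_variant needs position, ref_base and alt_base",
         call. = FALSE)
  }
  pv$position <- as.integer(pv$position)
  pv$ref_base <- toupper(pv$ref_base)
  pv$alt_base <- toupper(pv$alt_base)
  if (!any(starts <= pv$position & pv$position <= ends)) {
    stop("pathogenic_variant must lie inside an exon", call. = FALSE)
  }
  found <- substr(sequence, pv$position, pv$position)
  if (found != pv$ref_base) {
    stop(sprintf(
      "pathogenic_variant ref_base (%s) disagrees with locus sequence (%s) at position %d",
      pv$ref_base, found, pv$position), call. = FALSE)
  }
  if (pv$alt_base == pv$ref_base) {
    stop("pathogenic_variant alt_base must differ from ref_base", call. = FALSE)
  }

  stopifnot(inherits(short_amplicon, "amplicon_def"),
            inherits(long_amplicon, "amplicon_def"))
  if (long_amplicon$interval[2L] > n ||
      !iv_contains(c(1L, n), long_amplicon$interval)) {
    stop("long amplicon falls outside the locus", call. = FALSE)
  }
  if (!iv_contains(long_amplicon$interval, short_amplicon$interval)) {
    stop("short amplicon must nest inside the long amplicon", call. = FALSE)
  }

  locus <- structure(
    list(name = name, sequence = sequence,
         coordinate_origin = as.integer(coordinate_origin),
         exons = exons, cds_frame = as.integer(cds_frame),
         pathogenic_variant = pv,
         short_amplicon = short_amplicon, long_amplicon = long_amplicon,
         guides = NULL),
    class = "reference_locus"
  )
  if (!is.null(guides)) {
    stopifnot(inherits(guides, "guide_pair"))
    validate_guide(guides$left, locus)
    validate_guide(guides$right, locus)
    locus$guides <- guides
  }
  locus
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus '%s': %d bp, %d exon(s), variant %s>%s@%d>\n",
              x$name, nchar(x$sequence), length(x$exons),
              x$pathogenic_variant$ref_base, x$pathogenic_variant$alt_base,
              x$pathogenic_variant$position))
  if (!is.null(x$guides)) print(x$guides)
  invisible(x)
}

## ---- coding-sequence machinery shared by design and expression ----

exon_index_of <- function(locus, position) {
  for (i in seq_along(locus$exons)) {
    e <- locus$exons[[i]]
    if (position >= e[1L] && position <= e[2L]) return(i)
  }
  NA_integer_
}

## locus position -> index into the spliced exonic sequence (NA if intronic)
spliced_index <- function(locus, position) {
  idx <- exon_index_of(locus, position)
  if (is.na(idx)) return(NA_integer_)
  before <- if (idx > 1L) {
    sum(vapply(locus$exons[seq_len(idx - 1L)], iv_width, integer(1)))
  } else 0L
  before + (position - locus$exons[[idx]][1L] + 1L)
}

spliced_sequence <- function(locus) {
  paste(vapply(locus$exons, function(e) substr(locus$sequence, e[1L], e[2L]),
               character(1)), collapse = "")
}

## translate a DNA string with the standard code; partial trailing codon dropped
translate_dna <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## codon containing an exonic locus position, in-frame per cds_frame.
## Returns NULL when the position falls in the trimmed partial leading or
## trailing codon.
codon_at <- function(locus, position) {
  si <- spliced_index(locus, position)
  if (is.na(si)) return(NULL)
  cds_pos <- si - locus$cds_frame       # 1-based position within the CDS
  if (cds_pos < 1L) return(NULL)
  codon_i <- (cds_pos - 1L) %/% 3L      # 0-based codon index
  within <- (cds_pos - 1L) %% 3L + 1L   # 1, 2 or 3
  spl <- spliced_sequence(locus)
  lo <- locus$cds_frame + codon_i * 3L + 1L
  hi <- lo + 2L
  if (hi > nchar(spl)) return(NULL)
  list(codon = substr(spl, lo, hi), codon_pos = within, spliced_index = si)
}
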