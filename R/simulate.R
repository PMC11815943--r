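## Seedable generator of ground-truth allele mixtures and Nanopore-like
## amplicon/cDNA reads. PCR capture is modelled physically: an allele whose
## edits disrupt a primer footprint yields no product for that amplicon, and
## its mixture weight is renormalised over the capturable alleles (so
## requested read counts are exact and the capture bias stays measurable).
##
## Single-molecule errors are i.i.d. per base; indel error lengths are
## geometric with 90% single-base events (the dominant Nanopore error mode),
## capped at `max_indel_len`. Qualities are a constant Q12 placeholder —
## downstream analysis is alignment-based.

#' Specify one allele as a set of edits to the locus
#'
#' @param name Allele identifier.
#' @param snvs Optional data.frame of substitutions with columns `position`,
#'   `ref_base`, `alt_base` (e.g. the `snvs` table of a repair template, or a
#'   subset of it).
#' @param indels Optional list of small indels, each
#'   `list(position =, ins = "SEQ")` (inserted after `position`) or
#'   `list(position =, del = <length>)` (deletion starting at `position`).
#' @param deletion Optional `(start, end)` large deletion interval.
#' @param weight Non-negative mixture weight.
#' @return Object of class `allele_spec`.
#' @export
allele_spec <- function(name, snvs = NULL, indels = NULL, deletion = NULL,
                        weight = 1) {
  if (weight < 0) stop("weight must be non-negative", call. = FALSE)
  if (!is.null(snvs)) {
    stopifnot(all(c("position", "ref_base", "alt_base") %in% names(snvs)))
  }
  if (!is.null(deletion)) deletion <- check_interval(deletion, "deletion")
  structure(list(name = name, snvs = snvs, indels = indels %||% list(),
                 deletion = deletion, weight = weight),
            class = "allele_spec")
}

#' Combine allele specs into a mixture
#'
#' @param ... `allele_spec` objects.
#' @param normalise Rescale weights to sum to 1 (default TRUE).
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(..., normalise = TRUE) {
  alleles <- list(...)
  if (length(alleles) == 1L && is.list(alleles[[1L]]) &&
      !inherits(alleles[[1L]], "allele_spec")) {
    alleles <- alleles[[1L]]
  }
  stopifnot(all(vapply(alleles, inherits, logical(1), "allele_spec")))
  w <- vapply(alleles, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("mixture weights must sum to > 0", call. = FALSE)
  if (normalise) {
    for (i in seq_along(alleles)) alleles[[i]]$weight <- w[i] / sum(w)
  } else if (abs(sum(w) - 1) > 1e-9) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  names(alleles) <- vapply(alleles, `[[`, character(1), "name")
  structure(list(alleles = alleles), class = "mixture_spec")
}

#' Nanopore-like per-base error model
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities in \[0, 0.3\].
#' @param max_indel_len Cap on error indel length (bases).
#' @param indel_geom_p Geometric success parameter for indel error lengths;
#'   the default 0.9 makes 90% of indel errors single-base.
#' @return Object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.0025, del_rate = 0.0025,
                        max_indel_len = 10L, indel_geom_p = 0.9) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.3)) {
    stop("error rates must lie in [0, 0.3]", call. = FALSE)
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, max_indel_len = as.integer(max_indel_len),
                 indel_geom_p = indel_geom_p),
            class = "error_model")
}

#' Apply an allele spec to the locus
#'
#' Edits are applied with coordinate shifting handled via an explicit
#' locus-to-allele coordinate map; overlapping edits are an error.
#'
#' @param locus A [reference_locus()].
#' @param spec An [allele_spec()].
#' @return The allele sequence (character). Attribute `"coord_map"` holds the
#'   integer map locus position -> allele position (NA where deleted).
#' @export
build_allele <- function(locus, spec) {
  stopifnot(inherits(spec, "allele_spec"))
  n <- nchar(locus$sequence)
  ch <- strsplit(locus$sequence, "")[[1L]]

  ## collect edit footprints to detect overlap
  spans <- list()
  if (!is.null(spec$snvs) && nrow(spec$snvs)) {
    for (i in seq_len(nrow(spec$snvs))) {
      spans[[length(spans) + 1L]] <- rep(spec$snvs$position[i], 2L)
    }
  }
  for (ind in spec$indels) {
    w <- if (!is.null(ind$del)) c(ind$position, ind$position + ind$del - 1L)
    else rep(ind$position, 2L)
    spans[[length(spans) + 1L]] <- w
  }
  if (!is.null(spec$deletion)) spans[[length(spans) + 1L]] <- spec$deletion
  if (length(spans) > 1L) {
    m <- do.call(rbind, spans)
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[-1L, 1L] <= m[-nrow(m), 2L])) {
      stop("allele '", spec$name, "': overlapping edits", call. = FALSE)
    }
  }
  if (any(vapply(spans, function(s) s[1L] < 1L || s[2L] > n, logical(1)))) {
    stop("allele '", spec$name, "': edit outside the locus", call. = FALSE)
  }

  if (!is.null(spec$snvs) && nrow(spec$snvs)) {
    if (!all(ch[spec$snvs$position] == spec$snvs$ref_base)) {
      stop("allele '", spec$name, "': SNV ref_base mismatch", call. = FALSE)
    }
    ch[spec$snvs$position] <- spec$snvs$alt_base
  }

  drop <- rep(FALSE, n)
  ins_after <- character(n)  # sequence inserted after locus position i
  for (ind in spec$indels) {
    if (!is.null(ind$del)) {
      drop[seq(ind$position, ind$position + ind$del - 1L)] <- TRUE
    } else if (!is.null(ind$ins)) {
      ins_after[ind$position] <- toupper(ind$ins)
    } else {
      stop("indel entries need either $ins or $del", call. = FALSE)
    }
  }
  if (!is.null(spec$deletion)) {
    drop[seq(spec$deletion[1L], spec$deletion[2L])] <- TRUE
  }

  piece <- ifelse(drop, "", ch)
  piece <- paste0(piece, ins_after)
  seqs <- paste(piece, collapse = "")

  ## locus -> allele coordinate map
  contrib <- nchar(piece)
  endpos <- cumsum(contrib)
  coord_map <- ifelse(drop, NA_integer_,
                      as.integer(endpos - contrib + 1L))
  attr(seqs, "coord_map") <- coord_map
  seqs
}

## does the amplicon capture this allele? every primer base must be present
## and unmodified relative to the locus
allele_capturable <- function(locus, spec, amplicon) {
  disrupts <- function(iv) {
    hit <- FALSE
    if (!is.null(spec$deletion) && iv_overlaps(spec$deletion, iv)) hit <- TRUE
    for (ind in spec$indels) {
      w <- if (!is.null(ind$del)) c(ind$position, ind$position + ind$del - 1L)
      else rep(ind$position, 2L)
      if (iv_overlaps(w, iv)) hit <- TRUE
    }
    hit
  }
  !disrupts(amplicon$fwd_primer) && !disrupts(amplicon$rev_primer)
}

## extract the amplicon product from an allele sequence via its coord map
allele_amplicon_seq <- function(allele_seq, amplicon) {
  map <- attr(allele_seq, "coord_map")
  a <- map[amplicon$fwd_primer[1L]]
  b <- map[amplicon$rev_primer[2L]]
  substr(allele_seq, a, b)
}

## inject i.i.d. errors into one sequence; returns list(seq, n_errors)
inject_errors <- function(seq, error) {
  v <- strsplit(seq, "")[[1L]]
  L <- length(v)
  u <- runif(L)
  sub_i <- which(u < error$sub_rate)
  del_i <- which(u >= error$sub_rate & u < error$sub_rate + error$del_rate)
  ins_i <- which(u >= error$sub_rate + error$del_rate &
                   u < error$sub_rate + error$del_rate + error$ins_rate)
  n_err <- length(sub_i) + length(del_i) + length(ins_i)
  if (length(sub_i)) {
    idx <- match(v[sub_i], DNA_BASES)
    pick <- sample.int(3L, length(sub_i), replace = TRUE)
    alt <- matrix(DNA_BASES[outer(1:4, 1:4, "!=")[, idx]], nrow = 3L)
    ## column i of `alt` holds the three non-ref bases for sub_i[i]
    v[sub_i] <- alt[cbind(pick, seq_along(sub_i))]
  }
  if (length(del_i)) {
    lens <- pmin(1L + rgeom(length(del_i), error$indel_geom_p),
                 error$max_indel_len)
    for (k in seq_along(del_i)) {
      v[seq(del_i[k], min(L, del_i[k] + lens[k] - 1L))] <- ""
    }
  }
  if (length(ins_i)) {
    lens <- pmin(1L + rgeom(length(ins_i), error$indel_geom_p),
                 error$max_indel_len)
    ins <- vapply(lens, random_dna, character(1))
    v[ins_i] <- paste0(v[ins_i], ins)
  }
  list(seq = paste(v, collapse = ""), n_errors = n_err)
}

#' Simulate amplicon sequencing reads from an allele mixture
#'
#' Each read is drawn from an allele with probability proportional to its
#' weight *among the alleles whose primer sites survive intact for this
#' amplicon*; alleles that have lost a primer footprint contribute no reads
#' (the physical mechanism behind genotyping evasion). The read is the
#' allele's amplicon product on a random strand with errors injected at the
#' model rates.
#'
#' @param locus A [reference_locus()].
#' @param mixture A [mixture_spec()].
#' @param amplicon An [amplicon_def()] (short or long).
#' @param n_reads Number of reads to simulate.
#' @param error An [error_model()].
#' @param seed Optional integer seed; equal seeds give byte-identical output.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: read_id, allele, strand, n_errors). Attribute
#'   `"capture"` on `truth` records per-allele capturability and the
#'   renormalised weights actually sampled from.
#' @export
simulate_amplicon_reads <- function(locus, mixture, amplicon, n_reads,
                                    error = error_model(), seed = NULL) {
  stopifnot(inherits(mixture, "mixture_spec"), n_reads > 0)
  with_seed(seed, {
    alleles <- mixture$alleles
    capturable <- vapply(alleles, allele_capturable, logical(1),
                         locus = locus, amplicon = amplicon)
    if (!any(capturable)) {
      stop("no allele in the mixture is capturable by this amplicon",
           call. = FALSE)
    }
    w <- vapply(alleles, `[[`, numeric(1), "weight")
    w_eff <- ifelse(capturable, w, 0)
    w_eff <- w_eff / sum(w_eff)

    products <- lapply(alleles, function(a) {
      if (a$weight > 0 && allele_capturable(locus, a, amplicon)) {
        allele_amplicon_seq(build_allele(locus, a), amplicon)
      } else NA_character_
    })

    pick <- sample(names(alleles), n_reads, replace = TRUE, prob = w_eff)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- character(n_reads)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      e <- inject_errors(products[[pick[i]]], error)
      reads[i] <- if (strand[i] == "-") revcomp(e$seq) else e$seq
      n_err[i] <- e$n_errors
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    names(reads) <- ids
    truth <- data.frame(read_id = ids, allele = pick, strand = strand,
                        n_errors = n_err, stringsAsFactors = FALSE)
    attr(truth, "capture") <- data.frame(
      allele = names(alleles), weight = w, capturable = capturable,
      effective_weight = w_eff, row.names = NULL, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate cDNA reads with alternative target-exon inclusion
#'
#' Reads are spliced-transcript sequences from either the exon-including or
#' the exon-skipping isoform; inclusion status and template-SNV carrier
#' status are drawn independently per read.
#'
#' @param locus A [reference_locus()].
#' @param isoforms An [isoform_model()].
#' @param template A `repair_template` supplying the carried SNVs.
#' @param inclusion Fraction of transcripts containing the target exon.
#' @param snv_carrier_fraction Fraction of transcripts carrying the template
#'   SNVs (exonic SNVs only; applied only to exon-including transcripts for
#'   SNVs inside the target exon).
#' @param n_reads Number of reads.
#' @param error An [error_model()].
#' @param seed Optional integer seed.
#' @return List with `reads` and `truth` (read_id, includes_exon, carrier,
#'   strand, n_errors).
#' @export
simulate_cdna_reads <- function(locus, isoforms, template = NULL,
                                inclusion = 0.4, snv_carrier_fraction = 0,
                                n_reads, error = error_model(), seed = NULL) {
  stopifnot(inherits(isoforms, "isoform_model"))
  if (inclusion < 0 || inclusion > 1 ||
      snv_carrier_fraction < 0 || snv_carrier_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (snv_carrier_fraction > 0 && is.null(template)) {
    stop("a template is required when snv_carrier_fraction > 0", call. = FALSE)
  }
  with_seed(seed, {
    full_carrier <- isoforms$full
    if (!is.null(template)) {
      tx <- transcript_snv_positions(isoforms, template)
      tx <- tx[!is.na(tx$tx_position), ]
      if (nrow(tx)) {
        ch <- strsplit(full_carrier, "")[[1L]]
        stopifnot(all(ch[tx$tx_position] == tx$ref_base))
        ch[tx$tx_position] <- tx$alt_base
        full_carrier <- paste(ch, collapse = "")
      }
    }
    includes <- runif(n_reads) < inclusion
    carrier <- runif(n_reads) < snv_carrier_fraction
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- character(n_reads)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      base <- if (!includes[i]) isoforms$skipped
      else if (carrier[i]) full_carrier else isoforms$full
      e <- inject_errors(base, error)
      reads[i] <- if (strand[i] == "-") revcomp(e$seq) else e$seq
      n_err[i] <- e$n_errors
    }
    ids <- sprintf("cdna%06d", seq_len(n_reads))
    names(reads) <- ids
    truth <- data.frame(read_id = ids, includes_exon = includes,
                        carrier = carrier, strand = strand, n_errors = n_err,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}
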