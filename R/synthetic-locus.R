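## Deterministic synthetic loci emulating the study system: a LAMB3-like
## locus carrying a heterozygous premature-stop variant (TGA at the target
## codon; corrected to CGA/Arg), a PAM-out D10A guide pair with nicks 66 bp
## apart flanking the variant, a ~700 bp genotyping amplicon and a ~10.5 kb
## long amplicon symmetrically spanning the variant, and a 4-exon minigene
## (exon-12..15 analogue) whose third exon is the target exon.
##
## These builders construct *synthetic stand-ins* for the patient locus (the
## study deposited no sequence data); every feature is planted by
## construction so that ground truth is known exactly.

plant <- function(chars, start, what) {
  v <- strsplit(what, "")[[1L]]
  chars[seq(start, start + length(v) - 1L)] <- v
  chars
}

#' Build the bundled synthetic target locus
#'
#' With `compact = FALSE` (default): an 11,300-bp locus, variant at position
#' 5,650, nicks at 5,620 ("-" guide) and 5,686 ("+" guide) — 66 bp apart —
#' short amplicon 5,301..6,000 (700 bp), long amplicon 401..10,900
#' (10,500 bp), exons at 4,800..4,979 / 5,150..5,269 / 5,500..5,799 (target)
#' / 6,100..6,249.
#'
#' With `compact = TRUE`: a 700-bp single-exon toy locus with a 40-bp nick
#' offset, sized so that a 132-nt template with 40-bp arms is geometrically
#' feasible.
#'
#' @param seed Construction seed for the random background sequence.
#' @param compact Build the small toy locus instead of the full-size one.
#' @return A [reference_locus()] with the guide pair attached.
#' @export
synthetic_locus <- function(seed = 42L, compact = FALSE) {
  with_seed(seed, {
    if (compact) {
      n <- 700L
      varpos <- 300L
      chars <- strsplit(random_dna(n), "")[[1L]]
      chars <- plant(chars, varpos, "TGA")        # premature stop codon
      chars <- plant(chars, 277L, "CC")           # "-" guide PAM (s = 280)
      chars <- plant(chars, 327L, "GG")           # "+" guide PAM (s = 306)
      seq <- paste(chars, collapse = "")
      gl <- guide(revcomp(substr(seq, 280L, 299L)), start = 280L, strand = "-",
                  id = "sg1")
      gr <- guide(substr(seq, 306L, 325L), start = 306L, strand = "+",
                  id = "sg2")
      reference_locus(
        name = "toy_locus", sequence = seq,
        exons = list(c(201L, 440L)), cds_frame = 0L,
        pathogenic_variant = list(position = varpos, ref_base = "T",
                                  alt_base = "C"),
        short_amplicon = amplicon_def(c(211L, 230L), c(391L, 410L)),
        long_amplicon = amplicon_def(c(21L, 40L), c(661L, 680L)),
        guides = guide_pair(gl, gr)
      )
    } else {
      n <- 11300L
      varpos <- 5650L
      chars <- strsplit(random_dna(n), "")[[1L]]
      chars <- plant(chars, varpos, "TGA")        # p.R*-analogue stop codon
      chars <- plant(chars, 5615L, "CC")          # "-" guide PAM (s = 5618)
      chars <- plant(chars, 5691L, "GG")          # "+" guide PAM (s = 5670)
      seq <- paste(chars, collapse = "")
      gl <- guide(revcomp(substr(seq, 5618L, 5637L)), start = 5618L,
                  strand = "-", id = "sg1")
      gr <- guide(substr(seq, 5670L, 5689L), start = 5670L, strand = "+",
                  id = "sg2")
      reference_locus(
        name = "synthetic_LAMB3_locus", sequence = seq,
        coordinate_origin = 0L,
        exons = list(c(4800L, 4979L), c(5150L, 5269L), c(5500L, 5799L),
                     c(6100L, 6249L)),
        cds_frame = 0L,
        pathogenic_variant = list(position = varpos, ref_base = "T",
                                  alt_base = "C"),
        short_amplicon = amplicon_def(c(5301L, 5330L), c(5971L, 6000L)),
        long_amplicon = amplicon_def(c(401L, 430L), c(10871L, 10900L)),
        guides = guide_pair(gl, gr)
      )
    }
  })
}

#' Heterozygous unedited baseline mixture (50% T : 50% C)
#'
#' The compound-heterozygous starting state: the target allele carries the
#' premature-stop base (T), the other allele the reference base (C) at the
#' same position (its own distinct variant lies outside the modelled locus).
#'
#' @param locus A [reference_locus()].
#' @return A [mixture_spec()] of the two alleles at weight 0.5 each.
#' @export
het_baseline_mixture <- function(locus) {
  pv <- locus$pathogenic_variant
  mixture_spec(
    allele_spec("target_T", weight = 0.5),
    allele_spec("nontarget_C",
                snvs = planned_snv(pv$position, pv$ref_base, pv$alt_base,
                                   "correction"),
                weight = 0.5)
  )
}

#' Editing-outcome mixture for the short-amplicon experiment
#'
#' Ground-truth allele mixture emulating a bulk dual-nickase editing
#' outcome: perfect HDR (all template SNVs), imperfect HDR (partial template
#' integration: the distal guide's blocking SNV missing), a nick-site
#' deletion (end-joining), the unedited target allele (T) and the non-target
#' allele (C, no silent SNVs).
#'
#' @param locus A [reference_locus()] with guides attached.
#' @param template A `repair_template` from [design_template()].
#' @param weights Named numeric mixture weights for the five alleles.
#' @param indel_len Length of the nick-site deletion (default 21 bp centred
#'   on the right nick).
#' @return A [mixture_spec()].
#' @export
hdr_outcome_mixture <- function(locus, template,
                                weights = c(perfect_hdr = 0.48,
                                            imperfect_hdr = 0.12,
                                            nick_indel = 0.18,
                                            unedited_T = 0.11,
                                            nontarget_C = 0.11),
                                indel_len = 21L) {
  pv <- locus$pathogenic_variant
  snvs <- template$snvs
  varpos <- pv$position
  ## the imperfect allele lacks the distal blocking SNV: the blocking SNV
  ## farthest from the variant
  blocking <- which(snvs$role == "blocking")
  if (length(blocking) < 2L) {
    stop("template must carry a blocking SNV for each guide", call. = FALSE)
  }
  distal_snv <- blocking[which.max(abs(snvs$position[blocking] - varpos))]
  partial <- snvs[-distal_snv, ]
  ## the nick-site deletion sits on the proximal guide's nick
  pair <- locus$guides
  dL <- abs(pair$left$nick_position - varpos)
  dR <- abs(pair$right$nick_position - varpos)
  nick <- if (dL <= dR) pair$left$nick_position else pair$right$nick_position
  half <- indel_len %/% 2L
  mixture_spec(
    allele_spec("perfect_hdr", snvs = snvs, weight = weights[["perfect_hdr"]]),
    allele_spec("imperfect_hdr", snvs = partial,
                weight = weights[["imperfect_hdr"]]),
    allele_spec("nick_indel",
                indels = list(list(position = nick - half, del = indel_len)),
                weight = weights[["nick_indel"]]),
    allele_spec("unedited_T", weight = weights[["unedited_T"]]),
    allele_spec("nontarget_C",
                snvs = planned_snv(varpos, pv$ref_base, pv$alt_base,
                                   "correction"),
                weight = weights[["nontarget_C"]])
  )
}

#' Large-deletion mixture for the long-amplicon experiment
#'
#' Plants three deletion alleles on the target background: a 1.5-kb deletion
#' distal to the short amplicon, a 6-kb deletion spanning the variant that
#' removes both short-amplicon primer sites (and therefore evades
#' short-amplicon genotyping), and a 300-bp deletion interior to the short
#' amplicon (the target exon).
#'
#' @param locus A [reference_locus()] (full-size geometry).
#' @param weights Named weights for intact / del1500 / del6000 / del300.
#' @return A [mixture_spec()].
#' @export
large_deletion_mixture <- function(locus,
                                   weights = c(intact = 0.80, del1500 = 0.10,
                                               del6000 = 0.05, del300 = 0.05)) {
  v <- locus$pathogenic_variant$position
  mixture_spec(
    allele_spec("intact", weight = weights[["intact"]]),
    allele_spec("del1500", deletion = c(v + 400L, v + 1899L),
                weight = weights[["del1500"]]),
    allele_spec("del6000", deletion = c(v - 3000L, v + 2999L),
                weight = weights[["del6000"]]),
    allele_spec("del300", deletion = c(v - 150L, v + 149L),
                weight = weights[["del300"]])
  )
}
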