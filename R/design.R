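## Dual-nickase guide-pair enumeration and ssODN repair-template design.
##
## Templates carry an ordered SNV set: the corrective edit at the pathogenic
## position, one silent "blocking" SNV per guide (inside the guide's
## PAM-proximal seed or PAM, so the repaired allele can no longer be nicked)
## and, for the low/medium/full series, silent "bridging" SNVs between the
## proximal nick and the correction site (more bridging SNVs pull the distal
## edit along with the conversion tract).

#' Enumerate PAM-out nickase guide pairs around the pathogenic variant
#'
#' Scans both strands of `window` for NGG-adjacent 20-mers, keeps pairs whose
#' left guide is on "-" and right guide on "+" (PAMs facing away from the
#' inter-nick segment), whose nick-to-nick offset falls in `offset_range`,
#' and whose inter-nick segment contains the pathogenic variant. Pairs are
#' sorted by closeness of their offset to the midpoint of `offset_range`.
#'
#' @param locus A [reference_locus()].
#' @param window `(start, end)` locus interval to scan; must contain the
#'   pathogenic variant. Defaults to the short amplicon interval.
#' @param offset_range `(min, max)` allowed nick-to-nick distance in bp.
#' @return List of [guide_pair()] objects (possibly empty).
#' @export
find_pam_out_pairs <- function(locus, window = locus$short_amplicon$interval,
                               offset_range = c(40L, 100L)) {
  stopifnot(inherits(locus, "reference_locus"))
  window <- check_interval(window, "window")
  n <- nchar(locus$sequence)
  if (window[2L] > n) stop("window falls outside the locus", call. = FALSE)
  if (offset_range[1L] < 0L || offset_range[1L] > offset_range[2L]) {
    stop("offset_range must be a non-negative (min, max) pair", call. = FALSE)
  }
  varpos <- locus$pathogenic_variant$position
  if (varpos < window[1L] || varpos > window[2L]) {
    stop("window must contain the pathogenic variant", call. = FALSE)
  }
  seq <- locus$sequence
  chars <- strsplit(seq, "")[[1L]]

  ## "+" guides: protospacer [s, s+19], PAM NGG at [s+20, s+22]
  gg <- which(chars == "G")
  plus_pam <- gg[gg + 1L <= n & chars[pmin(gg + 1L, n)] == "G"] - 1L # PAM start p: GG at p+1,p+2
  plus_start <- plus_pam - 20L
  keep <- plus_start >= window[1L] & (plus_pam + 2L) <= window[2L] &
    plus_start >= 1L
  plus_start <- plus_start[keep]

  ## "-" guides: protospacer on locus [s, s+19], PAM = CC at [s-3, s-2]
  cc <- which(chars == "C")
  minus_pam_cc <- cc[cc + 1L <= n & chars[pmin(cc + 1L, n)] == "C"]
  minus_start <- minus_pam_cc + 3L
  keep <- (minus_start - 3L) >= window[1L] & (minus_start + 19L) <= window[2L] &
    (minus_start + 19L) <= n
  minus_start <- minus_start[keep]

  mk_guide <- function(s, strand) {
    fp <- substr(seq, s, s + 19L)
    proto <- if (strand == "+") fp else revcomp(fp)
    guide(proto, start = s, strand = strand, locus = locus)
  }

  pairs <- list()
  mid <- mean(offset_range)
  for (sL in minus_start) {
    gL <- mk_guide(sL, "-")
    for (sR in plus_start) {
      gR <- mk_guide(sR, "+")
      if (gL$nick_position >= gR$nick_position) next
      offset <- gR$nick_position - gL$nick_position
      if (offset < offset_range[1L] || offset > offset_range[2L]) next
      if (!(varpos > gL$nick_position && varpos <= gR$nick_position)) next
      pairs[[length(pairs) + 1L]] <- guide_pair(gL, gR)
    }
  }
  if (!length(pairs)) return(pairs)
  ord <- order(vapply(pairs, function(p) abs(p$offset - mid), numeric(1)),
               vapply(pairs, function(p) p$left$nick_position, numeric(1)))
  pairs[ord]
}

#' Is a substitution translationally silent?
#'
#' Translates the codon containing the substitution, in frame per the locus
#' CDS model, with and without the change.
#'
#' @param locus A [reference_locus()].
#' @param position Locus coordinate of the substitution (must be exonic).
#' @param alt_base Proposed base.
#' @return `TRUE` iff the amino acid is unchanged.
#' @export
verify_silent <- function(locus, position, alt_base) {
  alt_base <- toupper(alt_base)
  if (is.na(exon_index_of(locus, position))) {
    stop("position ", position, " is not inside an annotated exon",
         call. = FALSE)
  }
  cod <- codon_at(locus, position)
  if (is.null(cod)) {
    stop("position ", position,
         " falls in a partial codon outside the locus CDS model",
         call. = FALSE)
  }
  ref_base <- substr(locus$sequence, position, position)
  if (alt_base == ref_base) {
    stop("alt_base equals the reference base", call. = FALSE)
  }
  alt_codon <- cod$codon
  substr(alt_codon, cod$codon_pos, cod$codon_pos) <- alt_base
  translate_dna(cod$codon) == translate_dna(alt_codon)
}

## a planned SNV row
planned_snv <- function(position, ref_base, alt_base, role,
                        guide_id = NA_character_, silent = NA) {
  data.frame(position = as.integer(position), ref_base = ref_base,
             alt_base = alt_base, role = role, guide_id = guide_id,
             silent = silent, stringsAsFactors = FALSE)
}

apply_snvs <- function(sequence, snvs) {
  ch <- strsplit(sequence, "")[[1L]]
  if (nrow(snvs)) {
    stopifnot(all(ch[snvs$position] == snvs$ref_base))
    ch[snvs$position] <- snvs$alt_base
  }
  paste(ch, collapse = "")
}

## would applying `snvs` create a *new* NGG PAM (either strand) overlapping
## either guide's footprint/PAM region?
creates_new_pam <- function(locus, pair, snvs) {
  regions <- lapply(list(pair$left, pair$right), function(g) {
    r <- range(c(g$footprint, g$pam_interval))
    c(max(1L, r[1L] - 1L), min(nchar(locus$sequence), r[2L] + 1L))
  })
  after_full <- apply_snvs(locus$sequence, snvs)
  for (region in regions) {
    before <- substr(locus$sequence, region[1L], region[2L])
    after <- substr(after_full, region[1L], region[2L])
    pam_sites <- function(s) {
      f <- gregexpr("(?=GG)", s, perl = TRUE)[[1L]]
      r <- gregexpr("(?=CC)", s, perl = TRUE)[[1L]]
      c(paste0("+", f[f > 0]), paste0("-", r[r > 0]))
    }
    if (length(setdiff(pam_sites(after), pam_sites(before))) > 0L) {
      return(TRUE)
    }
  }
  FALSE
}

## candidate silent substitutions at one position, preference-ordered:
## transitions before transversions, then alphabetical
silent_alternatives <- function(locus, position) {
  if (is.na(exon_index_of(locus, position))) return(character(0))
  if (is.null(codon_at(locus, position))) return(character(0))
  ref <- substr(locus$sequence, position, position)
  cands <- setdiff(DNA_BASES, ref)
  ok <- cands[vapply(cands, function(b) verify_silent(locus, position, b),
                     logical(1))]
  if (!length(ok)) return(character(0))
  transition <- c(A = "G", G = "A", C = "T", T = "C")[[ref]]
  ok[order(ok != transition, ok)]
}

## seed positions of a guide: the 10 protospacer bases adjacent to the PAM,
## ordered PAM-proximal first; pam_gg = the two locus positions encoding the
## PAM GG
guide_seed_positions <- function(g) {
  if (g$strand == "+") {
    list(seed = seq(g$footprint[2L], g$footprint[2L] - 9L),
         pam_gg = c(g$pam_interval[1L] + 1L, g$pam_interval[2L]))
  } else {
    list(seed = seq(g$footprint[1L], g$footprint[1L] + 9L),
         pam_gg = c(g$pam_interval[2L] - 1L, g$pam_interval[1L]))
  }
}

## deterministic blocking-SNV choice for one guide. Seed positions are
## preferred over the PAM GG; within a tier: third codon position first,
## then transition, then PAM proximity.
choose_blocking_snv <- function(locus, pair, g, taken) {
  sp <- guide_seed_positions(g)
  tiers <- list(seed = sp$seed, pam = sp$pam_gg)
  best <- NULL
  for (tier_i in seq_along(tiers)) {
    cands <- list()
    for (rank in seq_along(tiers[[tier_i]])) {
      pos <- tiers[[tier_i]][rank]
      if (pos %in% taken) next
      alts <- silent_alternatives(locus, pos)
      for (alt_i in seq_along(alts)) {
        cod <- codon_at(locus, pos)
        cands[[length(cands) + 1L]] <- list(
          pos = pos, alt = alts[alt_i],
          key = c(cod$codon_pos != 3L, alt_i, rank))
      }
    }
    if (!length(cands)) next
    keys <- t(vapply(cands, `[[`, numeric(3), "key"))
    for (i in order(keys[, 1L], keys[, 2L], keys[, 3L])) {
      snv <- planned_snv(cands[[i]]$pos,
                        substr(locus$sequence, cands[[i]]$pos, cands[[i]]$pos),
                        cands[[i]]$alt, "blocking", g$id, silent = TRUE)
      if (!creates_new_pam(locus, pair, snv)) return(snv)
    }
  }
  NULL
}

#' Design an ssODN repair template
#'
#' The template is centred on the pathogenic variant with the requested total
#' length and carries: the corrective SNV; exactly one silent blocking SNV in
#' each guide's seed/PAM; and, for levels `low`/`medium`/`full`, 1/2/all
#' available silent bridging SNVs between the proximal nick (the nick closest
#' to the variant) and the correction site, ordered nick-proximal first.
#' Homology arms are measured from the outermost planned SNV to the template
#' ends and must each reach `arm_length`.
#'
#' @param locus A [reference_locus()].
#' @param pair A [guide_pair()] (PAM-out) flanking the variant.
#' @param bridging_level One of `"blocking"`, `"low"`, `"medium"`, `"full"`.
#' @param total_length Template length in nt (classic compact designs use 132).
#' @param arm_length Minimum homology-arm length in bp (default 40).
#' @return Object of class `repair_template` with fields `name`, `sequence`
#'   (locus-forward), `strand` (emission strand: complementary to the
#'   proximal guide's non-target strand), `locus_interval`, `snvs`
#'   (ordered data.frame) and `arm_lengths`.
#' @export
design_template <- function(locus, pair,
                            bridging_level = c("blocking", "low", "medium", "full"),
                            total_length = 132L, arm_length = 40L) {
  stopifnot(inherits(locus, "reference_locus"), inherits(pair, "guide_pair"))
  bridging_level <- match.arg(bridging_level)
  total_length <- as.integer(total_length)
  arm_length <- as.integer(arm_length)
  if (total_length < 2L * arm_length) {
    stop("total_length must be at least twice arm_length", call. = FALSE)
  }
  varpos <- locus$pathogenic_variant$position
  if (!(varpos > pair$left$nick_position && varpos <= pair$right$nick_position)) {
    stop("pathogenic variant must lie between the two nicks", call. = FALSE)
  }

  start <- varpos - (total_length - 1L) %/% 2L
  end <- start + total_length - 1L
  if (start < 1L || end > nchar(locus$sequence)) {
    stop("template interval extends beyond the locus", call. = FALSE)
  }

  snvs <- planned_snv(varpos, locus$pathogenic_variant$ref_base,
                      locus$pathogenic_variant$alt_base, "correction",
                      silent = FALSE)

  for (g in list(pair$left, pair$right)) {
    blk <- choose_blocking_snv(locus, pair, g, taken = snvs$position)
    if (is.null(blk)) {
      stop(sprintf(
        "design infeasible: no silent blocking substitution available in the seed or PAM of guide %s",
        g$id), call. = FALSE)
    }
    snvs <- rbind(snvs, blk)
  }

  ## proximal guide: nick closest to the variant (ties -> right guide)
  dL <- abs(pair$left$nick_position - varpos)
  dR <- abs(pair$right$nick_position - varpos)
  proximal <- if (dR <= dL) pair$right else pair$left
  nick <- proximal$nick_position
  bridge_region <- sort(c(nick, varpos))
  n_bridge <- switch(bridging_level, blocking = 0L, low = 1L, medium = 2L,
                     full = Inf)
  if (n_bridge > 0L) {
    cand_pos <- setdiff(seq(bridge_region[1L] + 1L, bridge_region[2L] - 1L),
                        snvs$position)
    cand_pos <- cand_pos[order(abs(cand_pos - nick))]  # nick-proximal first
    added <- 0L
    for (pos in cand_pos) {
      if (added >= n_bridge) break
      alts <- silent_alternatives(locus, pos)
      for (alt in alts) {
        snv <- planned_snv(pos, substr(locus$sequence, pos, pos), alt,
                           "bridging", proximal$id, silent = TRUE)
        if (!creates_new_pam(locus, pair, rbind(snvs, snv))) {
          snvs <- rbind(snvs, snv)
          added <- added + 1L
          break
        }
      }
    }
    if (bridging_level %in% c("low", "medium") && added < n_bridge) {
      stop("design infeasible: only ", added,
           " silent bridging site(s) available between nick and variant",
           call. = FALSE)
    }
  }

  snvs <- snvs[order(snvs$position), ]
  rownames(snvs) <- NULL
  if (any(snvs$position < start | snvs$position > end)) {
    stop("design infeasible: planned SNVs fall outside the template interval",
         call. = FALSE)
  }
  arms <- c(left = min(snvs$position) - start,
            right = end - max(snvs$position))
  if (any(arms < arm_length)) {
    stop(sprintf(
      "design infeasible: homology arms (%d/%d bp) shorter than %d bp; increase total_length",
      arms[1L], arms[2L], arm_length), call. = FALSE)
  }

  local <- snvs
  local$position <- local$position - start + 1L
  sequence <- apply_snvs(substr(locus$sequence, start, end), local)

  ## ssODN emitted complementary to the proximal guide's non-target (PAM)
  ## strand, i.e. on the guide's target strand
  strand <- if (proximal$strand == "+") "-" else "+"

  tpl <- structure(
    list(name = bridging_level, sequence = sequence, strand = strand,
         locus_interval = c(start, end), snvs = snvs,
         arm_lengths = as.integer(arms)),
    class = "repair_template"
  )
  rn <- renick_check(tpl, pair, locus)
  if (!all(rn)) {
    stop("design infeasible: corrected allele still matches guide(s) ",
         paste(names(rn)[!rn], collapse = ", "), call. = FALSE)
  }
  tpl
}

#' @export
print.repair_template <- function(x, ...) {
  cat(sprintf("<repair_template '%s': %d nt @ %d-%d, arms %d/%d bp, %d SNV(s)>\n",
              x$name, nchar(x$sequence), x$locus_interval[1L],
              x$locus_interval[2L], x$arm_lengths[1L], x$arm_lengths[2L],
              nrow(x$snvs)))
  print(x$snvs)
  invisible(x)
}

#' Would the corrected allele still be nicked?
#'
#' Applies the template SNVs to the locus and asks, per guide, whether the
#' protospacer still matches exactly on its strand with an intact NGG PAM.
#'
#' @param template A `repair_template`.
#' @param pair The [guide_pair()].
#' @param locus The [reference_locus()].
#' @return Named logical vector, `TRUE` = renicking prevented for that guide.
#' @export
renick_check <- function(template, pair, locus) {
  corrected <- apply_snvs(locus$sequence, template$snvs)
  chk <- function(g) {
    fp <- substr(corrected, g$footprint[1L], g$footprint[2L])
    pam <- substr(corrected, g$pam_interval[1L], g$pam_interval[2L])
    if (g$strand == "-") {
      fp <- revcomp(fp)
      pam <- revcomp(pam)
    }
    !(fp == g$protospacer && substr(pam, 2L, 3L) == "GG")
  }
  c(left = chk(pair$left), right = chk(pair$right))
}

#' Export a repair-template design
#'
#' Writes the template FASTA (on its emission strand) and a JSON design
#' report with the SNV table and codon context.
#'
#' @param template A `repair_template`.
#' @param locus The [reference_locus()].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_template_report <- function(template, locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emitted <- if (template$strand == "-") revcomp(template$sequence)
  else template$sequence
  fa <- file.path(dir, paste0("ssODN_", template$name, ".fa"))
  write_fasta(setNames(emitted, paste0("ssODN_", template$name)), fa)
  snvs <- template$snvs
  snvs$codon <- vapply(snvs$position, function(p) {
    cod <- codon_at(locus, p)
    if (is.null(cod)) NA_character_ else cod$codon
  }, character(1))
  js <- file.path(dir, paste0("ssODN_", template$name, ".json"))
  jsonlite::write_json(
    list(name = template$name, strand = template$strand,
         locus_interval = template$locus_interval,
         arm_lengths = template$arm_lengths, snvs = snvs),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, json = js))
}
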