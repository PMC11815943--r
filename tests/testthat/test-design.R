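test_that("planted PAM-out pair at 66 bp offset is found and ranked first", {
  pairs <- find_pam_out_pairs(fix_locus, window = c(5550, 5750),
                              offset_range = c(60, 72))
  expect_gt(length(pairs), 0)
  top <- pairs[[1]]
  expect_equal(top$offset, 66)
  expect_equal(top$orientation, "PAM-out")
  expect_equal(top$left$nick_position, 5620)
  expect_equal(top$right$nick_position, 5686)
  # variant strictly between the nicks for every pair
  v <- fix_locus$pathogenic_variant$position
  for (p in pairs) {
    expect_true(p$left$nick_position < v && v <= p$right$nick_position)
  }
})

test_that("pair enumeration matches brute force and degenerate inputs behave", {
  window <- c(5500, 5800)
  impl <- find_pam_out_pairs(fix_locus, window, offset_range = c(40, 100))
  oracle <- oracle_pam_out_pairs(fix_locus, window, c(40, 100))
  key <- function(l, r) paste(l, r)
  impl_keys <- sort(vapply(impl, function(p)
    key(p$left$footprint[1], p$right$footprint[1]), character(1)))
  oracle_keys <- sort(vapply(oracle, function(o)
    key(o["left"], o["right"]), character(1)))
  expect_identical(impl_keys, oracle_keys)

  # no G at all -> no "+" guide -> empty
  amp <- function(a, b, c, d) amplicon_def(c(a, b), c(c, d))
  noG <- reference_locus(
    "noG", paste(rep("ACT", 100), collapse = ""), exons = list(c(50, 250)),
    pathogenic_variant = list(position = 151, ref_base = "A", alt_base = "G"),
    short_amplicon = amp(40, 50, 250, 260), long_amplicon = amp(10, 20, 280, 290))
  expect_length(find_pam_out_pairs(noG, c(50, 250), c(10, 150)), 0)

  # window that excludes the variant is a precondition error
  expect_error(find_pam_out_pairs(fix_locus, c(5700, 5800), c(40, 100)),
               "variant")
})

test_that("verify_silent agrees with a full-CDS translation oracle", {
  set.seed(401)
  loc <- fix_toy
  exon <- loc$exons[[1]]
  checked <- 0
  while (checked < 200) {
    pos <- sample(exon[1]:exon[2], 1)
    ref <- substr(loc$sequence, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- tryCatch(verify_silent(loc, pos, alt), error = function(e) NA)
    if (is.na(got)) next           # trimmed partial codon
    expect_identical(got, oracle_is_silent(loc, pos, alt))
    checked <- checked + 1
  }
  # textbook cases: CTG->CTC leucine stays, ATG->TTG does not
  expect_error(verify_silent(loc, 5, "A"), "exon")   # intronic
})

test_that("template series is deterministic, nested and renick-proof", {
  levels <- c("blocking", "low", "medium", "full")
  tpls <- lapply(levels, function(lv) {
    design_template(fix_locus, fix_locus$guides, lv, total_length = 180,
                    arm_length = 40)
  })
  names(tpls) <- levels
  # deterministic
  again <- design_template(fix_locus, fix_locus$guides, "medium",
                           total_length = 180, arm_length = 40)
  expect_identical(again, tpls$medium)
  # blocking level: roles exactly correction + 2 blocking
  expect_equal(sort(tpls$blocking$snvs$role),
               sort(c("correction", "blocking", "blocking")))
  # nesting of position sets and non-decreasing counts
  sets <- lapply(tpls, function(t) t$snvs$position)
  for (i in 1:3) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
    expect_lte(length(sets[[i]]), length(sets[[i + 1]]))
  }
  expect_equal(length(sets$low), length(sets$blocking) + 1)
  expect_equal(length(sets$medium), length(sets$blocking) + 2)
  for (tpl in tpls) {
    # silent verification for every non-correction SNV
    sil <- tpl$snvs[tpl$snvs$role != "correction", ]
    for (i in seq_len(nrow(sil))) {
      expect_true(verify_silent(fix_locus, sil$position[i], sil$alt_base[i]))
    }
    # both guides blocked from renicking
    expect_true(all(renick_check(tpl, fix_locus$guides, fix_locus)))
    # geometry
    expect_equal(nchar(tpl$sequence), 180)
    expect_true(all(tpl$arm_lengths >= 40))
    # sequence equals locus subsequence with exactly the SNVs applied
    local <- tpl$snvs
    local$position <- local$position - tpl$locus_interval[1] + 1
    expect_identical(tpl$sequence, nickhdr:::apply_snvs(
      substr(fix_locus$sequence, tpl$locus_interval[1], tpl$locus_interval[2]),
      local))
  }
})

test_that("corrected haplotype translates to the wild-type protein", {
  tpl <- design_template(fix_locus, fix_locus$guides, "full",
                         total_length = 180)
  corrected <- nickhdr:::apply_snvs(fix_locus$sequence, tpl$snvs)
  # wild type: only the correction applied
  corr_only <- tpl$snvs[tpl$snvs$role == "correction", ]
  wildtype <- nickhdr:::apply_snvs(fix_locus$sequence, corr_only)
  splice_translate <- function(seq) {
    spl <- paste(vapply(fix_locus$exons, function(e) substr(seq, e[1], e[2]),
                        character(1)), collapse = "")
    nickhdr:::translate_dna(spl)
  }
  expect_identical(splice_translate(corrected), splice_translate(wildtype))
  # and the correction removes the premature stop at the variant codon
  v <- fix_locus$pathogenic_variant$position
  codon_aa <- function(seq) {
    nickhdr:::translate_dna(substr(seq, v, v + 2))
  }
  expect_identical(codon_aa(fix_locus$sequence), "*")
  expect_identical(codon_aa(corrected), "R")
})

test_that("renick_check agrees with direct string matching under random SNV removal", {
  set.seed(402)
  pair <- fix_locus$guides
  tpl <- design_template(fix_locus, fix_locus$guides, "blocking",
                         total_length = 180)
  oracle_renick <- function(snvs) {
    corrected <- nickhdr:::apply_snvs(fix_locus$sequence, snvs)
    chk <- function(g) {
      fp <- substr(corrected, g$footprint[1], g$footprint[2])
      pam <- substr(corrected, g$pam_interval[1], g$pam_interval[2])
      if (g$strand == "-") { fp <- revcomp(fp); pam <- revcomp(pam) }
      !(fp == g$protospacer && substr(pam, 2, 3) == "GG")
    }
    c(left = chk(pair$left), right = chk(pair$right))
  }
  # full template: both prevented
  expect_equal(renick_check(tpl, pair, fix_locus), c(left = TRUE, right = TRUE))
  # blocking SNVs removed: neither prevented
  naked <- tpl
  naked$snvs <- tpl$snvs[tpl$snvs$role == "correction", ]
  expect_equal(renick_check(naked, pair, fix_locus),
               c(left = FALSE, right = FALSE))
  # random subsets agree with the oracle
  for (i in 1:20) {
    sub <- tpl
    keep <- runif(nrow(tpl$snvs)) < 0.5
    sub$snvs <- tpl$snvs[keep, , drop = FALSE]
    expect_equal(renick_check(sub, pair, fix_locus),
                 oracle_renick(sub$snvs))
  }
})

test_that("infeasible geometry raises a design error naming the problem", {
  # 132-nt template with 40-bp arms cannot host the 66-bp-offset pair's SNVs
  expect_error(
    design_template(fix_locus, fix_locus$guides, "blocking",
                    total_length = 132, arm_length = 40),
    "arms")
  expect_error(
    design_template(fix_locus, fix_locus$guides, "blocking",
                    total_length = 60, arm_length = 40),
    "twice")
})

test_that("132-nt template with 40-bp arms is feasible on the compact pair", {
  tpl <- design_template(fix_toy, fix_toy$guides, "blocking",
                         total_length = 132, arm_length = 40)
  expect_equal(nchar(tpl$sequence), 132)
  expect_true(all(tpl$arm_lengths >= 40))
  expect_equal(sum(tpl$snvs$role == "correction"), 1)
})
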