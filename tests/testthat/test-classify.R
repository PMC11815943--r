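# classification decision rules, exercised through constructed alleles with
# zero sequencing error so each expected category is forced, then through a
# noisy truth-table round trip

toy_pipeline <- function(mix, n, error = error_model(0, 0, 0), seed = 600) {
  sim <- simulate_amplicon_reads(fix_locus, mix, fix_locus$short_amplicon, n,
                                 error = error, seed = seed)
  res <- classify_amplicon(sim$reads, fix_locus, fix_template, min_reads = 10)
  list(sim = sim, res = res)
}

test_that("constructed alleles force each category", {
  tpl <- fix_template
  pair <- fix_locus$guides
  snvs <- tpl$snvs
  silent <- snvs[snvs$role != "correction", ]
  corr <- snvs[snvs$role == "correction", ]
  mk <- function(name, ...) allele_spec(name, ..., weight = 1)
  cases <- list(
    # all template SNVs, no indel -> perfect
    list(mk("a", snvs = snvs), "perfect_hdr"),
    # blocking SNVs but ref at the correction -> imperfect
    list(mk("b", snvs = silent), "imperfect_hdr"),
    # one silent SNV only -> imperfect
    list(mk("c", snvs = silent[1, ]), "imperfect_hdr"),
    # all SNVs plus an in-window indel -> imperfect
    list(mk("d", snvs = snvs,
            indels = list(list(position = pair$right$nick_position + 2,
                               del = 6))), "imperfect_hdr"),
    # indel only -> indel
    list(mk("e", indels = list(list(position = pair$right$nick_position - 2,
                                    ins = "TTTTT"))), "indel"),
    # correction base alone (non-target allele) -> unedited
    list(mk("f", snvs = corr), "unedited"),
    # nothing -> unedited
    list(mk("g"), "unedited"),
    # correction base + indel (non-target allele with indel) -> indel
    list(mk("h", snvs = corr,
            indels = list(list(position = pair$left$nick_position, del = 5))),
         "indel")
  )
  for (cs in cases) {
    sim <- simulate_amplicon_reads(fix_locus, mixture_spec(cs[[1]]),
                                   fix_locus$short_amplicon, 4,
                                   error = error_model(0, 0, 0), seed = 601)
    res <- classify_amplicon(sim$reads, fix_locus, fix_template, min_reads = 1)
    expect_equal(unique(res$calls$category), cs[[2]],
                 label = paste("allele", cs[[1]]$name))
  }
})

test_that("sub-threshold indels and off-SNV substitutions never change the category", {
  tpl <- fix_template
  pair <- fix_locus$guides
  # 2-bp deletion in window (below min_indel_len = 3) on an unedited allele
  a <- allele_spec("x", indels = list(list(position = pair$left$nick_position,
                                           del = 2)), weight = 1)
  sim <- simulate_amplicon_reads(fix_locus, mixture_spec(a),
                                 fix_locus$short_amplicon, 3,
                                 error = error_model(0, 0, 0), seed = 602)
  res <- classify_amplicon(sim$reads, fix_locus, tpl, min_reads = 1)
  expect_equal(unique(res$calls$category), "unedited")
  # substitution away from any planned SNV, inside the window
  v <- fix_locus$pathogenic_variant$position
  pos <- v + 10
  b <- allele_spec("y", snvs = data.frame(
    position = pos, ref_base = substr(fix_locus$sequence, pos, pos),
    alt_base = setdiff(c("A", "C", "G", "T"),
                       substr(fix_locus$sequence, pos, pos))[1]), weight = 1)
  sim2 <- simulate_amplicon_reads(fix_locus, mixture_spec(b),
                                  fix_locus$short_amplicon, 3,
                                  error = error_model(0, 0, 0), seed = 603)
  res2 <- classify_amplicon(sim2$reads, fix_locus, tpl, min_reads = 1)
  expect_equal(unique(res2$calls$category), "unedited")
})

test_that("zero-error truth-table round trip is classified perfectly", {
  p <- toy_pipeline(hdr_outcome_mixture(fix_locus, fix_template), 600)
  expect_true(all(p$res$calls$category ==
                    allele_truth_category[p$sim$truth$allele]))
  # categories exclusive and exhaustive over retained reads
  s <- p$res$summary
  expect_equal(sum(s$fractions), 1, tolerance = 1e-9)
  expect_equal(s$n_retained, 600)
  expect_lte(s$total_editing, 1)
})

test_that("summary matches hand-counted tallies on a small fixture", {
  p <- toy_pipeline(hdr_outcome_mixture(fix_locus, fix_template), 50,
                    seed = 604)
  s <- p$res$summary
  hand <- table(factor(allele_truth_category[p$sim$truth$allele],
                       names(s$fractions)))
  expect_equal(unname(s$counts), unname(as.integer(hand)))
  expect_equal(unname(s$fractions), unname(as.integer(hand) / 50))
  expect_true(summarize_outcomes(p$res$calls)$low_coverage)  # 50 < 10,000
  expect_false(summarize_outcomes(p$res$calls, min_reads = 50)$low_coverage)
  expect_error(summarize_outcomes(p$res$calls[0, ]), "empty")
})

test_that("per-SNV incorporation recovers mixture fractions and ordering", {
  # 50% full-template allele, zero error -> every SNV at 0.5
  mix <- mixture_spec(
    allele_spec("hdr", snvs = fix_template$snvs, weight = 0.5),
    allele_spec("wt", weight = 0.5))
  p <- toy_pipeline(mix, 400, seed = 605)
  inc <- p$res$summary$snv_incorporation
  truth <- mean(p$sim$truth$allele == "hdr")
  for (i in seq_len(nrow(inc))) {
    expect_equal(inc$incorporation[i], truth, tolerance = 1e-9)
  }
  # gradient fixture: proximal SNVs incorporated more often than distal ones
  tpl <- design_template(fix_locus, fix_locus$guides, "medium",
                         total_length = 180)
  s <- tpl$snvs
  bridge <- s[s$role == "bridging", ]
  bridge <- bridge[order(bridge$position), ]
  grad <- mixture_spec(
    allele_spec("full", snvs = s, weight = 0.4),
    allele_spec("partial", snvs = s[s$position <= bridge$position[1] |
                                      s$role == "correction", ], weight = 0.3),
    allele_spec("wt", weight = 0.3))
  sim <- simulate_amplicon_reads(fix_locus, grad, fix_locus$short_amplicon,
                                 500, error = error_model(0, 0, 0), seed = 606)
  alns <- align_reads(sim$reads, fix_locus)
  calls <- classify_reads(alns, tpl, quant_window(fix_locus$guides), fix_locus)
  inc2 <- snv_incorporation(calls)
  first_bridge <- inc2$incorporation[inc2$position == bridge$position[1]]
  distal_block <- inc2$incorporation[inc2$role == "blocking" &
                                       inc2$guide_id == "sg2"]
  expect_gt(first_bridge, distal_block)
})

test_that("perfect-HDR fraction never exceeds any single SNV incorporation", {
  p <- toy_pipeline(hdr_outcome_mixture(fix_locus, fix_template), 500,
                    error = error_model(), seed = 607)
  s <- p$res$summary
  for (i in seq_len(nrow(s$snv_incorporation))) {
    expect_lte(s$fractions[["perfect_hdr"]],
               s$snv_incorporation$incorporation[i] + 1e-9)
  }
})

test_that("window-uncovered and rejected reads are discarded with reasons", {
  amp <- fix_locus$short_amplicon
  ref <- substr(fix_locus$sequence, amp$interval[1], amp$interval[2])
  frag <- substr(ref, 1, 120)        # too short to pass the span filter
  alns <- align_reads(c(frag = frag), fix_locus)
  calls <- classify_reads(alns, fix_template, quant_window(fix_locus$guides),
                          fix_locus)
  expect_equal(calls$category, "discarded")
  expect_match(calls$reason, "span")
  # retained read whose span misses the window: lower the filter to force it
  alns2 <- align_reads(c(frag = frag), fix_locus, min_span = 0.1)
  expect_true(alns2$frag$retained)
  calls2 <- classify_reads(alns2, fix_template, quant_window(fix_locus$guides),
                           fix_locus)
  expect_equal(calls2$category, "discarded")
  expect_equal(calls2$reason, "window_uncovered")
})
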