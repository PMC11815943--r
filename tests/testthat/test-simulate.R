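test_that("build_allele applies edits with correct coordinate shifting", {
  loc <- fix_toy
  # identity
  empty <- build_allele(loc, allele_spec("wt"))
  expect_identical(as.character(empty), loc$sequence)
  # large deletion shrinks by exactly its width
  del <- build_allele(loc, allele_spec("d", deletion = c(100, 299)))
  expect_equal(nchar(del), nchar(loc$sequence) - 200)
  # coord map: position after the deletion maps back by 200
  map <- attr(del, "coord_map")
  expect_true(all(is.na(map[100:299])))
  expect_equal(map[300], 100)
  # overlapping edits are an input error
  expect_error(
    build_allele(loc, allele_spec("bad",
      indels = list(list(position = 150, del = 20)),
      deletion = c(160, 300))),
    "overlapping")
})

test_that("build_allele equals a naive one-edit-at-a-time oracle", {
  set.seed(501)
  loc <- fix_toy
  n <- nchar(loc$sequence)
  naive_apply <- function(seq, spec) {
    # apply edits right-to-left so earlier coordinates stay valid
    edits <- list()
    if (!is.null(spec$snvs)) {
      for (i in seq_len(nrow(spec$snvs))) {
        edits[[length(edits) + 1]] <- list(pos = spec$snvs$position[i],
                                           type = "snv",
                                           alt = spec$snvs$alt_base[i])
      }
    }
    for (ind in spec$indels) {
      edits[[length(edits) + 1]] <-
        if (!is.null(ind$del)) list(pos = ind$position, type = "del",
                                    len = ind$del)
        else list(pos = ind$position, type = "ins", seq = ind$ins)
    }
    if (!is.null(spec$deletion)) {
      edits[[length(edits) + 1]] <- list(pos = spec$deletion[1], type = "del",
                                         len = spec$deletion[2] - spec$deletion[1] + 1)
    }
    edits <- edits[order(-vapply(edits, `[[`, numeric(1), "pos"))]
    for (e in edits) {
      seq <- switch(e$type,
        snv = paste0(substr(seq, 1, e$pos - 1), e$alt,
                     substr(seq, e$pos + 1, nchar(seq))),
        del = paste0(substr(seq, 1, e$pos - 1),
                     substr(seq, e$pos + e$len, nchar(seq))),
        ins = paste0(substr(seq, 1, e$pos), e$seq,
                     substr(seq, e$pos + 1, nchar(seq))))
    }
    seq
  }
  for (i in 1:25) {
    pos <- sort(sample(seq(10, n - 60, by = 1), 4))
    # keep edits separated to respect the non-overlap invariant
    while (any(diff(pos) < 15)) pos <- sort(sample(seq(10, n - 60), 4))
    spec <- allele_spec(
      "rnd",
      snvs = data.frame(position = pos[1],
                        ref_base = substr(loc$sequence, pos[1], pos[1]),
                        alt_base = sample(setdiff(c("A", "C", "G", "T"),
                                                  substr(loc$sequence, pos[1], pos[1])), 1)),
      indels = list(list(position = pos[2], ins = nickhdr:::random_dna(sample(1:6, 1))),
                    list(position = pos[3], del = sample(1:8, 1))),
      deletion = c(pos[4], pos[4] + sample(5:40, 1)))
    expect_identical(as.character(build_allele(loc, spec)),
                     naive_apply(loc$sequence, spec))
  }
})

test_that("same seed gives byte-identical FASTQ; different seed does not", {
  loc <- fix_toy
  mix <- het_baseline_mixture(loc)
  dir <- withr::local_tempdir()
  s1 <- simulate_amplicon_reads(loc, mix, loc$short_amplicon, 50, seed = 9)
  s2 <- simulate_amplicon_reads(loc, mix, loc$short_amplicon, 50, seed = 9)
  s3 <- simulate_amplicon_reads(loc, mix, loc$short_amplicon, 50, seed = 10)
  f1 <- write_fastq(s1$reads, file.path(dir, "a.fastq"))
  f2 <- write_fastq(s2$reads, file.path(dir, "b.fastq"))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("zero-error reads equal their allele's amplicon product", {
  loc <- fix_toy
  mix <- het_baseline_mixture(loc)
  sim <- simulate_amplicon_reads(loc, mix, loc$short_amplicon, 60,
                                 error = error_model(0, 0, 0), seed = 12)
  amp <- loc$short_amplicon
  ref_T <- substr(loc$sequence, amp$interval[1], amp$interval[2])
  ref_C <- ref_T
  local <- loc$pathogenic_variant$position - amp$interval[1] + 1
  substr(ref_C, local, local) <- "C"
  for (i in seq_along(sim$reads)) {
    want <- if (sim$truth$allele[i] == "target_T") ref_T else ref_C
    if (sim$truth$strand[i] == "-") want <- revcomp(want)
    expect_identical(unname(sim$reads[i]), want)
  }
  expect_true(all(sim$truth$n_errors == 0))
})

test_that("variant-position base frequencies match the 50:50 heterozygous mix", {
  loc <- fix_locus
  mix <- het_baseline_mixture(loc)
  sim <- simulate_amplicon_reads(loc, mix, loc$short_amplicon, 4000,
                                 error = error_model(0, 0, 0), seed = 13)
  frac_T <- mean(sim$truth$allele == "target_T")
  # binomial 3-sigma band around 0.5 at n = 4000
  expect_lt(abs(frac_T - 0.5), 3 * sqrt(0.25 / 4000))
  # and the reads themselves carry the expected base
  local <- loc$pathogenic_variant$position - loc$short_amplicon$interval[1] + 1
  base <- vapply(seq_along(sim$reads), function(i) {
    r <- sim$reads[[i]]
    if (sim$truth$strand[i] == "-") r <- revcomp(r)
    substr(r, local, local)
  }, character(1))
  expect_identical(unname(base == "T"), sim$truth$allele == "target_T")
})

test_that("observed substitution rate tracks the error model", {
  loc <- fix_toy
  mix <- mixture_spec(allele_spec("wt", weight = 1))
  em <- error_model(sub_rate = 0.02, ins_rate = 0, del_rate = 0)
  sim <- simulate_amplicon_reads(loc, mix, loc$short_amplicon, 2000,
                                 error = em, seed = 14)
  amp_len <- loc$short_amplicon$expected_length
  rate <- sum(sim$truth$n_errors) / (2000 * amp_len)
  expect_lt(abs(rate - 0.02), 0.002)
})

test_that("an allele deleting a primer site contributes zero reads", {
  loc <- fix_locus
  mix <- large_deletion_mixture(loc)
  sim <- simulate_amplicon_reads(loc, mix, loc$short_amplicon, 800, seed = 15)
  expect_false("del6000" %in% sim$truth$allele)
  cap <- attr(sim$truth, "capture")
  expect_false(cap$capturable[cap$allele == "del6000"])
  expect_equal(cap$effective_weight[cap$allele == "del6000"], 0)
  # renormalised weights: law-of-large-numbers recovery
  obs <- table(factor(sim$truth$allele, cap$allele[cap$capturable])) / 800
  for (a in names(obs)) {
    w <- cap$effective_weight[cap$allele == a]
    expect_lt(abs(obs[[a]] - w), 3 * sqrt(w * (1 - w) / 800) + 1e-9)
  }
  # all alleles lost -> simulation error
  gone <- mixture_spec(allele_spec("g", deletion = c(5301, 5330), weight = 1))
  expect_error(simulate_amplicon_reads(loc, gone, loc$short_amplicon, 10),
               "capturable")
})

test_that("cDNA simulator honours inclusion and carrier fractions", {
  loc <- fix_locus
  iso <- isoform_model(loc)
  tpl <- fix_template
  # inclusion 1 -> every truth record includes the exon
  s1 <- simulate_cdna_reads(loc, iso, tpl, inclusion = 1,
                            snv_carrier_fraction = 0.5, n_reads = 50, seed = 16)
  expect_true(all(s1$truth$includes_exon))
  # carrier 0 with zero error -> no template base anywhere
  s0 <- simulate_cdna_reads(loc, iso, tpl, inclusion = 0.5,
                            snv_carrier_fraction = 0, n_reads = 50,
                            error = error_model(0, 0, 0), seed = 17)
  tx <- nickhdr:::transcript_snv_positions(iso, tpl)
  blocked <- tx[tx$role == "blocking", ][1, ]
  for (i in seq_along(s0$reads)) {
    if (!s0$truth$includes_exon[i]) next
    r <- s0$reads[[i]]
    if (s0$truth$strand[i] == "-") r <- revcomp(r)
    expect_identical(substr(r, blocked$tx_position, blocked$tx_position),
                     blocked$ref_base)
  }
  # inclusion recovery at moderate depth
  s <- simulate_cdna_reads(loc, iso, tpl, inclusion = 0.4,
                           snv_carrier_fraction = 0.55, n_reads = 4000,
                           seed = 18)
  expect_lt(abs(mean(s$truth$includes_exon) - 0.4), 3 * sqrt(0.24 / 4000))
})
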