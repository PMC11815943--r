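# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the code paths they check.

# plain-R Gotoh semi-global aligner: the read is aligned end to end, the
# reference contributes a free-ended local window; gap of length L costs
# open + ext * L. Returns the optimal score only.
oracle_semiglobal_score <- function(read, ref, match = 2, mismatch = -4,
                                    open = 4, ext = 2) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(s)
  NEG <- -1e9
  # H: best ending in match/mismatch, X: gap in read open (read consumed),
  # Y: gap in ref open (ref consumed)
  H <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- function(i, j) max(H[i, j], X[i, j], Y[i, j])
  H[1, ] <- 0                      # free leading reference
  for (i in 2:(m + 1)) {
    X[i, 1] <- -(open + ext * (i - 1))
    for (j in 2:(n + 1)) {
      sub <- if (r[i - 1] == s[j - 1] && r[i - 1] != "N") match else mismatch
      H[i, j] <- max(H[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(H[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(H[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(H[m + 1, ], X[m + 1, ])      # free trailing reference
}

# translation oracle: full-CDS translate-both-and-compare via Biostrings
oracle_is_silent <- function(locus, position, alt_base) {
  splice <- function(seq) {
    paste(vapply(locus$exons, function(e) substr(seq, e[1], e[2]),
                 character(1)), collapse = "")
  }
  mutseq <- locus$sequence
  substr(mutseq, position, position) <- alt_base
  trim <- function(x) {
    x <- substr(x, locus$cds_frame + 1, nchar(x))
    substr(x, 1, 3 * (nchar(x) %/% 3))
  }
  aa <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(trim(x)), if.fuzzy.codon = "X"))
  aa(splice(locus$sequence)) == aa(splice(mutseq))
}

# exhaustive Fisher exact oracle: two-sided p by summing hypergeometric
# probabilities <= that of the observed table
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1
  n <- c + d          # row 2
  k <- a + c          # col 1
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force PAM-out pair enumeration over all 20-mers with NGG
oracle_pam_out_pairs <- function(locus, window, offset_range) {
  seq <- locus$sequence
  varpos <- locus$pathogenic_variant$position
  plus <- list(); minus <- list()
  for (s in window[1]:(window[2] - 19)) {
    if (s + 22 <= window[2] &&
        substr(seq, s + 21, s + 22) == "GG") {
      plus[[length(plus) + 1]] <- c(start = s, nick = s + 16)
    }
    if (s - 3 >= window[1] &&
        substr(seq, s - 3, s - 2) == "CC") {
      minus[[length(minus) + 1]] <- c(start = s, nick = s + 2)
    }
  }
  out <- list()
  for (gm in minus) for (gp in plus) {
    off <- gp["nick"] - gm["nick"]
    if (off >= offset_range[1] && off <= offset_range[2] &&
        varpos > gm["nick"] && varpos <= gp["nick"]) {
      out[[length(out) + 1]] <- c(left = unname(gm["start"]),
                                  right = unname(gp["start"]),
                                  offset = unname(off))
    }
  }
  out
}

# inject plain substitutions at a given per-base rate (no indels)
mutate_subs <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  i <- which(runif(length(v)) < rate)
  if (length(i)) {
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
  }
  paste(v, collapse = "")
}

# expected truth category per simulated allele name
allele_truth_category <- c(perfect_hdr = "perfect_hdr",
                           imperfect_hdr = "imperfect_hdr",
                           nick_indel = "indel",
                           unedited_T = "unedited",
                           nontarget_C = "unedited")

# shared fixtures (built once per test run)
fix_locus <- synthetic_locus()
fix_toy <- synthetic_locus(compact = TRUE)
fix_template <- design_template(fix_locus, fix_locus$guides, "blocking",
                                total_length = 180, arm_length = 40)
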