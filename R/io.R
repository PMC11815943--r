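## File-format plumbing: FASTA/FASTQ via Biostrings, YAML/JSON locus configs,
## and TSV export of per-read alignments.

#' Read sequencing reads from a FASTQ file
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write reads to a FASTQ file with constant placeholder qualities
#'
#' Per-base qualities are not modelled (downstream analysis is alignment
#' based); a constant Q12 string is emitted.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(names(reads)) || anyDuplicated(names(reads))) {
    stop("reads must carry unique names", call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("-", n), character(1)) # Q12
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read a single-sequence FASTA file
#'
#' @param path FASTA file.
#' @return Uppercase DNA string (first record).
#' @export
read_fasta_seq <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  toupper(as.character(x[[1L]]))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Load a locus model from a YAML/JSON config plus FASTA
#'
#' The config carries `sequence_file` (relative to the config), `origin`,
#' `exons`, `cds_frame`, `variant` (`position`/`ref`/`alt`), `amplicons`
#' (`short`/`long`, each with `fwd` and `rev` primer intervals) and optional
#' `guides` (each with `protospacer`, `start`, `strand`). Every
#' [reference_locus()] invariant is checked eagerly; a `ref` base that
#' disagrees with the FASTA raises a consistency error.
#'
#' @param path Path to the YAML (`.yml`/`.yaml`) or JSON config.
#' @return A validated [reference_locus()].
#' @export
load_locus_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("name", "sequence_file", "exons", "variant", "amplicons")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("locus config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  seq_path <- cfg$sequence_file
  if (!file.exists(seq_path)) {
    seq_path <- file.path(dirname(path), cfg$sequence_file)
  }
  sequence <- read_fasta_seq(seq_path)

  as_iv <- function(x, what) {
    v <- unlist(x, use.names = FALSE)
    check_interval(v, what)
  }
  exons <- if (is.matrix(cfg$exons)) {
    lapply(seq_len(nrow(cfg$exons)), function(i) cfg$exons[i, ])
  } else lapply(cfg$exons, as_iv, what = "exon")

  amp <- function(a, what) {
    if (is.null(a$fwd) || is.null(a$rev)) {
      stop("amplicon '", what, "' needs fwd and rev primer intervals",
           call. = FALSE)
    }
    amplicon_def(as_iv(a$fwd, paste0(what, " fwd")),
                 as_iv(a$rev, paste0(what, " rev")))
  }

  guides <- NULL
  if (!is.null(cfg$guides)) {
    gl <- if (is.data.frame(cfg$guides)) {
      lapply(seq_len(nrow(cfg$guides)), function(i) as.list(cfg$guides[i, ]))
    } else cfg$guides
    if (length(gl) != 2L) stop("config 'guides' must list two guides", call. = FALSE)
    gs <- lapply(gl, function(g) {
      guide(g$protospacer, start = g$start, strand = g$strand, id = g$id)
    })
    gs <- gs[order(vapply(gs, function(g) g$nick_position, numeric(1)))]
    guides <- guide_pair(gs[[1L]], gs[[2L]])
  }

  reference_locus(
    name = cfg$name, sequence = sequence,
    coordinate_origin = cfg$origin %||% 0L,
    exons = exons, cds_frame = cfg$cds_frame %||% 0L,
    pathogenic_variant = list(position = cfg$variant$position,
                              ref_base = cfg$variant$ref,
                              alt_base = cfg$variant$alt),
    short_amplicon = amp(cfg$amplicons$short, "short"),
    long_amplicon = amp(cfg$amplicons$long, "long"),
    guides = guides
  )
}

#' Serialise a locus model to YAML config + FASTA
#'
#' Round-trips through [load_locus_config()] field for field.
#'
#' @param locus A [reference_locus()].
#' @param dir Output directory (created if needed).
#' @param basename File stem for the `.yaml`/`.fa` pair.
#' @return Path to the written YAML config, invisibly.
#' @export
write_locus_config <- function(locus, dir, basename = locus$name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(basename, ".fa"))
  write_fasta(setNames(locus$sequence, locus$name), fa)
  amp_out <- function(a) list(fwd = as.integer(a$fwd_primer),
                              rev = as.integer(a$rev_primer))
  cfg <- list(
    name = locus$name,
    sequence_file = paste0(basename, ".fa"),
    origin = locus$coordinate_origin,
    exons = lapply(locus$exons, as.integer),
    cds_frame = locus$cds_frame,
    variant = list(position = locus$pathogenic_variant$position,
                   ref = locus$pathogenic_variant$ref_base,
                   alt = locus$pathogenic_variant$alt_base),
    amplicons = list(short = amp_out(locus$short_amplicon),
                     long = amp_out(locus$long_amplicon))
  )
  if (!is.null(locus$guides)) {
    cfg$guides <- lapply(list(locus$guides$left, locus$guides$right),
                         function(g) list(id = g$id,
                                          protospacer = g$protospacer,
                                          start = g$footprint[1L],
                                          strand = g$strand))
  }
  path <- file.path(dir, paste0(basename, ".yaml"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export per-read alignments as TSV
#'
#' Columns: read_id, strand, retained, reason, identity, ref_start, ref_end
#' and a CIGAR-style op string.
#'
#' @param alns List of alignments from [align_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(alns, path) {
  df <- alignment_table(alns)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
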