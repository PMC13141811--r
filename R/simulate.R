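# Run code under a temporary R RNG state seeded deterministically, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a random reference sequence
#'
#' Deterministic pseudo-random A/C/G/T sequence with a stable name, for
#' building self-contained test data.
#'
#' @param length reference length in bp (>= 1).
#' @param seed simulation seed.
#' @param name sequence name.
#' @return a [Biostrings::DNAStringSet] of length 1.
#' @examples
#' simulate_reference(100, seed = 1)
#' @export
simulate_reference <- function(length, seed, name = "ref1") {
  stopifnot(length >= 1)
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- name
  out
}

#' Write alignment records as a coordinate-sorted SAM file
#'
#' Low-level fixture builder: takes a data.frame of SAM fields, fills
#' defaults for the ones not given, sorts by (reference, position) and
#' writes a valid `SO:coordinate` SAM file. Used by the simulator and handy
#' for constructing exact test cases.
#'
#' @param records data.frame with at least `qname`, `flag`, `rname`, `pos`
#'   (1-based) and `cigar`; optional `mapq`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual`.
#' @param ref_lengths named integer vector of reference lengths (header
#'   `@SQ` lines, in order).
#' @param path output path (`.sam`).
#' @param sort sort records by (reference, position) before writing.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref_lengths, path, sort = TRUE) {
  defaults <- list(mapq = 60L, rnext = "*", pnext = 0L, tlen = 0L,
                   seq = "*", qual = "*")
  for (f in names(defaults)) {
    if (is.null(records[[f]])) records[[f]] <- rep(defaults[[f]], nrow(records))
  }
  if (sort && nrow(records)) {
    ord <- order(match(records$rname, names(ref_lengths)), records$pos)
    records <- records[ord, , drop = FALSE]
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  records$qname, as.integer(records$flag), records$rname,
                  as.integer(records$pos), as.integer(records$mapq),
                  records$cigar, records$rnext, as.integer(records$pnext),
                  as.integer(records$tlen), records$seq, records$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a coordinate-sorted alignment file
#'
#' Generates alignments over a reference with controlled depth structure so
#' every cap guarantee can be exercised without external data. Two modes:
#'
#' * `long_single_end`: unpaired reads with lognormal lengths (mean
#'   `read_length_mean`, log-sd `read_length_sdlog`), emulating high-depth
#'   long-read data.
#' * `paired_end`: proper 2 x `read_length_mean` bp pairs with Normal insert
#'   sizes; a fraction `unmapped_mate_rate` of second mates is emitted as an
#'   unmapped-with-mapped-mate record placed at its mate's position.
#'
#' Read starts are uniform over the positions where the read fits; the read
#' count per reference is chosen so the expected mean depth equals
#' `target_depth`. CIGARs are fully matched; bases are taken from the
#' reference (no error model — the downsampler never looks at them).
#'
#' @param reference a [Biostrings::DNAStringSet] (one or more references) or
#'   a FASTA path.
#' @param out output path ending in `.bam` (sorted and indexed) or `.sam`.
#' @param mode `"long_single_end"` or `"paired_end"`.
#' @param target_depth target mean depth per reference.
#' @param read_length_mean mean read length (default 5000 for long reads,
#'   150 for paired).
#' @param read_length_sdlog lognormal log-sd of long-read lengths.
#' @param insert_mean,insert_sd insert-size distribution (paired mode).
#' @param unmapped_mate_rate probability a template's second mate is
#'   unmapped (paired mode).
#' @param seed simulation seed (independent of the downsampler's seed).
#' @return the output path, with a plain-text manifest of the parameters at
#'   `<out>.manifest.txt`; for `.bam` output a `.bai` index is created.
#' @export
simulate_alignments <- function(reference, out,
                                mode = c("long_single_end", "paired_end"),
                                target_depth = 50,
                                read_length_mean = NULL,
                                read_length_sdlog = 0.5,
                                insert_mean = 300, insert_sd = 50,
                                unmapped_mate_rate = 0, seed) {
  mode <- match.arg(mode)
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))
  }
  ref_lengths <- stats::setNames(Biostrings::width(reference),
                                 names(reference))
  if (is.null(read_length_mean)) {
    read_length_mean <- if (mode == "long_single_end") 5000 else 150
  }
  if (read_length_mean > min(ref_lengths)) {
    stop("read_length_mean exceeds the shortest reference (",
         min(ref_lengths), " bp)")
  }

  recs <- with_seed(seed, {
    per_ref <- lapply(seq_along(ref_lengths), function(i) {
      L <- ref_lengths[[i]]
      nm <- names(ref_lengths)[i]
      refseq <- as.character(reference[[i]])
      if (mode == "long_single_end") {
        sim_long_reads(nm, L, refseq, target_depth, read_length_mean,
                       read_length_sdlog, prefix = sprintf("sim%d", i))
      } else {
        sim_pairs(nm, L, refseq, target_depth, read_length_mean,
                  insert_mean, insert_sd, unmapped_mate_rate,
                  prefix = sprintf("sim%d", i))
      }
    })
    do.call(rbind, per_ref)
  })

  sam <- if (grepl("\\.sam$", out, ignore.case = TRUE)) out
         else tempfile(fileext = ".sam")
  write_sam(recs, ref_lengths, sam)
  if (!grepl("\\.sam$", out, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam, destination = sub("\\.bam$", "", out),
                            overwrite = TRUE, indexDestination = TRUE)
    stopifnot(identical(normalizePath(bam), normalizePath(out)))
  }
  writeLines(c(
    paste0("mode=", mode),
    paste0("references=", paste(names(ref_lengths), ref_lengths,
                                sep = ":", collapse = ",")),
    paste0("target_depth=", target_depth),
    paste0("read_length_mean=", read_length_mean),
    paste0("read_length_sdlog=", read_length_sdlog),
    paste0("insert_mean=", insert_mean),
    paste0("insert_sd=", insert_sd),
    paste0("unmapped_mate_rate=", unmapped_mate_rate),
    paste0("seed=", seed)
  ), paste0(out, ".manifest.txt"))
  invisible(out)
}

sim_long_reads <- function(rname, L, refseq, depth, mean_len, sdlog,
                           prefix) {
  n <- max(1L, round(depth * L / mean_len))
  meanlog <- log(mean_len) - sdlog^2 / 2
  len <- pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), 50L), L)
  start0 <- floor(stats::runif(n, 0, L - len + 1))  # 0-based
  rev <- stats::runif(n) < 0.5
  data.frame(
    qname = sprintf("%s_r%06d", prefix, seq_len(n)),
    flag = ifelse(rev, 16L, 0L),
    rname = rname,
    pos = as.integer(start0 + 1L),
    cigar = sprintf("%dM", len),
    seq = substring(refseq, start0 + 1L, start0 + len),
    stringsAsFactors = FALSE)
}

sim_pairs <- function(rname, L, refseq, depth, rl, insert_mean, insert_sd,
                      unmapped_rate, prefix) {
  n <- max(1L, round(depth * L / (2 * rl)))
  insert <- pmin(pmax(round(stats::rnorm(n, insert_mean, insert_sd)),
                      2L * rl), L)
  fstart <- floor(stats::runif(n, 0, L - insert + 1))  # 0-based
  p1 <- as.integer(fstart + 1L)                        # 1-based POS
  p2 <- as.integer(fstart + insert - rl + 1L)
  unmapped <- stats::runif(n) < unmapped_rate
  qname <- sprintf("%s_t%06d", prefix, seq_len(n))
  cig <- sprintf("%dM", rl)

  r1 <- data.frame(
    qname = qname,
    flag = ifelse(unmapped, 73L, 99L),    # 0x1|0x8|0x40 : 0x1|0x2|0x20|0x40
    rname = rname, pos = p1, cigar = cig,
    rnext = "=", pnext = ifelse(unmapped, p1, p2),
    tlen = ifelse(unmapped, 0L, as.integer(insert)),
    seq = substring(refseq, p1, p1 + rl - 1L),
    stringsAsFactors = FALSE)
  r2 <- data.frame(
    qname = qname,
    flag = ifelse(unmapped, 133L, 147L),  # 0x1|0x4|0x80 : 0x1|0x2|0x10|0x80
    rname = rname,
    pos = ifelse(unmapped, p1, p2),       # unmapped mate sits at its mate
    cigar = ifelse(unmapped, "*", cig),
    mapq = ifelse(unmapped, 0L, 60L),
    rnext = "=", pnext = p1,
    tlen = ifelse(unmapped, 0L, -as.integer(insert)),
    seq = substring(refseq, p2, p2 + rl - 1L),
    stringsAsFactors = FALSE)
  r1$mapq <- 60L
  rbind(r1, r2)
}
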