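#' Infer the originating gene strand of a read
#'
#' Maps the alignment strand of a read (or read pair) to the strand of the
#' gene it derives from under a library protocol. Under the dUTP "reverse"
#' convention (`"R"`) the first mate aligns opposite to the gene strand;
#' under `"F"` it aligns on the gene strand; an unstranded library (`"U"`)
#' carries no information.
#'
#' @param alignment_strand character vector of `"+"`/`"-"`, the alignment
#'   strand of the read (single-end) or of the first mate (paired-end).
#' @param strandedness library protocol, one of `"U"`, `"F"`, `"R"`.
#' @param second_in_pair logical; `TRUE` where `alignment_strand` is that of
#'   a second mate (its strand is flipped before applying the protocol).
#' @return character vector of `"+"`, `"-"` or `"*"` (unknown).
#' @export
infer_read_gene_strand <- function(alignment_strand,
                                   strandedness = c("U", "F", "R"),
                                   second_in_pair = FALSE) {
  strandedness <- match.arg(strandedness)
  s <- as.character(alignment_strand)
  stopifnot(all(s %in% c("+", "-", "*")))
  flip <- function(x) ifelse(x == "+", "-", ifelse(x == "-", "+", "*"))
  if (any(second_in_pair)) s[second_in_pair] <- flip(s[second_in_pair])
  switch(strandedness, U = rep("*", length(s)), F = s, R = flip(s))
}

.read_alignments <- function(bam_path, mapq_min, keep_dups, keep_secondary,
                             unit) {
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for ", bam_path)
  paired_file <- suppressMessages(Rsamtools::testPairedEndBam(bam_path))
  if (unit == "auto") unit <- if (paired_file) "fragment" else "read"
  if (unit == "fragment" && !paired_file)
    stop("unit = 'fragment' requires a paired-end BAM")
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (keep_secondary) NA else FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (keep_dups) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq_min)
  aln <- if (unit == "fragment")
    GenomicAlignments::readGAlignmentPairs(bam_path, param = param,
                                           strandMode = 1)
  else
    GenomicAlignments::readGAlignments(bam_path, param = param)
  list(aln = aln, unit = unit)
}

#' Count reads over gene models in six ways
#'
#' Assigns the alignments of a coordinate-sorted, indexed BAM to the gene
#' models of a database, producing six per-gene tallies (exon-union
#' semantics, each evaluated independently per read or fragment):
#' \describe{
#'   \item{n_ust}{unstranded count: the read overlaps the gene's exon union
#'     by at least one base, strand ignored; a read over the exon overlap of
#'     several genes increments each of them.}
#'   \item{n_ustno}{unstranded count in the gene's unique region: the read's
#'     exons overlap exactly one gene's exon union; reads hitting two or
#'     more genes are ambiguous and counted for none.}
#'   \item{n_st}{as `n_ust` but restricted to genes on the read's inferred
#'     strand; `NA` for unstranded libraries.}
#'   \item{n_stno}{the subset of the gene's `n_ustno` reads whose inferred
#'     strand matches the gene — both unique-region counts therefore tally
#'     reads over the identical region, and the unstranded/stranded
#'     unique-region ratio directly measures opposite-strand
#'     contamination; `NA` for unstranded libraries.}
#'   \item{n_jctn}{reads with a spliced-alignment gap exactly matching an
#'     annotated junction of the gene (and counted in its `n_ust`).}
#'   \item{n_intr}{reads overlapping the gene's introns while touching no
#'     gene's exon union.}
#' }
#' By construction `n_stno <= n_ustno`, `n_stno <= n_st`,
#' `n_ustno <= n_ust` and `n_jctn <= n_ust` for every gene.
#'
#' Secondary, supplementary and (by default) duplicate alignments are
#' skipped, as are alignments below `mapq_min`. Paired-end files are counted
#' per fragment by default: both mates' aligned blocks are pooled and the
#' fragment counted once, with the inferred strand taken from the first
#' mate.
#'
#' @param bam_path path to an indexed BAM.
#' @param db a [build_db()] database.
#' @param strandedness `"U"` (unstranded), `"F"` or `"R"` (dUTP reverse).
#' @param mapq_min minimum mapping quality (default 10).
#' @param unit `"auto"` (fragment for paired files), `"read"` or
#'   `"fragment"`.
#' @param keep_dups,keep_secondary include duplicate / secondary alignments.
#' @return data.frame with one row per gene (`gene_id`, `n_st`, `n_stno`,
#'   `n_ust`, `n_ustno`, `n_jctn`, `n_intr`), ordered as in the database.
#'   Run diagnostics are attached as `attr(, "diagnostics")`: records used,
#'   ambiguous, no-feature, missing-chromosome, duplicate/secondary/low-mapq
#'   records skipped.
#' @examples
#' \donttest{
#' fx <- run_fixtures(tempfile("fx"), seed = 1, preset = "tiny")
#' db <- build_db(fx$gtf)
#' counts <- count_bam(fx$bam, db, strandedness = "R")
#' head(counts)
#' }
#' @export
count_bam <- function(bam_path, db, strandedness = c("U", "F", "R"),
                      mapq_min = 10L, unit = c("auto", "read", "fragment"),
                      keep_dups = FALSE, keep_secondary = FALSE) {
  strandedness <- match.arg(strandedness)
  unit <- match.arg(unit)
  stopifnot(inherits(db, "genome_db"))
  rd <- .read_alignments(bam_path, mapq_min, keep_dups, keep_secondary, unit)
  aln <- rd$aln

  ngene <- nrow(db$genes)
  gene_ids <- db$genes$gene_id

  ## drop alignments on chromosomes absent from the database
  db_chroms <- unique(db$genes$chrom)
  on_db <- as.character(seqnames(aln)) %in% db_chroms
  n_missing_chrom <- sum(!on_db)
  aln <- aln[on_db]
  nreads <- length(aln)

  blocks <- GenomicRanges::grglist(aln)
  exon_all <- .db_exon_all(db)
  intron_all <- .db_intron_all(db)

  ov <- findOverlaps(blocks, exon_all, ignore.strand = TRUE)
  pr <- unique(cbind(r = queryHits(ov), g = exon_all$gene_idx[subjectHits(ov)]))
  genes_per_read <- tabulate(pr[, "r"], nreads)

  n_ust <- tabulate(pr[, "g"], ngene)
  uniq <- pr[genes_per_read[pr[, "r"]] == 1L, , drop = FALSE]
  n_ustno <- tabulate(uniq[, "g"], ngene)

  if (strandedness == "U") {
    n_st <- n_stno <- rep(NA_integer_, ngene)
  } else {
    read_strand <- infer_read_gene_strand(as.character(strand(aln)),
                                          strandedness)
    same <- pr[db$genes$strand[pr[, "g"]] == read_strand[pr[, "r"]], ,
               drop = FALSE]
    n_st <- tabulate(same[, "g"], ngene)
    ## n_stno: the same-strand subset of the n_ustno reads, so that the
    ## unique-region stranded and unstranded counts refer to the identical
    ## reads and n_stno <= n_ustno holds by construction
    suniq <- uniq[db$genes$strand[uniq[, "g"]] == read_strand[uniq[, "r"]], ,
                  drop = FALSE]
    n_stno <- tabulate(suniq[, "g"], ngene)
  }

  ## junction reads: spliced gap exactly matching an annotated junction,
  ## read already counted in that gene's n_ust
  n_jctn <- integer(ngene)
  jx <- GenomicAlignments::junctions(aln)
  nj <- lengths(jx)
  if (sum(nj) > 0 && nrow(db$junctions) > 0) {
    jgr <- unlist(jx, use.names = FALSE)
    jread <- rep(seq_len(nreads), nj)
    key <- .junction_key(as.character(seqnames(jgr)), start(jgr), end(jgr))
    ann_key <- .junction_key(db$junctions$chrom, db$junctions$start,
                             db$junctions$end)
    jmap <- split(match(db$junctions$gene_id, gene_ids), ann_key)
    hitrows <- which(key %in% names(jmap))
    if (length(hitrows)) {
      gsets <- jmap[key[hitrows]]
      jp <- unique(cbind(r = rep(jread[hitrows], lengths(gsets)),
                         g = unlist(gsets, use.names = FALSE)))
      in_ust <- paste(jp[, "r"], jp[, "g"]) %in% paste(pr[, "r"], pr[, "g"])
      n_jctn <- tabulate(jp[in_ust, "g"], ngene)
    }
  }

  ## intronic reads: no exon overlap with any gene, overlap with introns
  n_intr <- integer(ngene)
  no_exon <- which(genes_per_read == 0L)
  intr_read_count <- 0L
  if (length(no_exon)) {
    iov <- findOverlaps(blocks[no_exon], intron_all, ignore.strand = TRUE)
    ipr <- unique(cbind(r = no_exon[queryHits(iov)],
                        g = intron_all$gene_idx[subjectHits(iov)]))
    n_intr <- tabulate(ipr[, "g"], ngene)
    intr_read_count <- length(unique(ipr[, "r"]))
  }

  res <- data.frame(gene_id = gene_ids, n_st = n_st, n_stno = n_stno,
                    n_ust = n_ust, n_ustno = n_ustno, n_jctn = n_jctn,
                    n_intr = n_intr, stringsAsFactors = FALSE)
  rownames(res) <- gene_ids

  attr(res, "diagnostics") <- c(
    used = nreads,
    ambiguous = sum(genes_per_read >= 2L),
    no_feature = length(no_exon) - intr_read_count,
    missing_chrom = n_missing_chrom,
    unit_fragment = as.integer(rd$unit == "fragment"))
  res
}

#' Transcripts-per-million normalization of a count type
#'
#' `TPM_g = (count_g / len_g) / sum_h(count_h / len_h) * 1e6` with lengths in
#' kb. The unique-region count types (`n_stno`, `n_ustno`) are normalized by
#' the gene's non-overlapping exonic length, the others by the full
#' exon-union length (lengths floored at 1 bp for fully overlapped genes).
#' All-zero counts give all-zero TPM.
#'
#' @param counts a [count_bam()] data.frame.
#' @param db the database the counts were produced with.
#' @param which count type to normalize (default `"n_ustno"`).
#' @return named numeric vector of TPM values summing to 1e6 (when any
#'   count is positive).
#' @export
compute_tpm <- function(counts, db,
                        which = c("n_ustno", "n_ust", "n_stno", "n_st",
                                  "n_jctn")) {
  which <- match.arg(which)
  stopifnot(inherits(db, "genome_db"))
  x <- counts[[which]]
  if (is.null(x)) stop("counts lack column ", which)
  if (anyNA(x)) stop(which, " is NA (unstranded library?); cannot compute TPM")
  g <- db$genes[counts$gene_id, ]
  len <- if (which %in% c("n_stno", "n_ustno")) g$nonoverlap_len else g$exonic_len
  rate <- x / (pmax(len, 1L) / 1000)
  tot <- sum(rate)
  tpm <- if (tot > 0) rate / tot * 1e6 else rate * 0
  setNames(tpm, counts$gene_id)
}

#' Write a six-count table to TSV
#'
#' @param counts a [count_bam()] data.frame.
#' @param path output file; diagnostics are written alongside as
#'   `<path>.diagnostics.tsv`.
#' @return `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- attr(counts, "diagnostics")
  if (!is.null(d))
    write.table(data.frame(metric = names(d), value = as.integer(d)),
                paste0(path, ".diagnostics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
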