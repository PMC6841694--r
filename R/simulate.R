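#' Configuration for the synthetic RNA-seq generator
#'
#' Bundles the layout and read parameters used by [simulate_annotation()]
#' and [simulate_reads()]. Defaults emulate the study conditions the
#' package is validated under: single-end 50 bp reads from a dUTP
#' reverse-stranded protocol, an aligner splice overhang of 8, and a gene
#' landscape mixing monoexonic and multiexonic genes with antisense exon
#' overlaps and close neighbor pairs — the configurations in which
#' opposite-strand carry-over arises.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param n_genes number of genes to lay out (minimum 6; the first six
#'   realize an antisense exon-overlap pair, a pair gapped under 2,000 bp
#'   and a pair gapped over 2,000 bp).
#' @param p_monoexonic probability that a gene is monoexonic (default 0.35,
#'   the approximate genome-wide fraction).
#' @param read_length read length in bp (default 50).
#' @param paired paired-end reads (default `FALSE`).
#' @param fragment_length fragment length in bp for paired reads.
#' @param min_overhang minimum aligned bases on each side of a splice
#'   junction; reads crossing a junction with a shorter overhang are
#'   emitted soft-clipped, as a spliced aligner would report them.
#' @param protocol library protocol of the emitted BAM: `"R"` (dUTP
#'   reverse), `"F"`, or `"U"` (strand flags randomized).
#' @param n_reads total intrinsic reads across genes (default 20000).
#' @param carry_over data.frame `source`, `target`, `fraction`: for each
#'   pair, unspliced reads from the source gene's strand are planted over
#'   the target gene's locus, `round(fraction * source reads)` of them.
#' @param intron_noise per-gene rate of additional same-strand unspliced
#'   reads placed uniformly over the gene's span, emulating nascent
#'   (pre-mRNA) background so that regular genes have finite
#'   exonic/intronic density ratios (default 0.03). Set to 0 for
#'   fixtures that must realize the junction-probability assumptions
#'   exactly.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 30L, p_monoexonic = 0.35,
                       read_length = 50L, paired = FALSE,
                       fragment_length = 200L, min_overhang = 8L,
                       protocol = c("R", "F", "U"), n_reads = 20000L,
                       carry_over = NULL, intron_noise = 0.03) {
  protocol <- match.arg(protocol)
  stopifnot(n_genes >= 6L, read_length >= 20L, min_overhang >= 1L,
            !paired || fragment_length >= read_length,
            intron_noise >= 0, intron_noise < 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 p_monoexonic = p_monoexonic,
                 read_length = as.integer(read_length), paired = paired,
                 fragment_length = as.integer(fragment_length),
                 min_overhang = as.integer(min_overhang),
                 protocol = protocol, n_reads = as.integer(n_reads),
                 carry_over = carry_over, intron_noise = intron_noise),
            class = "sim_config")
}

.flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Generate a synthetic gene annotation
#'
#' Lays out `cfg$n_genes` genes on one synthetic chromosome and writes a
#' Gencode-dialect GTF (gene, transcript and exon records with `gene_id`,
#' `transcript_id`, `gene_name`, `gene_type` attributes). The layout always
#' contains monoexonic genes, multiexonic genes with up to two isoforms
#' (the second skipping an internal exon), one antisense exon-overlapping
#' pair (genes 1 and 2), one pair gapped by less than 2,000 bp (genes 3 and
#' 4, opposite strands) and one pair gapped by more than 2,000 bp (genes 5
#' and 6). Byte-identical output for a given seed.
#'
#' @param cfg a [sim_config()].
#' @param gtf_path where to write the GTF.
#' @return invisibly, a `sim_layout` list: `chrom`, `chrom_len`, `genes`,
#'   `transcripts`, `exons` (1-based closed coordinates) and `gtf`.
#' @export
simulate_annotation <- function(cfg, gtf_path) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom <- "chrS"
  exon_w <- function(n) sample(120:280, n, replace = TRUE)
  intron_w <- function(n) sample(250:700, n, replace = TRUE)

  genes <- list(); transcripts <- list(); exons <- list()
  add_gene <- function(idx, start, strand, n_exons, overlap_anchor = NULL) {
    gid <- sprintf("G%03d", idx)
    ws <- exon_w(n_exons)
    gaps <- if (n_exons > 1L) intron_w(n_exons - 1L) else integer(0)
    es <- start + c(0L, cumsum(ws[-n_exons] + gaps))
    ee <- es + ws - 1L
    txs <- list(seq_len(n_exons))
    if (n_exons >= 3L && runif(1) < 0.5)
      txs <- c(txs, list(setdiff(seq_len(n_exons),
                                 sample(2:(n_exons - 1L), 1L))))
    for (t in seq_along(txs)) {
      tid <- sprintf("%s.T%d", gid, t)
      transcripts[[length(transcripts) + 1L]] <<-
        data.frame(transcript_id = tid, gene_id = gid)
      exons[[length(exons) + 1L]] <<-
        data.frame(transcript_id = tid, gene_id = gid,
                   start = es[txs[[t]]], end = ee[txs[[t]]])
    }
    genes[[length(genes) + 1L]] <<-
      data.frame(gene_id = gid, strand = strand,
                 span_start = es[1], span_end = ee[n_exons],
                 monoexonic = n_exons == 1L)
    c(es[1], ee[n_exons])
  }

  cursor <- 1000L
  ## 1+2: antisense exon-overlap pair
  sp <- add_gene(1L, cursor, "+", 3L)
  last_ex <- exons[[1]]; last_ex <- last_ex[nrow(last_ex), ]
  b_start <- last_ex$start + (last_ex$end - last_ex$start) %/% 2L
  sp2 <- add_gene(2L, b_start, "-", 2L)
  cursor <- max(sp[2], sp2[2]) + sample(2500:4000, 1L)
  ## 3+4: proximal pair (gap < 2000), opposite strands
  sp <- add_gene(3L, cursor, "+", 4L)
  gap <- sample(300:1500, 1L)
  sp <- add_gene(4L, sp[2] + gap + 1L, "-",
                 if (runif(1) < cfg$p_monoexonic) 1L else 3L)
  cursor <- sp[2] + sample(2500:4000, 1L)
  ## 5+6: distal pair (gap > 2000)
  sp <- add_gene(5L, cursor, "-", 2L)
  sp <- add_gene(6L, sp[2] + sample(2200:3500, 1L) + 1L, "+", 1L)
  cursor <- sp[2] + sample(2500:4000, 1L)
  ## remaining genes
  for (i in seq_len(cfg$n_genes - 6L) + 6L) {
    n_ex <- if (runif(1) < cfg$p_monoexonic) 1L
            else sample(2:5, 1L)
    strand <- sample(c("+", "-"), 1L)
    sp <- add_gene(i, cursor, strand, n_ex)
    gap <- if (runif(1) < 0.35) sample(300:1800, 1L) else sample(2500:6000, 1L)
    cursor <- sp[2] + gap + 1L
  }

  layout <- list(chrom = chrom, chrom_len = cursor + 10000L,
                 genes = do.call(rbind, genes),
                 transcripts = do.call(rbind, transcripts),
                 exons = do.call(rbind, exons), gtf = gtf_path)
  rownames(layout$genes) <- layout$genes$gene_id
  class(layout) <- "sim_layout"
  .write_gtf(layout, gtf_path)
  invisible(layout)
}

.write_gtf <- function(layout, path) {
  att <- function(gid, tid = NULL) {
    a <- sprintf('gene_id "%s"; ', gid)
    if (!is.null(tid)) a <- paste0(a, sprintf('transcript_id "%s"; ', tid))
    paste0(a, sprintf('gene_name "%s"; gene_type "protein_coding";', gid))
  }
  lines <- character(0)
  for (i in seq_len(nrow(layout$genes))) {
    g <- layout$genes[i, ]
    lines <- c(lines, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              layout$chrom, g$span_start, g$span_end,
                              g$strand, att(g$gene_id)))
    txs <- layout$transcripts$transcript_id[layout$transcripts$gene_id == g$gene_id]
    for (tid in txs) {
      e <- layout$exons[layout$exons$transcript_id == tid, ]
      lines <- c(lines, sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                                layout$chrom, min(e$start), max(e$end),
                                g$strand, att(g$gene_id, tid)))
      lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                                layout$chrom, e$start, e$end, g$strand,
                                att(g$gene_id, tid)))
    }
  }
  writeLines(c("##description: synthetic annotation", lines), path)
  invisible(path)
}

## Map read placements on the concatenated-exon (transcript) axis to
## genomic blocks. starts0 are 0-based placement starts; exons a data.frame
## with sorted start/end. Reads crossing a junction with fewer than
## min_overhang aligned bases on a terminal block are soft-clipped there.
## Returns data.frame pos, cigar, spans_junction.
.place_reads <- function(exons, starts0, read_len, min_overhang) {
  k <- nrow(exons)
  w <- exons$end - exons$start + 1L
  txe <- cumsum(w)          # 0-based exclusive ends on transcript axis
  txs <- c(0L, txe[-k])     # 0-based starts
  n <- length(starts0)
  ends0 <- pmin(starts0 + read_len, txe[k])
  pos <- integer(n); cig <- character(n); spans <- logical(n)
  for (i in seq_len(n)) {
    s <- starts0[i]; e <- ends0[i]
    ov_s <- pmax(s, txs); ov_e <- pmin(e, txe)
    len <- ov_e - ov_s
    j <- which(len > 0L)
    bl <- len[j]
    bs <- exons$start[j] + (ov_s[j] - txs[j])
    lc <- 0L; rc <- 0L
    if (length(j) > 1L) {
      if (bl[1] < min_overhang) {
        lc <- bl[1]; bs <- bs[-1]; bl <- bl[-1]; j <- j[-1]
      }
      if (length(bl) > 1L && bl[length(bl)] < min_overhang) {
        rc <- bl[length(bl)]
        bs <- bs[-length(bs)]; bl <- bl[-length(bl)]; j <- j[-length(j)]
      }
    }
    pos[i] <- bs[1]
    parts <- character(0)
    if (lc > 0L) parts <- c(parts, sprintf("%dS", lc))
    for (q in seq_along(bl)) {
      parts <- c(parts, sprintf("%dM", bl[q]))
      if (q < length(bl)) {
        gap <- bs[q + 1L] - (bs[q] + bl[q])
        parts <- c(parts, sprintf("%dN", gap))
      }
    }
    if (rc > 0L) parts <- c(parts, sprintf("%dS", rc))
    cig[i] <- paste(parts, collapse = "")
    spans[i] <- length(bl) > 1L
  }
  data.frame(pos = pos, cigar = cig, spans_junction = spans)
}

## exon-union, unique-region and span IRanges per gene from a layout
.layout_regions <- function(layout) {
  gid <- layout$genes$gene_id
  eu <- lapply(gid, function(g)
    reduce(IRanges(layout$exons$start[layout$exons$gene_id == g],
                   layout$exons$end[layout$exons$gene_id == g])))
  names(eu) <- gid
  uniq <- lapply(seq_along(gid), function(i) {
    others <- do.call(c, unname(eu[-i]))
    BiocGenerics::setdiff(eu[[i]], others)
  })
  names(uniq) <- gid
  list(exon_union = eu, unique = uniq)
}

## Replay generated reads against the layout with the unique-region
## assignment semantics, using the reads' true strands: yields the planted
## stranded/unstranded unique-region counts per gene.
.replay_unique_counts <- function(block_starts, block_ends, block_read,
                                  read_strand, layout, eps = 1) {
  reg <- .layout_regions(layout)
  gid <- layout$genes$gene_id
  ngene <- length(gid)
  nreads <- length(read_strand)
  eu_all <- do.call(c, unname(reg$exon_union))
  eu_gene <- rep(seq_len(ngene), lengths(reg$exon_union))
  bl <- IRanges(block_starts, block_ends)
  ov <- findOverlaps(bl, eu_all)
  pr <- unique(cbind(r = block_read[queryHits(ov)],
                     g = eu_gene[subjectHits(ov)]))
  gpr <- tabulate(pr[, "r"], nreads)
  uq <- pr[gpr[pr[, "r"]] == 1L, , drop = FALSE]
  n_ustno <- tabulate(uq[, "g"], ngene)
  suq <- uq[layout$genes$strand[uq[, "g"]] == read_strand[uq[, "r"]], ,
            drop = FALSE]
  n_stno <- tabulate(suq[, "g"], ngene)
  data.frame(gene_id = gid, planted_ustno = n_ustno, planted_stno = n_stno,
             planted_log2_ratio = log2((n_ustno + eps) / (n_stno + eps)),
             row.names = gid, stringsAsFactors = FALSE)
}

#' Simulate an aligned read set with planted opposite-strand carry-over
#'
#' Draws reads from the genes of a synthetic layout under exactly the two
#' assumptions of the junction-probability model — isoforms of a gene in
#' equal molar amounts, placements uniform along each molecule — writes a
#' coordinate-sorted, indexed BAM, and returns full ground truth. Spliced
#' reads carry `N` CIGAR operations that exactly match annotated junctions;
#' reads crossing a junction with fewer than `cfg$min_overhang` aligned
#' bases on one side are soft-clipped there, as an aligner would report
#' them. Carry-over reads for a pair `(source, target, fraction)` are
#' unspliced reads on the source gene's strand placed uniformly over the
#' target gene's span, `round(fraction * source reads)` of them —
#' emulating nascent-transcription read-through being mis-assigned in
#' unstranded data. Strand flags encode the configured protocol; under
#' `"U"` they are randomized.
#'
#' @param layout a [simulate_annotation()] layout.
#' @param cfg the [sim_config()] used for the layout.
#' @param bam_path output BAM path (`.bam`).
#' @param reads_per_gene optional named integer vector of intrinsic read
#'   counts per gene; by default `cfg$n_reads` is split over genes with
#'   log-normal weights.
#' @param carry_over overrides `cfg$carry_over`.
#' @param seed overrides `cfg$seed` (use to draw several samples from one
#'   layout).
#' @return list with `bam`, `read_truth` (per read: source gene and
#'   transcript, true strand, carry-over flag, junction-spanning flag),
#'   `gene_truth` (per gene: intrinsic and received carry-over reads and
#'   the planted unique-region stranded/unstranded counts and log2 ratio)
#'   and `config` echo.
#' @export
simulate_reads <- function(layout, cfg, bam_path, reads_per_gene = NULL,
                           carry_over = NULL, seed = NULL) {
  stopifnot(inherits(layout, "sim_layout"), inherits(cfg, "sim_config"))
  if (cfg$paired)
    stop("the read generator emits single-end reads only; ",
         "paired-end data are supported by count_bam() and ",
         "junction_probability()")
  if (is.null(carry_over)) carry_over <- cfg$carry_over
  set.seed(if (is.null(seed)) cfg$seed else seed)
  R <- cfg$read_length
  gid <- layout$genes$gene_id
  ngene <- length(gid)

  if (is.null(reads_per_gene)) {
    wts <- stats::rlnorm(ngene, meanlog = 0, sdlog = 1)
    reads_per_gene <- as.integer(round(wts / sum(wts) * cfg$n_reads))
    names(reads_per_gene) <- gid
  }
  stopifnot(all(gid %in% names(reads_per_gene)))

  ## intrinsic reads: sample (isoform, placement) uniformly over placements
  rows <- list()
  for (g in gid) {
    n <- reads_per_gene[[g]]
    if (n <= 0L) next
    txs <- layout$transcripts$transcript_id[layout$transcripts$gene_id == g]
    exl <- lapply(txs, function(t) {
      e <- layout$exons[layout$exons$transcript_id == t, ]
      e[order(e$start), ]
    })
    L <- vapply(exl, function(e) sum(e$end - e$start + 1L), integer(1))
    ptot <- pmax(L - R + 1L, 1L)
    pick <- sample.int(length(txs), n, replace = TRUE, prob = ptot)
    for (t in seq_along(txs)) {
      nt <- sum(pick == t)
      if (nt == 0L) next
      starts0 <- if (L[t] <= R) rep(0L, nt)
                 else sample.int(ptot[t], nt, replace = TRUE) - 1L
      pl <- .place_reads(exl[[t]], starts0, R, cfg$min_overhang)
      pl$gene_id <- g; pl$transcript_id <- txs[t]
      rows[[length(rows) + 1L]] <- pl
    }
  }
  reads <- do.call(rbind, rows)
  reads$true_strand <- layout$genes[reads$gene_id, "strand"]
  reads$carryover <- FALSE
  reads$carry_target <- NA_character_

  ## nascent background: same-strand unspliced reads over the gene span
  if (cfg$intron_noise > 0) {
    for (g in gid) {
      nn <- as.integer(round(cfg$intron_noise * reads_per_gene[[g]]))
      sp_s <- layout$genes[g, "span_start"]; sp_e <- layout$genes[g, "span_end"]
      if (nn == 0L || sp_e - sp_s + 1L <= R) next
      pos <- sample(sp_s:(sp_e - R + 1L), nn, replace = TRUE)
      reads <- rbind(reads, data.frame(
        pos = pos, cigar = sprintf("%dM", R), spans_junction = FALSE,
        gene_id = g, transcript_id = NA_character_,
        true_strand = layout$genes[g, "strand"], carryover = FALSE,
        carry_target = NA_character_))
    }
  }

  ## carry-over reads: unspliced, source strand, over the target span
  if (!is.null(carry_over) && nrow(carry_over) > 0) {
    for (i in seq_len(nrow(carry_over))) {
      src <- carry_over$source[i]; tgt <- carry_over$target[i]
      f <- carry_over$fraction[i]
      stopifnot(src %in% gid, tgt %in% gid, f >= 0)
      nc <- as.integer(round(f * reads_per_gene[[src]]))
      if (nc == 0L) next
      lo <- max(1L, layout$genes[tgt, "span_start"] - R + 1L)
      hi <- min(layout$chrom_len - R, layout$genes[tgt, "span_end"])
      pos <- sample(lo:hi, nc, replace = TRUE)
      rows_c <- data.frame(pos = pos, cigar = sprintf("%dM", R),
                           spans_junction = FALSE, gene_id = src,
                           transcript_id = NA_character_,
                           true_strand = layout$genes[src, "strand"],
                           carryover = TRUE, carry_target = tgt)
      reads <- rbind(reads, rows_c)
    }
  }
  reads$qname <- sprintf("r%07d", seq_len(nrow(reads)))

  ## alignment strand under the protocol
  aln_strand <- switch(cfg$protocol,
    R = .flip_strand(reads$true_strand),
    F = reads$true_strand,
    U = sample(c("+", "-"), nrow(reads), replace = TRUE))

  .write_bam(reads, aln_strand, layout, R, bam_path)

  ## ground truth: replay blocks with true strands
  cr <- GenomicAlignments::cigarRangesAlongReferenceSpace(reads$cigar,
                                                          pos = reads$pos,
                                                          ops = "M")
  bl <- unlist(cr)
  bread <- rep(seq_len(nrow(reads)), lengths(cr))
  planted <- .replay_unique_counts(start(bl), end(bl), bread,
                                   reads$true_strand, layout)
  intr <- table(factor(reads$gene_id[!reads$carryover], gid))
  recv <- table(factor(reads$carry_target[reads$carryover], gid))
  gene_truth <- data.frame(
    gene_id = gid,
    n_intrinsic = as.integer(intr),
    n_carry_received = as.integer(recv),
    planted[gid, c("planted_ustno", "planted_stno", "planted_log2_ratio")],
    row.names = gid, stringsAsFactors = FALSE)

  list(bam = bam_path, read_truth = reads, gene_truth = gene_truth,
       config = cfg)
}

.write_bam <- function(reads, aln_strand, layout, read_len, bam_path) {
  flag <- ifelse(aln_strand == "-", 16L, 0L)
  seq <- strrep("A", read_len)
  sam <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                 reads$qname, flag, layout$chrom, reads$pos, reads$cigar,
                 seq)
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom, layout$chrom_len))
  sam_path <- sub("\\.bam$", ".sam", bam_path)
  writeLines(c(header, sam), sam_path)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam_path, dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)
  invisible(bam_path)
}

#' Simulate a multi-sample training corpus of pseudo-cell-types
#'
#' Generates one annotation and `n_types` read samples from it, emulating
#' cell types: each type perturbs a shared log-normal expression profile
#' and plants opposite-strand carry-over into a shared set of target genes
#' plus a type-specific set, at fractions spanning sub- and super-threshold
#' planted ratios. Sources are up-weighted in expression (carry-over stems
#' from highly expressed genes), targets down-weighted. Designed for the
#' train-on-all-but-one / test-on-held-out evaluation of [sb_train()].
#'
#' @param dir output directory for GTF and BAMs.
#' @param seed master seed.
#' @param n_types number of pseudo-cell-types (default 15).
#' @param n_genes genes in the layout (default 60).
#' @param reads_per_type intrinsic reads per sample (default 12000).
#' @param read_length,min_overhang read configuration (defaults 50 / 8).
#' @return list with `gtf`, `layout`, `cfg`, and per-type lists `bam` and
#'   `truth` (the [simulate_reads()] ground truth).
#' @export
simulate_celltypes <- function(dir, seed = 1L, n_types = 15L, n_genes = 60L,
                               reads_per_type = 12000L, read_length = 50L,
                               min_overhang = 8L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    read_length = read_length, min_overhang = min_overhang,
                    protocol = "R", n_reads = reads_per_type)
  gtf <- file.path(dir, "annotation.gtf")
  layout <- simulate_annotation(cfg, gtf)
  gid <- layout$genes$gene_id
  ngene <- length(gid)

  ## candidate carry-over pairs: opposite-strand genes within 2 kb
  sp <- layout$genes
  cand <- list()
  for (i in seq_len(ngene - 1L)) for (j in (i + 1L):ngene) {
    gap <- max(sp$span_start[j] - sp$span_end[i],
               sp$span_start[i] - sp$span_end[j], 0L)
    if (gap <= 2000L && sp$strand[i] != sp$strand[j]) {
      cand[[length(cand) + 1L]] <- c(i, j)
      cand[[length(cand) + 1L]] <- c(j, i)
    }
  }
  set.seed(seed + 1000L)
  cand <- cand[sample.int(length(cand))]
  ## the shared (every-type) pairs cover both gene classes so that every
  ## sample carries affected monoexonic as well as multiexonic genes
  mono_tgt <- vapply(cand, function(p) sp$monoexonic[p[2]], logical(1))
  shared_idx <- c(utils::head(which(mono_tgt), 2L),
                  utils::head(which(!mono_tgt), 2L))
  shared <- cand[shared_idx]
  pool <- cand[setdiff(seq_along(cand), shared_idx)]

  base_w <- stats::rlnorm(ngene, meanlog = 0, sdlog = 1)
  names(base_w) <- gid

  out_bam <- character(n_types); out_truth <- vector("list", n_types)
  for (ct in seq_len(n_types)) {
    set.seed(seed + 2000L + ct)
    pairs <- shared
    n_shared <- length(shared)
    if (length(pool))
      pairs <- c(pairs, pool[sample.int(length(pool),
                                        min(2L, length(pool)))])
    co <- data.frame(source = gid[vapply(pairs, `[`, integer(1), 1L)],
                     target = gid[vapply(pairs, `[`, integer(1), 2L)],
                     fraction = c(runif(n_shared, 1.0, 2.5),
                                  runif(length(pairs) - n_shared, 0.3, 2.5)))
    w <- base_w * exp(stats::rnorm(ngene, 0, 0.4))
    w[co$source] <- w[co$source] * runif(nrow(co), 5, 10)
    w[co$target] <- w[co$target] * runif(nrow(co), 0.1, 0.4)
    rpg <- as.integer(pmax(round(w / sum(w) * reads_per_type), 20L))
    names(rpg) <- gid
    bam <- file.path(dir, sprintf("type%02d.bam", ct))
    out_truth[[ct]] <- simulate_reads(layout, cfg, bam,
                                      reads_per_gene = rpg,
                                      carry_over = co,
                                      seed = seed + 3000L + ct)
    out_bam[ct] <- bam
  }
  list(gtf = gtf, layout = layout, cfg = cfg, bam = out_bam,
       truth = out_truth)
}
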