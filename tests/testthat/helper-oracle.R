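# Independent brute-force oracles.
#
# oracle_counts() classifies every BAM record by exhaustive per-base
# membership against per-gene position masks, with its own CIGAR walker —
# no shared code with count_bam()'s overlap machinery.

.parse_cigar <- function(cig, pos) {
  n <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  op <- regmatches(cig, gregexpr("[A-Z]", cig))[[1]]
  blocks <- list(); gaps <- list()
  ref <- pos; bstart <- NA_integer_
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      if (is.na(bstart)) bstart <- ref
      ref <- ref + n[i]
    } else if (op[i] == "N") {
      blocks[[length(blocks) + 1L]] <- c(bstart, ref - 1L)
      gaps[[length(gaps) + 1L]] <- c(ref, ref + n[i] - 1L)
      bstart <- NA_integer_
      ref <- ref + n[i]
    }
    # S, I, H consume no reference
  }
  if (!is.na(bstart)) blocks[[length(blocks) + 1L]] <- c(bstart, ref - 1L)
  list(blocks = do.call(rbind, blocks),
       gaps = if (length(gaps)) do.call(rbind, gaps) else NULL)
}

# per-gene logical position masks over one chromosome
.region_mask <- function(grl, glen, ngene) {
  m <- matrix(FALSE, nrow = glen, ncol = ngene)
  for (i in seq_len(ngene)) {
    r <- grl[[i]]
    for (k in seq_along(r))
      m[IRanges::start(r)[k]:IRanges::end(r)[k], i] <- TRUE
  }
  m
}

oracle_counts <- function(bam, db, strandedness = "U", mapq_min = 10) {
  sc <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  ngene <- nrow(db$genes)
  gene_ids <- db$genes$gene_id
  stopifnot(length(unique(db$genes$chrom)) == 1L)  # oracle fixture scope
  glen <- max(db$genes$span_end) + 1000L
  exon_m <- .region_mask(db$exon_union, glen, ngene)
  intr_m <- .region_mask(db$introns, glen, ngene)
  jset <- paste(db$junctions$start, db$junctions$end,
                match(db$junctions$gene_id, gene_ids))

  z <- integer(ngene)
  res <- data.frame(gene_id = gene_ids, n_st = z, n_stno = z, n_ust = z,
                    n_ustno = z, n_jctn = z, n_intr = z,
                    row.names = gene_ids)
  flags <- sc$flag
  keep <- bitwAnd(flags, 4L) == 0L & bitwAnd(flags, 256L) == 0L &
    bitwAnd(flags, 2048L) == 0L & bitwAnd(flags, 1024L) == 0L &
    (!is.na(sc$mapq) & sc$mapq >= mapq_min) &
    as.character(sc$rname) %in% db$genes$chrom
  for (i in which(keep)) {
    pc <- .parse_cigar(sc$cigar[i], sc$pos[i])
    pos <- unlist(apply(pc$blocks, 1, function(b) b[1]:b[2],
                        simplify = FALSE))
    exon_hit <- which(colSums(exon_m[pos, , drop = FALSE]) > 0)
    aln_strand <- if (bitwAnd(flags[i], 16L) > 0L) "-" else "+"
    gstrand <- switch(strandedness, U = "*", F = aln_strand,
                      R = if (aln_strand == "+") "-" else "+")
    res$n_ust[exon_hit] <- res$n_ust[exon_hit] + 1L
    st_hit <- exon_hit[db$genes$strand[exon_hit] == gstrand]
    res$n_st[st_hit] <- res$n_st[st_hit] + 1L
    if (length(exon_hit) == 1L) {
      res$n_ustno[exon_hit] <- res$n_ustno[exon_hit] + 1L
      if (db$genes$strand[exon_hit] == gstrand)
        res$n_stno[exon_hit] <- res$n_stno[exon_hit] + 1L
    }
    if (!is.null(pc$gaps)) {
      jg <- integer(0)
      for (k in seq_len(nrow(pc$gaps))) {
        hit <- match(paste(pc$gaps[k, 1], pc$gaps[k, 2], seq_len(ngene)),
                     jset)
        jg <- c(jg, which(!is.na(hit)))
      }
      jg <- intersect(unique(jg), exon_hit)
      res$n_jctn[jg] <- res$n_jctn[jg] + 1L
    }
    if (length(exon_hit) == 0L) {
      intr_hit <- which(colSums(intr_m[pos, , drop = FALSE]) > 0)
      res$n_intr[intr_hit] <- res$n_intr[intr_hit] + 1L
    }
  }
  if (strandedness == "U") {
    res$n_st <- NA_integer_; res$n_stno <- NA_integer_
  }
  res
}

# Exhaustive placement-by-placement junction probability for single-end
# fixed-length reads: loops over every start of every isoform and tests
# each internal boundary directly.
oracle_junction_prob <- function(isoform_widths, read_len, overhang) {
  tot <- 0; jct <- 0
  for (w in isoform_widths) {
    L <- sum(w)
    b <- if (length(w) > 1) cumsum(w)[-length(w)] else numeric(0)
    starts <- if (L <= read_len) 0 else 0:(L - read_len)
    for (s in starts) {
      e <- min(s + read_len, L)
      tot <- tot + 1
      if (any(b > s & b < e & (b - s) >= overhang & (e - b) >= overhang))
        jct <- jct + 1
    }
  }
  c(total = tot, jct = jct, p = if (tot > 0) jct / tot else 0)
}
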