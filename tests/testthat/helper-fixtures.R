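# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# the 15 pseudo-cell-type corpus used for classifier tests
training_sim <- function() {
  cached_fixture("training_sim", {
    d <- file.path(tempdir(), "ss_training_corpus")
    simulate_celltypes(d, seed = 1, n_types = 15)
  })
}

training_db <- function() {
  cached_fixture("training_db", build_db(training_sim()$gtf))
}

toy_gtf_path <- function() {
  system.file("extdata", "toy.gtf", package = "strandsense")
}

toy_db <- function() {
  cached_fixture("toy_db", build_db(toy_gtf_path()))
}

# Write GTF exon records from a compact spec:
# genes = list(list(id=, strand=, tx=list(c(start1,end1, start2,end2, ...))))
write_test_gtf <- function(genes, path = tempfile(fileext = ".gtf"),
                           chrom = "chrZ") {
  lines <- character(0)
  for (g in genes) {
    for (t in seq_along(g$tx)) {
      co <- matrix(g$tx[[t]], ncol = 2, byrow = TRUE)
      att <- sprintf('gene_id "%s"; transcript_id "%s.T%d"; gene_name "%s"; gene_type "test";',
                     g$id, g$id, t, g$id)
      lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                                chrom, co[, 1], co[, 2], g$strand, att))
    }
  }
  writeLines(lines, path)
  path
}

# Write a sorted+indexed BAM from hand-specified alignment records.
# reads: data.frame qname, flag, pos, cigar, mapq (chrom shared)
write_test_bam <- function(reads, chrom = "chrT", chrom_len = 100000L,
                           bam = tempfile(fileext = ".bam")) {
  cig_len <- function(cig) {
    n <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    op <- regmatches(cig, gregexpr("[A-Z]", cig))[[1]]
    sum(n[op %in% c("M", "I", "S", "=", "X")])
  }
  if (is.null(reads$rnext)) {
    reads$rnext <- rep("*", nrow(reads))
    reads$pnext <- rep(0L, nrow(reads))
    reads$tlen <- rep(0L, nrow(reads))
  }
  rec <- vapply(seq_len(nrow(reads)), function(i) {
    len <- cig_len(reads$cigar[i])
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
            reads$qname[i], reads$flag[i], chrom, reads$pos[i],
            reads$mapq[i], reads$cigar[i], reads$rnext[i], reads$pnext[i],
            reads$tlen[i], strrep("A", len))
  }, character(1))
  sam <- sub("\\.bam$", ".sam", bam)
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len), rec), sam)
  Rsamtools::asBam(sam, sub("\\.bam$", "", bam), overwrite = TRUE,
                   indexDestination = TRUE)
  unlink(sam)
  bam
}

# Hand-placed single-end reads over the toy annotation (see
# test-counting.R for the per-read enumeration); r11 fails the mapq
# filter and r13 is flagged duplicate.
hand_reads <- function() {
  data.frame(
    qname = sprintf("r%02d", 1:13),
    flag = c(16L, 0L, 16L, 0L, 16L, 16L, 16L, 0L, 16L, 0L, 16L, 16L, 1024L),
    pos = c(110L, 110L, 101L, 101L, 181L, 191L, 221L, 251L, 5050L, 5050L,
            110L, 1000L, 5050L),
    cigar = c("50M", "50M", "40M", "40M", "20M100N30M", "10M100N40M",
              "50M", "50M", "50M", "50M", "50M", "50M", "50M"),
    mapq = c(60L, 60L, 60L, 60L, 60L, 60L, 60L, 60L, 60L, 60L, 5L, 60L, 60L))
}

# Five seeded counting fixtures with planted carry-over (>= 20 genes,
# >= 10,000 reads each), shared across the acceptance checks.
acc_fixtures <- function() {
  cached_fixture("acc_fixtures", {
    lapply(1:5, function(s) {
      dir <- file.path(tempdir(), sprintf("ss_acc_fixture_%d", s))
      dir.create(dir, showWarnings = FALSE)
      cfg <- sim_config(seed = s, n_genes = 20, n_reads = 10000,
                        carry_over = data.frame(
                          source = c("G001", "G003"),
                          target = c("G002", "G004"),
                          fraction = c(0.8, 1.2)))
      layout <- simulate_annotation(cfg, file.path(dir, "a.gtf"))
      set.seed(s)
      w <- stats::rlnorm(nrow(layout$genes), 0, 1)
      names(w) <- layout$genes$gene_id
      w[c("G001", "G003")] <- max(w) * c(6, 8)
      w[c("G002", "G004")] <- min(w) * c(0.5, 0.5)
      rpg <- as.integer(pmax(round(w / sum(w) * cfg$n_reads), 15L))
      names(rpg) <- layout$genes$gene_id
      sim <- simulate_reads(layout, cfg, file.path(dir, "s.bam"),
                            reads_per_gene = rpg)
      list(seed = s, layout = layout, cfg = cfg, sim = sim,
           db = build_db(layout$gtf))
    })
  })
}
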