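# Hand-placed reads (helper hand_reads()) over the toy annotation:
#   GA (+): exons 101-200 and 301-400, junction intron 201-300
#   GB (-): exon 151-250 (antisense overlap with GA over 151-200)
#   GC (+): exon 5001-5300, isolated
# Library protocol R: a read aligned "-" derives from a "+" gene.
# r1  110+50M  "-"->"+": exons of GA and GB -> ambiguous, same-strand GA
# r2  110+50M  "+"->"-": ditto, same-strand GB
# r3  101+40M  "-"->"+": unique GA -> all four counts of GA
# r4  101+40M  "+"->"-": unique GA but antisense -> unstranded counts only
# r5,r6 spliced over GA's junction (also overlap GB -> ambiguous)
# r7  221+50M: GB exon + GA intron -> GB unstranded counts
# r8  251+50M: GA intron only -> n_intr of GA
# r9,r10 within GC; r12 intergenic

test_that("the six count types match a hand enumeration of twelve placed reads", {
  db <- toy_db()
  bam <- write_test_bam(hand_reads())
  counts <- count_bam(bam, db, strandedness = "R")

  expect_equal(counts["GA", c("n_ust", "n_ustno", "n_st", "n_stno",
                              "n_jctn", "n_intr")],
               data.frame(n_ust = 6L, n_ustno = 2L, n_st = 4L, n_stno = 1L,
                          n_jctn = 2L, n_intr = 1L, row.names = "GA"))
  expect_equal(counts["GB", c("n_ust", "n_ustno", "n_st", "n_stno",
                              "n_jctn", "n_intr")],
               data.frame(n_ust = 5L, n_ustno = 1L, n_st = 1L, n_stno = 0L,
                          n_jctn = 0L, n_intr = 0L, row.names = "GB"))
  expect_equal(counts["GC", c("n_ust", "n_ustno", "n_st", "n_stno",
                              "n_jctn", "n_intr")],
               data.frame(n_ust = 2L, n_ustno = 2L, n_st = 1L, n_stno = 1L,
                          n_jctn = 0L, n_intr = 0L, row.names = "GC"))

  d <- attr(counts, "diagnostics")
  expect_equal(unname(d["used"]), 11L)       # mapq<10 and duplicate dropped
  expect_equal(unname(d["ambiguous"]), 4L)
  expect_equal(unname(d["no_feature"]), 1L)
  expect_equal(unname(d["missing_chrom"]), 0L)

  # unstranded pass: strand-aware columns undefined, the rest unchanged
  u <- count_bam(bam, db, strandedness = "U")
  expect_true(all(is.na(u$n_st)) && all(is.na(u$n_stno)))
  expect_equal(u$n_ust, counts$n_ust)
  expect_equal(u$n_ustno, counts$n_ustno)
  expect_equal(u$n_jctn, counts$n_jctn)
  expect_equal(u$n_intr, counts$n_intr)

  # determinism
  expect_identical(count_bam(bam, db, strandedness = "R"), counts)
})

test_that("strand inference follows the dUTP conventions", {
  expect_equal(infer_read_gene_strand("-", "R"), "+")
  expect_equal(infer_read_gene_strand("+", "F"), "+")
  expect_equal(infer_read_gene_strand(c("+", "-"), "U"), c("*", "*"))
  expect_equal(infer_read_gene_strand("+", "R", second_in_pair = TRUE), "+")
})

test_that("an empty BAM yields all-zero counts and adding reads never decreases them", {
  db <- toy_db()
  empty <- write_test_bam(hand_reads()[0, ])
  z <- count_bam(empty, db, strandedness = "R")
  expect_true(all(z[, c("n_st", "n_stno", "n_ust", "n_ustno",
                        "n_jctn", "n_intr")] == 0L))

  sub <- count_bam(write_test_bam(hand_reads()[1:8, ]), db, "R")
  full <- count_bam(write_test_bam(hand_reads()), db, "R")
  for (col in c("n_st", "n_stno", "n_ust", "n_ustno", "n_jctn", "n_intr"))
    expect_true(all(full[[col]] >= sub[[col]]))
})

test_that("flipping all read strands while swapping F and R leaves counts unchanged", {
  dirR <- tempfile(); dir.create(dirR)
  dirF <- tempfile(); dir.create(dirF)
  cfg <- sim_config(seed = 3, n_genes = 12, n_reads = 4000, protocol = "R")
  layR <- simulate_annotation(cfg, file.path(dirR, "a.gtf"))
  simR <- simulate_reads(layR, cfg, file.path(dirR, "r.bam"))
  cfgF <- sim_config(seed = 3, n_genes = 12, n_reads = 4000, protocol = "F")
  layF <- simulate_annotation(cfgF, file.path(dirF, "a.gtf"))
  simF <- simulate_reads(layF, cfgF, file.path(dirF, "f.bam"))

  db <- build_db(layR$gtf)
  cR <- count_bam(simR$bam, db, strandedness = "R")
  cF <- count_bam(simF$bam, db, strandedness = "F")
  expect_equal(cR, cF, ignore_attr = TRUE)
})

test_that("paired-end fragments pool both mates and are counted once", {
  db <- toy_db()
  pairs <- data.frame(
    qname = c("p1", "p1", "p2", "p2"),
    flag = c(163L, 83L, 163L, 83L),
    pos = c(301L, 351L, 181L, 351L),
    cigar = c("50M", "50M", "20M100N30M", "50M"),
    mapq = 60L,
    rnext = "=",
    pnext = c(351L, 301L, 351L, 181L),
    tlen = c(100L, -100L, 220L, -220L))
  bam <- write_test_bam(pairs)
  counts <- count_bam(bam, db, strandedness = "R")
  expect_equal(unname(attr(counts, "diagnostics")["unit_fragment"]), 1L)
  expect_equal(counts["GA", c("n_ust", "n_ustno", "n_st", "n_stno", "n_jctn")],
               data.frame(n_ust = 2L, n_ustno = 1L, n_st = 2L, n_stno = 1L,
                          n_jctn = 1L, row.names = "GA"))
  expect_equal(counts["GB", "n_ust"], 1L)
  expect_equal(counts["GB", "n_st"], 0L)
})

test_that("TPM normalization is length-corrected and sums to one million", {
  gtf <- write_test_gtf(list(
    list(id = "L1", strand = "+", tx = list(c(1001, 2000))),        # 1 kb
    list(id = "L2", strand = "+", tx = list(c(11001, 13000))),      # 2 kb
    list(id = "L3", strand = "+", tx = list(c(21001, 24000)))))     # 3 kb
  db <- build_db(gtf)
  mk <- function(x) data.frame(gene_id = c("L1", "L2", "L3"), n_ust = x,
                               row.names = c("L1", "L2", "L3"))

  # counts proportional to length: equal rates, equal TPM
  tpm <- compute_tpm(mk(c(10, 20, 30)), db, "n_ust")
  expect_equal(unname(tpm), rep(1e6 / 3, 3))
  expect_equal(sum(tpm), 1e6)

  # single expressed gene takes the full million
  expect_equal(unname(compute_tpm(mk(c(0, 7, 0)), db, "n_ust")),
               c(0, 1e6, 0))

  # equal counts, equal lengths -> half a million each
  gtf2 <- write_test_gtf(list(
    list(id = "E1", strand = "+", tx = list(c(1001, 2000))),
    list(id = "E2", strand = "+", tx = list(c(11001, 12000)))))
  db2 <- build_db(gtf2)
  c2 <- data.frame(gene_id = c("E1", "E2"), n_ust = c(5, 5))
  expect_equal(unname(compute_tpm(c2, db2, "n_ust")), c(5e5, 5e5))

  # all-zero counts stay zero, and NA stranded columns are rejected
  expect_equal(unname(compute_tpm(mk(c(0, 0, 0)), db, "n_ust")), rep(0, 3))
  cna <- mk(c(1, 2, 3)); cna$n_st <- NA_integer_
  expect_error(compute_tpm(cna, db, "n_st"), "NA")
})

test_that("count invariants hold gene-wise on simulated libraries", {
  sim <- training_sim()
  db <- training_db()
  for (i in c(1, 8)) {
    counts <- count_bam(sim$bam[i], db, strandedness = "R")
    expect_true(all(counts$n_stno <= counts$n_ustno))
    expect_true(all(counts$n_stno <= counts$n_st))
    expect_true(all(counts$n_ustno <= counts$n_ust))
    expect_true(all(counts$n_jctn <= counts$n_ust))
  }
})
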