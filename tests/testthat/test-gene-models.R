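test_that("exon unions, introns and junctions follow from the transcript structure", {
  gtf <- write_test_gtf(list(
    list(id = "G2EX", strand = "+", tx = list(c(101, 200, 301, 400))),
    list(id = "GMONO", strand = "-", tx = list(c(9001, 9400)))))
  db <- build_db(gtf)

  g <- db$genes["G2EX", ]
  expect_equal(g$exonic_len, 200L)
  expect_equal(g$intron_len, 100L)
  expect_false(g$monoexonic)
  expect_equal(db$junctions[db$junctions$gene_id == "G2EX", c("start", "end")],
               data.frame(start = 201L, end = 300L), ignore_attr = TRUE)
  expect_equal(as.data.frame(ranges(db$introns[["G2EX"]]))[, c("start", "end")],
               data.frame(start = 201L, end = 300L), ignore_attr = TRUE)

  m <- db$genes["GMONO", ]
  expect_true(m$monoexonic)
  expect_equal(m$intron_len, 0L)
  expect_equal(length(db$introns[["GMONO"]]), 0L)
  expect_equal(nrow(db$junctions[db$junctions$gene_id == "GMONO", ]), 0L)
})

test_that("exonic overlap is subtracted strand-blind and measured as a fraction", {
  gtf <- write_test_gtf(list(
    list(id = "A", strand = "+", tx = list(c(101, 200))),
    list(id = "B", strand = "-", tx = list(c(151, 250))),
    list(id = "ISO", strand = "+", tx = list(c(9001, 9100)))))
  db <- build_db(gtf)

  # brute-force per-base membership over the contested region
  base_in <- function(grl, g, p) any(p >= start(grl[[g]]) & p <= end(grl[[g]]))
  a_nonov <- vapply(101:250, function(p) base_in(db$nonoverlap, "A", p), logical(1))
  expect_equal(which(a_nonov) + 100L, 101:150)

  expect_equal(overlap_fraction("A", db), 0.5)
  expect_equal(overlap_fraction("B", db), 0.5)
  expect_equal(overlap_fraction("ISO", db), 0)
  expect_setequal(find_neighbors("A", db), "B")
  expect_setequal(find_neighbors("B", db), "A")
  expect_equal(find_neighbors("ISO", db), character(0))

  # full containment
  gtf2 <- write_test_gtf(list(
    list(id = "IN", strand = "+", tx = list(c(120, 180))),
    list(id = "OUT", strand = "-", tx = list(c(101, 300)))))
  db2 <- build_db(gtf2)
  expect_equal(overlap_fraction("IN", db2), 1.0)
})

test_that("neighbor relation is symmetric with an inclusive 2 kb span-gap threshold", {
  # span gaps of exactly 1999, 2000 and 2001 bases
  gtf <- write_test_gtf(list(
    list(id = "N1", strand = "+", tx = list(c(1000, 2000))),
    list(id = "N2", strand = "-", tx = list(c(4000, 5000))),    # gap 1999
    list(id = "N3", strand = "+", tx = list(c(7001, 8000))),    # gap 2000
    list(id = "N4", strand = "+", tx = list(c(10002, 11000))))) # gap 2001
  db <- build_db(gtf)
  expect_true("N2" %in% find_neighbors("N1", db))
  expect_true("N1" %in% find_neighbors("N2", db))
  expect_true("N3" %in% find_neighbors("N2", db))
  expect_false("N4" %in% find_neighbors("N3", db))
  expect_equal(find_neighbors("N3", db, max_distance = 2001), c("N2", "N4"))
})

test_that("nonoverlap, shared exonic regions and introns tile each gene span exactly", {
  db <- training_db()
  for (gid in sample(db$genes$gene_id, 10)) {
    g <- db$genes[gid, ]
    span <- g$span_start:g$span_end
    in_rgl <- function(grl) {
      r <- grl[[gid]]
      out <- rep(FALSE, length(span))
      for (k in seq_along(r))
        out[span >= start(r)[k] & span <= end(r)[k]] <- TRUE
      out
    }
    exonic <- in_rgl(db$exon_union)
    nonov <- in_rgl(db$nonoverlap)
    intronic <- in_rgl(db$introns)
    expect_true(all(nonov | intronic | exonic))      # covers the span
    expect_false(any(nonov & intronic))              # disjoint
    expect_false(any(intronic & exonic))
    expect_true(all(!nonov | exonic))                # nonoverlap inside union
    expect_equal(sum(exonic) + sum(intronic), length(span))
  }
})

test_that("junction coordinates are exon boundaries with donor before acceptor", {
  db <- training_db()
  j <- db$junctions
  expect_true(all(j$start <= j$end))
  for (i in sample(nrow(j), min(25, nrow(j)))) {
    tx <- db$tx2gene$transcript_id[db$tx2gene$gene_id == j$gene_id[i]]
    ends <- unlist(lapply(tx, function(t) end(db$tx_exons[[t]])))
    starts <- unlist(lapply(tx, function(t) start(db$tx_exons[[t]])))
    expect_true((j$start[i] - 1L) %in% ends)    # donor exon end
    expect_true((j$end[i] + 1L) %in% starts)    # acceptor exon start
  }
})

test_that("database rebuild and save/load round trips are bit-identical", {
  gtf <- toy_gtf_path()
  db1 <- build_db(gtf)
  db2 <- build_db(gtf)
  expect_identical(serialize(db1, NULL, version = 2),
                   serialize(db2, NULL, version = 2))

  d <- tempfile("dbdir")
  save_db(db1, d)
  expect_identical(serialize(load_db(d), NULL, version = 2),
                   serialize(db1, NULL, version = 2))
  expect_error(save_db(db1, d), "already exists")
  expect_silent(save_db(db1, d, force = TRUE))
})

test_that("malformed annotations are rejected with informative errors", {
  expect_error(build_db(tempfile()), "not found")

  # exon records without gene_id
  bad <- tempfile(fileext = ".gtf")
  writeLines("chrZ\tt\texon\t10\t20\t.\t+\t.\ttranscript_id \"T1\";", bad)
  expect_error(suppressWarnings(build_db(bad)))

  # gene with exons on both strands
  mixed <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrZ\tt\texon\t10\t20\t.\t+\t.\tgene_id "GX"; transcript_id "GX.T1";',
    'chrZ\tt\texon\t50\t60\t.\t-\t.\tgene_id "GX"; transcript_id "GX.T2";'),
    mixed)
  expect_error(build_db(mixed), "both strands")

  # overlapping exons within one transcript are merged with a warning
  selfov <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrZ\tt\texon\t10\t60\t.\t+\t.\tgene_id "GY"; transcript_id "GY.T1";',
    'chrZ\tt\texon\t40\t90\t.\t+\t.\tgene_id "GY"; transcript_id "GY.T1";'),
    selfov)
  expect_warning(dbm <- build_db(selfov), "merged")
  expect_equal(dbm$genes["GY", "exonic_len"], 81L)
})
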