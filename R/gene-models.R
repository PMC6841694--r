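#' Build a gene-model database from a GTF annotation
#'
#' Parses exon records of a Gencode-style GTF and constructs one immutable
#' model per gene: the exon union over all its transcripts, the portion of
#' that union not overlapping any other gene's exons (on either strand, so
#' stranded and unstranded unique-region counts refer to the identical
#' region), introns (gene span minus exon union), the set of annotated
#' splice junctions from consecutive exons of each transcript, per-transcript
#' exon chains, and the list of neighboring genes whose span lies within
#' `neighbor_distance` bp. The returned database is the input for
#' [count_bam()], [junction_probability()] and the analyze step; it can be
#' persisted with [save_db()] and reloaded bit-identically with [load_db()].
#'
#' GTF coordinates (1-based closed) are kept in that convention throughout;
#' a splice junction is identified by its intron interval, i.e. for adjacent
#' exons ending at position `d` and starting at position `a` the junction is
#' the interval `[d + 1, a - 1]`.
#'
#' @param gtf_path path to a GTF file with exon features.
#' @param attribute_keys named list mapping the internal keys `gene_id`,
#'   `transcript_id`, `gene_name`, `gene_type` to the attribute names used in
#'   the GTF. Defaults to the Gencode names.
#' @param transcript_tag optional character; when set, only transcripts whose
#'   `tag` attribute contains this value (e.g. `"basic"`) are used. Rare or
#'   low-confidence transcript models depress the expected junction
#'   probability of a gene, so pruning them is recommended when the
#'   annotation carries a suitable tag. Default `NULL` (keep all).
#' @param neighbor_distance maximum gap in bp between two gene spans for the
#'   genes to be considered neighbors (inclusive). Default 2000.
#'
#' @return An object of class `genome_db`; a list with elements
#'   \describe{
#'     \item{genes}{data.frame of per-gene scalars: `gene_id`, `gene_name`,
#'       `biotype`, `chrom`, `strand`, `span_start`, `span_end`,
#'       `exonic_len`, `nonoverlap_len`, `intron_len`, `overlap_fraction`,
#'       `n_junctions`, `monoexonic`.}
#'     \item{exon_union, nonoverlap, introns}{`GRangesList`s named by gene.}
#'     \item{junctions}{data.frame `gene_id`, `chrom`, `start`, `end`
#'       (intron coordinates).}
#'     \item{tx_exons}{`GRangesList` of exons per transcript.}
#'     \item{tx2gene}{data.frame `transcript_id`, `gene_id`.}
#'     \item{neighbors}{named list of neighbor gene_id vectors.}
#'   }
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "strandsense")
#' db <- build_db(gtf)
#' db$genes[, c("gene_id", "exonic_len", "monoexonic", "overlap_fraction")]
#' @export
build_db <- function(gtf_path,
                     attribute_keys = list(gene_id = "gene_id",
                                           transcript_id = "transcript_id",
                                           gene_name = "gene_name",
                                           gene_type = "gene_type"),
                     transcript_tag = NULL,
                     neighbor_distance = 2000L) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon records in ", gtf_path)

  getattr <- function(key, required = FALSE) {
    nm <- attribute_keys[[key]]
    v <- mcols(ex)[[nm]]
    if (is.null(v)) {
      if (required) stop("GTF exon records lack required attribute '", nm, "'")
      v <- rep(NA_character_, length(ex))
    }
    as.character(v)
  }
  gene_id <- getattr("gene_id", required = TRUE)
  tx_id <- getattr("transcript_id", required = TRUE)
  bad <- which(is.na(gene_id) | gene_id == "" | is.na(tx_id) | tx_id == "")
  if (length(bad))
    stop("exon record ", bad[1], " (of ", length(ex),
         ") is missing a gene_id or transcript_id attribute")
  gene_name <- getattr("gene_name")
  gene_type <- getattr("gene_type")

  if (!is.null(transcript_tag)) {
    tagv <- mcols(ex)[["tag"]]
    if (is.null(tagv)) stop("transcript_tag filtering requested but the GTF has no 'tag' attribute")
    keep <- vapply(tagv, function(t) any(!is.na(t) & t == transcript_tag), logical(1))
    ex <- ex[keep]; gene_id <- gene_id[keep]; tx_id <- tx_id[keep]
    gene_name <- gene_name[keep]; gene_type <- gene_type[keep]
    if (length(ex) == 0L) stop("no exon records left after tag filter '", transcript_tag, "'")
  }

  strand_chr <- as.character(strand(ex))
  if (any(strand_chr == "*"))
    stop("exon records without strand for gene(s): ",
         paste(unique(gene_id[strand_chr == "*"]), collapse = ", "))

  ## reject genes spanning several chromosomes or with mixed strands
  gsplit <- split(seq_along(ex), gene_id)
  for (g in names(gsplit)) {
    i <- gsplit[[g]]
    if (length(unique(as.character(seqnames(ex)[i]))) > 1L)
      stop("gene ", g, " has exons on multiple chromosomes")
    if (length(unique(strand_chr[i])) > 1L)
      stop("gene ", g, " has exons on both strands")
  }

  ## per-transcript exon chains; merge self-overlapping exons with a warning
  tx_exons <- GenomicRanges::reduce(S4Vectors::split(granges(ex), tx_id))
  n_in <- lengths(S4Vectors::split(seq_along(ex), tx_id))
  merged <- names(tx_exons)[lengths(tx_exons) < n_in[names(tx_exons)]]
  if (length(merged))
    warning("overlapping or adjacent exons merged within transcript(s): ",
            paste(merged, collapse = ", "))
  tx2gene <- unique(data.frame(transcript_id = tx_id, gene_id = gene_id,
                               stringsAsFactors = FALSE))
  if (anyDuplicated(tx2gene$transcript_id))
    stop("transcript assigned to more than one gene: ",
         tx2gene$transcript_id[duplicated(tx2gene$transcript_id)][1])
  rownames(tx2gene) <- tx2gene$transcript_id
  tx2gene <- tx2gene[names(tx_exons), ]

  exon_union <- GenomicRanges::reduce(S4Vectors::split(granges(ex), gene_id))
  gene_ids <- names(exon_union)
  ngene <- length(gene_ids)

  first_idx <- vapply(gsplit[gene_ids], `[`, integer(1), 1L)
  chrom <- as.character(seqnames(ex))[first_idx]
  gstrand <- strand_chr[first_idx]
  gname <- gene_name[first_idx]
  gtype <- gene_type[first_idx]

  span_start <- vapply(seq_len(ngene), function(i) min(start(exon_union[[i]])), integer(1))
  span_end <- vapply(seq_len(ngene), function(i) max(end(exon_union[[i]])), integer(1))
  span_gr <- GRanges(chrom, IRanges(span_start, span_end), strand = gstrand)
  names(span_gr) <- gene_ids

  introns <- IRanges::psetdiff(span_gr, exon_union)

  ## junctions: consecutive exons of each (merged) transcript chain
  jl <- lapply(names(tx_exons), function(t) {
    e <- tx_exons[[t]]
    if (length(e) < 2L) return(NULL)
    e <- e[order(start(e))]
    data.frame(gene_id = tx2gene[t, "gene_id"],
               chrom = as.character(seqnames(e))[1],
               start = end(e)[-length(e)] + 1L,
               end = start(e)[-1L] - 1L,
               stringsAsFactors = FALSE)
  })
  junctions <- unique(do.call(rbind, c(jl, list(NULL))))
  if (is.null(junctions))
    junctions <- data.frame(gene_id = character(), chrom = character(),
                            start = integer(), end = integer())
  rownames(junctions) <- NULL

  ## non-overlapping exonic region: subtract every other gene's exon union,
  ## regardless of strand
  exon_all <- unlist(exon_union, use.names = FALSE)
  exon_all$gene_idx <- rep(seq_len(ngene), lengths(exon_union))
  nonoverlap <- exon_union
  ov <- findOverlaps(exon_union, exon_all, ignore.strand = TRUE)
  ov <- ov[exon_all$gene_idx[subjectHits(ov)] != queryHits(ov)]
  for (i in unique(queryHits(ov))) {
    others <- exon_all[subjectHits(ov)[queryHits(ov) == i]]
    nonoverlap[[i]] <- BiocGenerics::setdiff(exon_union[[i]], others,
                                              ignore.strand = TRUE)
  }

  exonic_len <- sum(IRanges::width(exon_union))
  nonoverlap_len <- sum(IRanges::width(nonoverlap))
  intron_len <- sum(IRanges::width(introns))
  n_junctions <- as.integer(table(factor(junctions$gene_id, gene_ids)))
  monoexonic <- n_junctions == 0L

  ## neighbors: spans within neighbor_distance on either strand
  nh <- findOverlaps(span_gr, span_gr, maxgap = neighbor_distance,
                     ignore.strand = TRUE)
  nh <- nh[queryHits(nh) != subjectHits(nh)]
  neighbors <- split(gene_ids[subjectHits(nh)], factor(queryHits(nh), seq_len(ngene)))
  neighbors <- lapply(neighbors, function(x) sort(unname(x)))
  names(neighbors) <- gene_ids

  genes <- data.frame(
    gene_id = gene_ids, gene_name = gname, biotype = gtype,
    chrom = chrom, strand = gstrand,
    span_start = span_start, span_end = span_end,
    exonic_len = as.integer(exonic_len),
    nonoverlap_len = as.integer(nonoverlap_len),
    intron_len = as.integer(intron_len),
    overlap_fraction = 1 - as.numeric(nonoverlap_len) / as.numeric(exonic_len),
    n_junctions = n_junctions, monoexonic = monoexonic,
    stringsAsFactors = FALSE)
  rownames(genes) <- gene_ids

  db <- list(genes = genes, exon_union = exon_union, nonoverlap = nonoverlap,
             introns = introns, junctions = junctions, tx_exons = tx_exons,
             tx2gene = tx2gene, neighbors = neighbors,
             neighbor_distance = as.integer(neighbor_distance))
  class(db) <- "genome_db"
  db
}

#' @export
print.genome_db <- function(x, ...) {
  g <- x$genes
  cat("genome_db with", nrow(g), "genes on",
      length(unique(g$chrom)), "chromosome(s)\n")
  cat(sprintf("  monoexonic: %d (%.1f%%)\n", sum(g$monoexonic),
              100 * mean(g$monoexonic)))
  cat("  annotated junctions:", nrow(unique(x$junctions[c("chrom", "start", "end")])), "\n")
  cat(sprintf("  genes with exonic overlap: %d\n", sum(g$overlap_fraction > 0)))
  invisible(x)
}

#' Exonic overlap fraction of a gene
#'
#' Fraction of a gene's exon-union length that intersects exons of any other
#' gene (either strand): `1 - nonoverlap_len / exonic_len`. Zero for a gene
#' with no exonic overlap, one for a gene entirely contained in other genes'
#' exons.
#'
#' @param gene_id gene identifier(s).
#' @param db a [build_db()] database.
#' @return numeric vector in `[0, 1]`.
#' @export
overlap_fraction <- function(gene_id, db) {
  stopifnot(inherits(db, "genome_db"))
  missing <- setdiff(gene_id, db$genes$gene_id)
  if (length(missing)) stop("unknown gene_id: ", paste(missing, collapse = ", "))
  db$genes[gene_id, "overlap_fraction"]
}

#' Neighboring genes within a distance cutoff
#'
#' Genes (on either strand) whose genomic span lies within `max_distance` bp
#' of the query gene's span; overlapping spans are neighbors at distance 0.
#' The relation is symmetric. With the database default of 2,000 bp this is
#' the neighborhood used by the highly-expressed-neighbor metric.
#'
#' @inheritParams overlap_fraction
#' @param max_distance inclusive gap threshold in bp; defaults to the
#'   distance the database was built with.
#' @return character vector of gene_ids.
#' @export
find_neighbors <- function(gene_id, db, max_distance = NULL) {
  stopifnot(inherits(db, "genome_db"), length(gene_id) == 1L)
  if (!gene_id %in% db$genes$gene_id) stop("unknown gene_id: ", gene_id)
  if (is.null(max_distance) || max_distance == db$neighbor_distance)
    return(db$neighbors[[gene_id]])
  g <- db$genes
  sp <- GRanges(g$chrom, IRanges(g$span_start, g$span_end))
  i <- match(gene_id, g$gene_id)
  d <- distance(sp[i], sp, ignore.strand = TRUE)
  sort(g$gene_id[which(!is.na(d) & d <= max_distance & seq_len(nrow(g)) != i)])
}

#' Persist / reload a gene-model database
#'
#' `save_db()` writes the database into a directory: `db.rds` (the full
#' object) and `genes.tsv`, a plain-text per-gene summary for inspection.
#' `load_db()` restores the object; a round trip is bit-identical.
#'
#' @param db a `genome_db` object.
#' @param dir target directory (created if needed).
#' @param force overwrite an existing database directory. Default `FALSE`.
#' @return `save_db()` the directory path invisibly; `load_db()` the
#'   `genome_db` object.
#' @export
save_db <- function(db, dir, force = FALSE) {
  stopifnot(inherits(db, "genome_db"))
  if (file.exists(file.path(dir, "db.rds")) && !force)
    stop("database already exists in ", dir, " (use force = TRUE to overwrite)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(db, file.path(dir, "db.rds"))
  write.table(db$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_db
#' @export
load_db <- function(dir) {
  f <- file.path(dir, "db.rds")
  if (!file.exists(f)) stop("no database found in ", dir)
  db <- readRDS(f)
  stopifnot(inherits(db, "genome_db"))
  db
}

## unlisted exon/intron GRanges with gene index, cached views for counting
.db_exon_all <- function(db) {
  gr <- unlist(db$exon_union, use.names = FALSE)
  gr$gene_idx <- rep(seq_along(db$exon_union), lengths(db$exon_union))
  gr
}
.db_intron_all <- function(db) {
  gr <- unlist(db$introns, use.names = FALSE)
  gr$gene_idx <- rep(seq_along(db$introns), lengths(db$introns))
  gr
}
.junction_key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")
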