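#' Alignment-derived predictive metrics for strand-bias classification
#'
#' Computes, from strand-blind counts alone, the four per-gene metrics used
#' to predict whether a gene's unstranded count is inflated by
#' opposite-strand transcription:
#' \describe{
#'   \item{junction_log_ratio}{`log2((n_jctn + eps) / (p_expected * n_ust +
#'     eps))` — observed vs expected junction reads. Biased genes show far
#'     fewer spliced reads than their gene structure predicts.}
#'   \item{exon_intron_log_ratio}{`log2` of the length-normalized exonic
#'     read density (`n_ustno` over the unique exonic length) over the
#'     length-normalized intronic density (`n_intr` over the intronic
#'     length). Carry-over reads ignore the exon-intron structure, so
#'     biased genes have unusually high intronic coverage.}
#'   \item{neighbor_expression}{maximum over neighboring genes (within the
#'     database's neighbor distance) of `n_ust / exonic_len` — the
#'     expression density of the most active proximal gene, the putative
#'     source of carried-over reads. 0 for isolated genes.}
#'   \item{overlap_fraction}{fraction of the gene's exon union overlapping
#'     other genes' exons, from the database.}
#' }
#' The first two metrics are undefined (`NA`) for monoexonic genes, which
#' are classified from the last two only.
#'
#' @param counts a [count_bam()] data.frame from an unstranded pass (only
#'   the strand-blind columns are used).
#' @param expectations a [junction_probability()] data.frame matching the
#'   read configuration of the library.
#' @param db the database used for counting.
#' @param eps pseudocount added to read tallies before forming ratios
#'   (default 1; junction fractions of zero are common, so smoothing is
#'   required).
#' @return data.frame `gene_id`, `junction_log_ratio`,
#'   `exon_intron_log_ratio`, `neighbor_expression`, `overlap_fraction`,
#'   `monoexonic`.
#' @export
extract_features <- function(counts, expectations, db, eps = 1) {
  stopifnot(inherits(db, "genome_db"))
  g <- db$genes[counts$gene_id, ]
  pe <- expectations$p_expected[match(counts$gene_id, expectations$gene_id)]
  need <- !g$monoexonic & is.na(pe)
  if (any(need))
    stop("multiexonic gene(s) missing from junction expectations: ",
         paste(counts$gene_id[need][1:min(3, sum(need))], collapse = ", "),
         " (database/count mismatch?)")

  jlr <- log2((counts$n_jctn + eps) / (pe * counts$n_ust + eps))
  eilr <- log2(((counts$n_ustno + eps) / pmax(g$nonoverlap_len, 1L)) /
               ((counts$n_intr + eps) / pmax(g$intron_len, 1L)))
  jlr[g$monoexonic] <- NA_real_
  eilr[g$monoexonic] <- NA_real_

  dens <- counts$n_ust / pmax(g$exonic_len, 1L)
  names(dens) <- counts$gene_id
  nbr <- vapply(counts$gene_id, function(gid) {
    nb <- db$neighbors[[gid]]
    nb <- nb[nb %in% names(dens)]
    if (length(nb) == 0L) 0 else max(dens[nb])
  }, numeric(1))

  data.frame(gene_id = counts$gene_id,
             junction_log_ratio = jlr,
             exon_intron_log_ratio = eilr,
             neighbor_expression = unname(nbr),
             overlap_fraction = g$overlap_fraction,
             monoexonic = g$monoexonic,
             row.names = counts$gene_id,
             stringsAsFactors = FALSE)
}

#' Label strandedness-affected genes from a stranded library
#'
#' With strand information available, a gene's unstranded overestimation is
#' measured directly as `log2((n_ustno + eps) / (n_stno + eps))` — the
#' log-ratio of unstranded vs stranded counts over the gene's unique
#' region, non-negative by construction. A gene is labeled *affected* when
#' this ratio exceeds 1 (more than two-fold overestimation) and the gene is
#' detectable (unstranded TPM above `tpm_threshold`). These labels are the
#' training truth for [sb_train()].
#'
#' @param stranded_counts a [count_bam()] data.frame from a stranded
#'   library (`n_stno` present).
#' @param db the database used for counting.
#' @param tpm_threshold detectability cutoff on the `n_ustno` TPM
#'   (default 1).
#' @param eps pseudocount (default 1).
#' @return data.frame `gene_id`, `log2_ratio`, `tpm`, `detectable`,
#'   `affected`.
#' @export
label_genes <- function(stranded_counts, db, tpm_threshold = 1, eps = 1) {
  stopifnot(inherits(db, "genome_db"))
  if (anyNA(stranded_counts$n_stno))
    stop("labels require stranded counts (n_stno is NA; was the library counted with strandedness = 'U'?)")
  lr <- log2((stranded_counts$n_ustno + eps) / (stranded_counts$n_stno + eps))
  tpm <- compute_tpm(stranded_counts, db, "n_ustno")
  det <- tpm > tpm_threshold
  data.frame(gene_id = stranded_counts$gene_id,
             log2_ratio = lr,
             tpm = unname(tpm),
             detectable = unname(det),
             affected = lr > 1 & unname(det),
             row.names = stranded_counts$gene_id,
             stringsAsFactors = FALSE)
}
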