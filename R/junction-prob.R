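## Placement enumeration for one spliced molecule.
## L: transcript length; b: internal exon boundaries in transcript
## coordinates (bases before the boundary); R: read length; m: minimum
## aligned overhang on each side for a junction to be detected.
## Returns c(total placements, junction-spanning placements).
.placements_se <- function(L, b, R, m) {
  if (length(b) == 0L) return(c(total = if (L <= R) 1 else L - R + 1, jct = 0))
  if (L <= R) {
    jct <- as.numeric(any(b >= m & (L - b) >= m))
    return(c(total = 1, jct = jct))
  }
  total <- L - R + 1
  lo <- pmax(0, b - R + m)
  hi <- pmin(L - R, b - m)
  ok <- lo <= hi
  if (!any(ok)) return(c(total = total, jct = 0))
  jct <- sum(IRanges::width(reduce(IRanges(lo[ok] + 1L, hi[ok] + 1L))))
  c(total = total, jct = jct)
}

.placements_pe <- function(L, b, R, frag, m) {
  Rm <- min(R, frag)
  if (L <= frag) {
    total <- 1
    if (length(b) == 0L) return(c(total = total, jct = 0))
    m1 <- c(0, min(Rm, L))
    m2 <- c(max(0, L - Rm), L)
    in_mate <- function(sp) b > sp[1] & b < sp[2] & (b - sp[1]) >= m & (sp[2] - b) >= m
    jct <- as.numeric(any(in_mate(m1) | in_mate(m2)))
    return(c(total = total, jct = jct))
  }
  total <- L - frag + 1
  if (length(b) == 0L) return(c(total = total, jct = 0))
  ## start positions s of the fragment for which a mate spans boundary b
  lo1 <- b - Rm + m;        hi1 <- b - m
  lo2 <- b - frag + m;      hi2 <- b - frag + Rm - m
  lo <- c(lo1, lo2); hi <- c(hi1, hi2)
  lo <- pmax(0, lo); hi <- pmin(L - frag, hi)
  ok <- lo <= hi
  if (!any(ok)) return(c(total = total, jct = 0))
  jct <- sum(IRanges::width(reduce(IRanges(lo[ok] + 1L, hi[ok] + 1L))))
  c(total = total, jct = jct)
}

.isoform_placements <- function(exon_widths, read_length, paired,
                                fragment_length, fragment_weights,
                                min_overhang) {
  L <- sum(exon_widths)
  b <- if (length(exon_widths) > 1L) cumsum(exon_widths[-length(exon_widths)])
       else integer(0)
  if (!paired) return(.placements_se(L, b, read_length, min_overhang))
  acc <- c(total = 0, jct = 0)
  w <- fragment_weights / sum(fragment_weights)
  for (i in seq_along(fragment_length))
    acc <- acc + w[i] * .placements_pe(L, b, read_length, fragment_length[i],
                                       min_overhang)
  acc
}

#' Expected splice-junction read probability per gene
#'
#' Computes, by exact enumeration, the probability that a sequenced read (or
#' read pair) from a gene spans one of its annotated exon-exon junctions,
#' under two assumptions: all transcript isoforms of the gene are present in
#' equal molar amounts, and coverage is uniform along each transcript (every
#' read start position within a molecule is equally likely). For every
#' isoform all read placements are enumerated on the spliced transcript
#' sequence; a placement spans a junction when the read (either mate, for
#' paired-end) has at least `min_overhang` aligned bases on both sides of an
#' isoform-internal exon boundary — mirroring the minimum splice overhang a
#' spliced aligner requires. Placements are pooled across isoforms, so each
#' molecule contributes reads in proportion to its number of placements
#' (equal-molar weighting with uniform fragmentation), and
#' `p_expected = junction placements / all placements`.
#'
#' Transcripts shorter than the read (or fragment) contribute a single
#' placement covering the whole molecule. Monoexonic genes have
#' `p_expected = 0`. For paired-end configurations with a fragment-length
#' distribution, placements are pooled over fragment lengths with the given
#' weights (counts become expected values).
#'
#' @param db a [build_db()] database.
#' @param read_length read length in bp.
#' @param paired logical; paired-end configuration.
#' @param fragment_length fragment length(s) in bp (paired-end only).
#' @param fragment_weights optional weights for `fragment_length`
#'   (default equal).
#' @param min_overhang minimum aligned bases on each side of a junction for
#'   it to be detectable (default 8, a typical aligner splice overhang).
#' @param genes optional subset of gene_ids.
#' @return data.frame `gene_id`, `p_expected`, `n_positions_total`,
#'   `n_positions_junction`.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "strandsense")
#' db <- build_db(gtf)
#' junction_probability(db, read_length = 50, min_overhang = 8)
#' @export
junction_probability <- function(db, read_length, paired = FALSE,
                                 fragment_length = NULL,
                                 fragment_weights = NULL,
                                 min_overhang = 8L, genes = NULL) {
  stopifnot(inherits(db, "genome_db"), read_length >= 1, min_overhang >= 1)
  if (paired) {
    if (is.null(fragment_length))
      stop("paired-end configuration requires fragment_length")
    if (is.null(fragment_weights))
      fragment_weights <- rep(1, length(fragment_length))
    stopifnot(length(fragment_weights) == length(fragment_length))
  }
  gene_ids <- if (is.null(genes)) db$genes$gene_id else genes
  miss <- setdiff(gene_ids, db$genes$gene_id)
  if (length(miss)) stop("unknown gene_id: ", paste(miss, collapse = ", "))

  tx_by_gene <- split(db$tx2gene$transcript_id, db$tx2gene$gene_id)
  out <- lapply(gene_ids, function(g) {
    acc <- c(total = 0, jct = 0)
    for (t in tx_by_gene[[g]]) {
      e <- db$tx_exons[[t]]
      w <- IRanges::width(e)[order(start(e))]
      acc <- acc + .isoform_placements(w, read_length, paired,
                                       fragment_length, fragment_weights,
                                       min_overhang)
    }
    acc
  })
  tot <- vapply(out, `[`, numeric(1), "total")
  jct <- vapply(out, `[`, numeric(1), "jct")
  data.frame(gene_id = gene_ids,
             p_expected = ifelse(tot > 0, jct / tot, 0),
             n_positions_total = tot,
             n_positions_junction = jct,
             stringsAsFactors = FALSE)
}

#' Observed splice-junction read frequency
#'
#' The fraction of a gene's unstranded reads that span an annotated
#' junction, `n_jctn / n_ust` (0 for undetected genes). Compared against
#' [junction_probability()] this yields the observed-vs-expected junction
#' log-ratio, the strongest predictor of opposite-strand count inflation:
#' reads carried over from the opposite strand ignore the gene's
#' exon-intron structure and are depleted of spliced alignments.
#'
#' @param counts a [count_bam()] data.frame.
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
observed_junction_frequency <- function(counts) {
  stopifnot(all(c("n_jctn", "n_ust") %in% names(counts)))
  f <- ifelse(counts$n_ust > 0, counts$n_jctn / counts$n_ust, 0)
  setNames(f, counts$gene_id)
}
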