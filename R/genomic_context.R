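merge_intervals <- function(intervals) {
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start, intervals$end))
  red <- GenomicRanges::reduce(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red),
             end = GenomicRanges::end(red), stringsAsFactors = FALSE)
}

#' CpG-density context of sites
#'
#' Classifies each CpG as `island` (inside a CpG island), `shore` (within
#' 2,000 bp of an island boundary, inclusive, but not inside one) or
#' `outside`. Islands are merged first, so overlapping input intervals and
#' sites flanked by two islands are handled without double counting.
#'
#' @param sites Data.frame with `chrom`, `pos` (1-based).
#' @param islands Data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_intervals()].
#' @param shore_width Shore width in bp (default 2,000, boundary inclusive).
#' @return Character vector: island / shore / outside, one per site.
#' @export
classify_density <- function(sites, islands, shore_width = 2000L) {
  isl <- merge_intervals(islands)
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos))
  gr_isl <- GenomicRanges::GRanges(isl$chrom,
                                   IRanges::IRanges(isl$start, isl$end))
  in_island <- GenomicRanges::countOverlaps(gr_sites, gr_isl) > 0
  gr_shore <- GenomicRanges::GRanges(
    isl$chrom, IRanges::IRanges(pmax(isl$start - shore_width, 1L),
                                isl$end + shore_width))
  near <- GenomicRanges::countOverlaps(gr_sites, gr_shore) > 0
  ifelse(in_island, "island", ifelse(near, "shore", "outside"))
}

#' Genic context of sites
#'
#' Classifies each CpG against gene models with the precedence promoter >
#' exon > intron > intergenic: `promoter` when within `promoter_width` bp of
#' a transcription start site (strand-aware, boundary inclusive), else
#' `exon` when inside an exon block, else `intron` when inside a gene span,
#' else `intergenic`. The nearest gene (ties broken by lower gene start,
#' then id), the signed strand-aware distance to its TSS (positive =
#' downstream of the TSS, i.e. into the gene body), and the position
#' relative to that gene (`within` / `upstream` / `downstream`, `none` when
#' the chromosome carries no gene) are reported for every site.
#'
#' @param sites Data.frame with `chrom`, `pos`.
#' @param genes Gene models as returned by
#'   [read_intervals()] with `kind = "bed12"` (needs `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, list-column `exons`).
#' @param promoter_width Promoter half-width around the TSS, bp.
#' @return Data.frame: `genic` (promoter/exon/intron/intergenic),
#'   `position_rel_gene`, `nearest_gene`, `dist_tss`.
#' @export
classify_genic <- function(sites, genes, promoter_width = 2000L) {
  n <- nrow(sites)
  genic <- rep("intergenic", n)
  rel <- rep("none", n)
  nearest <- rep(NA_character_, n)
  dist_tss <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    pos <- sites$pos[i]
    d_span <- pmax(g$start - pos, pos - g$end, 0L)  # 0 when inside the span
    ng <- order(d_span, g$start, g$gene_id)[1L]
    nearest[i] <- g$gene_id[ng]
    dist_tss[i] <- if (g$strand[ng] == "+") pos - g$tss[ng] else g$tss[ng] - pos
    inside <- d_span[ng] == 0L
    rel[i] <- if (inside) "within" else if (dist_tss[i] < 0) "upstream" else "downstream"
    if (any(abs(pos - g$tss) <= promoter_width)) {
      genic[i] <- "promoter"
    } else if (inside) {
      ex <- g$exons[[ng]]
      if (is.null(ex) || nrow(ex) == 0L) {  # gene without exon blocks: single-exon
        genic[i] <- "exon"
      } else {
        genic[i] <- if (any(pos >= ex$start & pos <= ex$end)) "exon" else "intron"
      }
    }
  }
  data.frame(genic = genic, position_rel_gene = rel, nearest_gene = nearest,
             dist_tss = dist_tss, stringsAsFactors = FALSE)
}

#' Annotate clock CpGs with genomic context
#'
#' Joins density and genic context onto a table of clock sites with their
#' age correlations; the methylation direction (`hyper` when r > 0, `hypo`
#' when r < 0) is derived from the correlation sign.
#'
#' @param clock_sites Data.frame with `site` (key `"chrom:pos"`) and `r`
#'   (e.g. the selection table of a [train_clock()] model or [loiocv()]).
#' @param islands Island intervals (see [classify_density()]).
#' @param genes Gene models (see [classify_genic()]).
#' @return Data.frame: site, chrom, pos, r, direction, density, genic,
#'   position_rel_gene, nearest_gene, dist_tss.
#' @export
annotate_clock_sites <- function(clock_sites, islands, genes) {
  parts <- strsplit(clock_sites$site, ":", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      stringsAsFactors = FALSE)
  out <- data.frame(site = clock_sites$site, sites, r = clock_sites$r,
                    direction = ifelse(clock_sites$r > 0, "hyper", "hypo"),
                    density = classify_density(sites, islands),
                    classify_genic(sites, genes),
                    stringsAsFactors = FALSE)
  out
}

#' Summarise clock CpGs by genomic context
#'
#' Contingency and trend tables over the annotated clock sites: per density
#' and per genic category, the site counts, hyper/hypo counts and mean age
#' correlation; plus a one-way ANOVA of the per-site correlation across
#' density groups (empty categories are reported as zero and excluded from
#' the ANOVA).
#'
#' @param annotated Data.frame from [annotate_clock_sites()].
#' @return List: `density_table`, `genic_table`, `anova` (`f`, `df`, `p`;
#'   `NA` when fewer than 2 density groups are populated).
#' @export
summarize_by_context <- function(annotated) {
  ctab <- function(var, levels_all) {
    f <- factor(annotated[[var]], levels = levels_all)
    data.frame(category = levels_all,
               n = as.integer(table(f)),
               n_hyper = as.integer(table(f[annotated$direction == "hyper"])),
               n_hypo = as.integer(table(f[annotated$direction == "hypo"])),
               mean_r = as.numeric(tapply(annotated$r, f, mean)),
               stringsAsFactors = FALSE)
  }
  dens <- ctab("density", c("island", "shore", "outside"))
  gen <- ctab("genic", c("promoter", "exon", "intron", "intergenic"))
  populated <- droplevels(factor(annotated$density))
  an <- if (nlevels(populated) >= 2L) {
    s <- summary(stats::aov(annotated$r ~ populated))[[1L]]
    list(f = s$`F value`[1L], df = c(s$Df[1L], s$Df[2L]), p = s$`Pr(>F)`[1L])
  } else {
    list(f = NA_real_, df = c(NA_integer_, NA_integer_), p = NA_real_)
  }
  list(density_table = dens, genic_table = gen, anova = an)
}
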