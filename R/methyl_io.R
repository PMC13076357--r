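#' Read a Bismark-style coverage file
#'
#' Parses the 6-column coverage format emitted by Bismark's methylation
#' extractor (`chrom start end methylation_percent count_methylated
#' count_unmethylated`, tab-separated, 1-based with `start == end` for
#' single-cytosine records). The percentage column is never used for
#' computation; it is recomputed from the counts and a warning is raised when
#' the two disagree by more than 0.1 percentage points. Gzipped files are
#' accepted.
#'
#' @param path Path to the coverage file (optionally gzipped).
#' @param sample_id Label attached to the returned table.
#' @param collapse Collapse plus/minus strand records of the same CpG
#'   (positions `p` and `p + 1`) into one site by summing counts. Off by
#'   default; enable for raw, strand-resolved Bismark output.
#' @return A data.frame with columns `chrom`, `pos`, `methylated`, `total`
#'   (one row per site; `total = methylated + unmethylated`, `total == 0`
#'   rows are retained and mean "no data in this sample") and attribute
#'   `sample_id`.
#' @export
read_coverage_file <- function(path, sample_id, collapse = FALSE) {
  stopifnot(length(path) == 1L, file.exists(path))
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 6L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed coverage row in '%s': line %d has %d field(s), expected 6",
                 path, bad[1L], nf[bad[1L]]))
  }
  x <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                         col.names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric", "integer", "integer"))
  if (any(x$meth < 0 | x$unmeth < 0)) {
    stop(sprintf("negative read count in '%s' (first at line %d)",
                 path, which(x$meth < 0 | x$unmeth < 0)[1L]))
  }
  if (any(x$start < 1L)) {
    stop(sprintf("non-positive coordinate in '%s' (first at line %d)",
                 path, which(x$start < 1L)[1L]))
  }
  total <- x$meth + x$unmeth
  obs <- total > 0L
  recomputed <- ifelse(obs, 100 * x$meth / pmax(total, 1L), NA_real_)
  off <- obs & abs(x$pct - recomputed) > 0.1
  if (any(off)) {
    warning(sprintf("%d row(s) in '%s' have a methylation %% inconsistent with the counts (first at line %d); counts are used",
                    sum(off), path, which(off)[1L]))
  }
  out <- data.frame(chrom = x$chrom, pos = x$start,
                    methylated = x$meth, total = total,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$chrom, out$pos))) {
    stop(sprintf("duplicate (chrom, pos) records in '%s'", path))
  }
  if (collapse) out <- collapse_strands(out)
  attr(out, "sample_id") <- sample_id
  out
}

#' Write site counts in Bismark coverage format
#'
#' Inverse of [read_coverage_file()]: the methylated / unmethylated count
#' columns round-trip exactly. The percentage column is written with full
#' precision.
#'
#' @param counts Data.frame with `chrom`, `pos`, `methylated`, `total`.
#' @param path Output path (plain text; use a `.gz` suffix for gzip).
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(counts, path) {
  stopifnot(all(c("chrom", "pos", "methylated", "total") %in% names(counts)))
  pct <- ifelse(counts$total > 0, 100 * counts$methylated / pmax(counts$total, 1L), 0)
  out <- data.frame(counts$chrom, counts$pos, counts$pos,
                    format(pct, digits = 15, trim = TRUE, scientific = FALSE),
                    counts$methylated, counts$total - counts$methylated)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse plus/minus strand CpG records
#'
#' A CpG is symmetric: bisulphite callers may report the plus-strand cytosine
#' at position `p` and the minus-strand cytosine at `p + 1` separately. This
#' merges each such adjacent pair on the same chromosome by summing counts
#' (kept at the left position `p`). Scanning is greedy left-to-right, so the
#' operation is idempotent and conserves total read counts.
#'
#' @param counts Data.frame with `chrom`, `pos`, `methylated`, `total`.
#' @return A data.frame of the same shape, unique per (chrom, pos).
#' @export
collapse_strands <- function(counts) {
  stopifnot(all(c("chrom", "pos", "methylated", "total") %in% names(counts)))
  o <- order(counts$chrom, counts$pos)
  x <- counts[o, , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) return(x)
  keep <- logical(n)
  merge_into <- integer(0)  # row index merged into the previous kept row
  i <- 1L
  while (i <= n) {
    keep[i] <- TRUE
    if (i < n && x$chrom[i + 1L] == x$chrom[i] && x$pos[i + 1L] == x$pos[i] + 1L) {
      x$methylated[i] <- x$methylated[i] + x$methylated[i + 1L]
      x$total[i] <- x$total[i] + x$total[i + 1L]
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a sample metadata table
#'
#' Tab-separated with a header; required columns `sample_id`,
#' `individual_id`, `sex` (F/M, unknown permitted as NA) and `age_years`;
#' an optional `collection_date` column (ISO dates) is parsed when present.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "individual_id", "sex", "age_years")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0L) {
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  }
  m$age_years <- as.numeric(m$age_years)
  if (any(is.na(m$age_years)) || any(m$age_years < 0)) {
    stop("age_years must be non-negative and numeric for every sample")
  }
  m$sex[m$sex %in% c("", "NA", "unknown")] <- NA_character_
  if (!all(m$sex %in% c("F", "M", NA_character_))) {
    stop("sex must be coded F/M (or NA for unknown)")
  }
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  }
  if ("collection_date" %in% names(m)) {
    m$collection_date <- as.Date(m$collection_date)
  }
  m
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

#' Construct a methylation dataset
#'
#' The central container: a site table, a sample table, and two integer
#' matrices (methylated and total read counts, sites x samples). A site is
#' missing in a sample iff its total count there is zero.
#'
#' @param sites Data.frame with `chrom`, `pos` (1-based), one row per CpG.
#' @param samples Data.frame of sample metadata (see [read_metadata()]).
#' @param meth,total Integer matrices, `nrow(sites)` x `nrow(samples)`.
#' @return An object of class `MethylationDataset`.
#' @export
methylation_dataset <- function(sites, samples, meth, total) {
  stopifnot(nrow(meth) == nrow(sites), ncol(meth) == nrow(samples),
            identical(dim(meth), dim(total)))
  if (any(meth > total)) stop("methylated count exceeds total count")
  if (any(total < 0)) stop("negative total count")
  if (anyDuplicated(site_key(sites$chrom, sites$pos))) {
    stop("duplicate (chrom, pos) in site table")
  }
  rownames(meth) <- rownames(total) <- site_key(sites$chrom, sites$pos)
  colnames(meth) <- colnames(total) <- samples$sample_id
  structure(list(sites = sites, samples = samples,
                 meth = meth, total = total),
            class = "MethylationDataset")
}

#' @export
print.MethylationDataset <- function(x, ...) {
  nmiss <- sum(x$total == 0)
  cat(sprintf("MethylationDataset: %d CpG sites x %d samples (%d individuals)\n",
              nrow(x$sites), nrow(x$samples), length(unique(x$samples$individual_id))))
  cat(sprintf("  missing entries (total reads = 0): %d (%.1f%%)\n",
              nmiss, 100 * nmiss / length(x$total)))
  invisible(x)
}

#' Methylation ratio matrix of a dataset
#'
#' @param dataset A `MethylationDataset`.
#' @return Numeric matrix of methylated/total, `NA` where total is zero.
#' @export
get_ratios <- function(dataset) {
  r <- dataset$meth / dataset$total
  r[dataset$total == 0] <- NA_real_
  r
}

#' Assemble a cross-sample methylation dataset
#'
#' Builds the sites x samples count matrices from per-sample coverage files
#' and a metadata table. The site universe is the union of sites over all
#' samples, ordered by chromosome (lexicographic) then position; sites absent
#' from a sample get zero counts there (missing). The result is invariant to
#' the order of the input files.
#'
#' @param coverage_files Named character vector: `sample_id -> path`.
#' @param metadata Metadata data.frame or path to a metadata TSV.
#' @param collapse Passed to [read_coverage_file()].
#' @return A `MethylationDataset`.
#' @export
assemble_dataset <- function(coverage_files, metadata, collapse = FALSE) {
  if (is.null(names(coverage_files)) || any(names(coverage_files) == "")) {
    stop("coverage_files must be a named vector (names are sample ids)")
  }
  if (anyDuplicated(names(coverage_files))) {
    stop("duplicate sample_id among coverage files: ",
         paste(unique(names(coverage_files)[duplicated(names(coverage_files))]),
               collapse = ", "))
  }
  meta <- if (is.character(metadata)) read_metadata(metadata) else metadata
  ids <- names(coverage_files)
  not_in_meta <- setdiff(ids, meta$sample_id)
  not_in_cov <- setdiff(meta$sample_id, ids)
  if (length(not_in_meta) > 0L) {
    stop("sample(s) with coverage but no metadata: ",
         paste(not_in_meta, collapse = ", "))
  }
  if (length(not_in_cov) > 0L) {
    stop("sample(s) in metadata but without a coverage file: ",
         paste(not_in_cov, collapse = ", "))
  }
  meta <- meta[order(match(meta$sample_id, ids)), , drop = FALSE]
  rownames(meta) <- NULL

  per_sample <- lapply(ids, function(id) {
    read_coverage_file(coverage_files[[id]], id, collapse = collapse)
  })
  keys <- lapply(per_sample, function(d) site_key(d$chrom, d$pos))
  all_sites <- unique(do.call(rbind, lapply(per_sample, function(d)
    d[, c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  universe <- site_key(all_sites$chrom, all_sites$pos)

  meth <- matrix(0L, nrow = length(universe), ncol = length(ids))
  total <- matrix(0L, nrow = length(universe), ncol = length(ids))
  for (j in seq_along(ids)) {
    idx <- match(keys[[j]], universe)
    meth[idx, j] <- per_sample[[j]]$methylated
    total[idx, j] <- per_sample[[j]]$total
  }
  methylation_dataset(all_sites, meta, meth, total)
}

#' Write / read a dataset as a plain-text archive
#'
#' Serialises a `MethylationDataset` to a directory of TSV files
#' (`sites.tsv`, `samples.tsv`, `meth.tsv`, `total.tsv`) that round-trips
#' losslessly through [read_dataset()].
#'
#' @param dataset A `MethylationDataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$sites, file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$meth, file.path(dir, "meth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$total, file.path(dir, "total.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  sites <- utils::read.table(file.path(dir, "sites.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c("character", "integer"))
  samples <- read_metadata(file.path(dir, "samples.tsv"))
  meth <- as.matrix(utils::read.table(file.path(dir, "meth.tsv"), sep = "\t"))
  total <- as.matrix(utils::read.table(file.path(dir, "total.tsv"), sep = "\t"))
  storage.mode(meth) <- "integer"
  storage.mode(total) <- "integer"
  dimnames(meth) <- dimnames(total) <- NULL
  methylation_dataset(sites, samples, meth, total)
}

#' Read genomic intervals (BED) or gene models (BED12)
#'
#' BED input is 0-based half-open on disk and converted to the package's
#' 1-based inclusive convention on read. For BED12 the block fields define
#' exons and the transcription start site (TSS) is the 5' end of the gene
#' (start on plus strand, end on minus strand); blocks inconsistent with the
#' record span raise an error.
#'
#' @param path BED or BED12 file (optionally gzipped).
#' @param kind `"bed"` for plain intervals (e.g. CpG islands), `"bed12"` for
#'   gene models.
#' @return For `"bed"`: data.frame `chrom`, `start`, `end` (1-based
#'   inclusive), plus `name` when present. For `"bed12"`: data.frame
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, and a list-column
#'   `exons` of per-gene data.frames (`start`, `end`, 1-based inclusive).
#' @export
read_intervals <- function(path, kind = c("bed", "bed12")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path, format = "bed")
  if (kind == "bed") {
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
    nm <- S4Vectors::mcols(gr)$name
    if (!is.null(nm)) out$name <- nm
    return(out)
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$blocks)) {
    stop("'", path, "' has no block (exon) fields; expected 12-column BED")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("BED12 gene models must carry a strand")
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  n <- length(gr)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    bl <- mc$blocks[[i]]  # exon ranges relative to the record start (1-based)
    ex_start <- start[i] + IRanges::start(bl) - 1L
    ex_end <- start[i] + IRanges::end(bl) - 1L
    if (min(ex_start) != start[i] || max(ex_end) != end[i] || any(ex_end > end[i])) {
      stop(sprintf("BED12 blocks inconsistent with record span for '%s' in '%s'",
                   as.character(mc$name[i]), path))
    }
    exons[[i]] <- data.frame(start = ex_start, end = ex_end)
  }
  gene_id <- if (!is.null(mc$name)) as.character(mc$name) else
    sprintf("gene_%d", seq_len(n))
  out <- data.frame(gene_id = gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = start, end = end, strand = strand,
                    tss = ifelse(strand == "+", start, end),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  out
}
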