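#' Read a numeric matrix from a delimited file
#'
#' Expects a header row of sample IDs and row identifiers in the first
#' column (probes or genes). Comment lines starting with `#` are skipped,
#' so files written by [write_matrix_tsv()] (which carry a provenance
#' header) round-trip. Gzip-compressed files are read transparently.
#'
#' @param path file path (TSV by default; use `sep = ","` for CSV).
#' @param sep field separator.
#' @return numeric matrix with rownames/colnames.
#' @export
read_matrix_tsv <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a numeric matrix with a provenance header
#'
#' @param x matrix with rownames.
#' @param path output path.
#' @param id_col name for the row-identifier column.
#' @param provenance optional character vector written as `#`-prefixed
#'   header lines.
#' @export
write_matrix_tsv <- function(x, path, id_col = "id", provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 2, format, trim = TRUE, digits = 15, scientific = FALSE)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  writeLines(paste(rownames(x), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Write a data frame with a provenance header
#' @inheritParams write_matrix_tsv
#' @param df data frame.
#' @export
write_df_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a data frame written by [write_df_tsv()]
#' @param path TSV path (comment lines skipped).
#' @export
read_df_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a probe annotation table
#'
#' Columns: probe_id, gene, region (TSS200/FirstExon/TSS1500/Body),
#' chrom, pos.
#' @param path TSV path.
#' @return data frame of probe records.
#' @export
read_probe_annotation <- function(path) {
  ann <- read_df_tsv(path)
  needed <- c("probe_id", "gene", "region", "chrom", "pos")
  stopifnot(all(needed %in% names(ann)))
  bad <- setdiff(unique(ann$region), c("TSS200", "FirstExon", "TSS1500", "Body"))
  if (length(bad))
    stop("unknown probe region class(es): ", paste(bad, collapse = ", "))
  ann
}

#' Read a sample sheet (sample_id, group, cancer_type)
#' @param path TSV path.
#' @export
read_sample_sheet <- function(path) {
  ss <- read_df_tsv(path)
  stopifnot(all(c("sample_id", "group", "cancer_type") %in% names(ss)))
  stopifnot(all(ss$group %in% c("normal", "tumor")))
  ss
}

#' Read SEG-like copy-number segmentation records
#'
#' Columns: sample, chrom, start, end, num_probes, seg_mean
#' (1-based inclusive coordinates).
#' @param path TSV path.
#' @export
read_seg <- function(path) {
  seg <- read_df_tsv(path)
  stopifnot(all(c("sample", "chrom", "start", "end", "seg_mean") %in% names(seg)))
  stopifnot(all(seg$start <= seg$end), all(is.finite(seg$seg_mean)))
  seg
}

#' Read MAF-like mutation records
#'
#' Requires columns Hugo_Symbol, Tumor_Sample_Barcode,
#' Variant_Classification.
#' @param path TSV path.
#' @export
read_maf <- function(path) {
  maf <- read_df_tsv(path)
  stopifnot(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                  "Variant_Classification") %in% names(maf)))
  maf
}

#' Read a SIF-like undirected edge list (two columns: geneA, geneB)
#' @param path TSV path.
#' @export
read_sif <- function(path) {
  ed <- read_df_tsv(path)
  stopifnot(ncol(ed) >= 2)
  names(ed)[1:2] <- c("geneA", "geneB")
  ed[, 1:2]
}

#' Read a gene-to-localization-term table
#'
#' Two columns: gene, term; one row per (gene, term) pair.
#' @param path TSV path.
#' @return named list: gene -> character vector of terms.
#' @export
read_localization <- function(path) {
  df <- read_df_tsv(path)
  stopifnot(all(c("gene", "term") %in% names(df)))
  split(df$term, df$gene)
}

#' Read gene coordinates (gene, chrom, start, end; 1-based inclusive)
#' @param path TSV path.
#' @export
read_gene_coords <- function(path) {
  gc <- read_df_tsv(path)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gc)))
  stopifnot(all(gc$start <= gc$end))
  gc
}

#' Read a GMT gene-set collection
#' @param path GMT path (name, description, genes..., tab-separated).
#' @return named list of gene identifier vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of gene identifier vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
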