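# Readers and writers for the standard on-disk formats the pipeline
# consumes: expression/label/length TSV, SEG, BED, MAF, ground-truth JSON.

#' Read a gene x sample expression TSV
#'
#' Expects a header row of sample ids and gene ids in column 1.
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_value("expression matrix '%s' contains missing values", path)
  m
}

#' @rdname read_expression_tsv
#' @param x Matrix to write.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample response labels
#'
#' Two-column TSV (sample, label) with labels resistant/sensitive.
#' @param path File path.
#' @return Named character vector, sample -> label.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  labels <- stats::setNames(df[[2]], df[[1]])
  check_labels(labels)
}

#' Read cDNA gene lengths
#'
#' Two-column TSV (gene, length_bp).
#' @param path File path.
#' @return Named numeric vector of lengths in bp.
#' @export
read_lengths_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  len <- stats::setNames(as.numeric(df[[2]]), df[[1]])
  assert_that(all(is.finite(len)) && all(len > 0), "gene lengths must be > 0")
  len
}

#' Read a SEG copy-number segment file
#'
#' Tab-delimited with header; columns sample id, chromosome, start, end
#' (1-based inclusive), number of markers, segment mean (log2 ratio).
#' @param path File path.
#' @return data.frame with columns sample, chrom, start, end, num_mark,
#'   seg_mean.
#' @export
read_seg <- function(path) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop_value("cannot parse SEG '%s': %s",
                                                path, conditionMessage(e)))
  if (ncol(df) < 6) stop_value("SEG '%s': expected 6 columns, found %d", path, ncol(df))
  names(df)[1:6] <- c("sample", "chrom", "start", "end", "num_mark", "seg_mean")
  for (col in c("start", "end", "seg_mean")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_value("SEG '%s': malformed %s at line %d", path, col, bad[1] + 1L)
    df[[col]] <- v
  }
  df
}

#' Read a BED gene model (0-based half-open)
#'
#' @param path File path.
#' @return data.frame with columns chrom, start, end, gene.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop_value("BED '%s': expected >= 4 columns", path)
  names(df)[1:4] <- c("chrom", "start", "end", "gene")
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$end < df$start)
  if (length(bad))
    stop_value("BED '%s': malformed interval at line %d", path, bad[1])
  df
}

#' Read somatic mutation calls from a MAF file
#'
#' Requires columns Hugo_Symbol, Tumor_Sample_Barcode and
#' Variant_Classification; Silent calls are ignored.
#' @param path File path.
#' @return data.frame of non-silent calls.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_value("MAF '%s': missing required columns: %s", path,
               paste(missing_cols, collapse = ", "))
  df[df$Variant_Classification != "Silent", , drop = FALSE]
}

#' Convert MAF calls to a binary gene x sample matrix
#'
#' @param maf data.frame as returned by \code{\link{read_maf}}.
#' @param genes,samples Row/column universes; defaults to those observed.
#' @return Binary integer matrix, genes x samples.
#' @export
maf_to_matrix <- function(maf, genes = NULL, samples = NULL) {
  genes <- genes %||% sort(unique(maf$Hugo_Symbol))
  samples <- samples %||% sort(unique(maf$Tumor_Sample_Barcode))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- maf$Hugo_Symbol %in% genes & maf$Tumor_Sample_Barcode %in% samples
  if (any(keep))
    m[cbind(maf$Hugo_Symbol[keep], maf$Tumor_Sample_Barcode[keep])] <- 1L
  m
}

#' Read a bundle directory written by \code{\link{write_bundle}}
#'
#' @param dir Directory containing the bundle files.
#' @return A list with the same in-memory layout as a \code{synth_bundle}
#'   (minus the config), with CNV reconstructed from the SEG/BED pair.
#' @export
read_bundle <- function(dir) {
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  labels <- read_labels_tsv(file.path(dir, "labels.tsv"))
  lengths <- read_lengths_tsv(file.path(dir, "lengths.tsv"))
  seg <- read_seg(file.path(dir, "cnv.seg"))
  bed <- read_bed(file.path(dir, "genes.bed"))
  maf <- read_maf(file.path(dir, "mutations.maf"))
  cnv_log2 <- map_segments_to_genes(seg, bed)
  somatic <- maf_to_matrix(maf, genes = rownames(expr), samples = colnames(expr))
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(expression = expr,
       cnv_log2 = cnv_log2[rownames(expr), colnames(expr), drop = FALSE],
       somatic = somatic, labels = labels, lengths = lengths,
       gene_coords = bed, truth = truth)
}
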