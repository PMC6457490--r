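#' Write a probe-signal table and its sample sheet
#'
#' The probe-signal dialect is a TSV with header columns `probe_id`,
#' `chrom`, `start`, `end` followed by one value column and two flag
#' columns (Cy3, Cy5; 0/1) per sample. The sample sheet is a sidecar TSV
#' declaring, for every sample, its design metadata and which signal-table
#' columns hold its value and flags. Values are written with 17
#' significant digits so that read/write round-trips are byte-exact.
#'
#' @param bundle a [signal_bundle()].
#' @param path output path for the signal table.
#' @param samples_path output path for the sample sheet.
#' @return Invisibly, `c(path, samples_path)`.
#' @export
write_signal_table <- function(bundle, path, samples_path) {
  s <- bundle$samples
  s$value_col <- s$sample_id
  s$flag_cy3_col <- paste0(s$sample_id, ".flagCy3")
  s$flag_cy5_col <- paste0(s$sample_id, ".flagCy5")
  cols <- list(probe_id = bundle$probes$probe_id,
               chrom = bundle$probes$chrom,
               start = bundle$probes$start, end = bundle$probes$end)
  for (i in seq_len(nrow(s))) {
    cols[[s$value_col[i]]] <- sprintf("%.17g", bundle$values[, i])
    cols[[s$flag_cy3_col[i]]] <- as.integer(bundle$flags[, i, 1L])
    cols[[s$flag_cy5_col[i]]] <- as.integer(bundle$flags[, i, 2L])
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(s, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, samples_path))
}

#' Read a probe-signal table and its sample sheet
#'
#' Readers reject rather than repair: missing declared columns, duplicate
#' probe ids and non-numeric values are errors naming the offending
#' row/column. Any nonzero integer in a flag column is truthy.
#'
#' @param path signal-table TSV (dialect of [write_signal_table()]).
#' @param samples_path sample-sheet TSV.
#' @return A [signal_bundle()]; probe row order is preserved.
#' @export
read_signal_table <- function(path, samples_path) {
  s <- read.delim(samples_path, stringsAsFactors = FALSE,
                  check.names = FALSE)
  req_s <- c("sample_id", "strain", "timepoint", "replicate", "assay",
             "ip_dye", "value_col", "flag_cy3_col", "flag_cy5_col")
  miss <- setdiff(req_s, names(s))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  req_p <- c("probe_id", "chrom", "start", "end")
  miss <- setdiff(req_p, names(d))
  if (length(miss))
    stop("signal table is missing column(s): ", paste(miss, collapse = ", "))
  dup <- which(duplicated(d$probe_id))
  if (length(dup))
    stop("duplicate probe_id '", d$probe_id[dup[1L]], "' at row ", dup[1L])
  need <- c(s$value_col, s$flag_cy3_col, s$flag_cy5_col)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sample sheet references absent signal-table column(s): ",
         paste(miss, collapse = ", "))
  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric value '", d[[col]][bad[1L]], "' in column '", col,
           "', row ", bad[1L])
    v
  }
  probes <- data.frame(probe_id = d$probe_id, chrom = d$chrom,
                       start = as.integer(num_col("start")),
                       end = as.integer(num_col("end")),
                       stringsAsFactors = FALSE)
  n <- nrow(d)
  values <- matrix(NA_real_, n, nrow(s))
  flags <- array(FALSE, c(n, nrow(s), 2L))
  for (i in seq_len(nrow(s))) {
    values[, i] <- num_col(s$value_col[i])
    flags[, i, 1L] <- num_col(s$flag_cy3_col[i]) != 0
    flags[, i, 2L] <- num_col(s$flag_cy5_col[i]) != 0
  }
  signal_bundle(probes, s[, setdiff(names(s), c("value_col", "flag_cy3_col",
                                                "flag_cy5_col"))],
                values, flags)
}

#' Read genome annotation from GFF3 or TSV
#'
#' GFF3 (via rtracklayer; `gene` features, 1-based inclusive per the
#' standard) or a 5-column TSV with header `gene_id`, `chrom`, `start`,
#' `end`, `strand`. Both encodings of the same gene parse identically.
#'
#' @param path a `.gff`/`.gff3` file or a TSV.
#' @return A [genome_annotation()] sorted by start.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    if (nrow(df) && "type" %in% names(df) && any(df$type == "gene"))
      df <- df[df$type == "gene", , drop = FALSE]
    id <- NULL
    for (f in c("ID", "locus_tag", "Name"))
      if (is.null(id) && f %in% names(df)) id <- as.character(df[[f]])
    if (is.null(id)) id <- character(nrow(df))
    genes <- data.frame(gene_id = id, chrom = as.character(df$seqnames),
                        start = df$start, end = df$end,
                        strand = as.character(df$strand),
                        stringsAsFactors = FALSE)
  } else {
    genes <- read.delim(path, stringsAsFactors = FALSE)
  }
  genome_annotation(genes)
}

#' Write genome annotation as GFF3
#'
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotation)) {
    lines <- sprintf("%s\ttilebind\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$chrom, annotation$start, annotation$end,
                     annotation$strand, annotation$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write binding regions as BED6
#'
#' The only place the coordinate origin changes: internal 1-based
#' inclusive `[start, end]` becomes BED 0-based half-open
#' `[start - 1, end)`. `name` is `region_id|shape`; `score` is the
#' region's maximum log2 fold change scaled by 100 and clamped to
#' [0, 1000]. Lines are sorted by chromStart; an empty region set yields
#' an empty file with no header.
#'
#' @param regions a binding-region data.frame (see [cluster_regions()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  if (is.null(regions) || nrow(regions) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  score <- pmin(1000, pmax(0, round(100 * regions$max_fold_change)))
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                   paste0(regions$region_id, "|", regions$shape),
                   score, ".")
  df <- df[order(df[[2L]]), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 region file back to internal coordinates
#'
#' Inverse of [write_regions_bed()]: BED 0-based half-open back to
#' 1-based inclusive, splitting `name` into `region_id` and `shape`.
#'
#' @param path BED6 file.
#' @return data.frame with `region_id`, `chrom`, `start`, `end`, `shape`,
#'   `score`.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      shape = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  parts <- strsplit(d$V4, "|", fixed = TRUE)
  data.frame(region_id = vapply(parts, `[`, "", 1L), chrom = d$V1,
             start = d$V2 + 1L, end = d$V3,
             shape = vapply(parts, `[`, "", 2L), score = d$V5,
             stringsAsFactors = FALSE)
}

#' Write a Rank Product result table
#'
#' TSV with columns `gene_id`, `direction`, `RP`, `rank`, `pfp`.
#'
#' @param result a [rank_product_test()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(result, path) {
  tab <- result$table
  tab$RP <- sprintf("%.17g", tab$RP)
  tab$pfp <- sprintf("%.17g", tab$pfp)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a probe- or gene-level value matrix as TSV
#'
#' First column `id`, then one column per sample; 17 significant digits.
#'
#' @param mat numeric matrix with row and column names.
#' @param path TSV path.
#' @return `write_matrix_tsv` invisibly returns `path`;
#'   `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <-
      ifelse(is.na(mat[, j]), "NA", sprintf("%.17g", mat[, j]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1L]]
  m
}
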