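# File dialects. BED files are 0-based half-open; point positions in TSV
# tables are 1-based. All writers emit deterministic, locale-independent
# text so identical objects produce byte-identical files.

fmt_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
         sprintf("%.6f", x))
}

#' Read a BED3/BED4/BED6 file
#'
#' Column 4 is returned as `label` (compartment A/B, SE/TE flags), column 5
#' as `score`, column 6 as `strand`.
#' @param path file path
#' @return interval data frame
#' @export
read_bed <- function(path) {
  nf <- utils::count.fields(path, sep = "\t")
  if (!length(nf))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "label",
                                         "score", "strand")[seq_len(
                             max(3, nf[1]))],
                           fill = TRUE)
  iv_validate(raw, path)
}

#' Write an interval data frame as BED
#'
#' Emits BED3 by default; `label`/`score`/`strand` columns, when present,
#' extend to BED4/BED6 (missing middle columns are filled with `.`/`0`).
#' @param x interval data frame
#' @param path output path
#' @export
write_bed <- function(x, path) {
  iv_validate(x)
  cols <- list(x$chrom, fmt_num(x$start), fmt_num(x$end))
  has <- c(label = "label" %in% names(x), score = "score" %in% names(x),
           strand = "strand" %in% names(x))
  if (any(has)) cols <- c(cols, list(if (has["label"]) as.character(x$label)
                                     else rep(".", nrow(x))))
  if (has["score"] || has["strand"])
    cols <- c(cols, list(if (has["score"]) fmt_num(x$score)
                         else rep("0", nrow(x))))
  if (has["strand"]) cols <- c(cols, list(as.character(x$strand)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation TSV
#'
#' Columns: `id`, `chrom`, `tss` (1-based), `strand`, `start`, `end`
#' (0-based half-open gene body).
#' @param path file path
#' @return gene data frame
#' @export
read_genome_tsv <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("id", "chrom", "tss", "strand", "start", "end")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("gene table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  g
}

#' Write gene annotation TSV
#' @param genes gene data frame
#' @param path output path
#' @export
write_genome_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.variant_cols <- c("chrom", "pos", "ref", "alt", "t_depth", "t_alt",
                   "t_alt_hq", "alt_plus", "alt_minus", "edge_fracs", "af",
                   "n_depth", "n_alt", "posterior_p")

#' Write a per-sample variant table
#'
#' Tab-separated with the evidence dialect used throughout the package;
#' `edge_fracs` is comma-joined, missing values (no matched nontumor) are
#' written as `.`.
#' @param variants variant data frame
#' @param path output path
#' @export
write_variants_tsv <- function(variants, path) {
  v <- variants
  dot <- function(x, f) ifelse(is.na(x), ".", f(x))
  lines <- c(paste(.variant_cols, collapse = "\t"))
  if (nrow(v)) {
    ef <- vapply(v$edge_fracs, function(e)
      paste(sprintf("%.4f", e), collapse = ","), character(1))
    lines <- c(lines, paste(
      v$chrom, fmt_num(v$pos), v$ref, v$alt,
      dot(v$t_depth, fmt_num), dot(v$t_alt, fmt_num),
      dot(v$t_alt_hq, fmt_num), dot(v$alt_plus, fmt_num),
      dot(v$alt_minus, fmt_num), ef,
      dot(v$af, function(x) sprintf("%.6f", x)),
      dot(v$n_depth, fmt_num), dot(v$n_alt, fmt_num),
      dot(v$posterior_p, function(x) sprintf("%.6e", x)),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample variant table
#' @param path file path
#' @return variant data frame with `edge_fracs` as a list column
#' @export
read_variants_tsv <- function(path) {
  v <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = ".",
                         colClasses = c(edge_fracs = "character"))
  miss <- setdiff(.variant_cols, names(v))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  v$edge_fracs <- lapply(strsplit(v$edge_fracs, ","), as.numeric)
  v
}

#' Minimal VCF reader for candidate variants
#'
#' Maps standard per-sample FORMAT fields (`DP`, `AD`, `AF`) of the first
#' sample column onto the evidence dialect and fails loudly when evidence
#' required by the filter cascade cannot be recovered from the file.
#'
#' @param path VCF path (uncompressed)
#' @param require_evidence character vector of evidence columns that must be
#'   present; the read-level columns (`t_alt_hq`, `alt_plus`, `alt_minus`,
#'   `edge_fracs`, `posterior_p`) have no standard VCF encoding and are
#'   looked up in FORMAT keys `HQ`, `SP`, `SM`, `EF`, `PP`
#' @return variant data frame
#' @export
read_vcf_variants <- function(path, require_evidence = c("t_depth", "t_alt",
                                                         "af")) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1], "#CHROM"))
    stop("not a VCF: missing #CHROM header", call. = FALSE)
  header <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  if (length(header) < 10L)
    stop("VCF has no sample column", call. = FALSE)
  rows <- strsplit(body[-1], "\t")
  fmt_map <- c(DP = "t_depth", AD = "t_alt", AF = "af", HQ = "t_alt_hq",
               SP = "alt_plus", SM = "alt_minus", EF = "edge_fracs",
               PP = "posterior_p")
  out <- lapply(rows, function(r) {
    keys <- strsplit(r[9], ":")[[1]]
    vals <- strsplit(r[10], ":")[[1]]
    rec <- list(chrom = r[1], pos = as.numeric(r[2]), ref = r[4], alt = r[5])
    for (i in seq_along(keys)) {
      col <- fmt_map[keys[i]]
      if (is.na(col)) next
      rec[[col]] <- if (col == "edge_fracs")
        list(as.numeric(strsplit(vals[i], ",")[[1]]))
      else if (keys[i] == "AD")  # REF,ALT depths; keep ALT
        as.numeric(strsplit(vals[i], ",")[[1]][2])
      else as.numeric(vals[i])
    }
    rec
  })
  all_cols <- unique(unlist(lapply(out, names)))
  miss <- setdiff(require_evidence, all_cols)
  if (length(miss))
    stop("VCF lacks evidence column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num_cols <- setdiff(unname(fmt_map), "edge_fracs")
  df <- data.frame(
    chrom = vapply(out, `[[`, character(1), "chrom"),
    pos = vapply(out, `[[`, numeric(1), "pos"),
    ref = vapply(out, `[[`, character(1), "ref"),
    alt = vapply(out, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE)
  for (col in num_cols)
    df[[col]] <- vapply(out, function(r)
      if (is.null(r[[col]])) NA_real_ else r[[col]], numeric(1))
  df$edge_fracs <- lapply(out, function(r)
    if (is.null(r$edge_fracs)) numeric(0) else r$edge_fracs[[1]])
  df
}

#' Write an expression matrix TSV (genes x cell lines)
#' @param mat numeric matrix with gene rownames and cell-line colnames
#' @param path output path
#' @export
write_expression_tsv <- function(mat, path) {
  lines <- c(paste(c("gene", colnames(mat)), collapse = "\t"))
  for (i in seq_len(nrow(mat)))
    lines <- c(lines, paste(c(rownames(mat)[i], sprintf("%.6f", mat[i, ])),
                            collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix TSV
#' @param path file path
#' @return numeric matrix; load refuses missing values
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df)
  if (anyNA(mat))
    stop("expression matrix contains missing values; imputation is refused",
         call. = FALSE)
  mat
}

#' Write a proteome intensity matrix with factor header rows
#'
#' Two comment rows (`#genotype`, `#label`) carry the per-sample factors,
#' followed by a standard proteins x samples table.
#' @param mat proteins x samples matrix
#' @param factors data frame with `sample`, `genotype`, `label`
#' @param path output path
#' @export
write_proteome_tsv <- function(mat, factors, path) {
  stopifnot(identical(colnames(mat), as.character(factors$sample)))
  lines <- c(paste(c("#genotype", as.character(factors$genotype)),
                   collapse = "\t"),
             paste(c("#label", as.character(factors$label)), collapse = "\t"),
             paste(c("protein", colnames(mat)), collapse = "\t"))
  for (i in seq_len(nrow(mat)))
    lines <- c(lines, paste(c(rownames(mat)[i], sprintf("%.6f", mat[i, ])),
                            collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a proteome intensity matrix with factor header rows
#' @param path file path
#' @return list with `matrix` and `factors`
#' @export
read_proteome_tsv <- function(path) {
  lines <- readLines(path)
  gt <- strsplit(lines[1], "\t")[[1]]
  lb <- strsplit(lines[2], "\t")[[1]]
  if (gt[1] != "#genotype" || lb[1] != "#label")
    stop("missing factor header rows", call. = FALSE)
  tc <- textConnection(lines[-(1:2)])
  on.exit(close(tc))
  df <- utils::read.table(tc, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  mat <- as.matrix(df)
  list(matrix = mat,
       factors = data.frame(sample = colnames(mat), genotype = gt[-1],
                            label = lb[-1], stringsAsFactors = FALSE))
}
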