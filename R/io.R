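#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal but standards-conforming VCF with GT:DP:GQ FORMAT fields
#' (DP/GQ omitted when absent from the object) and contig lines carrying the
#' chromosome lengths, so quality filters and windowed statistics can be
#' exercised on the re-read file. Positions are written 1-based as required
#' by the format.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path (plain text).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  lens <- gm$chrom_len
  if (is.null(lens)) {
    lens <- tapply(gm$pos, gm$chrom, max)
  }
  for (ch in unique(gm$chrom))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       as.integer(lens[[ch]])), con)
  writeLines(c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[as.character(gm$geno[ok])]
  has_dp <- !is.null(gm$dp); has_gq <- !is.null(gm$gq)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  cell <- gt
  if (has_dp) cell <- matrix(paste(cell, gm$dp, sep = ":"), nrow(gt))
  if (has_gq) cell <- matrix(paste(cell, gm$gq, sep = ":"), nrow(gt))
  qual <- if (is.null(gm$qual)) rep(".", length(gm$pos)) else gm$qual
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, qual, "PASS", ".",
                fmt, apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read diploid genotypes from a VCF file
#'
#' Thin wrapper around `vcfR`. Genotypes are recoded to derived-allele counts
#' (0/1/2, NA for missing); multiallelic records are split into one biallelic
#' record per alternate allele, counting copies of that allele against all
#' others. DP and GQ FORMAT fields and the site QUAL column are carried along
#' when present. Contig lengths declared in the header populate `$chrom_len`.
#'
#' @param path VCF file.
#' @param populations optional data.frame (accession, group) or path to such
#'   a TSV; attaches population labels.
#' @return A [geno_matrix()].
#' @export
read_vcf_genotypes <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  gq <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  samples <- colnames(gt_raw)
  a1 <- substr(gt_raw, 1, 1)
  a2 <- substr(gt_raw, 3, 3)
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  out_rows <- rep(seq_along(pos), n_alt)
  allele_k <- sequence(n_alt)
  geno <- matrix(NA_integer_, length(out_rows), length(samples))
  for (r in seq_along(out_rows)) {
    i <- out_rows[r]; k <- as.character(allele_k[r])
    called <- a1[i, ] != "." & a2[i, ] != "."
    g <- (a1[i, ] == k) + (a2[i, ] == k)
    g[!called] <- NA_integer_
    geno[r, ] <- g
  }
  alt_split <- unlist(strsplit(alt, ",", fixed = TRUE))
  pops <- NULL
  if (!is.null(populations)) {
    if (is.character(populations))
      populations <- read.table(populations, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    pops <- populations$group[match(samples, populations$accession)]
    if (anyNA(pops)) stop("population assignment missing for some accessions")
  }
  gm <- geno_matrix(geno, chrom = chrom[out_rows], pos = pos[out_rows],
                    ref = ref[out_rows], alt = alt_split,
                    samples = samples, pops = pops,
                    qual = qual[out_rows],
                    dp = if (!is.null(dp)) dp[out_rows, , drop = FALSE],
                    gq = if (!is.null(gq)) gq[out_rows, , drop = FALSE])
  meta <- v@meta
  contig <- meta[grepl("^##contig=", meta)]
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
    lens <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1",
                                            contig)))
    gm$chrom_len <- setNames(lens, ids)
  }
  gm
}

#' Write gene models as GFF3
#'
#' @param gene_model data.frame with gene_id, chrom, start, end (1-based
#'   inclusive) and optional strand.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(gene_model, path) {
  strand <- if ("strand" %in% names(gene_model)) gene_model$strand else "+"
  lines <- c("##gff-version 3",
             paste(gene_model$chrom, "clonalpop", "gene",
                   gene_model$start, gene_model$end, ".", strand, ".",
                   paste0("ID=", gene_model$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Retains `gene` features (and `exon`/`CDS` children when present, exposed
#' through the `type` column). Coordinates stay 1-based inclusive as in the
#' format.
#'
#' @param path GFF3 file.
#' @param types feature types to keep.
#' @return data.frame (gene_id, chrom, start, end, strand, type), sorted.
#' @export
read_gene_models <- function(path, types = c("gene", "exon", "CDS")) {
  raw <- read.table(path, sep = "\t", comment.char = "#", quote = "",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "source", "type", "start", "end",
                                  "score", "strand", "frame", "attributes"))
  raw <- raw[raw$type %in% types, , drop = FALSE]
  if (!nrow(raw)) stop("no requested feature types found in ", path)
  id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", raw$attributes)
  no_id <- !grepl("ID=", raw$attributes)
  id[no_id] <- sub(".*(?:^|;)Parent=([^;]+).*", "\\1", raw$attributes[no_id])
  out <- data.frame(gene_id = id, chrom = raw$chrom,
                    start = as.integer(raw$start), end = as.integer(raw$end),
                    strand = raw$strand, type = raw$type,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with a `gene` column followed by one column per accession
#'   (FPKM scale).
#' @return numeric matrix genes x accessions.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative abundance values")
  m
}

#' Read a trait table from TSV
#'
#' @param path TSV with an `accession` column followed by numeric traits.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a per-site deleterious score table from TSV
#'
#' @param path TSV with chrom, pos, score columns (SIFT scale, 0-1).
#' @return data.frame.
#' @export
read_scores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "score") %in% names(df)))
    stop("score table must have chrom, pos, score columns")
  df
}
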