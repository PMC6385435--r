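#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.x with GT in FORMAT into a \code{genotype_matrix}.
#' GT codes map to alternate-allele dosage: 0/0 -> 0, 0/1 or 1/0 -> 1,
#' 1/1 -> 2, ./. -> missing; both '/' and '|' separators are accepted.
#' Multiallelic records are rejected: by default with an error naming the
#' offending record, or dropped with a report when \code{skip_multiallelic}.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param skip_multiallelic drop non-biallelic records instead of erroring.
#' @return A \code{genotype_matrix}; when records were skipped, the attribute
#'   \code{"skipped"} holds a data.frame of record number, id and reason.
#' @export
read_vcf <- function(path, skip_multiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  bad <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
    is.na(fix$ALT)
  if (any(bad) && !skip_multiallelic) {
    stop(sprintf("non-biallelic SNP record(s) at record %s (id %s)",
                 paste(which(bad), collapse = ","),
                 paste(fix$ID[bad], collapse = ",")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!bad)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_real_, length(x))
    out[x == "0/0"] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x == "1/1"] <- 2
    out
  }
  dos <- apply(gt[keep, , drop = FALSE], 2, code)
  if (length(keep) == 1L) dos <- matrix(dos, nrow = 1L)
  variants <- data.frame(
    id = ids[keep], chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep], stringsAsFactors = FALSE
  )
  g <- genotype_matrix(colnames(gt), variants, t(dos))
  if (any(bad)) {
    attr(g, "skipped") <- data.frame(
      record = which(bad), id = ids[bad], reason = "non-biallelic",
      stringsAsFactors = FALSE)
  }
  g
}

#' Write genotypes to a minimal VCF v4.2 file
#'
#' Emits GT-only records with unphased separators; missing dosages become
#' "./.". Round-trips through \code{\link{read_vcf}}.
#'
#' @param g a \code{genotype_matrix}.
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  ), con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(g$variants))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gtcode[d + 1L])
    writeLines(paste(c(g$variants$chrom[j], g$variants$pos[j],
                       g$variants$id[j], g$variants$ref[j], g$variants$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read the internal dosage TSV format
#'
#' A plain TSV with the five variant metadata columns followed by one column
#' per sample; missing dosages are written as NA. Reading reproduces the
#' matrix exactly.
#'
#' @param g a \code{genotype_matrix}.
#' @param path file path.
#' @return \code{read_dosage_tsv} returns a \code{genotype_matrix}.
#' @export
write_dosage_tsv <- function(g, path) {
  df <- cbind(g$variants, as.data.frame(t(g$dosages)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(chrom = "character"))
  meta <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta %in% names(df)))
    stop("not a dosage TSV: missing metadata columns")
  samples <- setdiff(names(df), meta)
  dos <- t(as.matrix(df[, samples, drop = FALSE]))
  genotype_matrix(samples, df[, meta], dos)
}

#' Read gene models from a BED file
#'
#' Accepts 4+ column BED (chrom, start0, end0, name). BED's half-open 0-based
#' coordinates are converted to the 1-based inclusive spans used internally:
#' start1 = start0 + 1, end1 = end0.
#'
#' @param path BED file path.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start1}, \code{end1}, in file order.
#' @export
read_bed_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) stop("no records in ", path)
  parts <- strsplit(lines, "\t| +")
  ncols <- vapply(parts, length, 1L)
  if (any(ncols < 4L))
    stop("BED line ", which(ncols < 4L)[1], " has fewer than 4 columns")
  start0 <- as.numeric(vapply(parts, `[`, "", 2L))
  end0 <- as.numeric(vapply(parts, `[`, "", 3L))
  bad <- which(!(start0 < end0))
  if (length(bad))
    stop("BED line ", bad[1], ": start must be < end (half-open intervals)")
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 4L),
    chrom = vapply(parts, `[`, "", 1L),
    start1 = as.integer(start0 + 1),
    end1 = as.integer(end0),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) stop("duplicate gene IDs in BED")
  out
}

#' Write gene models to BED4 (inverse of \code{read_bed_genes})
#' @param genes data.frame with gene_id, chrom, start1, end1.
#' @param path output path.
#' @export
write_bed_genes <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start1 - 1L, genes$end1, genes$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the phenotype/covariate table
#'
#' TSV with header: \code{sample_id}, \code{year}, \code{breed_group}, then
#' one column per trait. \code{year} is treated as a categorical covariate;
#' \code{breed_group} must be an integer in 1..6.
#'
#' @param path TSV path.
#' @return data.frame, one row per sample.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  req <- c("sample_id", "year", "breed_group")
  if (!all(req %in% names(df)))
    stop("phenotype table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id rows")
  if (!all(df$breed_group %in% 1:6))
    stop("breed_group must be in 1..6")
  df$year <- factor(df$year)
  df
}

#' @rdname read_phenotypes
#' @param pheno phenotype data.frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO annotation map
#'
#' TSV with columns \code{gene_id}, \code{go_id} and optionally \code{name}
#' (term description). Duplicate gene-term pairs collapse to one.
#'
#' @param path TSV path.
#' @return list with \code{gene2go} (named list: gene -> character vector of
#'   term IDs) and \code{term_names} (named character vector).
#' @export
read_go_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("gene_id", "go_id") %in% names(df)))
    stop("GO map must have columns gene_id, go_id")
  df <- unique(df[, intersect(c("gene_id", "go_id", "name"), names(df))])
  gene2go <- split(df$go_id, df$gene_id)
  gene2go <- lapply(gene2go, unique)
  term_names <- if ("name" %in% names(df)) {
    nm <- df[!duplicated(df$go_id), ]
    stats::setNames(as.character(nm$name), nm$go_id)
  } else {
    u <- unique(df$go_id)
    stats::setNames(u, u)
  }
  list(gene2go = gene2go, term_names = term_names)
}

#' Read a tissue background gene list (one gene ID per line)
#'
#' The background is both the pre-enrichment filter and the population of the
#' hypergeometric test. It is not required to be a subset of the gene models:
#' expression atlases routinely list genes absent from a given annotation
#' build, and such entries simply never intersect a gene list.
#'
#' @param path text file, one gene ID per line.
#' @return character vector of unique gene IDs.
#' @export
read_background <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L) stop("background list is empty")
  x
}

#' Write a QC report as TSV plus a JSON summary
#' @param report the report element from \code{\link{qc_filter}}.
#' @param path_tsv,path_json output paths (either may be NULL to skip).
#' @export
write_qc_report <- function(report, path_tsv = NULL, path_json = NULL) {
  df <- data.frame(metric = names(report),
                   value = unlist(report, use.names = FALSE))
  if (!is.null(path_tsv))
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
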