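#' Write per-sample signal files in PennCNV format
#'
#' One tab-delimited file per animal with header
#' `Name  Chr  Position  <sample>.Log R Ratio  <sample>.B Allele Freq`.
#'
#' @param signals `signal_set`.
#' @param map aligned SNP map.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_penncnv_signals <- function(signals, map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(signals$animal_ids))
  for (a in seq_along(signals$animal_ids)) {
    s <- signals$animal_ids[a]
    df <- data.frame(Name = map$snp_id, Chr = map$chrom,
                     Position = map$pos_bp,
                     lrr = signals$lrr[a, ], baf = signals$baf[a, ])
    names(df)[4:5] <- paste0(s, c(".Log R Ratio", ".B Allele Freq"))
    paths[a] <- file.path(dir, paste0(s, ".txt"))
    utils::write.table(df, paths[a], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read PennCNV-format signal files into a signal set
#'
#' @param files character vector of per-sample signal file paths.
#' @return list with a `signal_set` (genotypes all `NA`; PennCNV
#'   signal files carry no calls) and the `map` reconstructed from the
#'   first file (without GC or panel information).
#' @export
read_penncnv_signals <- function(files) {
  stopifnot(length(files) >= 1)
  first <- utils::read.delim(files[1], check.names = FALSE)
  map <- data.frame(snp_id = first$Name, chrom = first$Chr,
                    pos_bp = first$Position, on_md_panel = TRUE,
                    gc_frac = NA_real_, stringsAsFactors = FALSE)
  n_snp <- nrow(map)
  ids <- character(length(files))
  lrr <- matrix(NA_real_, length(files), n_snp)
  baf <- matrix(NA_real_, length(files), n_snp)
  for (i in seq_along(files)) {
    d <- utils::read.delim(files[i], check.names = FALSE)
    stopifnot(identical(d$Name, first$Name))
    lrr_col <- grep("\\.Log R Ratio$", names(d), value = TRUE)
    baf_col <- grep("\\.B Allele Freq$", names(d), value = TRUE)
    ids[i] <- sub("\\.Log R Ratio$", "", lrr_col)
    lrr[i, ] <- d[[lrr_col]]
    baf[i, ] <- d[[baf_col]]
  }
  signals <- structure(list(lrr = lrr, baf = baf,
                            geno = matrix(NA_integer_, length(files), n_snp),
                            cn = NULL, animal_ids = ids,
                            snp_ids = map$snp_id), class = "signal_set")
  list(signals = signals, map = map)
}

#' Write called genotypes as a minimal GT-only VCF
#'
#' Alleles are generic A/B; genotype codes 0/1/2 map to `0/0`, `0/1`,
#' `1/1` and missing to `./.`.
#'
#' @param signals `signal_set`.
#' @param map aligned SNP map.
#' @param path output file (uncompressed `.vcf`).
#' @return invisibly, `path`.
#' @export
write_genotype_vcf <- function(signals, map, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", signals$animal_ids),
                     collapse = "\t")), con)
  g <- t(signals$geno)  # SNPs x animals
  body <- vapply(seq_len(nrow(map)), function(j) {
    gt <- ifelse(is.na(g[j, ]), "./.", gt_code[g[j, ] + 1L])
    paste(c(map$chrom[j], map$pos_bp[j], map$snp_id[j], "A", "B", ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a GT-only VCF of called genotypes
#'
#' Uses the vcfR package; genotypes are returned as B-allele dosages
#' 0/1/2 with `NA` for missing.
#'
#' @param path VCF file.
#' @return list with `geno` (animals x SNPs integer matrix), `map`
#'   (snp_id/chrom/pos_bp), `animal_ids`.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  list(geno = t(dos),
       map = data.frame(snp_id = fix[, "ID"],
                        chrom = as.integer(fix[, "CHROM"]),
                        pos_bp = as.integer(fix[, "POS"]),
                        stringsAsFactors = FALSE),
       animal_ids = colnames(gt))
}

#' CNV calls to/from BED intervals
#'
#' BED uses 0-based half-open coordinates while calls are 1-based
#' closed; the conversion is `start0 = start_bp - 1`, `end0 = end_bp`.
#'
#' @param calls call data.frame.
#' @return `calls_to_bed`: data.frame with `chrom`, `start`, `end`,
#'   `name` (`animal:cn`), `score` (n_snps); `bed_to_calls` inverts
#'   the coordinate convention.
#' @export
calls_to_bed <- function(calls) {
  data.frame(chrom = calls$chrom, start = calls$start_bp - 1L,
             end = calls$end_bp,
             name = paste0(calls$animal_id, ":cn", calls$copy_number),
             score = calls$n_snps, stringsAsFactors = FALSE)
}

#' @rdname calls_to_bed
#' @param bed BED-style data.frame as written by `calls_to_bed`.
#' @export
bed_to_calls <- function(bed) {
  parts <- strsplit(bed$name, ":cn", fixed = TRUE)
  data.frame(animal_id = vapply(parts, `[`, "", 1),
             chrom = bed$chrom, start_bp = bed$start + 1L,
             end_bp = bed$end,
             copy_number = as.integer(vapply(parts, `[`, "", 2)),
             n_snps = bed$score, stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV (deterministic layout)
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
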