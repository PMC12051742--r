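# VCF and sidecar I/O.  Reading goes through vcfR; writing a GT-only
# VCF 4.2 from phased haplotype matrices is done directly.

#' Write a GT-only VCF 4.2
#'
#' @param sites Tibble with columns `contig`, `pos`, `ref`, `alt`.
#' @param haplotypes 0/1 matrix, haplotypes in rows (two consecutive rows
#'   per diploid sample), sites in columns; `NA` writes a missing call for
#'   the whole genotype.
#' @param sample_names Diploid sample names (rows/2).
#' @param contigs Tibble with columns `contig`, `length`.
#' @param path Output file.
#' @param phased Write `|`-separated genotypes (default; synthetic
#'   haplotypes are known-phase).
#' @return The path, invisibly.
#' @export
write_vcf <- function(sites, haplotypes, sample_names, contigs, path,
                      phased = TRUE) {
  stopifnot(nrow(haplotypes) == 2 * length(sample_names),
            ncol(haplotypes) == nrow(sites))
  sep <- if (phased) "|" else "/"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=crowdemog",
           paste0("##contig=<ID=", contigs$contig, ",length=",
                  contigs$length, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  ns <- length(sample_names)
  a1 <- haplotypes[2 * seq_len(ns) - 1, , drop = FALSE]
  a2 <- haplotypes[2 * seq_len(ns), , drop = FALSE]
  gt <- matrix(paste0(a1, sep, a2), nrow = ns)
  gt[is.na(a1) | is.na(a2)] <- paste0(".", sep, ".")
  body <- vapply(seq_len(nrow(sites)), function(k)
    paste(c(sites$contig[k], sites$pos[k], ".", sites$ref[k],
            sites$alt[k], ".", "PASS", ".", "GT", gt[, k]),
          collapse = "\t"),
    character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a population-genotype object
#'
#' Parses the VCF with [vcfR::read.vcfR()] and returns the haplotype (or
#' dosage) representation used by the statistics and SFS layers.
#'
#' @param vcf_path Path to a VCF (uncompressed or bgzipped).
#' @param pop_map Tibble/data frame with columns `sample`, `population`, or
#'   a path to such a TSV.
#' @param outgroup Optional outgroup allele table (`contig`, `pos`,
#'   `allele` with 0 = REF, 1 = ALT) or path to the sidecar TSV.
#' @return An object of class `pop_genotypes`: `sites` (tibble `contig`,
#'   `pos`, `ref`, `alt`), `haplotypes` (0/1 matrix, 2 rows per sample; NA
#'   for missing), `pop` (per-haplotype population), `samples`, `contigs`,
#'   and optionally `outgroup` (0/1 per site).
#' @export
read_pop_genotypes <- function(vcf_path, pop_map, outgroup = NULL) {
  if (is.character(pop_map)) {
    pop_map <- utils::read.table(pop_map, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- tibble::tibble(contig = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  miss <- setdiff(samples, pop_map$sample)
  if (length(miss) > 0)
    stop("samples absent from the population map: ",
         paste(miss, collapse = ", "), call. = FALSE)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  n_sites <- nrow(sites)
  H <- matrix(NA_integer_, 2 * length(samples), n_sites)
  for (s in seq_along(samples)) {
    H[2 * s - 1, ] <- as.integer(a1[, s])
    H[2 * s, ] <- as.integer(a2[, s])
  }
  pop <- rep(pop_map$population[match(samples, pop_map$sample)], each = 2)
  contigs <- vcf_contigs(vcf_path)
  og <- NULL
  if (!is.null(outgroup)) {
    if (is.character(outgroup))
      outgroup <- utils::read.table(outgroup, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
    key <- paste(sites$contig, sites$pos)
    og <- outgroup$allele[match(key, paste(outgroup$contig, outgroup$pos))]
  }
  structure(list(sites = sites, haplotypes = H, pop = pop,
                 samples = samples, contigs = contigs, outgroup = og),
            class = "pop_genotypes")
}

vcf_contigs <- function(vcf_path) {
  hdr <- readLines(vcf_path, n = 5000)
  hdr <- hdr[startsWith(hdr, "##contig")]
  if (length(hdr) == 0)
    return(tibble::tibble(contig = character(), length = integer()))
  tibble::tibble(
    contig = sub('.*ID=([^,>]+).*', "\\1", hdr),
    length = as.integer(sub(".*length=([0-9]+).*", "\\1", hdr)))
}

#' @export
print.pop_genotypes <- function(x, ...) {
  cat("<pop_genotypes> ", length(x$samples), " samples (",
      nrow(x$haplotypes), " haplotypes), ", nrow(x$sites),
      " sites, populations: ",
      paste(unique(x$pop), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an accessibility mask in BED format
#'
#' Standard BED (0-based, half-open) converted to the 1-based inclusive
#' intervals used internally.
#'
#' @param path BED3+ file.
#' @return Tibble with columns `contig`, `start`, `end` (1-based inclusive).
#' @export
read_bed_mask <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  tibble::tibble(contig = b[[1]], start = b[[2]] + 1L, end = b[[3]])
}
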