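#' Write a SNP haplotype matrix as TSV
#'
#' Plain-text dialect: a header line
#' `#population=<X|Y> Ne=<int> L=<int> generation=<int>` followed by `Ne`
#' rows of `L` tab-separated 0/1 values (loci 1-based, left to right).
#'
#' @param pop `Ne x L` binary matrix.
#' @param path Output file path.
#' @param population `"X"` or `"Y"`.
#' @param generation Generation counter recorded in the header.
#' @export
write_snp_tsv <- function(pop, path, population = "X", generation = 0L) {
  stopifnot(population %in% c("X", "Y"))
  header <- sprintf("#population=%s Ne=%d L=%d generation=%d",
                    population, nrow(pop), ncol(pop), as.integer(generation))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(pop, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a SNP haplotype matrix TSV
#'
#' @param path File written by [write_snp_tsv()].
#' @return List with the integer `matrix`, `population`, and `generation`.
#' @export
read_snp_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#population="))
    stop("not a SNP matrix TSV: missing '#population=' header in ", path)
  fields <- strsplit(sub("^#", "", header), " ")[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  mat <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(mat) <- NULL
  storage.mode(mat) <- "integer"
  stopifnot(nrow(mat) == as.integer(meta[["Ne"]]),
            ncol(mat) == as.integer(meta[["L"]]),
            all(mat %in% 0:1))
  list(matrix = mat, population = meta[["population"]],
       generation = as.integer(meta[["generation"]]))
}

#' Export a haplotype matrix as a haploid VCF
#'
#' One sample per carrier; the GT field holds a single allele (0 or 1).
#' `CHROM` is fixed to `sim1` and `POS = locus_index * snp_spacing`.
#'
#' @param pop `Ne x L` binary matrix.
#' @param path Output file path (uncompressed VCF).
#' @param snp_spacing bp between adjacent SNPs.
#' @param chrom Chromosome label (default `"sim1"`).
#' @export
write_haploid_vcf <- function(pop, path, snp_spacing, chrom = "sim1") {
  Ne <- nrow(pop); L <- ncol(pop)
  samples <- sprintf("carrier%d", seq_len(Ne))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       L * as.integer(snp_spacing) + as.integer(snp_spacing)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (l in seq_len(L)) {
    row <- c(chrom, l * as.integer(snp_spacing), sprintf("snp%d", l),
             "A", "T", ".", "PASS", ".", "GT", as.character(pop[, l]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read a simulation configuration
#'
#' Configurations are stored as DCF (Debian-control-format) structured
#' text with the fixed parameters, the seed, and the prior blocks
#' (`s_bound`, `candidate_loci`, `m_set`, `sex_set`).
#'
#' @param config Named list with at least the [fixed_params()] fields.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  flat <- lapply(config, function(v) paste(v, collapse = ", "))
  write.dcf(as.data.frame(flat, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config()` returns a named list; numeric-looking fields are
#'   converted, comma-separated fields become vectors.
#' @export
read_config <- function(path) {
  rec <- read.dcf(path)
  out <- lapply(stats::setNames(as.list(rec[1, ]), colnames(rec)), function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  out
}

#' Write the drawn-parameter sidecar for a simulation run
#'
#' @param drawn A [drawn_params()] object.
#' @param path File path (DCF structured text).
#' @export
write_drawn_params <- function(drawn, path) {
  write_config(list(sel_loci = drawn$sel_loci, sel_coeffs = drawn$sel_coeffs,
                    sel_alleles = drawn$sel_alleles, m = drawn$m,
                    sex = drawn$sex), path)
}
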