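#' Read a genetic map file
#'
#' Tab-delimited with one header line and columns `marker_id`,
#' `chromosome`, `position_cM`.
#'
#' @param path File path.
#' @return Genetic map tibble (`marker`, `chr`, `pos_cM`).
#' @export
read_genetic_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("marker", "chr", "pos_cM")
  validate_map(tibble::as_tibble(df[, c("marker", "chr", "pos_cM")]))
}

#' Read genotypes from a tab-delimited matrix
#'
#' Lines in rows (first column = line id, header = marker ids), cells
#' holding biallelic calls such as `AA`, `BB`, `A/B` or `NA`. Calls are
#' coded via [code_genotypes()].
#'
#' @param path File path.
#' @param map Optional genetic map supplying marker positions.
#' @param ... Passed to [code_genotypes()].
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, map = NULL, ...) {
  df <- read.table(path,
    header = TRUE, sep = "\t", row.names = 1,
    stringsAsFactors = FALSE, check.names = FALSE, na.strings = c("NA", ".")
  )
  calls <- as.matrix(df)
  if (!ncol(calls)) abort(sprintf("no usable markers in %s.", path))
  code_genotypes(calls, map = map, ...)
}

#' Write genotypes as a tab-delimited call matrix
#'
#' Inverse of [read_genotype_matrix()]; a read-write round trip is
#' byte-stable.
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_matrix <- function(G, path) {
  calls <- decode_genotypes(G)
  df <- data.frame(line = rownames(calls), calls, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Keeps biallelic SNP records only; multi-allelic records are skipped
#' with a counted warning. Genotype fields are interpreted as inbred
#' calls; positions (1-based) and chromosomes are carried into the marker
#' metadata unchanged.
#'
#' @param path VCF path (plain text or gzipped).
#' @param ... Passed to [code_genotypes()].
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path, ...) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 | nchar(fix[, "ALT"]) != 1
  if (any(multi)) {
    warn(sprintf("%d non-biallelic-SNP record(s) skipped.", sum(multi)))
  }
  keep <- which(!multi)
  if (!length(keep)) abort("no usable biallelic SNP records in the VCF.")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ref <- fix[keep, "REF"]
  alt <- fix[keep, "ALT"]
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[noid]
  calls <- matrix(NA_character_, ncol(gt), nrow(gt),
    dimnames = list(colnames(gt), ids)
  )
  for (j in seq_len(nrow(gt))) {
    al <- c(`0` = ref[j], `1` = alt[j])
    g <- gt[j, ]
    parts <- strsplit(g, "[/|]")
    calls[, j] <- vapply(parts, function(pp) {
      if (length(pp) != 2 || anyNA(pp) || any(!pp %in% names(al))) {
        NA_character_
      } else {
        paste0(al[pp[1]], al[pp[2]])
      }
    }, "")
  }
  map <- tibble::tibble(
    marker = ids,
    chr = fix[keep, "CHROM"],
    pos_cM = as.numeric(fix[keep, "POS"])
  )
  code_genotypes(calls, map = map, ...)
}

#' Read a long-format phenotype table
#'
#' Tab- or comma-delimited text with header columns `line_id`,
#' `environment`, `value`. Duplicate (line, environment) pairs are an
#' error; missing values are kept as `NA` and excluded downstream with a
#' logged count.
#'
#' @param path File path.
#' @param G Optional [genotype_matrix()]; unknown line ids raise an error
#'   listing the offenders.
#' @return Phenotype tibble (`line`, `env`, `value`).
#' @export
read_phenotypes <- function(path, G = NULL) {
  head_lines <- readLines(path, n = 10)
  first <- head_lines[!startsWith(head_lines, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 3) abort("phenotype file needs columns line_id, environment, value.")
  names(df)[1:3] <- c("line", "env", "value")
  pheno <- tibble::as_tibble(df[, c("line", "env", "value")])
  pheno$value <- as.numeric(pheno$value)
  validate_phenotypes(pheno, G)
  n_na <- sum(is.na(pheno$value))
  if (n_na) inform(sprintf("%d missing phenotype value(s) retained as NA.", n_na))
  pheno
}

#' Write a results table as TSV
#'
#' All pipeline TSVs carry a single commented header line naming units and
#' conventions before the column header.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param comment Convention/unit note written as a leading `#` line.
#' @export
write_results_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  x <- as.data.frame(x)
  for (j in seq_along(x)) if (is.list(x[[j]])) x[[j]] <- vapply(x[[j]], paste, "", collapse = ",")
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
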