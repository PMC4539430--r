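#' Pipeline configuration
#'
#' Validates and normalizes the configuration for [run_qts_pipeline()].
#' Referenced paths must exist; parameters must lie in their documented
#' ranges.
#'
#' @param genotypes Path to a genotype file (tab-delimited matrix or VCF).
#' @param phenotypes Path to a long-format phenotype file.
#' @param out_dir Output directory (created if missing).
#' @param map Optional path to a genetic map file.
#' @param format `"matrix"` or `"vcf"`.
#' @param max_order,retain,k_folds Screen parameters.
#' @param B,alpha Scan permutation parameters.
#' @param iterations,burnin,thin MCMC parameters.
#' @param clump_cM Locus clump window for the screen and full model (cM).
#' @param exclusion_cM Cofactor exclusion window for the scan (cM).
#' @param seed Global seed.
#' @param verbose Emit progress messages.
#' @return A validated config list of class `qts_config`.
#' @export
qts_config <- function(genotypes, phenotypes, out_dir, map = NULL,
                       format = c("matrix", "vcf"),
                       max_order = 2, retain = 10, k_folds = 10,
                       B = 1000, alpha = 0.05,
                       iterations = 12000, burnin = 2000, thin = 2,
                       clump_cM = 20, exclusion_cM = 30, seed = 1L, verbose = TRUE) {
  format <- match.arg(format)
  for (p in c(genotypes, phenotypes, map)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("path does not exist: %s", p))
  }
  stopifnot(
    max_order %in% 1:3, retain >= 1, k_folds >= 2,
    B >= 19, alpha > 0, alpha < 1,
    iterations > burnin, burnin >= 0, thin >= 1
  )
  structure(
    list(
      genotypes = genotypes, phenotypes = phenotypes, out_dir = out_dir,
      map = map, format = format,
      max_order = max_order, retain = retain, k_folds = k_folds,
      B = B, alpha = alpha,
      iterations = iterations, burnin = burnin, thin = thin,
      clump_cM = clump_cM, exclusion_cM = exclusion_cM,
      seed = as.integer(seed), verbose = verbose
    ),
    class = "qts_config"
  )
}

#' Run the two-step mapping pipeline end to end
#'
#' Reads genotypes and phenotypes, runs the GMDR screen, the 1D/2D scan
#' with permutation thresholds, and the MCMC full-model estimation, and
#' writes `candidates.tsv`, `scan.tsv`, `effects.tsv`, a reproducibility
#' manifest (`manifest.json`: all parameters, seeds, input checksums,
#' package version) and a log. With a fixed seed, reruns are
#' byte-identical apart from the manifest timestamp.
#'
#' @param config A [qts_config()].
#' @return Invisibly, a list with the screen, scan and MCMC objects and
#'   the output paths.
#' @export
run_qts_pipeline <- function(config) {
  stopifnot(inherits(config, "qts_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (config$verbose) inform(line)
  }
  manifest <- list(
    package = "qtsmap",
    version = as.character(utils::packageVersion("qtsmap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = config[setdiff(names(config), "verbose")],
    inputs = lapply(
      Filter(Negate(is.null), list(
        genotypes = config$genotypes, phenotypes = config$phenotypes, map = config$map
      )),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))
    ),
    status = "running"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, null = "null"
    )
  }
  write_manifest()
  stage <- "read"
  result <- tryCatch(
    {
      map <- if (!is.null(config$map)) read_genetic_map(config$map) else NULL
      G <- if (config$format == "vcf") {
        read_genotypes_vcf(config$genotypes)
      } else {
        read_genotype_matrix(config$genotypes, map = map)
      }
      pheno <- read_phenotypes(config$phenotypes, G)
      logf("read %d lines x %d markers, %d phenotype rows", nrow(G), ncol(G), nrow(pheno))

      stage <- "screen"
      cand <- gmdr_screen(G, pheno,
        max_order = config$max_order, retain = config$retain,
        k_folds = config$k_folds, seed = config$seed,
        clump_cM = config$clump_cM
      )
      write_results_tsv(tidy(cand), file.path(config$out_dir, "candidates.tsv"),
        comment = "GMDR screen: mean testing balanced accuracy (0-1), CV consistency (folds)"
      )
      logf("screen retained %d models, %d candidate markers", nrow(cand$models), nrow(cand$candidates))

      stage <- "scan"
      scan <- qts_scan(G, pheno, cand,
        B = config$B, alpha = config$alpha, seed = config$seed,
        exclusion_cM = config$exclusion_cM
      )
      write_results_tsv(tidy(scan), file.path(config$out_dir, "scan.tsv"),
        comment = sprintf(
          "1D/2D QTS scan: F tests locus effects jointly across environments; permutation threshold, experiment-wise alpha = %g per family",
          config$alpha
        )
      )
      logf("scan: %d terms, %d significant", nrow(scan), sum(scan$significant, na.rm = TRUE))

      stage <- "estimate"
      fit <- fit_qts_mcmc(G, pheno, build_full_model(scan, exclusion_cM = config$clump_cM),
        iterations = config$iterations, burnin = config$burnin,
        thin = config$thin, seed = config$seed
      )
      arch <- summarize_architecture(fit, G)
      write_results_tsv(arch, file.path(config$out_dir, "effects.tsv"),
        comment = "posterior-mean effects (trait units), -log10(P) from posterior t tests, h2 in % of modeled phenotypic variance"
      )
      logf("estimate: total h2 = %.2f%%, sigma2 = %.4g", attr(fit, "total_h2"), attr(fit, "sigma2"))

      manifest$status <- "ok"
      list(candidates = cand, scan = scan, fit = fit, out_dir = config$out_dir)
    },
    error = function(e) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- stage
      manifest$error <<- conditionMessage(e)
      write_manifest()
      abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
    }
  )
  write_manifest()
  invisible(result)
}
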