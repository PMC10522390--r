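#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-rowed delimited table (delimiter auto-detected among
#' tab, comma and space), maps its columns onto the standard fields via
#' \code{columnMap}, and validates every row. Rows violating the record
#' invariants are rejected and logged, never silently dropped: the
#' returned \linkS4class{GwasDataset} carries a rejection table with one
#' machine-readable reason per rejected row. Multi-character alleles
#' (indels, multi-allelics) are rejected; alleles are upper-cased.
#'
#' @param path file path to a delimited text file with a header row.
#' @param columnMap named character vector mapping standard field names
#'   to file column names, e.g. \code{c(snp_id = "SNP", beta = "b")}.
#'   Must cover at least snp_id, effect_allele, other_allele, beta, se,
#'   pval; chrom, pos, eaf and n are optional. Defaults to the identity
#'   mapping on the standard names.
#' @param traitId trait identifier (defaults to the file name).
#' @param traitType,nCase,nControl,label trait metadata, see
#'   \code{\link{GwasDataset}}.
#' @param sep field delimiter; NULL (default) auto-detects.
#' @return A \linkS4class{GwasDataset}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tA1\tA2\tb\tse\tp",
#'              "rs1\tA\tG\t0.1\t0.02\t1e-6"), tf)
#' ds <- readSummaryStats(tf, columnMap = c(snp_id = "SNP",
#'   effect_allele = "A1", other_allele = "A2", beta = "b",
#'   se = "se", pval = "p"), traitId = "demo")
#' @export
readSummaryStats <- function(path, columnMap = NULL, traitId = basename(path),
                             traitType = "continuous", nCase = NA_real_,
                             nControl = NA_real_, label = traitId,
                             sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detectDelimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE, quote = "\"")
  if (is.null(columnMap)) {
    columnMap <- structure(.STANDARD_COLS, names = .STANDARD_COLS)
    columnMap <- columnMap[columnMap %in% names(raw)]
  }
  needed <- .MANDATORY_COLS
  missing <- setdiff(needed, names(columnMap))
  if (length(missing))
    stop("columnMap must cover mandatory field(s): ",
         paste(missing, collapse = ", "))
  absent <- setdiff(unname(columnMap), names(raw))
  if (length(absent))
    stop("column(s) not found in file: ", paste(absent, collapse = ", "))
  df <- raw[, unname(columnMap), drop = FALSE]
  names(df) <- names(columnMap)
  GwasDataset(df, traitId = traitId, traitType = traitType, nCase = nCase,
              nControl = nControl, label = label)
}

.detectDelimiter <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(first, gregexpr("\t", first))),
              "," = lengths(regmatches(first, gregexpr(",", first))),
              " " = lengths(regmatches(first, gregexpr(" +", first))))
  names(counts) <- c("\t", ",", " ")
  if (all(counts == 0)) stop("cannot detect delimiter in ", path)
  names(counts)[which.max(counts)]
}

#' Read a pairwise LD table
#'
#' Loads the standard pairwise-LD layout (columns SNP_A, SNP_B, R2,
#' optionally BP_A/BP_B) produced by common LD tools into an
#' \linkS4class{LDSource}.
#'
#' @param path delimited text file with a header row.
#' @param panel reference-panel label recorded on the source.
#' @param sep delimiter; NULL auto-detects.
#' @return An \linkS4class{LDSource}.
#' @export
readLDTable <- function(path, panel = basename(path), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detectDelimiter(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  LDSource(tab, panel = panel)
}

#' Write an LD table
#' @param ld an \linkS4class{LDSource}.
#' @param path output path (tab-delimited).
#' @return invisibly, the path.
#' @export
writeLDTable <- function(ld, path) {
  keys <- strsplit(names(ld@r2), "\r", fixed = TRUE)
  tab <- data.frame(SNP_A = vapply(keys, `[`, "", 1L),
                    SNP_B = vapply(keys, `[`, "", 2L),
                    R2 = unname(ld@r2), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Fixed results-table schema mirroring the per-method OR(95%CI)/P layout
## of forward-MR report tables.
.RESULT_COLS <- c("exposure", "outcome", "method", "n_snp", "beta", "se",
                  "OR", "ci_low", "ci_high", "pval", "qval", "label")

#' Assemble a results table from estimates
#'
#' Builds one row per estimate in the deterministic column order
#' (exposure, outcome, method, n_snp, beta, se, OR, ci_low, ci_high,
#' pval, qval, label), stably sorted by (exposure, outcome, method).
#'
#' @param estimates list of \linkS4class{MREstimate}s.
#' @param exposure,outcome trait labels (recycled).
#' @param qval,label optional per-estimate q-values and classification
#'   labels (recycled; NA allowed).
#' @return data.frame in the standard schema.
#' @export
resultsTable <- function(estimates, exposure = "exposure",
                         outcome = "outcome", qval = NA_real_,
                         label = NA_character_) {
  if (is(estimates, "MREstimate")) estimates <- list(estimates)
  if (!length(estimates)) stop("results must be non-empty")
  n <- length(estimates)
  df <- data.frame(
    exposure = rep_len(exposure, n), outcome = rep_len(outcome, n),
    method = vapply(estimates, function(e) e@method, ""),
    n_snp = vapply(estimates, function(e) e@nSnp, 0L),
    beta = vapply(estimates, function(e) e@beta, 0),
    se = vapply(estimates, function(e) e@se, 0),
    OR = vapply(estimates, function(e) e@orValue, 0),
    ci_low = vapply(estimates, function(e) e@ciLow, 0),
    ci_high = vapply(estimates, function(e) e@ciHigh, 0),
    pval = vapply(estimates, function(e) e@pval, 0),
    qval = rep_len(qval, n), label = rep_len(label, n),
    stringsAsFactors = FALSE)
  df[order(df$exposure, df$outcome, df$method, method = "radix"), ,
     drop = FALSE]
}

#' Write a results table
#'
#' Serializes a results table (or a list of estimates) as tab-delimited
#' text at full stored precision, so that write-then-read reproduces the
#' values exactly. Rows are stably sorted by (exposure, outcome, method).
#'
#' @param results data.frame in the standard schema (see
#'   \code{\link{resultsTable}}), a \linkS4class{PipelineResult}, or a
#'   list of \linkS4class{MREstimate}s.
#' @param path output file path.
#' @param ... passed to \code{\link{resultsTable}} when \code{results} is
#'   a list of estimates.
#' @return invisibly, the path.
#' @export
writeResultsTable <- function(results, path, ...) {
  if (is(results, "PipelineResult")) results <- results@results
  if (!is.data.frame(results)) results <- resultsTable(results, ...)
  if (!nrow(results)) stop("results must be non-empty")
  keep <- intersect(c(.RESULT_COLS,
                      setdiff(names(results), .RESULT_COLS)),
                    names(results))
  results <- results[, keep, drop = FALSE]
  results <- results[order(results$exposure, results$outcome,
                           results$method, method = "radix"), ,
                     drop = FALSE]
  out <- results
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a results table written by writeResultsTable
#' @param path file path.
#' @return data.frame in the standard schema.
#' @export
readResultsTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", "nan"))
  for (col in intersect(c("n_snp"), names(df)))
    df[[col]] <- as.integer(df[[col]])
  df
}

#' Serialize a sensitivity report as JSON
#'
#' @param report a \linkS4class{SensitivityReport}.
#' @param path output path; NULL returns the JSON string.
#' @return the path (invisibly) or the JSON string.
#' @export
writeSensitivityJSON <- function(report, path = NULL) {
  obj <- list(
    cochran_q = list(Q = report@qIvw, df = report@qDf, pval = report@qPval),
    egger_intercept = as.list(report@eggerIntercept),
    presso = list(global_pval = report@pressoGlobalP,
                  outliers = report@pressoOutliers),
    leave_one_out = report@loo,
    meta = report@meta)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
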