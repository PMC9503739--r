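#' @include AllClasses.R
NULL

#' Write a spectra set to a delimited text file
#'
#' One row per spectrum: `id,label,` followed by the intensities; the
#' header row carries the wavenumbers (cm^-1) as column names.  Values are
#' serialized with 17 significant digits so that a read/write round trip
#' reproduces the doubles bit-exactly.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param path output file path.
#'
#' @return `path`, invisibly.
#' @seealso [readSpectra()]
#' @export
writeSpectra <- function(x, path) {
  stopifnot(methods::is(x, "SpectraSet"))
  X <- spectraMatrix(x)
  header <- paste(c("id", "label",
                    sprintf("%.17g", wavenumbers(x))), collapse = ",")
  lab <- spectraLabels(x)
  rows <- vapply(seq_len(nrow(X)), function(i)
    paste(c(rownames(X)[i], lab[i],
            sprintf("%.17g", X[i, ])), collapse = ","),
    character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a spectra set from a delimited text file
#'
#' Expects the format written by [writeSpectra()]: a header row
#' `id,label,<w1>,...,<wp>` with strictly increasing numeric wavenumbers,
#' then one row per spectrum with a 0/1 label and `p` numeric
#' intensities.  Malformed content (ragged rows, non-numeric intensities,
#' labels outside 0/1) raises an error naming the offending row.
#'
#' @param path input file path.
#'
#' @return a \linkS4class{SpectraSet}.
#' @export
readSpectra <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("file must contain a header row and at least one spectrum")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "id" || header[2L] != "label")
    stop("header must be 'id,label,<wavenumbers...>'")
  w <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(w)) stop("non-numeric wavenumber in the header row")
  p <- length(w)
  n <- length(lines) - 1L
  ids <- character(n); labels <- integer(n)
  X <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    if (length(f) != p + 2L)
      stop(sprintf("row %d: expected %d fields, found %d", i, p + 2L,
                   length(f)))
    lab <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(lab) || !lab %in% c(0, 1))
      stop(sprintf("row %d: label must be 0 or 1", i))
    vals <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(vals))
      stop(sprintf("row %d: non-numeric intensity value", i))
    ids[i] <- f[1L]; labels[i] <- as.integer(lab); X[i, ] <- vals
  }
  SpectraSet(X, wavenumbers = w, labels = labels, ids = ids)
}

fmtCell <- function(v, digits) {
  if (is.na(v)) "" else formatC(round(v, digits), format = "f",
                                digits = digits)
}

mdTable <- function(mat, digits = 1L) {
  headers <- c("", colnames(mat))
  lines <- c(paste0("| ", paste(headers, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(headers)),
                               collapse = "|"), "|"))
  for (i in seq_len(nrow(mat))) {
    cells <- vapply(mat[i, ], fmtCell, character(1L), digits = digits)
    lines <- c(lines, paste0("| ", paste(c(rownames(mat)[i], cells),
                                         collapse = " | "), " |"))
  }
  lines
}

#' Write evaluation results to JSON and markdown reports
#'
#' Serializes the output of [evaluateJoint()] as a machine-readable JSON
#' document and as a human-readable markdown report: optimal thresholds
#' and AUC per method, the averaged percentage confusion matrices, Cohen's
#' kappa (2 decimals), and the joint outcome / correctness tables with
#' structurally impossible cells left blank.  Rerunning with identical
#' results produces byte-identical files.
#'
#' @param results list from [evaluateJoint()].
#' @param path stem for the output files; `<path>.json` and `<path>.md`
#'   are written.
#'
#' @return character vector of the two file paths, invisibly.
#' @export
writeReport <- function(results, path) {
  stopifnot(all(c("local", "global", "kappa", "joint") %in% names(results)))
  jsonPath <- paste0(path, ".json")
  mdPath <- paste0(path, ".md")

  payload <- list(
    seed = results$local$seed,
    methods = list(
      local = list(optimalLambda = results$local$optimalParameter,
                   auc = results$local$auc,
                   youden = results$local$youdenAtOptimum,
                   confusionPercent = as.list(results$local$confusion),
                   kappa = unname(results$kappa["local"])),
      global = list(optimalTau = results$global$optimalParameter,
                    auc = results$global$auc,
                    youden = results$global$youdenAtOptimum,
                    confusionPercent = as.list(results$global$confusion),
                    kappa = unname(results$kappa["global"]))),
    joint = list(outcomeCrosstab = results$joint$outcomeCrosstab,
                 correctnessCrosstab = results$joint$correctnessCrosstab,
                 rates = results$joint$rates))
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  cm4 <- function(cv) {
    m <- matrix(cv$confusion[c("TP", "FP", "FN", "TN")], 2L, 2L,
                byrow = TRUE,
                dimnames = list(c("predicted positive", "predicted negative"),
                                c("positive (%)", "negative (%)")))
    m
  }
  md <- c(
    "# Classification report", "",
    sprintf("Cross-validation seed: %d", results$local$seed), "",
    "## Optimal tuning parameters and AUC", "",
    "| Method | Optimal parameter | AUC |", "|---|---|---|",
    sprintf("| local | lambda = %.2f | %.3f |",
            results$local$optimalParameter, results$local$auc),
    sprintf("| global | tau = %.2f | %.3f |",
            results$global$optimalParameter, results$global$auc), "",
    "## Averaged confusion matrix, local method (%)", "",
    mdTable(cm4(results$local)), "",
    "## Averaged confusion matrix, global method (%)", "",
    mdTable(cm4(results$global)), "",
    sprintf("Cohen's kappa: local %.2f, global %.2f",
            results$kappa["local"], results$kappa["global"]), "",
    "## Joint outcome cross-tab, local (rows) vs global (%)",
    "", "Blank cells are impossible outcome combinations.", "",
    mdTable(results$joint$outcomeCrosstab), "",
    "## Correct vs wrong predictions, local (rows) vs global (%)", "",
    mdTable(results$joint$correctnessCrosstab), "",
    sprintf(paste0("NPV %.1f%%, PPV %.1f%%, joint accuracy %.1f%%, ",
                   "disagreement %.1f%%, wrong joint negatives %.1f%%"),
            results$joint$rates$npv, results$joint$rates$ppv,
            results$joint$rates$jointAccuracy,
            results$joint$rates$disagreementRate,
            results$joint$rates$wrongNegativeRate))
  writeLines(md, mdPath)
  invisible(c(jsonPath, mdPath))
}
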