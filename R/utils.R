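## internal helpers: logging and TSV plumbing shared by the io layer

xcLog <- function(..., verbose = getOption("xconcord.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[xconcord] ", ...)
  invisible(NULL)
}

#' @importFrom utils read.delim write.table
readTsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

writeTsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

## 6 significant digits for on-disk numeric matrices
fmtNum <- function(x) signif(x, 6)

stopFmt <- function(...) stop(..., call. = FALSE)
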