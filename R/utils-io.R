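#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.strip_gz <- function(path) sub("\\.gz$", "", path)

# Delimiter from file extension; `.gz` suffix is transparent.
.guess_delim <- function(path) {
  ext <- tolower(tools::file_ext(.strip_gz(path)))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", "\t")
}

# Fail early on ragged files, naming the first offending line.
.check_rectangular <- function(path, sep) {
  cf <- tryCatch(
    utils::count.fields(path, sep = sep, quote = "\"", comment.char = ""),
    error = function(e) integer()
  )
  cf <- cf[!is.na(cf)]
  if (length(cf) > 1L && length(unique(cf)) > 1L) {
    bad <- which(cf != cf[1L])[1L]
    stop(sprintf("malformed delimited file '%s': line %d has %d fields, expected %d",
                 path, bad, cf[bad], cf[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a delimited table with delimiter auto-detection
#'
#' CSV and TSV are detected from the file extension (`.csv` = comma,
#' `.tsv`/`.txt` = tab); gzip-compressed files are read transparently via
#' their `.gz` suffix. Ragged files raise an error naming the first bad line.
#'
#' @param path File path.
#' @param delimiter Optional explicit delimiter overriding auto-detection.
#' @param header Logical; does the first row hold column names?
#' @return A data frame (zero rows and columns for an empty file).
#' @export
read_delim_auto <- function(path, delimiter = NULL, header = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  sep <- delimiter %||% .guess_delim(path)
  .check_rectangular(path, sep)
  tryCatch(
    utils::read.table(path, sep = sep, header = header, stringsAsFactors = FALSE,
                      check.names = FALSE, quote = "\"", comment.char = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame()
      } else {
        stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
             call. = FALSE)
      }
    }
  )
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic substream seeds so that adding one consumer of randomness
# does not perturb the draws of another. Kept below 2^31.
.substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
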