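#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (0.05 -> 0.1),
#' the convention used when reporting category percentages to one decimal.
#' Base `round()` rounds ties to even, which would report 10.25% as 10.2%.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Write a data.frame as TSV preceded by "# key = value" metadata comment lines.
write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s = %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x)) {
    rows <- do.call(paste, c(lapply(x, function(col) {
      if (is.double(col)) format(col, trim = TRUE, scientific = FALSE, digits = 15)
      else as.character(col)
    }), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t", header = TRUE)
}
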