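#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor kruskal.test loess median optimize p.adjust predict
#'   quantile rbinom rexp rnorm rpois runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL

## internal convention: coordinates are 0-based half-open; GFF/VCF dialects are
## converted at the I/O boundary only.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)

#' Parse a samtools-style region string
#'
#' @param region A string `"contig"` or `"contig:start-end"` with 1-based
#'   inclusive coordinates, or `NULL`.
#' @return `NULL`, or a list with `contig`, `start`, `end` (1-based inclusive;
#'   `start`/`end` are `NA` when the whole contig is meant).
#' @keywords internal
parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  stopifnot(is.character(region), length(region) == 1L)
  if (!grepl(":", region, fixed = TRUE)) {
    return(list(contig = region, start = NA_real_, end = NA_real_))
  }
  contig <- sub(":.*$", "", region)
  span <- sub("^[^:]*:", "", region)
  parts <- strsplit(span, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stopf("malformed region string: %s", region)
  start <- suppressWarnings(as.numeric(gsub(",", "", parts[1L])))
  end <- suppressWarnings(as.numeric(gsub(",", "", parts[2L])))
  if (is.na(start) || is.na(end) || start > end) {
    stopf("malformed region string: %s", region)
  }
  list(contig = contig, start = start, end = end)
}

## deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
## integer whatever the user passes.
derive_seed <- function(seed, salt) {
  ## double arithmetic is exact here and avoids 32-bit integer overflow
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %%
               2147483629)
}

## atomic write helper: materialise in a temp file in the same directory, then
## rename over the destination.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
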