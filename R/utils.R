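## Internal helpers shared across modules.

#' @importFrom methods is new validObject slot
#' @importFrom stats cor dist hclust cutree p.adjust pt fisher.test rnbinom
#'   rbinom rnorm runif sd setNames binom.test
#' @importFrom utils read.delim write.table head
NULL

## Ordered treatment groups: L0/L4/L8 are low-birth-weight piglets at 0%,
## 0.4% and 0.8% dietary tryptophan; N0 is the normal-birth-weight reference.
GROUP_LEVELS <- c("L0", "L4", "L8", "N0")
GROUP_DOSES <- c(L0 = 0, L4 = 0.4, L8 = 0.8, N0 = 0)

PROFILE_CATEGORIES <- c("increased_dose_effect", "sensitive_dose", "counter_effect")
EVENT_TYPES <- c("SE", "A5SS", "A3SS", "MXE", "RI")
CONSERVATION_SPECIES <- c("human", "mouse", "blue_whale", "dog", "horse", "sheep", "cow")

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL runs in the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer or NULL")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed so independent generators seeded from
## one master seed do not share a stream. Kept below 2^31 - 1.
childSeed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.integer(seed) * 2654435L + as.integer(offset) * 97L) %% .Machine$integer.max
}

## Stage-level INFO logging; silenced via options(doseTx.verbose = FALSE).
txInfo <- function(...) {
  if (isTRUE(getOption("doseTx.verbose", TRUE))) {
    message("[doseTx] ", sprintf(...))
  }
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Canonical table writer: UTF-8, tab-separated, '.' decimal, no quoting, no
## row names. Numeric formatting is R's default full-precision `as.character`,
## which is deterministic, so reruns at a fixed seed are byte-identical.
writeCanonicalTsv <- function(df, path) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8",
              na = "NA")
  invisible(path)
}

readCanonicalTsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
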