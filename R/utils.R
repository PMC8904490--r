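# Shared internal helpers: TSV I/O with provenance comments, deterministic
# hashing for config fingerprints and derived seeds, interval arithmetic.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## bp overlap of [s1,e1) with [s2,e2); vectorized
.overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

## Polynomial rolling hash mod (2^31 - 1). Exact in double arithmetic
## (intermediate products stay below 2^40). Used only for config
## fingerprints and derived seeds, not for security.
.hash_bytes <- function(bytes) {
  h <- 5381
  m <- 2147483647
  for (b in as.integer(bytes)) h <- (h * 257 + b) %% m
  h
}

.hash_string <- function(s) .hash_bytes(utf8ToInt(paste(s, collapse = "\r")))

#' Fingerprint an R object
#'
#' Deterministic hash of an arbitrary R object (via its serialized bytes),
#' used for configuration hashes in manifests and provenance lines.
#'
#' @param x any R object
#' @return hex string
#' @export
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", .hash_bytes(raw))
}

## Derive a per-unit seed from a global seed and identifying strings.
## Independent of execution order; always in [1, 2^31 - 2].
.derive_seed <- function(global_seed, ...) {
  h <- .hash_string(paste(c(as.character(global_seed), ...), collapse = "|"))
  as.integer(h %% 2147483646L + 1L)
}

.prov_line <- function(hash = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("regmir")), error = function(e) "0")
  if (is.null(hash)) sprintf("# regmir %s", v) else sprintf("# regmir %s config=%s", v, hash)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path, hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.prov_line(hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Run code with a local RNG state: saves/restores .Random.seed so library
## functions do not perturb the caller's stream.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

## genomic coordinates: plain integer text, never scientific notation
.as_coord <- function(x) {
  if (all(abs(x) < .Machine$integer.max)) as.integer(round(x)) else round(x)
}

.is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
.is_prob <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x > 0 && x < 1
.is_num <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
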