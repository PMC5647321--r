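# Internal helpers: seeded RNG scopes, stable string hashing, atomic file writes.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic 31-adic string hash modulo a Mersenne prime; independent of
# gene processing order, so per-gene RNG streams are stable across runs.
stable_hash <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a substream seed from a root seed and a string key (kept < 2^31 - 1).
stream_seed <- function(seed, key) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m + stable_hash(key)) %% m)
}

.write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("failed to write ", path)
  invisible(path)
}

.write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("failed to write ", path)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "")
}

.check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("`", name, "` must be a single number", call. = FALSE)
  if (if (strict) x <= lower else x < lower)
    stop("`", name, "` must be ", if (strict) "> " else ">= ", lower, call. = FALSE)
  invisible(x)
}
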