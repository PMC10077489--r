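#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and an index; stays inside the
# 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1009) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (strict_min && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

# Atomic file write: emit to a sibling temp file, then rename into place, so
# a failure mid-write never leaves a partial output.
atomic_write <- function(path, writer) {
  tmp <- tempfile(pattern = paste0(".", basename(path), "."),
                  tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not move temporary file onto '%s'", path)
  ok <- TRUE
  invisible(path)
}

# CSV with a single leading provenance comment line ("# key=value ...").
write_csv_prov <- function(df, path, provenance = NULL) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    if (!is.null(provenance)) {
      writeLines(paste0("# ", paste(names(provenance), unname(provenance),
                                    sep = "=", collapse = " ")), con)
    }
    utils::write.csv(df, con, row.names = FALSE)
  })
}

read_csv_prov <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
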